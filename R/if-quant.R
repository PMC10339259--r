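#' Marker-positive area fraction of an immunofluorescence image
#'
#' Median filtering removes shot noise, CLAHE flattens illumination
#' artifacts, and an automatic threshold (Otsu by default) separates
#' marker-positive from negative pixels; the result is the positive-pixel
#' fraction. Near-unimodal images (dynamic range below `min_range` after
#' preprocessing) cannot be meaningfully auto-thresholded and return fraction
#' 0 with `degenerate = TRUE`.
#'
#' @param image single-channel numeric matrix (any linear intensity scale).
#' @param median_radius_px half-width of the median filter (0 disables).
#' @param clahe_grid CLAHE tile count per side (0 disables CLAHE).
#' @param clahe_clip CLAHE clip limit.
#' @param method `"otsu"`, `"triangle"` or `"mean"`.
#' @param min_range minimum post-preprocessing dynamic range (on the
#'   normalized 0..1 scale) for thresholding to be attempted.
#' @return A list of class `area_fraction`: `fraction`, `threshold` (on the
#'   normalized scale), `degenerate`, `mask`, and the preprocessing record.
#' @export
area_fraction <- function(image, median_radius_px = 2L, clahe_grid = 8L,
                          clahe_clip = 2, method = c("otsu", "triangle", "mean"),
                          min_range = 0.1) {
  method <- match.arg(method)
  if (length(dim(image)) != 2L)
    stopf("`image` must be a single-channel matrix; split channels first")
  img <- image
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  if (median_radius_px > 0)
    img <- as.matrix(EBImage::medianFilter(EBImage::Image(img),
                                           size = median_radius_px))
  if (clahe_grid > 0)
    img <- as.matrix(EBImage::clahe(EBImage::Image(img), nx = clahe_grid,
                                    limit = clahe_clip))
  if (diff(range(img)) < min_range) {
    return(structure(list(fraction = 0, threshold = NA_real_, degenerate = TRUE,
                          mask = matrix(FALSE, nrow(img), ncol(img)),
                          preprocessing = list(median_radius_px = median_radius_px,
                                               clahe_grid = clahe_grid,
                                               clahe_clip = clahe_clip,
                                               method = method)),
                     class = "area_fraction"))
  }
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256),
    triangle = triangle_threshold(img),
    mean = mean(img))
  mask <- img > thr
  structure(list(fraction = mean(mask), threshold = thr, degenerate = FALSE,
                 mask = mask,
                 preprocessing = list(median_radius_px = median_radius_px,
                                      clahe_grid = clahe_grid,
                                      clahe_clip = clahe_clip, method = method)),
            class = "area_fraction")
}

# Triangle threshold on a 256-bin histogram: maximal distance between the
# histogram and the chord from its peak to its far tail.
triangle_threshold <- function(img) {
  h <- tabulate(pmin(pmax(floor((img - min(img)) / diff(range(img)) * 255) + 1L,
                          1L), 256L), nbins = 256L)
  pk <- which.max(h)
  tail_end <- max(which(h > 0))
  if (tail_end <= pk) tail_end <- 256L
  xs <- pk:tail_end
  # distance from (x, h[x]) to the chord (pk, h[pk]) -> (tail_end, h[tail_end])
  vx <- tail_end - pk; vy <- h[tail_end] - h[pk]
  d <- abs(vy * (xs - pk) - vx * (h[xs] - h[pk])) / sqrt(vx^2 + vy^2)
  cut <- xs[which.max(d)]
  min(img) + (cut - 0.5) / 256 * diff(range(img))
}

#' Detect crescent-shaped ridges in a fluorescence image
#'
#' Sequential denoising (Gaussian, median, then adaptive Wiener) followed by
#' Hessian-eigenvalue multiscale ridge enhancement (bright curvilinear
#' structures give a strongly negative principal curvature); the ridge
#' response, maximized over scales, is Otsu-thresholded and components
#' smaller than `min_size_px` are discarded.
#'
#' @param image single-channel numeric matrix.
#' @param scales_px ridge scales in pixels; pick scales near half the
#'   expected crescent stroke width (default `c(1, 2)` for ~2-4 px strokes;
#'   scales much wider than the stroke blur the response into a halo).
#' @param gaussian_sigma,median_size,wiener_size denoising kernel parameters.
#' @param min_size_px minimum connected-component size kept (px).
#' @param min_contrast minimum-signal guard: ratio of the denoised image's
#'   robust upper contrast (99.5th percentile minus median) to its MAD below
#'   which the image is treated as structure-free noise (empty mask).
#' @return A logical crescent mask.
#' @export
detect_crescents <- function(image, scales_px = c(1, 2), gaussian_sigma = 1,
                             median_size = 1L, wiener_size = 5L,
                             min_size_px = 10L, min_contrast = 6) {
  if (!length(scales_px)) stopf("`scales_px` must list at least one scale")
  if (length(dim(image)) != 2L) stopf("`image` must be a single-channel matrix")
  img <- image
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  if (gaussian_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = gaussian_sigma))
  if (median_size > 0)
    img <- as.matrix(EBImage::medianFilter(EBImage::Image(pmin(pmax(img, 0), 1)),
                                           size = median_size))
  if (wiener_size > 0) img <- wiener_filter(img, size = wiener_size)
  contrast <- (quantile(img, 0.995, names = FALSE) - median(img)) /
    max(stats::mad(img), .Machine$double.eps)
  if (contrast < min_contrast) return(matrix(FALSE, nrow(img), ncol(img)))
  resp <- ridge_response(img, scales_px)
  if (max(resp) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- EBImage::otsu(EBImage::Image(resp / max(resp)), range = c(0, 1),
                       levels = 256) * max(resp)
  mask <- resp > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- table(as.integer(lab)[as.integer(lab) > 0])
  keep <- as.integer(names(sizes)[sizes >= min_size_px])
  matrix(as.integer(lab) %in% keep, nrow(img), ncol(img))
}

#' Crescent density from a binary mask
#'
#' Each connected crescent is skeletonized to a single-pixel centerline whose
#' length is measured with sqrt(2)-weighted diagonal steps (naive pixel
#' counting underestimates diagonal runs). The density is
#' \eqn{D_C = \sum_i L_i / A} with \eqn{L_i} the length of crescent \eqn{i}
#' in um and \eqn{A} the field area in um^2.
#'
#' @param mask logical crescent mask.
#' @param pixel_size_um pixel pitch.
#' @param area_um2 field-of-view area in um^2 (> 0); defaults to the mask's
#'   own footprint.
#' @return A list of class `crescent_result`: `lengths_um` (per crescent),
#'   `total_length_um`, `n_crescents`, `area_um2`, `density_per_um`
#'   (\eqn{D_C}, um^-1), `skeleton`.
#' @export
crescent_density <- function(mask, pixel_size_um,
                             area_um2 = prod(dim(mask)) * pixel_size_um^2) {
  stopifnot(is.logical(mask))
  if (area_um2 <= 0) stopf("`area_um2` must be positive")
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask), ncol(mask))
  n <- max(lab)
  skel_all <- matrix(FALSE, nrow(mask), ncol(mask))
  lengths <- numeric(0)
  for (k in seq_len(n)) {
    comp <- lab == k
    sk <- skeletonize(comp)
    len <- skeleton_length_px(sk) * pixel_size_um
    if (len > 0) lengths <- c(lengths, len)
    skel_all <- skel_all | sk
  }
  structure(list(lengths_um = lengths, total_length_um = sum(lengths),
                 n_crescents = length(lengths), area_um2 = area_um2,
                 density_per_um = sum(lengths) / area_um2,
                 skeleton = skel_all),
            class = "crescent_result")
}

#' Average crescent density across fields of view
#'
#' The reported per-donor density is the unweighted mean of \eqn{D_C} over
#' all imaged fields.
#'
#' @param results list of `crescent_result` objects.
#' @return Mean density (um^-1).
#' @export
summarize_crescents <- function(results) {
  if (!length(results)) stopf("need at least one field of view")
  mean(vapply(results, `[[`, numeric(1), "density_per_um"))
}
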