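#' Random crescent arcs with known analytic lengths
#'
#' Draws `n` circular arcs, each of exact arc length `length_um`, at random
#' positions and orientations within the field (with margin so arcs stay
#' inside). Radii are sampled uniformly; the subtended angle is
#' `length_um / radius`, capped at `max_span_rad` (a crescent lines at most
#' about half of a cell boundary, so the default cap is a half circle; the
#' radius is raised where needed to respect it). Arcs belong to distinct
#' cells and must not touch: candidates closer than `min_sep_um` to an
#' already placed arc are rejected and redrawn.
#'
#' @param n number of arcs.
#' @param length_um arc length of each arc, in um.
#' @param field_size_um field extent (x, y) in um.
#' @param radius_um range of circle radii to sample (um).
#' @param max_span_rad largest subtended angle (radians).
#' @param min_sep_um minimum curve-to-curve separation between arcs.
#' @param seed RNG seed.
#' @return A list of arcs: `center` (x, y um), `radius_um`, `theta0_rad`,
#'   `span_rad`, `length_um`.
#' @export
crescent_arcs <- function(n, length_um = 20, field_size_um = c(100, 100),
                          radius_um = c(4, 10), max_span_rad = pi,
                          min_sep_um = 3, seed = 1L) {
  r_min <- max(radius_um[1], length_um / max_span_rad)
  r_max <- max(radius_um[2], r_min)
  with_seed(seed, {
    arcs <- list()
    placed_pts <- NULL
    for (i in seq_len(n)) {
      for (attempt in 1:200) {
        r <- runif(1, r_min, r_max)
        span <- length_um / r
        margin <- r + 2
        a <- list(center = c(runif(1, margin, field_size_um[1] - margin),
                             runif(1, margin, field_size_um[2] - margin)),
                  radius_um = r, theta0_rad = runif(1, 0, 2 * pi),
                  span_rad = span, length_um = length_um)
        pts <- sample_curve(a, step_um = 1)
        ok <- is.null(placed_pts) ||
          min(sqrt(outer(pts[, 1], placed_pts[, 1], "-")^2 +
                   outer(pts[, 2], placed_pts[, 2], "-")^2)) >= min_sep_um
        if (ok) break
      }
      if (!ok) warning("could not separate arc ", i, "; field may be crowded")
      arcs[[i]] <- a
      placed_pts <- rbind(placed_pts, pts)
    }
    arcs
  })
}

#' A straight stroke expressed as a segment "arc"
#'
#' @param from,to endpoints (x, y) in um.
#' @return A segment element usable in the arc list of
#'   [gen_crescent_image()]; its analytic length is the Euclidean distance.
#' @export
crescent_segment <- function(from, to) {
  list(from = as.numeric(from), to = as.numeric(to),
       length_um = sqrt(sum((to - from)^2)))
}

# Sample points (um) along an arc or segment at ~`step_um` spacing.
sample_curve <- function(a, step_um) {
  n <- max(2L, ceiling(a$length_um / step_um) + 1L)
  if (!is.null(a$from)) {
    s <- seq(0, 1, length.out = n)
    cbind(a$from[1] + s * (a$to[1] - a$from[1]),
          a$from[2] + s * (a$to[2] - a$from[2]))
  } else {
    th <- a$theta0_rad + seq(0, a$span_rad, length.out = n)
    cbind(a$center[1] + a$radius_um * cos(th),
          a$center[2] + a$radius_um * sin(th))
  }
}

#' Render curvilinear crescents onto a noisy background
#'
#' Each arc is stamped as an anti-aliased bright stroke with a Gaussian
#' cross-section; stroke pixels take the maximum over nearby curve samples so
#' overlapping strokes do not over-add. The manifest records the exact
#' analytic arc lengths.
#'
#' @param arcs list of arcs from [crescent_arcs()] / [crescent_segment()].
#' @param field_size_um field extent (x, y) in um.
#' @param pixel_size_um pixel pitch.
#' @param width_px full stroke width in pixels (>= 2).
#' @param peak stroke peak intensity (image is on a 0..1-ish scale).
#' @param noise_sd background Gaussian noise s.d.
#' @param seed RNG seed.
#' @return A list with `image` (numeric matrix `[y, x]`), `pixel_size_um`, and
#'   `manifest` (a [gt_manifest] with `lengths_um`, `total_length_um`,
#'   `area_um2`, `true_density_per_um`).
#' @export
gen_crescent_image <- function(arcs, field_size_um = c(100, 100),
                               pixel_size_um = 0.32, width_px = 3,
                               peak = 0.8, noise_sd = 0.05, seed = 1L) {
  if (width_px < 2) stopf("stroke width must be >= 2 px")
  nx <- round(field_size_um[1] / pixel_size_um)
  ny <- round(field_size_um[2] / pixel_size_um)
  img <- matrix(0, ny, nx)
  sigma_px <- width_px / 2.355  # FWHM = width
  w <- ceiling(3 * sigma_px)
  for (a in arcs) {
    pts <- sample_curve(a, step_um = pixel_size_um / 3)
    for (j in seq_len(nrow(pts))) {
      px <- pts[j, 1] / pixel_size_um + 0.5
      py <- pts[j, 2] / pixel_size_um + 0.5
      cols <- max(1, floor(px - w)):min(nx, ceiling(px + w))
      rws <- max(1, floor(py - w)):min(ny, ceiling(py + w))
      if (!length(cols) || !length(rws)) next
      g <- peak * outer(exp(-(rws - py)^2 / (2 * sigma_px^2)),
                        exp(-(cols - px)^2 / (2 * sigma_px^2)))
      img[rws, cols] <- pmax(img[rws, cols], g)
    }
  }
  stroke_mask <- img > peak * 0.5
  img <- img + with_seed(seed, matrix(rnorm(ny * nx, 0.1, noise_sd), ny, nx))
  img[img < 0] <- 0; img[img > 1] <- 1
  lengths <- vapply(arcs, function(a) a$length_um, numeric(1))
  area <- prod(field_size_um)
  manifest <- gt_manifest("crescents",
                          lengths_um = lengths,
                          total_length_um = sum(lengths),
                          area_um2 = area,
                          true_density_per_um = sum(lengths) / area,
                          stroke_mask = stroke_mask,
                          pixel_size_um = pixel_size_um, seed = seed)
  list(image = img, pixel_size_um = pixel_size_um, manifest = manifest)
}

#' Generate a marker image with an exact positive-area fraction
#'
#' A smooth Gaussian random field is thresholded at the quantile that yields
#' exactly the requested pixel fraction, producing blob-shaped positive
#' regions; positive and negative pixels then receive well-separated (bimodal)
#' intensities plus noise. The pre-noise fraction is exact by construction and
#' is recorded in the manifest.
#'
#' @param true_fraction target positive-pixel fraction in `[0, 1)`;
#'   `true_fraction = 1` is rejected as degenerate (no background class, so
#'   automatic thresholding is undefined).
#' @param field_size_px image extent (width, height) in px.
#' @param blob_scale_px Gaussian smoothing scale controlling blob size.
#' @param fg_level,bg_level mean intensities of the two classes (0..1 scale).
#' @param noise_sd additive Gaussian noise s.d.
#' @param seed RNG seed.
#' @return A list with `image` (matrix), `mask` (logical ground-truth mask)
#'   and `manifest` (with `true_fraction`).
#' @export
gen_marker_image <- function(true_fraction, field_size_px = c(256L, 256L),
                             blob_scale_px = 8, fg_level = 0.8, bg_level = 0.2,
                             noise_sd = 0.05, seed = 1L) {
  if (true_fraction < 0 || true_fraction > 1)
    stopf("`true_fraction` must be in [0, 1]")
  if (true_fraction >= 1)
    stopf("degenerate scene: fraction 1 leaves no background class to threshold against")
  nx <- field_size_px[1]; ny <- field_size_px[2]
  out <- with_seed(seed, {
    field <- matrix(rnorm(ny * nx), ny, nx)
    field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = blob_scale_px))
    n_pos <- round(true_fraction * ny * nx)
    mask <- matrix(FALSE, ny, nx)
    if (n_pos > 0)
      mask[order(field, decreasing = TRUE)[seq_len(n_pos)]] <- TRUE
    img <- ifelse(mask, fg_level, bg_level) + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
    list(img = img, mask = mask)
  })
  img <- out$img; img[img < 0] <- 0; img[img > 1] <- 1
  manifest <- gt_manifest("marker",
                          true_fraction = mean(out$mask),
                          field_size_px = c(nx, ny), seed = seed)
  list(image = img, mask = out$mask, manifest = manifest)
}
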