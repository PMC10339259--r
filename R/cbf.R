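#' Per-pixel motion map of a video
#'
#' Motion is revealed by the temporal variability of each pixel: the map is
#' the population standard deviation of every pixel's intensity over time.
#' Static pixels map to zero.
#'
#' @param video a [video_stack] with at least 2 frames.
#' @return A numeric matrix (same spatial shape as the video) of class
#'   `motion_map`, all values >= 0.
#' @export
motion_map <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  nt <- n_frames(video)
  if (nt < 2) stopf("motion map needs at least 2 frames")
  d <- dim(video$frames)
  m <- matrix(video$frames, d[1] * d[2], nt)
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu * mu
  v[v < 0] <- 0  # numeric guard
  structure(matrix(sqrt(v), d[1], d[2]), class = c("motion_map", "matrix"))
}

#' Segment the moving area of a motion map
#'
#' Otsu's threshold (256-bin histogram over the map's full range) separates
#' moving from static pixels. A minimum-motion floor guards against
#' segmenting pure noise: if the map's dynamic range is below `min_motion`,
#' or Otsu's threshold itself falls below the floor, the mask is empty (with
#' a warning in the former case).
#'
#' @param map a [motion_map] (any nonnegative matrix works).
#' @param min_motion absolute floor (intensity units) below which variation is
#'   treated as noise.
#' @return A logical matrix: `TRUE` where motion is detected.
#' @export
segment_motion <- function(map, min_motion = 1e-3) {
  map <- unclass(map)
  if (any(map < 0)) stopf("motion map must be nonnegative")
  rng <- range(map)
  if (diff(rng) <= min_motion) {
    warning("motion map is near-constant; returning empty mask")
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  scaled <- (map - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  thr_abs <- rng[1] + thr * diff(rng)
  map > max(thr_abs, min_motion)
}

#' Ciliary beat density
#'
#' The fraction of the field with detected motion: moving pixels divided by
#' all pixels.
#'
#' @param mask logical motion mask from [segment_motion()].
#' @return A fraction in `[0, 1]`.
#' @export
beat_density <- function(mask) {
  stopifnot(is.logical(mask))
  mean(mask)
}

#' Dominant beat frequency per pixel and per sample
#'
#' For each masked pixel the intensity trace is detrended (mean subtracted),
#' temporally smoothed (moving average of `smooth_frames` frames; 1 disables
#' smoothing), and Fourier transformed; the dominant frequency is the
#' magnitude-spectrum argmax within the physiological band
#' (`f_min_hz`, Nyquist). Pixels whose in-band spectral peak does not rise
#' above `peak_floor` times their total spectral energy are excluded
#' (a temporally flat pixel has no beat frequency). The per-pixel map is
#' averaged within 8-connected mask regions, and the sample value is the mean
#' over masked pixels.
#'
#' @param video a [video_stack].
#' @param mask logical motion mask.
#' @param f_min_hz lower band edge in Hz (default 2, excluding DC and drift).
#' @param smooth_frames moving-average window (frames).
#' @param peak_floor minimum in-band peak share of spectral energy for a
#'   pixel to count as oscillating.
#' @return A list of class `cbf_frequency`: `frequency_map` (NA outside the
#'   mask and for excluded pixels), `region_map` (integer region labels),
#'   `region_mean_hz` (named vector, mean frequency per region),
#'   `sample_mean_cbf_hz` (NA and `defined = FALSE` if the mask is empty),
#'   `defined`, `delta_f_hz` (FFT bin width).
#' @export
dominant_frequency <- function(video, mask, f_min_hz = 2, smooth_frames = 3L,
                               peak_floor = 0.05) {
  stopifnot(inherits(video, "video_stack"), is.logical(mask))
  nt <- n_frames(video)
  fs <- video$frame_rate_hz
  nyquist <- fs / 2
  if (f_min_hz >= nyquist)
    stopf("f_min_hz (%g) must be below Nyquist (%g Hz)", f_min_hz, nyquist)
  d <- dim(video$frames)
  fmap <- matrix(NA_real_, d[1], d[2])
  delta_f <- fs / nt
  idx <- which(mask)
  if (!length(idx)) {
    return(structure(list(frequency_map = fmap, region_map = matrix(0L, d[1], d[2]),
                          region_mean_hz = numeric(0),
                          sample_mean_cbf_hz = NA_real_, defined = FALSE,
                          delta_f_hz = delta_f),
                     class = "cbf_frequency"))
  }
  traces <- matrix(video$frames, d[1] * d[2], nt)[idx, , drop = FALSE]
  traces <- traces - rowMeans(traces)
  if (smooth_frames > 1) {
    kern <- rep(1 / smooth_frames, smooth_frames)
    traces <- t(apply(traces, 1, function(x)
      stats::filter(x, kern, sides = 2, circular = TRUE)))
  }
  spec <- Mod(mvfft(t(traces)))            # nt x npix, column per pixel
  freqs <- (seq_len(nt) - 1L) * delta_f
  band <- which(freqs > f_min_hz & freqs < nyquist)
  sub <- spec[band, , drop = FALSE]
  peak <- band[max.col(t(sub), ties.method = "first")]
  fpk <- freqs[peak]
  # exclusion of non-oscillating pixels: in-band peak must carry real energy
  tot <- colSums(spec[seq_len(floor(nt / 2)), , drop = FALSE])
  share <- sub[cbind(match(peak, band), seq_len(ncol(sub)))] / pmax(tot, .Machine$double.eps)
  fpk[share < peak_floor] <- NA_real_
  fmap[idx] <- fpk

  region_map <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                       d[1], d[2])
  reg <- region_map[idx]
  ok <- !is.na(fpk)
  region_mean <- if (any(ok)) tapply(fpk[ok], reg[ok], mean) else numeric(0)
  structure(list(frequency_map = fmap, region_map = region_map,
                 region_mean_hz = region_mean,
                 sample_mean_cbf_hz = if (any(ok)) mean(fpk[ok]) else NA_real_,
                 defined = any(ok), delta_f_hz = delta_f),
            class = "cbf_frequency")
}

#' Run the full CBF pipeline on one field of view
#'
#' Motion map, Otsu motion segmentation, beat density and dominant-frequency
#' extraction in one call.
#'
#' @inheritParams dominant_frequency
#' @param min_motion noise floor for [segment_motion()].
#' @return A list of class `cbf_result`: `motion_map`, `mask`, `beat_density`,
#'   and the fields of [dominant_frequency()].
#' @export
analyze_cbf <- function(video, f_min_hz = 2, smooth_frames = 3L,
                        min_motion = 1e-3) {
  mm <- motion_map(video)
  mask <- segment_motion(mm, min_motion = min_motion)
  freq <- dominant_frequency(video, mask, f_min_hz = f_min_hz,
                             smooth_frames = smooth_frames)
  structure(c(list(motion_map = mm, mask = mask, beat_density = beat_density(mask)),
              unclass(freq)),
            class = "cbf_result")
}

#' Average CBF and beat density across fields of view
#'
#' Per-sample summaries are unweighted means over the sample's movies.
#' A field with an empty motion mask contributes density 0 but is excluded
#' from the frequency mean (frequency is undefined without motion).
#'
#' @param results list of `cbf_result` objects (one per field of view).
#' @return A list with `sample_mean_cbf_hz`, `sample_mean_density`,
#'   `n_fields`, `n_fields_with_motion`.
#' @export
summarize_cbf <- function(results) {
  if (!length(results)) stopf("need at least one field of view")
  dens <- vapply(results, function(r) r$beat_density, numeric(1))
  cbf <- vapply(results, function(r) r$sample_mean_cbf_hz, numeric(1))
  def <- vapply(results, function(r) isTRUE(r$defined), logical(1))
  list(sample_mean_cbf_hz = if (any(def)) mean(cbf[def]) else NA_real_,
       sample_mean_density = mean(dens),
       n_fields = length(results), n_fields_with_motion = sum(def))
}
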