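#' Scene description for synthetic bead transport
#'
#' Describes a tracer-bead experiment combining two motion classes:
#' \emph{MCC beads} carried by directed mucociliary flow (per-bead speed drawn
#' from a normal distribution, direction given relative to the inlet axis,
#' small isotropic jitter), and \emph{background beads} undergoing Brownian
#' motion (per-axis step variance \eqn{2 D \Delta t}) plus a slow constant
#' drift. Defaults mirror typical acquisitions: ~1200 x 1200 um fields at 30
#' frames/s for 10 s; MCC speeds of order tens of um/s ("strong" flow);
#' a Brownian coefficient near the Stokes-Einstein value for a 1-um bead in
#' aqueous buffer (~0.4 um^2/s).
#'
#' @param field_size_um field extent (x, y) in um.
#' @param frame_rate_hz acquisition rate (Hz).
#' @param n_frames frames per movie.
#' @param n_mcc,n_background counts of directed and background beads.
#' @param mcc_direction_deg flow direction relative to the inlet axis
#'   (0 = toward inlet).
#' @param mcc_speed_um_s (mean, sd) of per-bead MCC speeds in um/s.
#' @param mcc_jitter_um_s s.d. of isotropic per-step velocity jitter on MCC
#'   beads (um/s).
#' @param bg_diffusion_um2_s Brownian diffusion coefficient D (um^2/s).
#' @param bg_drift_um_s drift velocity vector (x, y) in um/s.
#' @param min_track_frames shortest generated track, in frames.
#' @param inlet inlet convention passed to [channel_geometry()].
#' @param seed integer RNG seed; a fixed seed makes output bit-reproducible.
#' @return A `flow_scene` specification list.
#' @export
flow_scene <- function(field_size_um = c(1200, 1200), frame_rate_hz = 30,
                       n_frames = 300L, n_mcc = 50L, n_background = 50L,
                       mcc_direction_deg = 0, mcc_speed_um_s = c(20, 5),
                       mcc_jitter_um_s = 2, bg_diffusion_um2_s = 0.4,
                       bg_drift_um_s = c(0.5, 0), min_track_frames = 30L,
                       inlet = "-x", seed = 1L) {
  if (n_mcc < 0 || n_background < 0) stopf("bead counts must be >= 0")
  if (any(mcc_speed_um_s < 0) || bg_diffusion_um2_s < 0 || mcc_jitter_um_s < 0)
    stopf("speeds, jitter and diffusion must be >= 0")
  if (min_track_frames < 2 || min_track_frames > n_frames)
    stopf("`min_track_frames` must be in [2, n_frames]")
  structure(list(field_size_um = as.numeric(field_size_um),
                 frame_rate_hz = frame_rate_hz, n_frames = as.integer(n_frames),
                 n_mcc = as.integer(n_mcc), n_background = as.integer(n_background),
                 mcc_direction_deg = mcc_direction_deg,
                 mcc_speed_um_s = mcc_speed_um_s,
                 mcc_jitter_um_s = mcc_jitter_um_s,
                 bg_diffusion_um2_s = bg_diffusion_um2_s,
                 bg_drift_um_s = as.numeric(bg_drift_um_s),
                 min_track_frames = as.integer(min_track_frames),
                 inlet = inlet, seed = as.integer(seed)),
            class = "flow_scene")
}

#' Generate labelled synthetic bead trajectories
#'
#' MCC tracks advance each frame by
#' \eqn{v_i \Delta t \, \hat d(\theta) + } jitter; background tracks take
#' Brownian steps of per-axis variance \eqn{2 D \Delta t} plus
#' \eqn{\mathrm{drift} \cdot \Delta t}. Track durations are drawn uniformly
#' between `min_track_frames` and `n_frames`, start frames uniformly within
#' the movie, and start positions uniformly within the field (with a margin
#' for directed tracks so they do not immediately exit).
#'
#' @param scene a [flow_scene()].
#' @return A list with `tracks` (a [track_set]) and `manifest`
#'   (a [gt_manifest] with a per-track label table, `"mcc"` or
#'   `"background"`).
#' @export
gen_bead_tracks <- function(scene) {
  stopifnot(inherits(scene, "flow_scene"))
  geom <- channel_geometry(scene$field_size_um, scene$inlet)
  dt <- 1 / scene$frame_rate_hz
  n_tot <- scene$n_mcc + scene$n_background
  labels <- rep(c("mcc", "background"), c(scene$n_mcc, scene$n_background))
  dir_vec <- drop(direction_to_vector(scene$mcc_direction_deg, geom))

  out <- with_seed(scene$seed, {
    rows <- vector("list", n_tot)
    speeds <- numeric(n_tot)
    for (i in seq_len(n_tot)) {
      len <- if (scene$min_track_frames == scene$n_frames) scene$n_frames else
        sample(scene$min_track_frames:scene$n_frames, 1L)
      f0 <- if (len == scene$n_frames) 0L else sample(0:(scene$n_frames - len), 1L)
      is_mcc <- labels[i] == "mcc"
      if (is_mcc) {
        v <- max(0.1, rnorm(1, scene$mcc_speed_um_s[1], scene$mcc_speed_um_s[2]))
        speeds[i] <- v
        # keep directed tracks inside the field for their whole lifetime
        travel <- abs(dir_vec) * v * len * dt
        x0 <- runif(1, max(0, -dir_vec[1]) * travel[1],
                    scene$field_size_um[1] - max(0, dir_vec[1]) * travel[1])
        y0 <- runif(1, max(0, -dir_vec[2]) * travel[2],
                    scene$field_size_um[2] - max(0, dir_vec[2]) * travel[2])
        sx <- v * dt * dir_vec[1] + rnorm(len - 1, 0, scene$mcc_jitter_um_s * dt)
        sy <- v * dt * dir_vec[2] + rnorm(len - 1, 0, scene$mcc_jitter_um_s * dt)
      } else {
        speeds[i] <- NA_real_
        x0 <- runif(1, 0, scene$field_size_um[1])
        y0 <- runif(1, 0, scene$field_size_um[2])
        step_sd <- sqrt(2 * scene$bg_diffusion_um2_s * dt)
        sx <- rnorm(len - 1, scene$bg_drift_um_s[1] * dt, step_sd)
        sy <- rnorm(len - 1, scene$bg_drift_um_s[2] * dt, step_sd)
      }
      rows[[i]] <- data.frame(track_id = i,
                              frame = f0 + 0:(len - 1),
                              x_um = x0 + cumsum(c(0, sx)),
                              y_um = y0 + cumsum(c(0, sy)))
    }
    list(df = do.call(rbind, rows), speeds = speeds)
  })

  tracks <- track_set(out$df, frame_rate_hz = scene$frame_rate_hz,
                      field_size_um = scene$field_size_um)
  manifest <- gt_manifest("beads",
                          labels = data.frame(track_id = seq_len(n_tot),
                                              label = labels,
                                              true_speed_um_s = out$speeds),
                          mcc_direction_deg = scene$mcc_direction_deg,
                          field_size_um = scene$field_size_um,
                          frame_rate_hz = scene$frame_rate_hz,
                          seed = scene$seed)
  list(tracks = tracks, manifest = manifest)
}

#' Render bead trajectories into a fluorescence video
#'
#' Each bead is drawn as an isotropic Gaussian spot (the effective point
#' spread function) on a noisy baseline; intensities are clipped to the
#' 16-bit range. Enables end-to-end testing of spot detection and linking.
#'
#' @param tracks a [track_set] (coordinates in um).
#' @param pixel_size_um pixel pitch of the rendered video.
#' @param psf_sigma_px Gaussian spot sigma in pixels.
#' @param amplitude peak spot intensity above baseline.
#' @param baseline background level.
#' @param noise_sd additive Gaussian noise s.d.
#' @param max_spots_per_100x100_px density guard: mean spots per 100 x 100 px
#'   tile above which a warning about overlapping spots is emitted.
#' @param seed RNG seed for the noise field.
#' @return A [video_stack] spanning the track set's field of view.
#' @export
render_bead_video <- function(tracks, pixel_size_um = 2, psf_sigma_px = 1.5,
                              amplitude = 40000, baseline = 2000,
                              noise_sd = 800, max_spots_per_100x100_px = 25,
                              seed = 1L) {
  meta <- track_meta(tracks)
  field <- meta$field_size_um
  nx <- ceiling(field[1] / pixel_size_um)
  ny <- ceiling(field[2] / pixel_size_um)
  frames_idx <- sort(unique(tracks$frame))
  nt <- max(frames_idx) + 1L
  df <- as.data.frame(tracks)

  dens <- nrow(df) / nt / (nx * ny) * 1e4
  if (dens > max_spots_per_100x100_px)
    warning(sprintf(
      "spot density %.1f per 100x100 px exceeds limit %g; overlaps likely",
      dens, max_spots_per_100x100_px))

  w <- ceiling(4 * psf_sigma_px)
  arr <- with_seed(seed, array(rnorm(ny * nx * nt, baseline, noise_sd),
                               dim = c(ny, nx, nt)))
  for (r in seq_len(nrow(df))) {
    # pixel centre of pixel (row, col) is at ((col-0.5), (row-0.5)) * pitch
    px <- df$x_um[r] / pixel_size_um + 0.5
    py <- df$y_um[r] / pixel_size_um + 0.5
    cols <- max(1, floor(px - w)):min(nx, ceiling(px + w))
    rws <- max(1, floor(py - w)):min(ny, ceiling(py + w))
    if (!length(cols) || !length(rws)) next
    gx <- exp(-(cols - px)^2 / (2 * psf_sigma_px^2))
    gy <- exp(-(rws - py)^2 / (2 * psf_sigma_px^2))
    k <- df$frame[r] + 1L
    arr[rws, cols, k] <- arr[rws, cols, k] + amplitude * outer(gy, gx)
  }
  arr[arr < 0] <- 0
  arr[arr > 65535] <- 65535
  video_stack(arr, meta$frame_rate_hz, pixel_size_um)
}
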