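#' Main transport direction of each trajectory
#'
#' For every trajectory the angle between the channel axis and the line from
#' its start point to its end point, measured from the inlet direction
#' (0 deg = toward inlet, 180 deg = toward outlet), in (-180, 180].
#' Trajectories with exactly zero net displacement have no direction and are
#' excluded (their count is recorded).
#'
#' @param tracks a [track_set].
#' @param geom a [channel_geometry()].
#' @return A numeric vector of class `angle_set` (degrees), with attributes
#'   `n_excluded` and `track_id`.
#' @export
trajectory_angles <- function(tracks, geom) {
  parts <- split_tracks(tracks)
  if (!length(parts))
    return(structure(numeric(0), class = "angle_set", n_excluded = 0L,
                     track_id = integer(0)))
  ends <- do.call(rbind, lapply(parts, function(p) {
    n <- nrow(p)
    c(dx = p$x_um[n] - p$x_um[1], dy = p$y_um[n] - p$y_um[1])
  }))
  moving <- ends[, "dx"] != 0 | ends[, "dy"] != 0
  ang <- angle_from_displacement(ends[moving, "dx"], ends[moving, "dy"], geom)
  structure(ang, class = "angle_set",
            n_excluded = sum(!moving),
            track_id = as.integer(names(parts))[moving])
}

#' Polar order parameter of a set of transport directions
#'
#' The average unit vector over trajectories,
#' \eqn{\hat u = \langle [\sin\theta_i, \cos\theta_i] \rangle}, dotted with
#' the unit vector \eqn{\hat n} pointing toward the channel inlet:
#' \eqn{PO = \hat u \cdot \hat n}. With angles measured from the inlet axis
#' this equals \eqn{\langle \cos\theta_i \rangle}. PO ranges over [-1, 1]:
#' 1 means all flow toward the inlet, -1 toward the outlet, and values near 0
#' indicate isotropic or wall-bound (perpendicular) flow.
#'
#' @param angles numeric vector of trajectory angles in degrees (0 = inlet),
#'   e.g. an `angle_set` from [trajectory_angles()].
#' @return The PO, a dimensionless scalar in [-1, 1]; `NA` (with a warning)
#'   for an empty angle set.
#' @export
polar_order <- function(angles) {
  if (!length(angles)) {
    warning("empty angle set: polar order undefined")
    return(NA_real_)
  }
  th <- deg2rad(as.numeric(angles))
  # u_hat in the (perpendicular, inlet) basis; n_hat is (0, 1) in that basis
  u_hat <- c(mean(sin(th)), mean(cos(th)))
  sum(u_hat * c(0, 1))
}

#' Histogram of transport directions
#'
#' Equal-width bins over (-180, 180]; one count per trajectory, so counts sum
#' to the number of angles.
#'
#' @param angles angle vector in degrees.
#' @param n_bins number of bins (>= 4).
#' @return A list with `breaks` (length `n_bins + 1`), `counts`, `mids`.
#' @export
angle_histogram <- function(angles, n_bins = 36L) {
  if (n_bins < 4) stopf("need at least 4 bins")
  breaks <- seq(-180, 180, length.out = n_bins + 1L)
  a <- wrap_angle_deg(as.numeric(angles))
  counts <- tabulate(findInterval(a, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE), nbins = n_bins)
  list(breaks = breaks, counts = counts,
       mids = (head(breaks, -1) + breaks[-1]) / 2)
}

#' Eulerian velocity field from Lagrangian bead tracks
#'
#' Each per-step velocity (displacement x frame rate) is deposited into the
#' square grid cell containing the step's midpoint; every cell averages the
#' u (x) and v (y) components of all observations falling in it over time,
#' since several beads may pass the same location. Cells with at least one
#' observation form the active mask.
#'
#' @param tracks a [track_set].
#' @param grid_um grid spacing in um (> 0); default 20.
#' @return A `velocity_field`: matrices `u`, `v`, `speed` (um/s, `NA` where
#'   inactive), `n_obs`, logical `active`, plus `grid_um` and `field_size_um`.
#' @export
velocity_field <- function(tracks, grid_um = 20) {
  if (grid_um <= 0) stopf("`grid_um` must be positive")
  meta <- track_meta(tracks)
  field <- meta$field_size_um
  nxc <- max(1L, ceiling(field[1] / grid_um))
  nyc <- max(1L, ceiling(field[2] / grid_um))
  u <- v <- matrix(0, nyc, nxc)
  nob <- matrix(0L, nyc, nxc)
  df <- as.data.frame(tracks)
  if (nrow(df)) {
    same <- c(diff(df$track_id) == 0, FALSE)
    i0 <- which(same)
    dxs <- df$x_um[i0 + 1L] - df$x_um[i0]
    dys <- df$y_um[i0 + 1L] - df$y_um[i0]
    dtf <- df$frame[i0 + 1L] - df$frame[i0]
    mx <- (df$x_um[i0] + df$x_um[i0 + 1L]) / 2
    my <- (df$y_um[i0] + df$y_um[i0 + 1L]) / 2
    cx <- pmin(pmax(ceiling(mx / grid_um), 1L), nxc)
    cy <- pmin(pmax(ceiling(my / grid_um), 1L), nyc)
    cell <- (cx - 1L) * nyc + cy
    vu <- dxs / dtf * meta$frame_rate_hz
    vv <- dys / dtf * meta$frame_rate_hz
    su <- tapply(vu, cell, sum); sv <- tapply(vv, cell, sum)
    cnt <- tapply(vu, cell, length)
    idx <- as.integer(names(cnt))
    nob[idx] <- as.integer(cnt)
    u[idx] <- su / cnt
    v[idx] <- sv / cnt
  }
  active <- nob > 0L
  u[!active] <- NA_real_; v[!active] <- NA_real_
  structure(list(u = u, v = v, speed = sqrt(u^2 + v^2), n_obs = nob,
                 active = active, grid_um = grid_um, field_size_um = field),
            class = "velocity_field")
}

#' MCC coverage from the active-flow area
#'
#' The coherent area with measurable transport, \eqn{A_{MCC}}, is estimated
#' from the active grid cells by closing the rasterized cell set with a disk
#' of radius `alpha_um` (a concave-hull construction at characteristic radius
#' alpha: gaps narrower than the disk are absorbed into the coherent area,
#' isolated cells keep only their own footprint). Coverage is
#' \eqn{C_{MCC} = A_{MCC} / A_{Total}}, clipped to [0, 1]. Fewer than 3
#' active cells yield \eqn{A_{MCC} = 0}.
#'
#' @param field a [velocity_field()].
#' @param alpha_um disk radius in um; default 2 x the grid spacing.
#' @param geom a [channel_geometry()] supplying \eqn{A_{Total}}.
#' @return A list with `c_mcc`, `a_mcc_um2`, `a_total_um2`, `n_active`.
#' @export
mcc_coverage <- function(field, alpha_um = 2 * field$grid_um, geom) {
  if (geom$area_um2 <= 0) stopf("total area must be positive")
  n_active <- sum(field$active)
  if (n_active < 3)
    return(list(c_mcc = 0, a_mcc_um2 = 0, a_total_um2 = geom$area_um2,
                n_active = n_active))
  r_px <- max(1L, round(alpha_um / field$grid_um))
  pad <- r_px + 1L
  m <- matrix(0, nrow(field$active) + 2 * pad, ncol(field$active) + 2 * pad)
  m[pad + seq_len(nrow(field$active)), pad + seq_len(ncol(field$active))] <-
    field$active * 1
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  closed <- as.matrix(EBImage::closing(EBImage::Image(m), brush))
  closed <- closed[pad + seq_len(nrow(field$active)),
                   pad + seq_len(ncol(field$active))]
  a_mcc <- sum(closed > 0) * field$grid_um^2
  list(c_mcc = min(1, a_mcc / geom$area_um2), a_mcc_um2 = a_mcc,
       a_total_um2 = geom$area_um2, n_active = n_active)
}

#' Area-averaged transport speed
#'
#' The mean flow magnitude over active cells, weighted down by the covered
#' surface fraction: \eqn{\bar M = C_{MCC} \langle |U| \rangle}. Zero when no
#' cell is active. By construction \eqn{\bar M \le \langle |U| \rangle}, with
#' equality only at full coverage.
#'
#' @param field a [velocity_field()].
#' @param c_mcc coverage computed from the same field ([mcc_coverage()]).
#' @return A list with `m_bar_um_s`, `mean_speed_um_s`.
#' @export
area_avg_speed <- function(field, c_mcc) {
  if (!sum(field$active))
    return(list(m_bar_um_s = 0, mean_speed_um_s = 0))
  mean_speed <- mean(field$speed[field$active])
  list(m_bar_um_s = c_mcc * mean_speed, mean_speed_um_s = mean_speed)
}

#' All MCC statistics for one movie
#'
#' @param tracks a (background-filtered) [track_set].
#' @param geom a [channel_geometry()].
#' @param grid_um velocity-field grid spacing (um).
#' @param alpha_um coverage disk radius (um).
#' @param n_bins angle-histogram bins.
#' @return An `mcc_stats` list: `po`, `c_mcc`, `m_bar_um_s`,
#'   `mean_speed_um_s`, `histogram`, `angles`, `n_trajectories`,
#'   `field_area_um2`, `velocity_field`.
#' @export
mcc_stats <- function(tracks, geom, grid_um = 20, alpha_um = 2 * grid_um,
                      n_bins = 36L) {
  angles <- trajectory_angles(tracks, geom)
  vf <- velocity_field(tracks, grid_um = grid_um)
  cov <- mcc_coverage(vf, alpha_um = alpha_um, geom = geom)
  spd <- area_avg_speed(vf, cov$c_mcc)
  structure(list(po = polar_order(angles), c_mcc = cov$c_mcc,
                 m_bar_um_s = spd$m_bar_um_s,
                 mean_speed_um_s = spd$mean_speed_um_s,
                 histogram = angle_histogram(angles, n_bins),
                 angles = as.numeric(angles),
                 n_trajectories = length(angles),
                 field_area_um2 = geom$area_um2,
                 velocity_field = vf),
            class = "mcc_stats")
}

#' Pool per-movie MCC statistics into one sample
#'
#' Trajectory angles from all movies are concatenated before recomputing PO
#' and the angle histogram (a trajectory-level pool); field-level metrics
#' (coverage, area-averaged speed) are averaged weighted by each movie's
#' field area.
#'
#' @param stats_list list of `mcc_stats`, one per movie.
#' @param n_bins histogram bins for the pooled angle set.
#' @return An `mcc_stats`-like list (without per-movie velocity fields).
#' @export
pool_sample <- function(stats_list, n_bins = 36L) {
  if (!length(stats_list)) stopf("need at least one movie")
  angles <- unlist(lapply(stats_list, `[[`, "angles"))
  w <- vapply(stats_list, `[[`, numeric(1), "field_area_um2")
  wm <- function(f) sum(vapply(stats_list, `[[`, numeric(1), f) * w) / sum(w)
  structure(list(po = polar_order(angles), c_mcc = wm("c_mcc"),
                 m_bar_um_s = wm("m_bar_um_s"),
                 mean_speed_um_s = wm("mean_speed_um_s"),
                 histogram = angle_histogram(angles, n_bins),
                 angles = angles, n_trajectories = length(angles),
                 field_area_um2 = sum(w), n_movies = length(stats_list)),
            class = "mcc_stats")
}

#' @export
print.mcc_stats <- function(x, ...) {
  cat(sprintf(
    "<mcc_stats> n = %d trajectories | PO = %.3f | C_MCC = %.3f | M_bar = %.2f um/s\n",
    x$n_trajectories, x$po, x$c_mcc, x$m_bar_um_s))
  invisible(x)
}
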