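#' Detect bead spots in a single frame
#'
#' Laplacian-of-Gaussian blob detection at scale `sigma_px`: the frame is
#' Gaussian-smoothed, the scale-normalized negative Laplacian is computed, and
#' strict local maxima of the response above `response_floor` are kept.
#' Centres are refined to sub-pixel precision by 1-D quadratic interpolation
#' of the response along x and y.
#'
#' @param frame numeric matrix `[y, x]` (one grayscale frame).
#' @param pixel_size_um pixel pitch, for reporting positions in um.
#' @param sigma_px LoG scale in pixels (match to spot radius / sqrt(2)).
#' @param response_floor absolute response threshold; `NULL` (default) uses a
#'   robust noise-derived floor of 8 x MAD of the response.
#' @param saturation_level intensity treated as sensor saturation; a frame
#'   with > 1\% saturated pixels triggers a warning (detection proceeds).
#' @return A data frame with columns `x_um`, `y_um`, `intensity` (response at
#'   the peak), one row per spot; zero rows for a blank frame.
#' @export
detect_spots <- function(frame, pixel_size_um, sigma_px = 1.5,
                         response_floor = NULL, saturation_level = 65535) {
  stopifnot(is.matrix(frame))
  if (mean(frame >= saturation_level) > 0.01)
    warning("frame appears saturated; spot positions may be biased")
  sm <- as.matrix(EBImage::gblur(EBImage::Image(frame), sigma = sigma_px))
  lap_kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- -sigma_px^2 * as.matrix(EBImage::filter2(EBImage::Image(sm), lap_kern))
  if (is.null(response_floor))
    response_floor <- 8 * stats::mad(resp)
  ny <- nrow(resp); nx <- ncol(resp)
  if (ny < 3 || nx < 3) return(data.frame(x_um = numeric(), y_um = numeric(),
                                          intensity = numeric()))
  c0 <- resp[2:(ny - 1), 2:(nx - 1)]
  is_max <- c0 > response_floor
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (c0 > resp[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (!nrow(pk)) return(data.frame(x_um = numeric(), y_um = numeric(),
                                   intensity = numeric()))
  rr <- pk[, 1] + 1L; cc <- pk[, 2] + 1L
  quad_off <- function(m, p, z) {  # sub-pixel offset along one axis
    num <- 0.5 * (m - p)
    den <- m - 2 * z + p
    off <- ifelse(abs(den) > .Machine$double.eps, num / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  z <- resp[cbind(rr, cc)]
  dx <- quad_off(resp[cbind(rr, cc - 1L)], resp[cbind(rr, cc + 1L)], z)
  dy <- quad_off(resp[cbind(rr - 1L, cc)], resp[cbind(rr + 1L, cc)], z)
  data.frame(x_um = (cc - 0.5 + dx) * pixel_size_um,
             y_um = (rr - 0.5 + dy) * pixel_size_um,
             intensity = z)
}

#' Link per-frame spots into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames: a link
#' is made when two spots are each other's nearest neighbour and closer than
#' `max_disp_um`. There is no gap closing: a missed detection terminates the
#' track and a new one starts. Ties are broken by smallest distance, then
#' lowest spot index, so linking is fully deterministic. Tracks shorter than
#' `min_track_len` nodes are discarded.
#'
#' @param spots_by_frame data frame with columns `frame` (0-based), `x_um`,
#'   `y_um` (e.g. row-bound output of [detect_spots()] with a `frame` column
#'   added).
#' @param max_disp_um maximum per-frame displacement for a link.
#' @param min_track_len minimum surviving track length (nodes).
#' @param frame_rate_hz,field_size_um acquisition metadata for the returned
#'   set.
#' @return A [track_set].
#' @export
link_trajectories <- function(spots_by_frame, max_disp_um, min_track_len = 5L,
                              frame_rate_hz, field_size_um) {
  df <- as.data.frame(spots_by_frame)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(df)))
  df <- df[order(df$frame), , drop = FALSE]
  if (!nrow(df))
    return(track_set(data.frame(track_id = integer(), frame = integer(),
                                x_um = numeric(), y_um = numeric()),
                     frame_rate_hz, field_size_um))
  frames <- split(df, df$frame)
  fidx <- as.integer(names(frames))
  track_of <- vector("list", length(frames))  # per frame: track id per spot
  next_id <- 1L
  track_of[[1]] <- seq_len(nrow(frames[[1]]))
  next_id <- nrow(frames[[1]]) + 1L
  for (k in seq_len(length(frames) - 1L)) {
    a <- frames[[k]]; b <- frames[[k + 1L]]
    ids_b <- rep(NA_integer_, nrow(b))
    if (fidx[k + 1L] == fidx[k] + 1L && nrow(a) && nrow(b)) {
      dmat <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
      nn_ab <- max.col(-dmat, ties.method = "first")      # per a: best b
      nn_ba <- max.col(-t(dmat), ties.method = "first")   # per b: best a
      for (i in seq_len(nrow(a))) {
        j <- nn_ab[i]
        if (nn_ba[j] == i && dmat[i, j] <= max_disp_um^2)
          ids_b[j] <- track_of[[k]][i]
      }
    }
    new <- which(is.na(ids_b))
    if (length(new)) {
      ids_b[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    track_of[[k + 1L]] <- ids_b
  }
  out <- do.call(rbind, lapply(seq_along(frames), function(k) {
    data.frame(track_id = track_of[[k]], frame = fidx[k],
               x_um = frames[[k]]$x_um, y_um = frames[[k]]$y_um)
  }))
  keep <- names(which(table(out$track_id) >= min_track_len))
  out <- out[out$track_id %in% as.integer(keep), , drop = FALSE]
  # renumber surviving tracks compactly and deterministically
  out$track_id <- match(out$track_id, sort(unique(out$track_id)))
  track_set(out, frame_rate_hz, field_size_um)
}

#' Detect and link beads across a whole video
#'
#' Convenience wrapper: [detect_spots()] on every frame, then
#' [link_trajectories()].
#'
#' @param video a [video_stack].
#' @inheritParams detect_spots
#' @inheritParams link_trajectories
#' @return A [track_set].
#' @export
track_beads <- function(video, sigma_px = 1.5, response_floor = NULL,
                        max_disp_um, min_track_len = 5L) {
  d <- dim(video$frames)
  spots <- do.call(rbind, lapply(seq_len(d[3]), function(k) {
    s <- detect_spots(video$frames[, , k], video$pixel_size_um,
                      sigma_px = sigma_px, response_floor = response_floor)
    if (nrow(s)) s$frame <- k - 1L
    s
  }))
  field <- c(d[2], d[1]) * video$pixel_size_um
  link_trajectories(spots, max_disp_um = max_disp_um,
                    min_track_len = min_track_len,
                    frame_rate_hz = video$frame_rate_hz, field_size_um = field)
}
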