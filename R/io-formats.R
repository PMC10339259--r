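#' Calibrated video stack
#'
#' A `video_stack` holds a grayscale frame sequence with its acquisition
#' calibration. Frames are stored as a 3-D numeric array indexed
#' `[row, col, frame]` (y, x, t); intensities are on an arbitrary linear scale.
#'
#' @param frames numeric 3-D array `[y, x, t]`, or a list of equally sized
#'   matrices.
#' @param frame_rate_hz acquisition frame rate in Hz (> 0).
#' @param pixel_size_um physical pixel pitch in micrometres (> 0).
#' @return An object of class `video_stack`: a list with elements `frames`,
#'   `frame_rate_hz`, `pixel_size_um`.
#' @examples
#' v <- video_stack(array(0, c(8, 8, 4)), frame_rate_hz = 200, pixel_size_um = 1/3)
#' dim(v$frames)
#' @export
video_stack <- function(frames, frame_rate_hz, pixel_size_um) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("`frames` must be a 3-D array [y, x, t]")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("`frame_rate_hz` must be a positive number")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("`pixel_size_um` must be a positive number")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um),
    class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d x %d px, %d frames @ %g Hz, %g um/px\n",
              d[2], d[1], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

n_frames <- function(video) dim(video$frames)[3]

#' Read a grayscale multi-page TIFF as a calibrated video stack
#'
#' TIFF files rarely carry frame-rate or pixel-size metadata in a portable
#' way, so calibration must be supplied explicitly; computation never proceeds
#' without it.
#'
#' @param path path to a grayscale (single-channel) multi-page TIFF.
#' @param frame_rate_hz,pixel_size_um acquisition calibration (required).
#' @return A [video_stack].
#' @export
read_video <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stopf("video file not found: %s", path)
  if (is.null(frame_rate_hz) || is.null(pixel_size_um))
    stopf("calibration missing for %s: supply `frame_rate_hz` and `pixel_size_um`",
          path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stopf("failed to read TIFF %s: %s",
                                              path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L)
    stopf("%s is multi-channel (RGB); extract a single channel first", path)
  video_stack(simplify2array(pages), frame_rate_hz, pixel_size_um)
}

#' Write a video stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` over the stack's full range (TIFF
#' stores normalized samples) and written losslessly at the requested depth.
#'
#' @param video a [video_stack].
#' @param path output path.
#' @param bits_per_sample 8 or 16.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path, bits_per_sample = 16L) {
  fr <- video$frames
  rng <- range(fr)
  if (diff(rng) > 0) fr <- (fr - rng[1]) / diff(rng)
  pages <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample),
                  compression = "deflate")
  invisible(path)
}

#' Trajectory sets
#'
#' A `track_set` is a data frame of bead positions with one row per
#' (trajectory, frame) observation and columns `track_id`, `frame`, `x_um`,
#' `y_um`, carrying acquisition metadata as attributes. Frames are 0-based and
#' strictly increasing within a track.
#'
#' @param df data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param field_size_um numeric pair, field of view extent (x, y) in um.
#' @return A `track_set` (data frame subclass).
#' @export
track_set <- function(df, frame_rate_hz, field_size_um) {
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("track table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$track_id, df$frame)
  if (anyDuplicated(key)) stopf("duplicate (track_id, frame) pairs in track table")
  dup <- unlist(tapply(df$frame, df$track_id, function(f) any(diff(f) <= 0)))
  if (any(dup)) stopf("frames not strictly increasing within track(s): %s",
                      paste(names(dup)[dup], collapse = ", "))
  structure(df, class = c("track_set", "data.frame"),
            frame_rate_hz = frame_rate_hz, field_size_um = field_size_um)
}

track_meta <- function(tracks) {
  list(frame_rate_hz = attr(tracks, "frame_rate_hz"),
       field_size_um = attr(tracks, "field_size_um"))
}

#' Read / write trajectory CSV
#'
#' The on-disk dialect is a plain comma-separated file with header
#' `track_id,frame,x_um,y_um`, coordinates in micrometres printed to 6
#' decimals (round trips are lossless at that precision). If `unit = "px"`
#' the coordinates are converted to micrometres at read time using
#' `pixel_size_um`.
#'
#' @param path CSV path.
#' @param frame_rate_hz,field_size_um acquisition metadata attached to the
#'   returned set.
#' @param unit `"um"` (default) or `"px"`.
#' @param pixel_size_um required when `unit = "px"`.
#' @return [read_tracks()] returns a [track_set]; [write_tracks()] returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path, frame_rate_hz, field_size_um,
                        unit = c("um", "px"), pixel_size_um = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stopf("track file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (unit == "px") {
    if (is.null(pixel_size_um))
      stopf("`pixel_size_um` required to convert px coordinates to um")
    if (all(c("x_px", "y_px") %in% names(df))) {
      df$x_um <- df$x_px * pixel_size_um
      df$y_um <- df$y_px * pixel_size_um
    } else {
      df$x_um <- df$x_um * pixel_size_um
      df$y_um <- df$y_um * pixel_size_um
    }
  }
  track_set(df, frame_rate_hz = frame_rate_hz, field_size_um = field_size_um)
}

#' @rdname read_tracks
#' @param tracks a [track_set].
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  df$x_um <- round(df$x_um, 6)
  df$y_um <- round(df$y_um, 6)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a track_set into per-track data frames (ordered by frame).
split_tracks <- function(tracks) {
  split(as.data.frame(tracks), tracks$track_id)
}

#' Assemble a provenance-stamped result table
#'
#' One row per sample/field with named metric columns; every metric carries a
#' unit string and the run's provenance (input identifier, config hash, seed)
#' so results are traceable to their origin.
#'
#' @param metrics named list of scalar metric values.
#' @param units named character vector, one unit string per metric (use `""`
#'   for dimensionless).
#' @param input input file or identifier.
#' @param config_hash hash of the run configuration (see [config_hash()]).
#' @param seed integer seed used, or `NA`.
#' @return A one-row data frame of class `result_table`.
#' @export
result_table <- function(metrics, units, input = NA_character_,
                         config_hash = NA_character_, seed = NA_integer_) {
  if (!all(names(metrics) %in% names(units)))
    stopf("every metric needs a unit string: missing %s",
          paste(setdiff(names(metrics), names(units)), collapse = ", "))
  df <- as.data.frame(metrics)
  df$input <- input
  df$config_hash <- config_hash
  df$seed <- seed
  structure(df, class = c("result_table", "data.frame"),
            units = units[names(metrics)])
}

#' Deterministic hash of a configuration list
#'
#' Serializes the config to canonical JSON and returns a short hex digest, so
#' identical configs always map to the same hash in provenance records.
#'
#' @param config a list of parameters (must be JSON-serializable).
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the serialized bytes; portable, dependency-free
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
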