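#' Kinematic feature vector of one trajectory
#'
#' The nine features used to separate true mucociliary transport from
#' background motion: mean, median and s.d. of per-step speed (um/s); total
#' path length and net Euclidean distance (um); directness (net / path, 0 for
#' a degenerate zero-path track); mean flow angle (deg, angle of the mean
#' displacement vector measured from the inlet axis); number of nodes; and
#' maximal acceleration (max |change in step speed| x frame rate, um/s^2).
#'
#' Features are invariant to rigid translation of the trajectory; only
#' `mean_flow_angle` depends on the channel-axis convention.
#'
#' @param traj data frame with `frame`, `x_um`, `y_um` for one track
#'   (>= 2 rows, frames increasing).
#' @param frame_rate_hz acquisition frame rate.
#' @param geom a [channel_geometry()] fixing the inlet axis.
#' @return A one-row data frame with the nine feature columns.
#' @export
extract_features <- function(traj, frame_rate_hz, geom) {
  n <- nrow(traj)
  if (n < 2) stopf("cannot featurize a trajectory with fewer than 2 nodes")
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  dframes <- diff(traj$frame)
  dt <- dframes / frame_rate_hz
  step <- sqrt(dx^2 + dy^2)
  speed <- step / dt
  path <- sum(step)
  euclid <- sqrt((traj$x_um[n] - traj$x_um[1])^2 + (traj$y_um[n] - traj$y_um[1])^2)
  accel <- if (length(speed) > 1) max(abs(diff(speed)) * frame_rate_hz) else 0
  data.frame(
    mean_speed = mean(speed),
    median_speed = median(speed),
    sd_speed = if (length(speed) > 1) sd(speed) else 0,
    path_length = path,
    euclid_dist = euclid,
    directness = if (path > 0) euclid / path else 0,
    mean_flow_angle = angle_from_displacement(mean(dx), mean(dy), geom),
    n_nodes = n,
    max_accel = accel)
}

#' Feature table for a whole trajectory set
#'
#' @param tracks a [track_set].
#' @param geom a [channel_geometry()]; defaults to the set's field with the
#'   inlet at -x.
#' @return A data frame, one row per track (`track_id` + nine features).
#' @export
feature_table <- function(tracks, geom = NULL) {
  meta <- track_meta(tracks)
  if (is.null(geom)) geom <- channel_geometry(meta$field_size_um)
  parts <- split_tracks(tracks)
  out <- do.call(rbind, lapply(parts, extract_features,
                               frame_rate_hz = meta$frame_rate_hz, geom = geom))
  out <- cbind(track_id = as.integer(names(parts)), out)
  rownames(out) <- NULL
  out
}

feature_names <- c("mean_speed", "median_speed", "sd_speed", "path_length",
                   "euclid_dist", "directness", "mean_flow_angle", "n_nodes",
                   "max_accel")

# deterministic stratified k-fold assignment
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Train the background-vs-MCC decision tree with cross-validation
#'
#' Fits a depth-limited classification tree on the nine kinematic features
#' and reports stratified k-fold cross-validated (held-out) accuracy — never
#' training accuracy. The final model is refit on all data. Deterministic
#' under a fixed seed.
#'
#' @param features data frame containing the nine feature columns.
#' @param labels factor or character vector (`"mcc"` / `"background"`), one
#'   per row.
#' @param n_folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param max_depth,min_leaf tree size limits.
#' @return A `traj_classifier` of kind `"tree"` with elements `fit` (rpart),
#'   `cv_accuracy`, `fold_accuracy`, `n_folds`, `seed`.
#' @export
train_tree <- function(features, labels, n_folds = 5L, seed = 1L,
                       max_depth = 5L, min_leaf = 5L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need at least 2 classes to train a classifier")
  if (length(labels) < n_folds) stopf("need at least n_folds observations")
  dat <- features[, feature_names, drop = FALSE]
  dat$.label <- labels
  ctrl <- rpart::rpart.control(maxdepth = max_depth, minbucket = min_leaf,
                               cp = 0, xval = 0)
  fold <- stratified_folds(labels, n_folds, seed)
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- dat[fold != f, , drop = FALSE]
    te <- dat[fold == f, , drop = FALSE]
    fit <- rpart::rpart(.label ~ ., data = tr, method = "class", control = ctrl)
    mean(predict(fit, te, type = "class") == te$.label)
  }, numeric(1))
  fit_all <- rpart::rpart(.label ~ ., data = dat, method = "class", control = ctrl)
  structure(list(kind = "tree", fit = fit_all, cv_accuracy = mean(acc),
                 fold_accuracy = acc, n_folds = n_folds, seed = seed),
            class = "traj_classifier")
}

#' Calibrate the simplified three-feature threshold rule
#'
#' The simplified classifier declares a trajectory background when its net
#' Euclidean distance, median speed, \emph{and} directness all fall below
#' their thresholds. Calibration grid-searches threshold triples over
#' within-data quantiles (up to each feature's maximum, so a feature that
#' does not discriminate in a given data set can be effectively neutralized)
#' and keeps the triple maximizing balanced accuracy on the provided
#' (calibration) set. When many triples tie at the optimum (the usual case
#' for well-separated classes), the component-wise median of the tying
#' thresholds is returned, placing each cut mid-gap rather than hugging
#' either class.
#'
#' @param features feature data frame (needs `euclid_dist`, `median_speed`,
#'   `directness`).
#' @param labels `"mcc"` / `"background"` per row.
#' @param n_grid candidate quantiles per feature.
#' @return A `traj_classifier` of kind `"threshold"` with `d_max_um`,
#'   `s_max_um_s`, `r_max`, and the calibration `balanced_accuracy`.
#' @export
calibrate_thresholds <- function(features, labels, n_grid = 15L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stopf("need both classes to calibrate thresholds")
  is_bg <- labels == "background"
  cand <- lapply(c("euclid_dist", "median_speed", "directness"), function(f) {
    unique(quantile(features[[f]], probs = seq(0.05, 1, length.out = n_grid),
                    names = FALSE))
  })
  grid <- expand.grid(d = cand[[1]], s = cand[[2]], r = cand[[3]])
  ba <- vapply(seq_len(nrow(grid)), function(i) {
    pred_bg <- features$euclid_dist < grid$d[i] &
      features$median_speed < grid$s[i] & features$directness < grid$r[i]
    (mean(pred_bg[is_bg]) + mean(!pred_bg[!is_bg])) / 2
  }, numeric(1))
  top <- grid[ba == max(ba), , drop = FALSE]
  pick <- c(d = median(top$d), s = median(top$s), r = median(top$r))
  pred_bg <- features$euclid_dist < pick["d"] &
    features$median_speed < pick["s"] & features$directness < pick["r"]
  ba_pick <- (mean(pred_bg[is_bg]) + mean(!pred_bg[!is_bg])) / 2
  if (ba_pick < max(ba)) {  # tie region not box-shaped: fall back to a vertex
    pick <- unlist(top[1, ])
    ba_pick <- max(ba)
  }
  structure(list(kind = "threshold",
                 d_max_um = unname(pick["d"]), s_max_um_s = unname(pick["s"]),
                 r_max = unname(pick["r"]), balanced_accuracy = ba_pick),
            class = "traj_classifier")
}

#' Classify trajectories with the three-feature threshold rule
#'
#' @param features feature data frame.
#' @param d_max_um,s_max_um_s,r_max thresholds on Euclidean distance, median
#'   speed and directness (all must be undershot for "background").
#' @return Character vector `"background"` / `"mcc"`.
#' @export
threshold_classify <- function(features, d_max_um, s_max_um_s, r_max) {
  if (any(c(d_max_um, s_max_um_s, r_max) <= 0)) stopf("thresholds must be > 0")
  bg <- features$euclid_dist < d_max_um & features$median_speed < s_max_um_s &
    features$directness < r_max
  ifelse(bg, "background", "mcc")
}

#' Predict labels with a fitted trajectory classifier
#'
#' @param object a `traj_classifier` from [train_tree()] or
#'   [calibrate_thresholds()].
#' @param features feature data frame.
#' @param ... unused.
#' @return Character vector of labels.
#' @export
predict.traj_classifier <- function(object, features, ...) {
  if (object$kind == "tree")
    as.character(predict(object$fit, features, type = "class"))
  else
    threshold_classify(features, object$d_max_um, object$s_max_um_s, object$r_max)
}

#' @export
print.traj_classifier <- function(x, ...) {
  if (x$kind == "tree")
    cat(sprintf("<traj_classifier: tree> %d-fold CV accuracy %.3f\n",
                x$n_folds, x$cv_accuracy))
  else
    cat(sprintf(
      "<traj_classifier: threshold> euclid < %.2f um & median speed < %.2f um/s & directness < %.3f -> background (cal. bal. acc. %.3f)\n",
      x$d_max_um, x$s_max_um_s, x$r_max, x$balanced_accuracy))
  invisible(x)
}

#' Remove background-flow trajectories from a set
#'
#' Applies a fitted classifier and returns only the trajectories labelled as
#' true transport signal, with their coordinates untouched. Counts of kept
#' and removed tracks are attached and reported via a message.
#'
#' @param tracks a [track_set].
#' @param model a `traj_classifier`.
#' @param geom optional [channel_geometry()] for feature extraction.
#' @param quiet suppress the tally message.
#' @return The filtered [track_set] with attributes `n_kept`, `n_removed`.
#' @export
filter_background <- function(tracks, model, geom = NULL, quiet = FALSE) {
  feats <- feature_table(tracks, geom = geom)
  lab <- predict(model, feats)
  keep_ids <- feats$track_id[lab != "background"]
  meta <- track_meta(tracks)
  out <- track_set(as.data.frame(tracks)[tracks$track_id %in% keep_ids, ,
                                         drop = FALSE],
                   meta$frame_rate_hz, meta$field_size_um)
  attr(out, "n_kept") <- length(keep_ids)
  attr(out, "n_removed") <- nrow(feats) - length(keep_ids)
  if (!quiet)
    message(sprintf("filter_background: kept %d, removed %d trajectories",
                    length(keep_ids), nrow(feats) - length(keep_ids)))
  out
}
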