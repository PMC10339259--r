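test_that("feature arithmetic matches hand computation on canonical tracks", {
  g <- channel_geometry(c(100, 100))
  # straight line, constant 1-um steps at 30 fps, 10 nodes
  straight <- track_set(data.frame(track_id = 1, frame = 0:9,
                                   x_um = seq(0, 9), y_um = 0),
                        30, c(100, 100))
  f <- extract_features(as.data.frame(straight), 30, g)
  expect_equal(f$mean_speed, 30)
  expect_equal(f$median_speed, 30)
  expect_equal(f$sd_speed, 0)
  expect_equal(f$path_length, 9)
  expect_equal(f$euclid_dist, 9)
  expect_equal(f$directness, 1)
  expect_equal(f$n_nodes, 10)
  expect_equal(f$max_accel, 0)
  expect_equal(f$mean_flow_angle, 180)  # +x is away from the -x inlet

  # closed square loop: euclid 0, directness 0
  sq <- data.frame(track_id = 1, frame = 0:4,
                   x_um = c(0, 1, 1, 0, 0), y_um = c(0, 0, 1, 1, 0))
  fs <- extract_features(sq, 30, g)
  expect_equal(fs$euclid_dist, 0)
  expect_equal(fs$directness, 0)

  # stationary 2-node track: degenerate convention
  st <- data.frame(track_id = 1, frame = 0:1, x_um = c(5, 5), y_um = c(5, 5))
  f0 <- extract_features(st, 30, g)
  expect_equal(f0$mean_speed, 0)
  expect_equal(f0$directness, 0)

  expect_error(extract_features(st[1, ], 30, g), "2 nodes")
})

test_that("features are translation invariant and bounded as documented", {
  b <- gen_bead_tracks(mixed_flow_scene(30L, seed = 13L))
  g <- channel_geometry(c(1200, 1200))
  f1 <- feature_table(b$tracks, g)
  shifted <- as.data.frame(b$tracks)
  shifted$x_um <- shifted$x_um + 37.5
  shifted$y_um <- shifted$y_um - 11.25
  f2 <- feature_table(track_set(shifted, 30, c(1200, 1200)), g)
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_true(all(f1$directness >= 0 & f1$directness <= 1))
  expect_true(all(f1$path_length >= f1$euclid_dist - 1e-9))
  expect_true(all(f1$mean_speed >= 0))
})

test_that("tree and threshold classifiers reach >= 95% held-out accuracy on the default benchmark", {
  bench <- gen_bead_tracks(mixed_flow_scene(300L, seed = 21L))
  calib <- gen_bead_tracks(mixed_flow_scene(300L, seed = 22L))
  g <- channel_geometry(c(1200, 1200))
  fb <- feature_table(bench$tracks, g)
  fc <- feature_table(calib$tracks, g)
  lab_b <- bench$manifest$labels$label[match(fb$track_id,
                                             bench$manifest$labels$track_id)]
  lab_c <- calib$manifest$labels$label[match(fc$track_id,
                                             calib$manifest$labels$track_id)]
  tree <- train_tree(fb, lab_b, seed = 23L)
  expect_gte(tree$cv_accuracy, 0.95)
  thr <- calibrate_thresholds(fc, lab_c)
  acc <- mean(predict(thr, fb) == lab_b)
  expect_gte(acc, 0.95)
  # the two strategies agree on >= 95% of tracks
  expect_gte(mean(predict(thr, fb) == predict(tree, fb)), 0.95)
})

test_that("CV accuracy is honest: ~0.5 under permuted labels, 1.0 for a separable rule", {
  b <- gen_bead_tracks(mixed_flow_scene(150L, seed = 31L))
  f <- feature_table(b$tracks)
  lab <- b$manifest$labels$label[match(f$track_id, b$manifest$labels$track_id)]
  perm <- with(list(), {set.seed(32); sample(lab)})
  null_tree <- train_tree(f, perm, seed = 33L)
  expect_lt(abs(null_tree$cv_accuracy - 0.5), 0.07)

  # labels perfectly determined by one feature threshold, all other
  # features uninformative: CV accuracy is exactly 1
  sep <- f
  for (nm in setdiff(names(f), "track_id")) sep[[nm]] <- 1
  sep$euclid_dist <- ifelse(lab == "mcc", 100, 1)
  expect_equal(train_tree(sep, lab, seed = 34L)$cv_accuracy, 1.0)
})

test_that("degenerate classifier inputs are rejected", {
  b <- gen_bead_tracks(mixed_flow_scene(10L, seed = 41L))
  f <- feature_table(b$tracks)
  expect_error(train_tree(f, rep("mcc", nrow(f))), "2 classes")
  expect_error(threshold_classify(f, -1, 5, 0.5), "> 0")
})

test_that("threshold rule labels canonical tracks as the field would expect", {
  fast <- data.frame(euclid_dist = 120, median_speed = 25, directness = 0.98)
  slow <- data.frame(euclid_dist = 3, median_speed = 4, directness = 0.1)
  expect_equal(threshold_classify(fast, 20, 10, 0.5), "mcc")
  expect_equal(threshold_classify(slow, 20, 10, 0.5), "background")
})

test_that("filter_background keeps coordinates intact and handles pure sets", {
  b <- gen_bead_tracks(mixed_flow_scene(50L, seed = 51L))
  g <- channel_geometry(c(1200, 1200))
  fc <- feature_table(b$tracks, g)
  lab <- b$manifest$labels$label[match(fc$track_id, b$manifest$labels$track_id)]
  thr <- calibrate_thresholds(fc, lab)

  kept <- filter_background(b$tracks, thr, geom = g, quiet = TRUE)
  expect_equal(attr(kept, "n_kept") + attr(kept, "n_removed"), 100)
  expect_equal(attr(kept, "n_kept"), 50, tolerance = 0.1)  # 50/50 mix
  # surviving coordinates untouched
  orig <- as.data.frame(b$tracks)
  kdf <- as.data.frame(kept)
  for (id in unique(kdf$track_id))
    expect_equal(unname(as.matrix(kdf[kdf$track_id == id, c("x_um", "y_um")])),
                 unname(as.matrix(orig[orig$track_id == id, c("x_um", "y_um")])))

  pure_mcc <- gen_bead_tracks(flow_scene(n_mcc = 20L, n_background = 0L,
                                         seed = 52L))
  k2 <- filter_background(pure_mcc$tracks, thr, geom = g, quiet = TRUE)
  expect_equal(attr(k2, "n_removed"), 0)
  pure_bg <- gen_bead_tracks(flow_scene(n_mcc = 0L, n_background = 20L,
                                        seed = 53L))
  k3 <- filter_background(pure_bg$tracks, thr, geom = g, quiet = TRUE)
  expect_equal(attr(k3, "n_kept"), 0)
  expect_equal(nrow(k3), 0)
})
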