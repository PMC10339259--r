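test_that("trajectory angles follow the inlet convention", {
  g <- channel_geometry(c(100, 100))  # inlet at -x
  tr <- tracks_from_displacements(list(
    c(50, 50, -1, 0),   # toward inlet
    c(50, 50, 1, 0),    # toward outlet
    c(50, 50, 0, 1),    # perpendicular
    c(50, 50, 0, -1),   # perpendicular, other side
    c(50, 50, 0, 0)))   # zero displacement -> excluded
  a <- trajectory_angles(tr, g)
  expect_equal(as.numeric(abs(a)), c(0, 180, 90, 90))
  expect_equal(attr(a, "n_excluded"), 1L)
})

test_that("polar order matches its closed forms and bounds", {
  expect_equal(polar_order(rep(0, 100)), 1)
  expect_equal(polar_order(rep(180, 100)), -1)
  expect_equal(polar_order(rep(c(90, -90), 50)), 0)
  expect_equal(polar_order(c(0, 90)), 0.5)
  set.seed(7)
  expect_lt(abs(polar_order(runif(1e4, -180, 180))), 0.03)
  expect_warning(p <- polar_order(numeric(0)), "undefined")
  expect_true(is.na(p))
  # always bounded, any input
  set.seed(8)
  for (k in 1:20)
    expect_lte(abs(polar_order(runif(50, -180, 180))), 1)
})

test_that("reversing the inlet vector negates PO exactly", {
  g1 <- channel_geometry(c(100, 100), inlet = "-x")
  g2 <- channel_geometry(c(100, 100), inlet = "+x")
  set.seed(9)
  tr <- tracks_at_angles(runif(200, -180, 180), g1)
  po1 <- polar_order(trajectory_angles(tr, g1))
  po2 <- polar_order(trajectory_angles(tr, g2))
  expect_equal(po2, -po1)
})

test_that("PO recovers the generator's mean-direction cosine on simulated flow", {
  for (dir in c(0, 45, 135)) {
    sc <- flow_scene(n_mcc = 400L, n_background = 0L, mcc_direction_deg = dir,
                     seed = 10L + dir)
    b <- gen_bead_tracks(sc)
    po <- polar_order(trajectory_angles(b$tracks,
                                        channel_geometry(sc$field_size_um)))
    expect_lt(abs(po - cos(dir * pi / 180)), 2 / sqrt(400) + 0.02)
  }
})

test_that("angle histograms conserve counts and fill uniformly", {
  h1 <- angle_histogram(rep(0, 25), n_bins = 36)
  expect_equal(sum(h1$counts), 25)
  expect_equal(sum(h1$counts > 0), 1)
  set.seed(11)
  a <- runif(36000, -180, 180)
  h <- angle_histogram(a, n_bins = 36)
  expect_equal(sum(h$counts), 36000)
  expect_true(all(abs(h$counts - 1000) < 5 * sqrt(1000)))  # multinomial sd
  expect_error(angle_histogram(a, n_bins = 2), "4 bins")
})

test_that("velocity field averages per-cell observations at step midpoints", {
  # single track, constant velocity (30, 15) um/s at 30 fps
  tr <- track_set(data.frame(track_id = 1, frame = 0:9,
                             x_um = seq(5, 14), y_um = seq(5, 9.5, by = 0.5)),
                  30, c(100, 100))
  vf <- velocity_field(tr, grid_um = 10)
  expect_equal(unique(vf$u[vf$active]), 30)
  expect_equal(unique(vf$v[vf$active]), 15)

  # two antiparallel passes: cell velocity 0 but cell active
  tr2 <- track_set(data.frame(track_id = c(1, 1, 2, 2), frame = c(0, 1, 0, 1),
                              x_um = c(4, 6, 6, 4), y_um = c(5, 5, 5, 5)),
                   30, c(10, 10))
  vf2 <- velocity_field(tr2, grid_um = 10)
  expect_equal(vf2$u[1, 1], 0)
  expect_true(vf2$active[1, 1])
  expect_equal(vf2$n_obs[1, 1], 2L)

  empty <- track_set(data.frame(track_id = integer(), frame = integer(),
                                x_um = numeric(), y_um = numeric()),
                     30, c(100, 100))
  expect_equal(sum(velocity_field(empty, 10)$active), 0)
})

test_that("coverage matches the grid-count oracle and its analytic extremes", {
  g <- channel_geometry(c(400, 400))
  # tracks tiling the whole field
  set.seed(12)
  full <- gen_bead_tracks(flow_scene(field_size_um = c(400, 400),
                                     n_mcc = 0L, n_background = 400L,
                                     bg_diffusion_um2_s = 30,
                                     n_frames = 80L, min_track_frames = 80L,
                                     seed = 13L))
  vf <- velocity_field(full$tracks, grid_um = 40)
  cov <- mcc_coverage(vf, geom = g)
  expect_equal(cov$c_mcc, 1, tolerance = 0.02)

  # active cells confined to the left half band
  half <- as.data.frame(full$tracks)
  half <- half[half$x_um < 200, ]
  keep <- names(which(table(half$track_id) >= 2))
  half <- half[half$track_id %in% as.integer(keep), ]
  vfh <- velocity_field(track_set(half, 30, c(400, 400)), grid_um = 40)
  vfh$active[, 6:10] <- FALSE; vfh$n_obs[, 6:10] <- 0L  # hard band edge
  covh <- mcc_coverage(vfh, geom = g)
  expect_equal(covh$c_mcc, 0.5, tolerance = 0.05)

  # brute-force grid-cell-count oracle within 10% (alpha = 2 x spacing)
  oracle <- sum(vfh$active) * 40^2 / g$area_um2
  expect_lt(abs(covh$c_mcc - oracle) / oracle, 0.10)

  # degenerate inputs
  empty <- velocity_field(track_set(data.frame(track_id = integer(),
                                               frame = integer(),
                                               x_um = numeric(),
                                               y_um = numeric()),
                                    30, c(400, 400)), 40)
  expect_equal(mcc_coverage(empty, geom = g)$c_mcc, 0)
})

test_that("area-averaged speed follows M = C_MCC <|U|> with its equality condition", {
  mkf <- function(speeds, active) {
    sp <- matrix(NA_real_, 2, 2); sp[active] <- speeds
    list(speed = sp, active = active, grid_um = 10)
  }
  act_full <- matrix(TRUE, 2, 2)
  f1 <- mkf(rep(10, 4), act_full)
  expect_equal(area_avg_speed(f1, 1)$m_bar_um_s, 10)
  expect_equal(area_avg_speed(f1, 0.5)$m_bar_um_s, 5)
  act_none <- matrix(FALSE, 2, 2)
  expect_equal(area_avg_speed(mkf(numeric(0), act_none), 0)$m_bar_um_s, 0)
  # M <= <|U|>, equality iff full coverage
  expect_lte(area_avg_speed(f1, 0.7)$m_bar_um_s,
             area_avg_speed(f1, 0.7)$mean_speed_um_s)
})

test_that("pooling concatenates angles and area-weights field metrics", {
  g <- channel_geometry(c(100, 100))
  s1 <- mcc_stats(tracks_at_angles(rep(0, 50), g), g)
  s2 <- mcc_stats(tracks_at_angles(rep(180, 50), g), g)
  pooled <- pool_sample(list(s1, s2))
  expect_equal(pooled$po, 0)
  expect_equal(pooled$n_trajectories, 100)
  expect_equal(sum(pooled$histogram$counts), 100)
  solo <- pool_sample(list(s1))
  expect_equal(solo$po, s1$po)
  expect_equal(solo$c_mcc, s1$c_mcc)
})

test_that("end-to-end: rendered video through tracking, filtering and stats recovers PO and coverage", {
  sc <- flow_scene(field_size_um = c(300, 300), n_frames = 80L, n_mcc = 30L,
                   n_background = 20L, min_track_frames = 80L,
                   mcc_speed_um_s = c(12, 3), seed = 61L)
  b <- gen_bead_tracks(sc)
  geom <- channel_geometry(c(300, 300))

  # ground truth restricted to true MCC tracks
  ids <- b$manifest$labels$track_id[b$manifest$labels$label == "mcc"]
  truth <- track_set(as.data.frame(b$tracks)[b$tracks$track_id %in% ids, ],
                     30, c(300, 300))
  st_truth <- mcc_stats(truth, geom, grid_um = 20)

  v <- render_bead_video(b$tracks, pixel_size_um = 2, seed = 62L)
  rec <- track_beads(v, max_disp_um = 6, min_track_len = 10)

  thr <- calibrate_on_rendered(seed = 63L)
  kept <- filter_background(rec, thr, geom = geom, quiet = TRUE)
  st <- mcc_stats(kept, geom, grid_um = 20)
  expect_lt(abs(st$po - st_truth$po), 0.05)
  expect_lt(abs(st$c_mcc - st_truth$c_mcc), 0.05)
})
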