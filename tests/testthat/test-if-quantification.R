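test_that("area fraction recovers generator truth across fractions", {
  for (frac in c(0.1, 0.3, 0.5)) {
    mk <- gen_marker_image(frac, c(192L, 192L), seed = round(100 * frac))
    af <- area_fraction(mk$image)
    expect_false(af$degenerate)
    expect_equal(af$fraction, mk$manifest$true_fraction, tolerance = 0.02)
  }
})

test_that("area fraction flags blank images and survives affine rescaling", {
  blank <- matrix(0.5, 64, 64)
  af <- area_fraction(blank)
  expect_true(af$degenerate)
  expect_equal(af$fraction, 0)

  mk <- gen_marker_image(0.3, c(128L, 128L), seed = 7L)
  a1 <- area_fraction(mk$image)
  a2 <- area_fraction(mk$image * 1000 + 50)
  expect_equal(a1$fraction, a2$fraction, tolerance = 0.01)

  expect_error(area_fraction(array(0.5, c(8, 8, 3))), "single-channel")
})

test_that("alternative auto-threshold methods stay close on bimodal input", {
  mk <- gen_marker_image(0.3, c(128L, 128L), seed = 8L)
  fo <- area_fraction(mk$image, method = "otsu")$fraction
  fm <- area_fraction(mk$image, method = "mean")$fraction
  ft <- area_fraction(mk$image, method = "triangle")$fraction
  expect_lt(abs(fm - fo), 0.05)
  expect_lt(abs(ft - fo), 0.05)
})

test_that("ridge detection finds crescents (Dice >= 0.7) but suppresses disks and noise", {
  arcs <- crescent_arcs(5, 20, c(100, 100), seed = 3L)
  ci <- gen_crescent_image(arcs, c(100, 100), pixel_size_um = 0.32, seed = 4L)
  mask <- detect_crescents(ci$image)
  truth <- ci$manifest$stroke_mask
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.7)

  set.seed(5)
  noise <- matrix(runif(150 * 150, 0, 0.2), 150, 150)
  expect_equal(sum(detect_crescents(noise)), 0)

  # a filled disk responds much less than an equal-intensity arc
  img <- matrix(0.1, 120, 120)
  yy <- row(img); xx <- col(img)
  img[(yy - 30)^2 + (xx - 30)^2 <= 15^2] <- 0.9  # disk, radius 15
  arc_img <- gen_crescent_image(list(list(center = c(70, 70), radius_um = 15,
                                          theta0_rad = 0, span_rad = 3,
                                          length_um = 45)),
                                c(120, 120), pixel_size_um = 1, peak = 0.9,
                                noise_sd = 0, seed = 6L)$image
  resp_disk <- mucoflow:::ridge_response(img, c(1, 2))
  resp_arc <- mucoflow:::ridge_response(arc_img, c(1, 2))
  # the flat disk interior (away from its edge, which is legitimately
  # curvature-bearing) must respond far less than the equal-intensity arc
  disk_core <- (yy - 30)^2 + (xx - 30)^2 <= 5^2
  expect_gt(max(resp_arc), 2 * max(resp_disk[disk_core]))

  expect_error(detect_crescents(ci$image, scales_px = numeric(0)), "scale")
})

test_that("crescent density follows D_C = sum(L_i)/A on analytic fixtures", {
  # one straight 100 um stroke over a field of view of A = 10^4 um^2
  # -> D_C = 0.01 per um (stroke kept interior so no border truncation)
  seg <- list(crescent_segment(c(10, 60), c(110, 60)))
  ci <- gen_crescent_image(seg, c(120, 120), pixel_size_um = 0.5,
                           noise_sd = 0.02, seed = 5L)
  res <- crescent_density(detect_crescents(ci$image), 0.5, 1e4)
  expect_equal(res$density_per_um, 0.01, tolerance = 0.05)

  # empty mask
  r0 <- crescent_density(matrix(FALSE, 50, 50), 0.5, 625)
  expect_equal(r0$density_per_um, 0)
  expect_equal(r0$n_crescents, 0)

  # five 20-um arcs: total length within 5%
  arcs <- crescent_arcs(5, 20, c(100, 100), seed = 3L)
  ci5 <- gen_crescent_image(arcs, c(100, 100), pixel_size_um = 0.32, seed = 4L)
  r5 <- crescent_density(detect_crescents(ci5$image), 0.32,
                         ci5$manifest$area_um2)
  # arcs may touch and merge into fewer components; the length total is
  # the quantity the density formula consumes
  expect_gte(r5$n_crescents, 3)
  expect_equal(r5$total_length_um, 100, tolerance = 0.05 * 100)
  expect_equal(r5$density_per_um, r5$total_length_um / r5$area_um2)
})

test_that("skeleton length of digitized straight segments stays within 5% of geometry", {
  mk_stroke <- function(x0, y0, x1, y1, w = 1.5, n = 300) {
    m <- matrix(FALSE, 100, 100)
    xs <- seq(x0, x1, length.out = n); ys <- seq(y0, y1, length.out = n)
    for (j in seq_len(n)) {
      rr <- max(1, floor(ys[j] - w)):min(100, ceiling(ys[j] + w))
      cc <- max(1, floor(xs[j] - w)):min(100, ceiling(xs[j] + w))
      m[rr, cc] <- m[rr, cc] |
        outer((rr - ys[j])^2, (cc - xs[j])^2, "+") <= w^2
    }
    m
  }
  cases <- list(c(10, 50, 90, 50), c(15, 15, 85, 85),
                c(10, 20, 90, 60), c(10, 40, 90, 73))
  for (v in cases) {
    true_len <- sqrt((v[3] - v[1])^2 + (v[4] - v[2])^2)
    est <- crescent_density(mk_stroke(v[1], v[2], v[3], v[4]), 1)$total_length_um
    expect_lt(abs(est - true_len) / true_len, 0.05)
  }
})

test_that("density scales inversely with area and field averaging is unweighted", {
  mask <- matrix(FALSE, 60, 60); mask[30, 10:50] <- TRUE
  d1 <- crescent_density(mask, 1, 3600)$density_per_um
  big <- matrix(FALSE, 120, 120); big[30, 10:50] <- TRUE
  d2 <- crescent_density(big, 1, 14400)$density_per_um
  expect_equal(d1 / d2, 4)

  mk <- function(d) structure(list(density_per_um = d), class = "crescent_result")
  expect_equal(summarize_crescents(list(mk(0.01), mk(0.03))), 0.02)
  expect_equal(summarize_crescents(list(mk(0.02))), 0.02)
  expect_equal(summarize_crescents(list(mk(0.03), mk(0.01))),
               summarize_crescents(list(mk(0.01), mk(0.03))))
})
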