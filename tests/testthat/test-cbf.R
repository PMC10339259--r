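test_that("motion map is the population temporal std-dev", {
  v <- video_stack(array(5, c(4, 4, 10)), 200, 1 / 3)
  expect_true(all(motion_map(v) == 0))

  alt <- array(0, c(2, 2, 8)); alt[1, 1, ] <- rep(c(0, 1), 4)
  expect_equal(motion_map(video_stack(alt, 200, 1))[1, 1], 0.5)

  # pure sinusoid over whole periods: std -> a / sqrt(2)
  tt <- (0:199) / 200
  sine <- array(rep(3 * sin(2 * pi * 10 * tt), each = 4), c(2, 2, 200))
  expect_equal(motion_map(video_stack(sine, 200, 1))[1, 1], 3 / sqrt(2),
               tolerance = 0.01)

  expect_error(motion_map(video_stack(array(0, c(2, 2, 1)), 200, 1)), "2 frames")
})

test_that("Otsu motion segmentation recovers the beating patch; noise floor guards empty scenes", {
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 128L))
  mask <- segment_motion(motion_map(gen$video))
  truth <- gen$manifest$label_map > 0
  # mask area within 2% of the analytic patch area
  expect_equal(mean(mask), mean(truth), tolerance = 0.02)
  expect_gt(sum(mask & truth) / sum(mask | truth), 0.9)  # spatial overlap
  expect_equal(beat_density(mask), mean(mask))  # identity

  flat <- matrix(1e-5 * runif(64), 8, 8)
  expect_warning(m0 <- segment_motion(flat, min_motion = 1e-3), "near-constant")
  expect_equal(sum(m0), 0)
})

test_that("beat density is invariant to intensity rescaling of the video", {
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 128L))
  d1 <- beat_density(segment_motion(motion_map(gen$video)))
  v2 <- video_stack(gen$video$frames * 7 + 11, 200, 1 / 3)
  d2 <- beat_density(segment_motion(motion_map(v2)))
  expect_equal(d1, d2)
})

test_that("dominant frequency recovers synthetic frequencies within one FFT bin", {
  # 8 Hz at 200 fps, 512 frames (expected value from the FFT oracle: the
  # magnitude-spectrum argmax of the generating sinusoid falls on bin 20,
  # i.e. 7.8125 Hz, within delta_f = 0.390625 Hz of the true 8 Hz)
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 512L, freq = 8))
  r <- analyze_cbf(gen$video)
  expect_lt(abs(r$sample_mean_cbf_hz - 8), 200 / 512 + 1e-9)

  # two patches at 5 and 12 Hz: per-region means match patch truth
  sc <- cilia_scene(field_size_px = c(96L, 96L), frame_rate_hz = 200,
                    n_frames = 256L,
                    patches = list(
                      list(center = c(25, 25), radius_px = 10,
                           frequency_hz = 5, phase_rad = 0, amplitude = 20),
                      list(center = c(70, 70), radius_px = 10,
                           frequency_hz = 12, phase_rad = 1, amplitude = 20)),
                    noise_sd = 2, seed = 9L)
  gen2 <- gen_cilia_video(sc)
  r2 <- analyze_cbf(gen2$video)
  truth <- gen2$manifest$patches
  df <- 200 / 256
  # match each labelled region to the nearest true frequency
  for (f in sort(r2$region_mean_hz))
    expect_lt(min(abs(f - truth$frequency_hz)), df + 1e-9)
  expect_error(dominant_frequency(gen2$video, matrix(TRUE, 96, 96),
                                  f_min_hz = 150), "Nyquist")
})

test_that("smoothing choice does not move the peak on clean signals", {
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 256L, freq = 10))
  mask <- segment_motion(motion_map(gen$video))
  f3 <- dominant_frequency(gen$video, mask, smooth_frames = 3L)
  f1 <- dominant_frequency(gen$video, mask, smooth_frames = 1L)
  expect_equal(f3$sample_mean_cbf_hz, f1$sample_mean_cbf_hz,
               tolerance = 200 / 256)
})

test_that("empty masks are flagged and masked static pixels excluded", {
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 128L))
  r <- dominant_frequency(gen$video, matrix(FALSE, 96, 96))
  expect_false(r$defined)
  expect_true(is.na(r$sample_mean_cbf_hz))

  # mask that includes static pixels: they must not contribute a frequency
  mask <- gen_cilia_video(small_cbf_scene(n_frames = 128L))$manifest$label_map >= 0
  const_video <- video_stack(array(5, c(96, 96, 128)), 200, 1 / 3)
  rs <- dominant_frequency(const_video, mask)
  expect_false(rs$defined)
})

test_that("sample summaries average fields; empty-mask fields drop out of the CBF mean", {
  mk <- function(cbf, dens, def = TRUE)
    structure(list(sample_mean_cbf_hz = cbf, beat_density = dens,
                   defined = def), class = "cbf_result")
  s <- summarize_cbf(list(mk(8, 0.2), mk(10, 0.4)))
  expect_equal(s$sample_mean_cbf_hz, 9)
  expect_equal(s$sample_mean_density, 0.3)
  s2 <- summarize_cbf(list(mk(8, 0.2), mk(NA, 0, def = FALSE)))
  expect_equal(s2$sample_mean_cbf_hz, 8)   # hand computation: only field 1
  expect_equal(s2$sample_mean_density, 0.1)
  expect_equal(s2$n_fields_with_motion, 1)
  expect_equal(summarize_cbf(list(mk(8, 0.2)))$sample_mean_cbf_hz, 8)
})

test_that("adding masked-out static area leaves the sample CBF unchanged", {
  gen <- gen_cilia_video(small_cbf_scene(n_frames = 128L))
  mask <- segment_motion(motion_map(gen$video))
  r1 <- dominant_frequency(gen$video, mask)
  big <- array(100, c(96, 192, 128))
  big[, 1:96, ] <- gen$video$frames
  bigmask <- matrix(FALSE, 96, 192); bigmask[, 1:96] <- mask
  r2 <- dominant_frequency(video_stack(big, 200, 1 / 3), bigmask)
  expect_equal(r2$sample_mean_cbf_hz, r1$sample_mean_cbf_hz)
})
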