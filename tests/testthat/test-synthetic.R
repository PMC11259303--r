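test_that("degenerate config (no amplitude, no noise) yields silence", {
  tab <- default_band_amplitudes()
  tab$normal <- 0
  tab$sickness <- 0
  cfg <- sim_config(n_subjects = 1, n_videos = 1, duration_s = 2,
                    band_amplitude_table = tab, pink_noise_sd = 0,
                    white_noise_sd = 0)
  rec <- simulate_recording(cfg, "normal", seed = 3)
  expect_equal(max(abs(rec$data)), 0)
  expect_equal(dim(rec$data), c(10L, 1000L))
})

test_that("recordings are reproducible by seed and respond to it", {
  cfg <- sim_config(n_subjects = 1, n_videos = 1, duration_s = 2)
  a <- simulate_recording(cfg, "sickness", severity = 0.7, seed = 42)
  b <- simulate_recording(cfg, "sickness", severity = 0.7, seed = 42)
  c <- simulate_recording(cfg, "sickness", severity = 0.7, seed = 43)
  expect_identical(a$data, b$data)
  expect_gt(max(abs(a$data - c$data)), 0)
})

test_that("a single-band config concentrates spectral power in that band", {
  cfg <- single_band_config("occipital", "alpha", amp = 10)
  rec <- simulate_recording(cfg, "normal", seed = 2)
  o1 <- rec$data[which(rec$channels == "O1"), ]
  expect_gte(band_power_frac(o1, cfg$fs, 8, 13), 0.95)
  # mastoids carry nothing in a noise-free config
  expect_equal(max(abs(rec$data[which(rec$channels == "M1"), ])), 0)
})

test_that("unknown state and unmapped channels are rejected", {
  cfg <- tiny_config()
  expect_error(simulate_recording(cfg, "queasy"), "arg")
  expect_error(sim_config(channels = c("FP1", "XX9")), "XX9")
  expect_error(sim_config(n_subjects = 0), "at least 1")
})

test_that("latent trajectory is a bounded nondecreasing ramp from ~0", {
  t <- seq(0, 120, by = 0.5)
  m <- latent_trajectory(t, onset_s = 56, slope = 0.25, level = 0.9)
  expect_lt(m[1], 1e-5)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0 & m <= 0.9))
  expect_lt(abs(m[t == 56] - 0.45), 1e-12)
})

test_that("SSQ simulation floors, ceils and shifts monotonically", {
  expect_identical(simulate_ssq(0, seed = 1), rep(0L, 16))
  expect_identical(simulate_ssq(1, seed = 1, item_weights = rep(1, 16)),
                   rep(3L, 16))
  expect_error(simulate_ssq(1.2), "\\[0, 1\\]")
  means <- vapply(c(0.2, 0.5, 0.8), function(m) {
    mean(vapply(1:300, function(i) sum(simulate_ssq(m, seed = i)), 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("simulated corpus has the promised shape and labelling", {
  cfg <- tiny_config()
  ds <- simulate_dataset(cfg, window_s = 5, preprocess = FALSE)
  # 2 subjects x 2 videos x 2 states x 4 windows of 5 s in 20 s
  expect_equal(n_epochs(ds$epochs), 2 * 2 * 2 * 4)
  expect_equal(cfg$n_subjects * cfg$n_videos * 2 * cfg$duration_s,
               n_epochs(ds$epochs) * 5)
  expect_true(all(ds$epochs$label %in% 0:1))
  expect_identical(ds$epochs$label == 1L,
                   ds$epochs$origin$state == "sickness")
  expect_equal(nrow(ds$ssq), 4)
  # identical metadata layout, different noise under another seed
  cfg2 <- tiny_config()
  cfg2$seed <- 6
  ds2 <- simulate_dataset(cfg2, window_s = 5, preprocess = FALSE)
  expect_identical(ds$epochs$origin[c("subject_id", "video_id", "state",
                                      "offset_s")],
                   ds2$epochs$origin[c("subject_id", "video_id", "state",
                                       "offset_s")])
  expect_gt(max(abs(ds$epochs$data - ds2$epochs$data)), 0)
})

test_that("sickness epochs carry more central beta power than normal", {
  cfg <- tiny_config()
  ds <- simulate_dataset(cfg, window_s = 5, preprocess = FALSE)
  c3 <- which(cfg$channels == "C3")
  beta <- vapply(seq_len(n_epochs(ds$epochs)), function(i) {
    x <- ds$epochs$data[c3, , i]
    sum(Mod(fft(x))^2 *
          (pmin((seq_along(x) - 1), length(x) - (seq_along(x) - 1)) *
             cfg$fs / length(x) >= 13 &
           pmin((seq_along(x) - 1), length(x) - (seq_along(x) - 1)) *
             cfg$fs / length(x) < 30))
  }, 0)
  expect_gt(mean(beta[ds$epochs$label == 1]),
            mean(beta[ds$epochs$label == 0]))
})

test_that("the transition recording blends states along the trajectory", {
  cfg <- sim_config(n_subjects = 1, n_videos = 1, duration_s = 120,
                    seed = 4)
  tr <- simulate_transition_recording(cfg, severity = 1, seed = 4)
  expect_equal(length(tr$trajectory), ncol(tr$recording$data))
  # frontal broadband power should be higher late than early
  fp1 <- tr$recording$data[1, ]
  early <- fp1[1:(30 * cfg$fs)]
  late <- fp1[(90 * cfg$fs):(120 * cfg$fs)]
  expect_gt(mean(late^2), mean(early^2))
})
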