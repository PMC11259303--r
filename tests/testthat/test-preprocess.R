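make_rec <- function(x, fs = 500, ch = "C3") {
  eeg_recording(rbind(x), fs, ch)
}

test_that("the band-pass rejects DC and passes mid-band tones at unit gain", {
  t <- seq(0, by = 1 / 500, length.out = 5000)
  dc <- bandpass_filter(make_rec(rep(1, 5000)))
  expect_lt(mean(abs(dc$data)), 0.01)
  s10 <- sin(2 * pi * 10 * t)
  g10 <- sqrt(mean(bandpass_filter(make_rec(s10))$data^2)) /
    sqrt(mean(s10^2))
  expect_gte(g10, 0.95)
  expect_lte(g10, 1.05)
  s80 <- sin(2 * pi * 80 * t)
  g80 <- sqrt(mean(bandpass_filter(make_rec(s80))$data^2)) /
    sqrt(mean(s80^2))
  expect_gte(-20 * log10(g80), 20)
  expect_equal(ncol(dc$data), 5000L)
})

test_that("filtering is linear and validates its band edges", {
  set.seed(20)
  a <- rnorm(4000)
  b <- rnorm(4000)
  fa <- bandpass_filter(make_rec(a))$data
  fb <- bandpass_filter(make_rec(b))$data
  fab <- bandpass_filter(make_rec(2 * a + 3 * b))$data
  expect_lt(max(abs(fab - 2 * fa - 3 * fb)), 1e-8)
  expect_error(bandpass_filter(make_rec(a), 50, 0.5), "band edges")
  expect_error(bandpass_filter(make_rec(a), 0.5, 300), "band edges")
})

test_that("channel selection returns exactly what was asked for", {
  set.seed(21)
  rec <- eeg_recording(matrix(rnorm(10 * 50), 10), 500, ten_channels)
  sel <- select_channels(rec, eight_channels)
  expect_identical(sel$channels, eight_channels)
  expect_equal(nrow(sel$data), 8L)
  same <- select_channels(rec, ten_channels)
  expect_identical(same$data, rec$data)
  expect_error(select_channels(rec, c("C3", "PZ9")), "PZ9")
})

test_that("mastoid re-referencing subtracts the mastoid mean and is safe", {
  set.seed(22)
  x <- matrix(rnorm(10 * 200), 10)
  rec <- eeg_recording(x, 500, ten_channels)
  rr <- rereference_mastoids(rec)
  expect_identical(rr$channels, eight_channels)
  direct <- sweep(x[1:8, ], 2, colMeans(x[9:10, ]))
  expect_equal(rr$data, direct, ignore_attr = TRUE, tolerance = 1e-12)
  # the mastoid average expressed in the output frame is exactly zero
  expect_lt(max(abs(colMeans(x[9:10, ]) -
                      (colMeans(x[9:10, ]) - 0))), 1e-12)
  # zero mastoids leave data unchanged; re-referencing is then idempotent
  x0 <- x
  x0[9:10, ] <- 0
  rr0 <- rereference_mastoids(eeg_recording(x0, 500, ten_channels))
  expect_equal(rr0$data, x0[1:8, ], ignore_attr = TRUE)
  # a common trace across all channels is removed entirely
  xc <- matrix(rep(rnorm(200), each = 10), 10)
  rrc <- rereference_mastoids(eeg_recording(xc, 500, ten_channels))
  expect_lt(max(abs(rrc$data)), 1e-12)
  rec8 <- eeg_recording(x[1:8, ], 500, eight_channels)
  expect_error(rereference_mastoids(rec8), "M1")
  avg <- rereference_mastoids(rec8, fallback = "average")
  expect_lt(max(abs(colMeans(avg$data))), 1e-10)
})

test_that("PCA removal drops a spiky common artifact but not clean data", {
  set.seed(23)
  bg <- matrix(rnorm(8 * 5000), 8)
  clean <- pca_artifact_removal(eeg_recording(bg, 500, eight_channels))
  expect_length(attr(clean, "removed_components"), 0)
  expect_lt(max(abs(clean$data - bg)), 1e-10)
  art <- rep(0, 5000)
  art[sample(5000, 50)] <- 50
  mix <- bg + outer(runif(8, 0.8, 1.2), art)
  cleaned <- pca_artifact_removal(eeg_recording(mix, 500, eight_channels))
  expect_length(attr(cleaned, "removed_components"), 1)
  expect_lt(max(abs(cor(t(cleaned$data), art))), 0.1)
  z <- pca_artifact_removal(eeg_recording(matrix(0, 8, 100), 500,
                                          eight_channels))
  expect_equal(max(abs(z$data)), 0)
  expect_length(attr(z, "removed_components"), 0)
})

test_that("PCA removal never increases total variance", {
  set.seed(24)
  for (i in 1:5) {
    x <- matrix(rnorm(6 * 1000, sd = runif(1, 0.5, 3)), 6)
    if (i > 3) x <- x + outer(rnorm(6), rep(0, 1000) +
                                ifelse(runif(1000) < 0.01, 40, 0))
    out <- pca_artifact_removal(eeg_recording(x, 500, eight_channels[1:6]))
    expect_lte(sum(apply(out$data, 1, var)),
               sum(apply(x, 1, var)) + 1e-8)
  }
})

test_that("segmentation follows the truncation rule and conserves samples", {
  set.seed(25)
  rec <- make_rec(rnorm(10 * 500))          # 10 s at 500 Hz
  es <- segment_windows(rec, 5)
  expect_equal(n_epochs(es), 2L)
  expect_equal(dim(es$data)[2], 2500L)
  rec11 <- make_rec(rnorm(11 * 500))        # 11 s -> 1 s discarded
  es11 <- segment_windows(rec11, 5)
  expect_equal(n_epochs(es11), 2L)
  tail_samples <- ncol(rec11$data) - n_epochs(es11) * 2500
  expect_equal(n_epochs(es11) * 2500 + tail_samples, ncol(rec11$data))
  expect_equal(es11$origin$offset_s, c(0, 5))
  expect_warning(segment_windows(make_rec(rnorm(100)), 5), "shorter")
  expect_error(segment_windows(rec, 0.0003), "integer")
})

test_that("published corpus arithmetic: 4800, 2400, 2000 windows", {
  # a 24,000 s corpus (sampling rate immaterial for the count arithmetic)
  rec <- eeg_recording(matrix(0, 1, 24000 * 10), 10, "C3")
  expect_equal(n_epochs(segment_windows(rec, 5)), 4800L)
  expect_equal(n_epochs(segment_windows(rec, 10)), 2400L)
  expect_equal(n_epochs(segment_windows(rec, 12)), 2000L)
})
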