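# Level-3 db4 wavelet packet coefficients (periodization mode, natural
# node order) of x[t] = sin(2*pi*5*t/64) + 0.5*cos(2*pi*13*t/64 + 1)
# + 0.1*t/64, t = 0..63, computed once with an independent wavelet
# packet implementation (PyWavelets 1.9.0) and frozen here.
.ref_wpt_level3 <- c(
  9.1602107993750304e-01, -7.6419956280070633e-01, 8.1408320158848313e-01,
  -2.3245207546419271e-03, -6.1901566240690342e-01, 1.1499164865703666e+00,
  -6.1448921732777206e-01, 2.3370137556248188e-01, -6.6803975591205544e-01,
  2.2303310258821130e+00, -2.4632410236782309e+00, 1.2474104802243973e+00,
  6.9728138042862797e-01, -2.2334510521769366e+00, 2.4582508605026514e+00,
  -1.2395218352196853e+00, -6.6079198175178699e-01, 9.3789357603303447e-01,
  -7.1005078808556110e-01, 6.5300370167243965e-02, 6.1616500567735644e-01,
  -9.3661045008005195e-01, 7.0598618265205815e-01, -5.3009162152228506e-02,
  -2.1869969230210531e-01, 8.7527267333012615e-01, -1.0159916262697124e+00,
  5.6120165383668619e-01, 2.2240334354826283e-01, -8.7401383491747597e-01,
  9.7079689441193961e-01, -5.8211913969296991e-01, -1.0378537271481946e-02,
  -9.2791795757143913e-04, 3.6198453298758190e-02, -3.1035533962163256e-02,
  7.9327935871974248e-03, 1.9796067942810813e-02, -3.6263800936377211e-02,
  3.2356144828490641e-02, 4.9720778355635716e-02, -2.8984154044742642e-02,
  -5.0710817099794067e-03, 3.5333675042375723e-02, -4.4909337963468833e-02,
  2.7725508980254072e-02, -4.1405014506146580e-03, -5.0039739979189125e-02,
  -6.0165085119755290e-01, 4.5187222589827436e-01, -3.8180019823049222e-02,
  -3.9746550546731485e-01, 6.0025545627442090e-01, -4.5155840150671139e-01,
  3.9165495339044065e-02, 3.9346539184330487e-01, -1.8887769043672109e-01,
  2.2825198550807679e-01, -1.3375375475125165e-01, -3.9121235081981183e-02,
  1.8908071689344344e-01, -2.3120318213931967e-01, 1.3921999062988544e-01,
  3.8357263612188927e-02)

test_that("decomposition matches an independent reference implementation", {
  t <- 0:63
  x <- sin(2 * pi * 5 * t / 64) + 0.5 * cos(2 * pi * 13 * t / 64 + 1.0) +
    0.1 * t / 64
  tr <- wpt_decompose(x, 3)
  expect_lt(max(abs(unlist(tr$nodes) - .ref_wpt_level3)), 1e-10)
})

test_that("the db4 pair is orthogonal and quadrature-mirrored", {
  f <- wpt_filters()
  for (m in 0:3) {
    lag <- 2 * m
    expect_equal(sum(f$h[seq_len(8 - lag)] * f$h[seq_len(8 - lag) + lag]),
                 as.numeric(m == 0), tolerance = 1e-12)
  }
  expect_equal(f$g, (-1)^(1:8) * rev(f$h))
})

test_that("zero signals give zero trees and zero reconstructions", {
  tr <- wpt_decompose(rep(0, 256), 4)
  expect_equal(max(abs(unlist(tr$nodes))), 0)
  expect_equal(max(abs(reconstruct_nodes(tr, 0:15))), 0)
})

test_that("Parseval holds at every level on dyadic-length signals", {
  set.seed(30)
  x <- rnorm(512)
  for (lev in 1:6) {
    tr <- wpt_decompose(x, lev)
    e <- sum(vapply(tr$nodes, function(v) sum(v^2), 0))
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("perfect reconstruction holds, including odd-length chains", {
  set.seed(31)
  for (n in c(512, 5000, 2500)) {
    x <- rnorm(n)
    lev <- if (n == 512) 4 else 8
    tr <- wpt_decompose(x, lev)
    xr <- reconstruct_nodes(tr, 0:(2^lev - 1))
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  }
  expect_error(wpt_decompose(rnorm(100), 8), "too short")
})

test_that("band reconstructions partition the signal", {
  set.seed(32)
  x <- rnorm(5000)
  tr <- wpt_decompose(x, 8)
  bands <- band_specs()
  used <- integer(0)
  total <- rep(0, 5000)
  for (b in seq_len(nrow(bands))) {
    idx <- vimseeg:::select_band_nodes(8, 500, bands$low_hz[b],
                                       bands$high_hz[b])
    expect_length(intersect(used, idx), 0)
    used <- c(used, idx)
    total <- total + reconstruct_band(tr, bands$band[b], 500)
  }
  rest <- reconstruct_nodes(tr, setdiff(0:255, used))
  expect_lt(max(abs(total + rest - x)) / max(abs(x)), 1e-8)
})

test_that("natural-to-frequency ordering is the inverse Gray code and a
           permutation", {
  expect_equal(natural_to_frequency_order(1, 0:1), c(0L, 1L))
  expect_equal(natural_to_frequency_order(2, 0:3), c(0L, 1L, 3L, 2L))
  for (lev in 1:8) {
    r <- natural_to_frequency_order(lev, 0:(2^lev - 1))
    expect_setequal(r, 0:(2^lev - 1))
  }
  expect_error(natural_to_frequency_order(2, 4), "out of range")
})

test_that("frequency ordering agrees with a tone-sweep oracle, levels 1-6", {
  fs <- 500
  for (lev in 1:6) {
    nn <- 2^lev
    peak <- integer(nn)
    for (r in 0:(nn - 1)) {
      f <- (r + 0.5) * (fs / 2) / nn
      x <- sin(2 * pi * f * seq(0, by = 1 / fs, length.out = 2048))
      tr <- wpt_decompose(x, lev)
      peak[r + 1] <- which.max(vapply(tr$nodes,
                                      function(v) sum(v^2), 0)) - 1L
    }
    rank <- natural_to_frequency_order(lev, 0:(nn - 1))
    oracle_natural <- vapply(0:(nn - 1),
                             function(r) which(rank == r) - 1L, 0L)
    expect_equal(peak, oracle_natural)
  }
})

test_that("a 10 Hz tone is captured by the alpha band, not delta", {
  t <- seq(0, by = 1 / 500, length.out = 5000)
  tone <- sin(2 * pi * 10 * t)
  tr <- wpt_decompose(tone, 8)
  e <- function(b) sum(reconstruct_band(tr, b, 500)^2) / sum(tone^2)
  fr <- vapply(band_specs()$band, e, 0)
  # db4's deep-tree aliasing leaks some energy out of band (a 10 Hz tone
  # near the 8 Hz boundary sheds ~11% into theta nodes); alpha must
  # still hold most of the energy and dominate every other band
  expect_gte(fr[["alpha"]], 0.75)
  expect_lte(fr[["delta"]], 0.05)
  expect_gt(fr[["alpha"]], 5 * max(fr[c("delta", "theta", "beta")]))
  expect_error(reconstruct_band(tr, "gamma", 500), "unknown band")
  expect_error(reconstruct_band(wpt_decompose(tone, 3), "delta", 500),
               "no node")
})

test_that("feature extraction yields the 40-stream layout with band
           selectivity", {
  epoch0 <- matrix(0, 8, 5000, dimnames = list(eight_channels, NULL))
  f0 <- extract_features(epoch0, 500)
  expect_equal(dim(f0), c(100L, 40L))
  expect_equal(max(abs(f0)), 0)
  expect_equal(colnames(f0)[1:5],
               paste0("FP1_", c("orig", "delta", "theta", "alpha", "beta")))
  t <- seq(0, by = 1 / 500, length.out = 5000)
  epoch <- matrix(rep(sin(2 * pi * 10 * t), each = 8), 8,
                  dimnames = list(eight_channels, NULL))
  f <- extract_features(epoch, 500)
  for (chan in eight_channels) {
    en <- colMeans(f[, paste0(chan, c("_delta", "_theta", "_alpha",
                                      "_beta"))]^2)
    expect_gt(en[3], 5 * max(en[-3]))
  }
  expect_error(extract_features(epoch[, 1:100], 500), "too short")
})

test_that("feature energy is stable under time shifts of a pure tone", {
  t <- seq(0, by = 1 / 500, length.out = 6000)
  for (shift in c(0, 0.25, 0.5)) {
    x <- sin(2 * pi * 10 * (t + shift))
    ep <- matrix(rep(x[1:5000], each = 8), 8,
                 dimnames = list(eight_channels, NULL))
    en <- mean(extract_features(ep, 500)[, "O1_alpha"]^2)
    if (shift == 0) en0 <- en else expect_lt(abs(en - en0) / en0, 0.02)
  }
})
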