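# Hand-rolled scalar GRU recursion written directly from the update
# equations; deliberately loop-based and independent of the package's
# vectorized and compiled implementations.
scalar_gru <- function(Wz, Wr, Wc, h, x) {
  H <- length(h)
  out <- numeric(H)
  sig <- function(a) 1 / (1 + exp(-a))
  for (i in seq_len(H)) {
    az <- 0
    ar <- 0
    for (k in seq_along(c(h, x))) {
      v <- c(h, x)[k]
      az <- az + Wz[i, k] * v
      ar <- ar + Wr[i, k] * v
    }
    z <- sig(az)
    r_full <- numeric(H)
    for (j in seq_len(H)) {
      arj <- 0
      for (k in seq_along(c(h, x))) arj <- arj + Wr[j, k] * c(h, x)[k]
      r_full[j] <- sig(arj)
    }
    ac <- 0
    vc <- c(r_full * h, x)
    for (k in seq_along(vc)) ac <- ac + Wc[i, k] * vc[k]
    out[i] <- (1 - z) * h[i] + z * tanh(ac)
  }
  out
}

test_that("the GRU cell reproduces its closed-form corner cases", {
  cell0 <- list(Wz = matrix(0, 1, 2), Wr = matrix(0, 1, 2),
                Wc = matrix(0, 1, 2))
  # zero weights: z = 0.5, candidate = 0, so h = 0.5 * h_prev
  expect_equal(gru_cell_step(cell0, 0.8, 0), 0.4)
  expect_equal(gru_cell_step(cell0, 0, 0), 0)
  expect_error(gru_cell_step(cell0, c(0, 0), 0), "columns")
})

test_that("the cell agrees with a scalar oracle and the compiled path", {
  set.seed(50)
  H <- 2
  D <- 3
  Tn <- 7
  Wz <- matrix(rnorm(H * (H + D)), H)
  Wr <- matrix(rnorm(H * (H + D)), H)
  Wc <- matrix(rnorm(H * (H + D)), H)
  cell <- list(Wz = Wz, Wr = Wr, Wc = Wc)
  U <- matrix(rnorm(Tn * D), Tn, D)
  Hs <- vimseeg:::cpp_gru_hidden(Wz, numeric(H), Wr, numeric(H), Wc,
                                 numeric(H), U)
  h_r <- numeric(H)
  h_s <- numeric(H)
  for (t in seq_len(Tn)) {
    h_r <- gru_cell_step(cell, h_r, U[t, ])
    h_s <- scalar_gru(Wz, Wr, Wc, h_s, U[t, ])
    expect_lt(max(abs(h_r - h_s)), 1e-10)
    expect_lt(max(abs(h_r - Hs[t, ])), 1e-6)
  }
})

test_that("the state update is convex and bounded", {
  set.seed(51)
  for (i in 1:20) {
    H <- sample(2:5, 1)
    D <- sample(2:5, 1)
    cell <- list(Wz = matrix(rnorm(H * (H + D), sd = 2), H),
                 Wr = matrix(rnorm(H * (H + D), sd = 2), H),
                 Wc = matrix(rnorm(H * (H + D), sd = 2), H))
    h <- runif(H, -1.5, 1.5)
    x <- rnorm(D)
    hn <- gru_cell_step(cell, h, x)
    expect_true(all(abs(hn) <= pmax(abs(h), 1) + 1e-12))
    # convexity: h_t lies between h_{t-1} and the candidate
    v <- c(h, x)
    z <- 1 / (1 + exp(-as.vector(cell$Wz %*% v)))
    r <- 1 / (1 + exp(-as.vector(cell$Wr %*% v)))
    ctil <- tanh(as.vector(cell$Wc %*% c(r * h, x)))
    expect_true(all(hn >= pmin(h, ctil) - 1e-12 &
                      hn <= pmax(h, ctil) + 1e-12))
  }
})

test_that("losses match their analytic values", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(0, 0.9), -log(0.1), tolerance = 1e-9)
  expect_error(bce_loss(c(1, 0), 0.5), "equal length")
  expect_equal(prediction_loss(0.5, 0.5), 0)
  expect_equal(prediction_loss(0.2, 0.5), 0.09, tolerance = 1e-9)
  p <- c(0.1, 0.4, 0.8, 0.3)
  t_ <- c(0.2, 0.2, 0.9, 0.0)
  expect_equal(prediction_loss(p, t_), mean((p - t_)^2), tolerance = 1e-12)
})

test_that("deviation signals are absolute baseline differences", {
  f <- matrix(c(1, -2), 1)
  expect_equal(deviation_signal(f, c(0, 1)), matrix(c(1, 3), 1),
               ignore_attr = TRUE)
  f2 <- matrix(rnorm(20), 5)
  expect_equal(max(abs(deviation_signal(f2, f2))), 0)
  expect_true(all(deviation_signal(f2, rnorm(4)) >= 0))
})

test_that("compiled gradients match finite differences", {
  set.seed(52)
  p <- vimseeg:::gru_init_params(3, 4, c(3))
  X <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
  y <- c(1, 0, 1)
  for (lt in 0:1) {
    lg <- vimseeg:::cpp_gru_loss_grad(p, X, y, lt)
    for (pi in seq_along(p)) {
      for (j in seq_len(min(length(p[[pi]]), 3))) {
        eps <- 1e-6
        pp <- p
        pp[[pi]][j] <- pp[[pi]][j] + eps
        pm <- p
        pm[[pi]][j] <- pm[[pi]][j] - eps
        fd <- (vimseeg:::cpp_gru_loss_grad(pp, X, y, lt)$loss -
                 vimseeg:::cpp_gru_loss_grad(pm, X, y, lt)$loss) / (2 * eps)
        expect_lt(abs(fd - lg$grads[[pi]][j]) / max(1e-6, abs(fd)), 1e-3)
      }
    }
  }
})

make_toy_features <- function(n = 40, Tn = 20, seed = 1) {
  set.seed(seed)
  lab <- rep(0:1, length.out = n)
  x <- array(rnorm(Tn * 8 * n), c(Tn, 8, n))
  for (i in which(lab == 1)) x[, 1:2, i] <- x[, 1:2, i] + 1.5
  list(x = x, label = lab,
       origin = data.frame(subject_id = rep(1:4, each = n / 4)))
}

test_that("training is deterministic under a fixed seed and learns", {
  toy <- make_toy_features()
  cfg <- train_config(epochs = 8, seed = 3, hidden = 8, lr = 5e-3)
  m1 <- train_classifier(toy, cfg = cfg)
  m2 <- train_classifier(toy, cfg = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_lte(m1$history$train_loss[nrow(m1$history)],
             m1$history$train_loss[1])
  p <- predict(m1, toy$x)
  expect_true(all(p > 0 & p < 1))
  m3 <- train_classifier(toy, cfg = train_config(epochs = 8, seed = 4,
                                                 hidden = 8, lr = 5e-3))
  expect_gt(max(abs(m3$params[[1]] - m1$params[[1]])), 0)
})

test_that("a predictor on uninformative inputs approaches a constant target", {
  set.seed(53)
  n <- 32
  toy <- list(x = array(rnorm(10 * 6 * n), c(10, 6, n)),
              label = rep(0:1, length.out = n),
              origin = data.frame(subject_id = rep(1:4, each = 8)))
  targets <- rep(0.3, n)
  cfg <- train_config(epochs = 60, seed = 5, hidden = 4, lr = 5e-3)
  m <- train_predictor(toy, targets, cfg = cfg)
  expect_lte(m$history$train_loss[nrow(m$history)],
             m$history$train_loss[1])
  p <- predict(m, toy$x)
  expect_lt(abs(mean(p) - 0.3), abs(0.5 - 0.3))
  expect_true(all(p > 0 & p < 1))
})

test_that("sliding-window prediction has the right length and stability", {
  set.seed(54)
  n <- 16
  toy <- list(x = array(rnorm(100 * 40 * n), c(100, 40, n)),
              label = rep(0:1, length.out = n),
              origin = data.frame(subject_id = rep(1:4, each = 4)))
  cfg <- train_config(epochs = 2, seed = 3, hidden = 4, lr = 1e-3,
                      window_s = 10, frames_per_s = 10)
  m <- train_predictor(toy, rep(0.4, n), cfg = cfg)
  # constant recording -> near-constant trajectory
  rec <- eeg_recording(matrix(1, 8, 500 * 30), 500, eight_channels)
  traj <- predict_timeseries(m, rec, window_s = 10, stride_s = 2)
  expect_equal(nrow(traj), floor((30 - 10) / 2) + 1)
  expect_lt(sd(traj$level_norm), 0.05)
  expect_equal(traj$level_ssq, traj$level_norm * 235.62)
  expect_error(predict_timeseries(m, eeg_recording(matrix(1, 8, 500), 500,
                                                   eight_channels)),
               "shorter")
})
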