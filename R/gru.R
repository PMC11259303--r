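# GRU models: the recurrent cell, losses, parameter initialization,
# training via the compiled ADAM/backpropagation-through-time loop, and
# sliding-window real-time prediction.

sigmoid <- function(a) 1 / (1 + exp(-a))

#' One GRU cell step
#'
#' The gated recurrent unit update:
#' \deqn{z_t = \sigma(W_z [h_{t-1}, x_t] + b_z)}
#' \deqn{r_t = \sigma(W_r [h_{t-1}, x_t] + b_r)}
#' \deqn{\tilde h_t = \tanh(W [r_t \odot h_{t-1}, x_t] + b)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#' so the new state is a convex combination of the previous state and the
#' candidate, gated by `z`.
#'
#' @param cell List with `Wz`, `Wr`, `Wc` (each hidden x (hidden+input))
#'   and optional biases `bz`, `br`, `bc` (default 0).
#' @param h_prev Hidden state vector.
#' @param x_t Input vector.
#' @return The new hidden state `h_t`.
#' @export
gru_cell_step <- function(cell, h_prev, x_t) {
  H <- length(h_prev)
  if (ncol(cell$Wz) != H + length(x_t)) {
    stop("weight matrices must act on [h_prev, x_t] (",
         H + length(x_t), " columns expected)")
  }
  bz <- if (is.null(cell$bz)) 0 else cell$bz
  br <- if (is.null(cell$br)) 0 else cell$br
  bc <- if (is.null(cell$bc)) 0 else cell$bc
  v <- c(h_prev, x_t)
  z <- sigmoid(as.vector(cell$Wz %*% v) + bz)
  r <- sigmoid(as.vector(cell$Wr %*% v) + br)
  ctil <- tanh(as.vector(cell$Wc %*% c(r * h_prev, x_t)) + bc)
  (1 - z) * h_prev + z * ctil
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum y log p + (1-y) log(1-p)`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities.
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Squared-error prediction loss
#'
#' Mean squared error between predicted and true normalized SSQ totals.
#'
#' @param preds Predicted levels.
#' @param targets True normalized totals in `[0, 1]`.
#' @return Mean squared error (scalar).
#' @export
prediction_loss <- function(preds, targets) {
  if (length(preds) != length(targets)) {
    stop("preds and targets must have equal length")
  }
  mean((preds - targets)^2)
}

#' Baseline-deviation feature sequence
#'
#' The elementwise absolute deviation `E_t = |x_t - R(x_t)|` of a feature
#' sequence from a per-subject resting-state baseline operator. The
#' shipped baseline is the mean feature frame over the subject's normal
#' recordings, broadcast over time.
#'
#' @param features T x streams feature matrix.
#' @param baseline Baseline vector (one value per stream) or a matrix of
#'   the same shape as `features`.
#' @return Nonnegative T x streams deviation matrix.
#' @export
deviation_signal <- function(features, baseline) {
  if (is.matrix(baseline)) {
    stopifnot(all(dim(baseline) == dim(features)))
    return(abs(features - baseline))
  }
  stopifnot(length(baseline) == ncol(features))
  abs(sweep(features, 2, baseline))
}

#' Fit per-subject resting baselines
#'
#' Mean standardized feature frame over each subject's normal-state
#' epochs.
#'
#' @param x Standardized feature array T x streams x n.
#' @param subjects Subject id per epoch.
#' @param normal Logical, TRUE for normal-state epochs.
#' @return Named list: one baseline vector per subject id.
#' @export
fit_baselines <- function(x, subjects, normal) {
  out <- list()
  for (s in unique(subjects)) {
    idx <- which(subjects == s & normal)
    if (length(idx) == 0) stop("no normal-state epochs for subject ", s)
    out[[as.character(s)]] <- apply(x[, , idx, drop = FALSE], 2, mean)
  }
  out
}

#' Training configuration
#'
#' Defaults follow the training regime used throughout: ADAM with
#' learning rate 5e-5, beta1 0.9, beta2 0.999, decoupled weight decay
#' 1e-8, batch size 4, 50 epochs.
#'
#' @param window_s Epoch window the model is trained on, seconds.
#' @param epochs,batch,lr,beta1,beta2,weight_decay ADAM settings.
#' @param hidden GRU hidden width.
#' @param frames_per_s Feature frame rate the model expects.
#' @param seed Integer seed controlling init and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(window_s = 10, epochs = 50, batch = 4, lr = 5e-5,
                         beta1 = 0.9, beta2 = 0.999, weight_decay = 1e-8,
                         hidden = 32, frames_per_s = 10, seed = 1) {
  stopifnot(lr > 0, batch >= 1, epochs >= 1)
  structure(list(window_s = window_s, epochs = epochs, batch = batch,
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, hidden = hidden,
                 frames_per_s = frames_per_s, seed = seed),
            class = "train_config")
}

# Glorot-uniform parameter list in the flat order the compiled code
# expects: Wi, bi, Wz, bz, Wr, br, Wc, bc, W1, b1, ..., Wk, bk.
gru_init_params <- function(input_dim, hidden, head_dims) {
  glorot <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  p <- list(
    glorot(input_dim, input_dim), numeric(input_dim),
    glorot(hidden, hidden + input_dim), numeric(hidden),
    glorot(hidden, hidden + input_dim), numeric(hidden),
    glorot(hidden, hidden + input_dim), numeric(hidden)
  )
  dims <- c(hidden, head_dims, 1)
  for (l in seq_len(length(dims) - 1)) {
    p <- c(p, list(glorot(dims[l + 1], dims[l]), numeric(dims[l + 1])))
  }
  p
}

# Grouped subject split: 70/15/15 by unique subject id, shuffled by the
# configured seed so no subject leaks across splits.
subject_split <- function(subjects, seed, frac = c(0.7, 0.15, 0.15)) {
  us <- unique(subjects)
  ord <- with_seed(seed, sample(us))
  n <- length(us)
  n_tr <- max(1, round(frac[1] * n))
  n_va <- max(1, min(n - n_tr - 1, round(frac[2] * n)))
  if (n_tr + n_va >= n) {
    n_tr <- max(1, n - 2)
    n_va <- 1
  }
  tr <- ord[seq_len(n_tr)]
  va <- ord[n_tr + seq_len(n_va)]
  te <- setdiff(ord, c(tr, va))
  list(train = which(subjects %in% tr), val = which(subjects %in% va),
       test = which(subjects %in% te),
       subjects = list(train = tr, val = va, test = te))
}

train_core <- function(x, y, idx_tr, idx_va, cfg, head_dims, loss_type) {
  input_dim <- dim(x)[2]
  n_tr <- length(idx_tr)
  init <- with_seed(cfg$seed, gru_init_params(input_dim, cfg$hidden,
                                              head_dims))
  perms <- with_seed(cfg$seed + 1, {
    vapply(seq_len(cfg$epochs), function(e) sample.int(n_tr) - 1L,
           integer(n_tr))
  })
  res <- cpp_gru_train(init, x[, , idx_tr, drop = FALSE], y[idx_tr],
                       x[, , idx_va, drop = FALSE], y[idx_va],
                       perms, cfg$batch, cfg$lr, cfg$beta1, cfg$beta2,
                       cfg$weight_decay, 1e-8, loss_type)
  hist <- as.data.frame(res$history)
  names(hist) <- c("train_loss", "train_metric", "val_loss", "val_metric")
  hist$epoch <- seq_len(nrow(hist))
  list(params = res$params, history = hist)
}

#' Train the motion-sickness classifier
#'
#' Architecture: time-distributed 40-unit ReLU input layer, GRU(32, tanh)
#' emitting its final hidden state, dense ReLU layers of 16 and 8 units,
#' and a 1-unit sigmoid output, trained with binary cross-entropy under
#' ADAM. Features are standardized with training-set statistics and the
#' split is grouped by subject (70/15/15).
#'
#' @param features A list as from [extract_features_epochset()] (fields
#'   `x`, `label`, `origin`) or a raw T x streams x n array.
#' @param labels Binary labels, required when `features` is an array.
#' @param subjects Subject ids, required when `features` is an array.
#' @param cfg A [train_config()].
#' @return A `vims_gru` model (type "classifier") with elements `params`,
#'   `stats`, `history`, `split`, `cfg`.
#' @export
train_classifier <- function(features, labels = NULL, subjects = NULL,
                             cfg = train_config()) {
  if (is.list(features) && !is.null(features$x)) {
    labels <- features$label
    subjects <- features$origin$subject_id
    features <- features$x
  }
  stopifnot(!is.null(labels), !is.null(subjects))
  split <- subject_split(subjects, cfg$seed)
  if (length(split$train) == 0 || length(split$val) == 0) {
    stop("empty training or validation split")
  }
  stats <- feature_stats(features[, , split$train, drop = FALSE])
  xs <- apply_feature_stats(features, stats)
  fit <- train_core(xs, as.numeric(labels), split$train, split$val, cfg,
                    head_dims = c(16, 8), loss_type = 0L)
  structure(list(type = "classifier", params = fit$params, stats = stats,
                 history = fit$history, split = split, cfg = cfg),
            class = "vims_gru")
}

#' Train the motion-sickness level predictor
#'
#' Architecture: 40-unit ReLU input layer, GRU(32, tanh), dense ReLU
#' layers of 32, 16, 16 and 8 units, 1-unit sigmoid output; trained with
#' squared error against normalized SSQ totals on baseline-deviation
#' sequences `E_t = |x_t - baseline|`. Normal-state epochs carry target
#' 0 (resting level).
#'
#' @param features List from [extract_features_epochset()] or array.
#' @param targets Normalized SSQ totals in `[0, 1]`, one per epoch.
#' @param subjects Subject ids (required when `features` is an array).
#' @param normal Logical per epoch, TRUE for normal-state epochs
#'   (required when `features` is an array; used for the baselines).
#' @param cfg A [train_config()].
#' @return A `vims_gru` model (type "predictor") with per-subject
#'   `baselines` in addition to the classifier fields.
#' @export
train_predictor <- function(features, targets, subjects = NULL,
                            normal = NULL, cfg = train_config()) {
  if (is.list(features) && !is.null(features$x)) {
    subjects <- features$origin$subject_id
    normal <- features$label == 0
    features <- features$x
  }
  stopifnot(!is.null(subjects), !is.null(normal))
  if (any(targets < 0 | targets > 1)) {
    stop("targets must be normalized SSQ totals in [0, 1]")
  }
  split <- subject_split(subjects, cfg$seed)
  stats <- feature_stats(features[, , split$train, drop = FALSE])
  xs <- apply_feature_stats(features, stats)
  baselines <- fit_baselines(xs[, , split$train, drop = FALSE],
                             subjects[split$train],
                             normal[split$train])
  # pooled baseline for subjects unseen in training
  pooled <- Reduce(`+`, baselines) / length(baselines)
  xd <- xs
  for (i in seq_len(dim(xs)[3])) {
    b <- baselines[[as.character(subjects[i])]]
    if (is.null(b)) b <- pooled
    xd[, , i] <- deviation_signal(xs[, , i], b)
  }
  fit <- train_core(xd, as.numeric(targets), split$train, split$val, cfg,
                    head_dims = c(32, 16, 16, 8), loss_type = 1L)
  structure(list(type = "predictor", params = fit$params, stats = stats,
                 baselines = baselines, pooled_baseline = pooled,
                 history = fit$history, split = split, cfg = cfg),
            class = "vims_gru")
}

#' @export
print.vims_gru <- function(x, ...) {
  cat(sprintf("<vims_gru> %s, hidden %d, trained %d epochs\n",
              x$type, x$cfg$hidden, nrow(x$history)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, val loss %.4f, val metric %.4f\n",
              last$train_loss, last$val_loss, last$val_metric))
  invisible(x)
}

#' Predict from feature sequences
#'
#' @param object A `vims_gru` model.
#' @param x Feature array T x streams x n (unstandardized; the model's
#'   stored statistics are applied). For predictors, pass raw features
#'   together with `baseline`, or already-deviation sequences with
#'   `baseline = NULL` and `standardize = FALSE`.
#' @param baseline Baseline vector for predictor inputs; defaults to the
#'   model's pooled baseline.
#' @param standardize Apply the stored feature statistics.
#' @param ... Unused.
#' @return Numeric vector of probabilities / normalized levels in (0, 1).
#' @export
predict.vims_gru <- function(object, x, baseline = NULL,
                             standardize = TRUE, ...) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  if (standardize) x <- apply_feature_stats(x, object$stats)
  if (object$type == "predictor") {
    if (is.null(baseline)) baseline <- object$pooled_baseline
    for (i in seq_len(dim(x)[3])) {
      x[, , i] <- deviation_signal(x[, , i], baseline)
    }
  }
  as.vector(cpp_gru_predict(object$params, x))
}

#' Sliding-window real-time sickness trajectory
#'
#' Runs the predictor over sliding windows of a continuous preprocessed
#' 8-channel recording and returns the predicted level at each window
#' end.
#'
#' @param model A `vims_gru` predictor.
#' @param rec A preprocessed [eeg_recording()] (8 analysis channels).
#' @param window_s Window width, seconds (defaults to the model's).
#' @param stride_s Hop between windows, seconds.
#' @param baseline Per-subject baseline vector; defaults to the model's
#'   pooled baseline.
#' @param level Wavelet packet depth for feature extraction.
#' @return data.frame with `t_end` (window end, s), `level_norm` in
#'   (0, 1) and `level_ssq` (rescaled by 235.62).
#' @export
predict_timeseries <- function(model, rec, window_s = model$cfg$window_s,
                               stride_s = 1, baseline = NULL, level = 8) {
  dur <- recording_duration(rec)
  if (dur < window_s) stop("recording shorter than the prediction window")
  starts <- seq(0, dur - window_s, by = stride_s)
  w <- as.integer(round(window_s * rec$fs))
  preds <- numeric(length(starts))
  for (i in seq_along(starts)) {
    i0 <- as.integer(round(starts[i] * rec$fs))
    epoch <- rec$data[, (i0 + 1):(i0 + w), drop = FALSE]
    f <- extract_features(epoch, rec$fs, level = level,
                          frames_per_s = model$cfg$frames_per_s)
    preds[i] <- predict(model, array(f, c(dim(f), 1)), baseline = baseline)
  }
  data.frame(t_end = starts + window_s, level_norm = preds,
             level_ssq = preds * ssq_max_total())
}

#' Locate the sickness onset in a predicted trajectory
#'
#' Finds the largest increase of the (lightly smoothed) predicted level
#' and corrects the window-end timestamp by the sliding window's group
#' delay (`window_s / 2`): a causal window first reflects a state change
#' when the change sits near its centre.
#'
#' @param traj A [predict_timeseries()] result.
#' @param window_s The window width used for the trajectory, seconds.
#' @param smooth_k Moving-average half-width (frames) applied before
#'   differencing; 1 disables smoothing.
#' @return Estimated onset time, seconds.
#' @export
detect_onset <- function(traj, window_s, smooth_k = 3) {
  y <- traj$level_norm
  if (smooth_k > 1) {
    y <- as.vector(stats::filter(y, rep(1 / smooth_k, smooth_k),
                                 sides = 2))
  }
  d <- diff(y)
  i <- which.max(d)
  traj$t_end[i + 1] - window_s / 2
}
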