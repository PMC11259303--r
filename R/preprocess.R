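# Preprocessing chain: band-pass filter -> PCA artifact removal ->
# bilateral-mastoid re-reference -> channel selection -> fixed windows.

#' Zero-phase band-pass filter
#'
#' Filters every channel with an exactly zero-phase band-pass: the signal
#' is reflect-padded, transformed with the FFT, multiplied by a real
#' frequency response that is 1 on `[low_hz, high_hz]` and rolls off to 0
#' over raised-cosine transition bands of width 25% of each edge
#' frequency, and transformed back. Being a real, even response this is
#' linear-phase with zero delay, preserves signal length, and rejects DC
#' exactly.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Passband edges, `0 < low_hz < high_hz < fs/2`.
#' @param transition_frac Transition width as a fraction of each edge
#'   frequency.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 50,
                            transition_frac = 0.25) {
  fs <- rec$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  }
  n <- ncol(rec$data)
  pad <- min(n - 1, round(4 * fs))
  tl <- transition_frac * low_hz
  th <- transition_frac * high_hz
  np <- n + 2 * pad
  f <- (seq_len(np) - 1) / np * fs
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  resp <- numeric(np)
  resp[f >= low_hz & f <= high_hz] <- 1
  lo0 <- low_hz - tl
  ramp_up <- f > lo0 & f < low_hz
  resp[ramp_up] <- 0.5 - 0.5 * cos(pi * (f[ramp_up] - lo0) / tl)
  hi1 <- min(high_hz + th, fs / 2)
  ramp_dn <- f > high_hz & f < hi1
  resp[ramp_dn] <- 0.5 + 0.5 * cos(pi * (f[ramp_dn] - high_hz) /
                                     (hi1 - high_hz))
  out <- rec
  for (ci in seq_len(nrow(rec$data))) {
    x <- rec$data[ci, ]
    xp <- if (pad > 0) {
      c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    } else x
    y <- Re(fft(fft(xp) * resp, inverse = TRUE)) / np
    out$data[ci, ] <- y[(pad + 1):(pad + n)]
  }
  out
}

#' Select channels by name
#'
#' @param rec An [eeg_recording()].
#' @param names Channel names to keep, in the requested output order.
#' @return An [eeg_recording()] with exactly those channels.
#' @export
select_channels <- function(rec, names) {
  idx <- match(names, rec$channels)
  if (anyNA(idx)) {
    stop("unknown channel(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  eeg_recording(rec$data[idx, , drop = FALSE], rec$fs, names,
                rec$start_time_s)
}

#' Re-reference to the bilateral mastoids
#'
#' Subtracts the mean of the two mastoid channels from every other
#' channel and drops the mastoids from the output. If the mastoids are
#' absent this errors rather than silently changing the reference; pass
#' `fallback = "average"` to re-reference to the common average instead.
#'
#' @param rec An [eeg_recording()].
#' @param ref_names The two mastoid channel names.
#' @param fallback `"none"` (error when mastoids are missing) or
#'   `"average"` (explicit common-average re-reference).
#' @return An [eeg_recording()] without the reference channels.
#' @export
rereference_mastoids <- function(rec, ref_names = c("M1", "M2"),
                                 fallback = c("none", "average")) {
  fallback <- match.arg(fallback)
  idx <- match(ref_names, rec$channels)
  if (anyNA(idx)) {
    if (fallback == "average") {
      ref <- colMeans(rec$data)
      return(eeg_recording(sweep(rec$data, 2, ref), rec$fs, rec$channels,
                           rec$start_time_s))
    }
    stop("missing mastoid channel(s): ",
         paste(ref_names[is.na(idx)], collapse = ", "),
         " (pass fallback = \"average\" for an explicit average reference)")
  }
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$data)), idx)
  eeg_recording(sweep(rec$data[keep, , drop = FALSE], 2, ref), rec$fs,
                rec$channels[keep], rec$start_time_s)
}

# Excess-free moment kurtosis of a vector (normal ~ 3).
moment_kurtosis <- function(x) {
  v <- var(x)
  if (v <= 0) return(0)
  mean((x - mean(x))^4) / v^2
}

#' PCA artifact removal
#'
#' Decomposes the channel covariance and zeroes principal components that
#' look like large non-neural artifacts: variance share above
#' `var_threshold` AND score kurtosis above `kurt_threshold` (large,
#' spiky, non-Gaussian components). Genuine oscillatory rhythms have
#' near-Gaussian scores and are left intact.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @param var_threshold Minimum variance share of a flagged component.
#' @param kurt_threshold Minimum moment kurtosis of a flagged component.
#' @return The cleaned [eeg_recording()]; the indices of removed
#'   components are attached as attribute `"removed_components"`.
#' @export
pca_artifact_removal <- function(rec, var_threshold = 0.35,
                                 kurt_threshold = 8) {
  x <- t(rec$data)               # samples x channels
  if (ncol(x) < 2) stop("PCA artifact removal needs at least 2 channels")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  ev <- sv$d^2
  if (sum(ev) == 0) {
    out <- rec
    attr(out, "removed_components") <- integer(0)
    return(out)
  }
  share <- ev / sum(ev)
  scores <- xc %*% sv$v
  kur <- apply(scores, 2, moment_kurtosis)
  flag <- which(share > var_threshold & kur > kurt_threshold)
  if (length(flag)) {
    xc <- scores[, -flag, drop = FALSE] %*% t(sv$v[, -flag, drop = FALSE])
  }
  out <- rec
  out$data <- t(sweep(xc, 2, mu, "+"))
  rownames(out$data) <- rec$channels
  attr(out, "removed_components") <- as.integer(flag)
  out
}

#' Cut a recording into fixed non-overlapping windows
#'
#' Contiguous half-open windows `[t, t + window_s)` from time 0; a
#' trailing partial window is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window width in seconds; `window_s * fs` must be a
#'   whole number of samples.
#' @return An [epoch_set()] whose `origin` records each window's
#'   `offset_s`.
#' @export
segment_windows <- function(rec, window_s) {
  w <- window_s * rec$fs
  if (abs(w - round(w)) > 1e-9 || w <= 0) {
    stop("window_s * fs must be a positive integer sample count")
  }
  w <- as.integer(round(w))
  n <- ncol(rec$data)
  n_win <- n %/% w
  if (n_win == 0) {
    warning("recording shorter than one window; returning empty epoch set")
  }
  dat <- array(0, c(nrow(rec$data), w, n_win))
  for (i in seq_len(n_win)) {
    dat[, , i] <- rec$data[, ((i - 1) * w + 1):(i * w)]
  }
  origin <- data.frame(offset_s = (seq_len(n_win) - 1) * window_s)
  if (n_win == 0) origin <- data.frame(offset_s = numeric(0))
  epoch_set(dat, rec$fs, window_s, rec$channels, origin = origin)
}

#' Standard preprocessing chain
#'
#' Band-pass 0.5-50 Hz, PCA artifact removal, bilateral-mastoid
#' re-referencing, then selection of the 8 analysis channels
#' (FP1, FP2, C3, C4, P3, P4, O1, O2).
#'
#' @param rec An [eeg_recording()] containing the analysis channels and,
#'   unless `reference = "average"`, both mastoids.
#' @param low_hz,high_hz Passband edges.
#' @param channels Analysis channels to keep after re-referencing.
#' @param reference `"mastoids"` or `"average"`.
#' @param pca Apply PCA artifact removal.
#' @param var_threshold,kurt_threshold PCA flagging thresholds.
#' @return The preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, low_hz = 0.5, high_hz = 50,
                                 channels = c("FP1", "FP2", "C3", "C4",
                                              "P3", "P4", "O1", "O2"),
                                 reference = c("mastoids", "average"),
                                 pca = TRUE, var_threshold = 0.35,
                                 kurt_threshold = 8) {
  reference <- match.arg(reference)
  rec <- bandpass_filter(rec, low_hz, high_hz)
  if (pca) {
    rec <- pca_artifact_removal(rec, var_threshold, kurt_threshold)
  }
  rec <- if (reference == "mastoids") {
    rereference_mastoids(rec)
  } else {
    rereference_mastoids(rec, fallback = "average",
                         ref_names = c("__none__", "__none__"))
  }
  select_channels(rec, channels)
}
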