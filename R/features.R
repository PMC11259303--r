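# Per-epoch feature sequences: for each of the 8 channels, the original
# signal plus its four band reconstructions (delta/theta/alpha/beta) are
# reduced to an RMS-envelope frame sequence, giving a T x 40 matrix per
# epoch (channel-major stream layout).

#' Extract a band-feature sequence from one epoch
#'
#' Each channel is wavelet-packet decomposed to `level` and the four
#' rhythm bands are reconstructed; the original signal and the four band
#' signals form 5 streams per channel. Every stream is pooled to
#' `frames_per_s` frames per second by the RMS over consecutive
#' non-overlapping sample blocks (an amplitude envelope; a plain mean
#' would cancel the oscillations the bands carry).
#'
#' @param epoch Numeric matrix, channels x samples (one epoch).
#' @param fs Sampling rate, Hz.
#' @param level Wavelet packet depth (default 8).
#' @param frames_per_s Feature frame rate; `fs / frames_per_s` must be a
#'   whole number of samples.
#' @param bands Band table as from [band_specs()].
#' @param filters [wpt_filters()] pair.
#' @return T x (channels * 5) matrix with column names
#'   `<channel>_<orig|delta|theta|alpha|beta>`.
#' @export
extract_features <- function(epoch, fs, level = 8, frames_per_s = 10,
                             bands = band_specs(),
                             filters = wpt_filters()) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n < 2^level) {
    stop("epoch too short for wavelet packet level ", level)
  }
  block <- fs / frames_per_s
  if (abs(block - round(block)) > 1e-9) {
    stop("fs / frames_per_s must be an integer block size")
  }
  block <- as.integer(round(block))
  n_frames <- n %/% block
  chn <- rownames(epoch)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(epoch)))
  keep <- matrix(FALSE, nrow(bands), 2^level)
  for (bi in seq_len(nrow(bands))) {
    keep[bi, select_band_nodes(level, fs, bands$low_hz[bi],
                               bands$high_hz[bi]) + 1L] <- TRUE
  }
  n_streams <- 1L + nrow(bands)
  out <- matrix(0, n_frames, nrow(epoch) * n_streams)
  cn <- character(ncol(out))
  pool <- function(x) {
    m <- matrix(x[seq_len(n_frames * block)], block, n_frames)
    sqrt(colMeans(m^2))
  }
  for (ci in seq_len(nrow(epoch))) {
    x <- epoch[ci, ]
    bsig <- cpp_wpt_band_signals(x, level, filters$h, filters$g, keep)
    col0 <- (ci - 1) * n_streams
    out[, col0 + 1] <- pool(x)
    cn[col0 + 1] <- paste0(chn[ci], "_orig")
    for (bi in seq_len(nrow(bands))) {
      out[, col0 + 1 + bi] <- pool(bsig[, bi])
      cn[col0 + 1 + bi] <- paste0(chn[ci], "_", bands$band[bi])
    }
  }
  colnames(out) <- cn
  out
}

#' Extract feature sequences for every epoch in a set
#'
#' @param es An [epoch_set()] (8 channels for the shipped models).
#' @param level,frames_per_s,bands,filters See [extract_features()].
#' @return List with `x` (array T x streams x n_epochs), `label`,
#'   `origin` and `streams` (column names).
#' @export
extract_features_epochset <- function(es, level = 8, frames_per_s = 10,
                                      bands = band_specs(),
                                      filters = wpt_filters()) {
  ne <- n_epochs(es)
  stopifnot(ne > 0)
  first <- extract_features(
    `rownames<-`(es$data[, , 1], es$channels), es$fs, level, frames_per_s,
    bands, filters)
  x <- array(0, c(nrow(first), ncol(first), ne))
  x[, , 1] <- first
  if (ne > 1) {
    for (i in 2:ne) {
      x[, , i] <- extract_features(
        `rownames<-`(es$data[, , i], es$channels), es$fs, level,
        frames_per_s, bands, filters)
    }
  }
  list(x = x, label = es$label, origin = es$origin,
       streams = colnames(first))
}

#' Per-stream standardization statistics
#'
#' Mean and standard deviation of every feature stream over a (training)
#' feature array, for z-scoring before the recurrent models.
#'
#' @param x Feature array T x streams x n (or a T x streams matrix).
#' @return List with `mean` and `sd` per stream.
#' @export
feature_stats <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  ns <- dim(x)[2]
  mu <- numeric(ns)
  sdv <- numeric(ns)
  for (s in seq_len(ns)) {
    v <- as.vector(x[, s, ])
    mu[s] <- mean(v)
    sdv[s] <- sd(v)
    if (!is.finite(sdv[s]) || sdv[s] < 1e-12) sdv[s] <- 1
  }
  list(mean = mu, sd = sdv)
}

#' Apply standardization statistics
#'
#' @param x Feature array T x streams x n or matrix T x streams.
#' @param stats A [feature_stats()] result.
#' @return Standardized array/matrix of the same shape.
#' @export
apply_feature_stats <- function(x, stats) {
  if (length(dim(x)) == 2) {
    return(sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/"))
  }
  for (i in seq_len(dim(x)[3])) {
    x[, , i] <- sweep(sweep(x[, , i], 2, stats$mean), 2, stats$sd, "/")
  }
  x
}
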