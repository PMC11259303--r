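#' Construct an EEG recording
#'
#' Container for a continuous multi-channel EEG signal in microvolts.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel names (10-20 labels), one
#'   per row of `data`.
#' @param start_time_s Start time of the first sample, seconds.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channels`, `start_time_s`.
#' @export
eeg_recording <- function(data, fs, channels, start_time_s = 0) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (length(channels) != nrow(data)) {
    stop("`channels` must name every row of `data` (",
         nrow(data), " channels, ", length(channels), " names)")
  }
  if (anyDuplicated(channels)) stop("channel names must be unique")
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         start_time_s = start_time_s),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct an epoch set
#'
#' Fixed-width, non-overlapping EEG windows cut from one or more
#' recordings, each optionally carrying a binary state label and its
#' provenance.
#'
#' @param data 3-d numeric array, channels x samples x epochs.
#' @param fs Sampling rate in Hz.
#' @param window_s Window width in seconds.
#' @param channels Channel names.
#' @param label Optional integer vector (0 = normal, 1 = sickness), one
#'   per epoch.
#' @param origin Optional data.frame with one row per epoch (subject_id,
#'   video_id, offset_s, ...).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, window_s, channels, label = NULL,
                      origin = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_ep <- dim(data)[3]
  if (dim(data)[2] != round(window_s * fs)) {
    stop("each epoch must have window_s * fs samples")
  }
  if (!is.null(label) && length(label) != n_ep) {
    stop("one label per epoch required")
  }
  if (!is.null(origin) && nrow(origin) != n_ep) {
    stop("one origin row per epoch required")
  }
  structure(
    list(data = data, fs = fs, window_s = window_s,
         channels = as.character(channels), label = label, origin = origin),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d channels @ %g Hz)\n",
              n_epochs(x), x$window_s, dim(x$data)[1], x$fs))
  if (!is.null(x$label)) {
    cat(sprintf("  labels: %d normal / %d sickness\n",
                sum(x$label == 0), sum(x$label == 1)))
  }
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(es) dim(es$data)[3]

#' Combine epoch sets
#' @param ... `epoch_set` objects with identical channels, fs and window.
#' @return A single `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  ref <- sets[[1]]
  for (s in sets) {
    stopifnot(identical(s$channels, ref$channels), s$fs == ref$fs,
              s$window_s == ref$window_s)
  }
  dat <- array(0, c(dim(ref$data)[1], dim(ref$data)[2],
                    sum(vapply(sets, n_epochs, 0L))))
  lab <- NULL
  org <- NULL
  k <- 0
  for (s in sets) {
    idx <- seq_len(n_epochs(s)) + k
    dat[, , idx] <- s$data
    if (!is.null(s$label)) lab <- c(lab, s$label)
    if (!is.null(s$origin)) org <- rbind(org, s$origin)
    k <- k + n_epochs(s)
  }
  epoch_set(dat, ref$fs, ref$window_s, ref$channels, label = lab,
            origin = org)
}
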