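# Run configuration: YAML in, schema-checked, defaults filled, unknown
# keys rejected.

#' Default run configuration
#'
#' @return Nested list with sections `sim`, `preprocess`, `features`,
#'   `train`, `evaluate` and a global `seed`.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    sim = list(n_subjects = 25, n_videos = 20, duration_s = 120, fs = 500,
               channels = c("FP1", "FP2", "C3", "C4", "P3", "P4",
                            "O1", "O2", "M1", "M2"),
               contrast = 1, pink_noise_sd = 2, white_noise_sd = 1,
               onset_s = 56, onset_slope = 0.25),
    preprocess = list(low_hz = 0.5, high_hz = 50,
                      channels = c("FP1", "FP2", "C3", "C4", "P3", "P4",
                                   "O1", "O2"),
                      reference = "mastoids", pca_var_threshold = 0.35,
                      pca_kurtosis_threshold = 8, window_s = 10),
    features = list(wpt_level = 8, frames_per_s = 10),
    train = list(epochs = 50, batch = 4, lr = 5e-5, beta1 = 0.9,
                 beta2 = 0.999, weight_decay = 1e-8, hidden = 32),
    evaluate = list(threshold = 0.5, positive = 1)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section ", path, " must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown
#' keys, and checks cross-field constraints: the window must hold a whole
#' number of samples, it must be long enough for the wavelet packet
#' depth, and the filter band must sit inside the Nyquist range.
#'
#' @param path_or_list Path to a YAML file, a list, or `NULL` (defaults).
#' @return The resolved configuration (class `run_config`).
#' @export
validate_config <- function(path_or_list = NULL) {
  user <- path_or_list
  if (is.character(user)) {
    if (!file.exists(user)) stop("config file not found: ", user)
    user <- yaml::read_yaml(user)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(default_run_config(), user)
  fs <- cfg$sim$fs
  w <- cfg$preprocess$window_s
  if (abs(w * fs - round(w * fs)) > 1e-9) {
    stop("preprocess.window_s: window_s * fs must be a whole sample count")
  }
  n_win <- round(w * fs)
  if (n_win < 2^cfg$features$wpt_level) {
    stop(sprintf(
      "features.wpt_level: window of %d samples is shorter than 2^%d",
      n_win, cfg$features$wpt_level))
  }
  if (!(cfg$preprocess$low_hz > 0 &&
        cfg$preprocess$low_hz < cfg$preprocess$high_hz &&
        cfg$preprocess$high_hz < fs / 2)) {
    stop("preprocess: band edges must satisfy 0 < low < high < fs/2")
  }
  if (!cfg$preprocess$reference %in% c("mastoids", "average")) {
    stop("preprocess.reference must be \"mastoids\" or \"average\"")
  }
  class(cfg) <- "run_config"
  cfg
}

config_sim <- function(cfg) {
  sim_config(
    n_subjects = cfg$sim$n_subjects, n_videos = cfg$sim$n_videos,
    duration_s = cfg$sim$duration_s, fs = cfg$sim$fs,
    channels = cfg$sim$channels,
    band_amplitude_table = default_band_amplitudes(cfg$sim$contrast),
    pink_noise_sd = cfg$sim$pink_noise_sd,
    white_noise_sd = cfg$sim$white_noise_sd,
    onset_s = cfg$sim$onset_s, onset_slope = cfg$sim$onset_slope,
    seed = cfg$seed
  )
}
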