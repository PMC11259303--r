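# Synthetic EEG + SSQ corpus generator. The generator is the package's
# canonical test input: recordings are band-limited random-tone mixtures
# whose delta/theta/alpha/beta amplitudes depend on scalp region and on
# the normal vs. motion-sickness state, over a pink + white noise floor.

# Run `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default per-region band amplitude table
#'
#' Amplitudes (microvolt) of each EEG rhythm per scalp region and state.
#' The sickness column encodes the qualitative pattern reported for VIMS:
#' broadband increase over frontal and temporal cortex, reduced alpha with
#' increased beta over central and occipital cortex, and the same pattern
#' minus the beta increase over parietal cortex.
#'
#' @param contrast Scales the normal-to-sickness amplitude difference;
#'   `contrast = 0` makes both states identical (chance-level corpus),
#'   `contrast = 1` is the default separable corpus.
#' @return data.frame with columns `region`, `band`, `normal`, `sickness`.
#' @export
default_band_amplitudes <- function(contrast = 1) {
  tab <- expand.grid(
    region = c("frontal", "central", "parietal", "occipital", "temporal"),
    band = c("delta", "theta", "alpha", "beta"),
    stringsAsFactors = FALSE
  )
  normal <- c(
    frontal_delta = 8, central_delta = 8, parietal_delta = 8,
    occipital_delta = 8, temporal_delta = 8,
    frontal_theta = 6, central_theta = 6, parietal_theta = 6,
    occipital_theta = 6, temporal_theta = 6,
    frontal_alpha = 5, central_alpha = 7, parietal_alpha = 8,
    occipital_alpha = 10, temporal_alpha = 5,
    frontal_beta = 3, central_beta = 3, parietal_beta = 3,
    occipital_beta = 3, temporal_beta = 3
  )
  sickness <- c(
    frontal_delta = 13, central_delta = 8, parietal_delta = 8,
    occipital_delta = 8, temporal_delta = 13,
    frontal_theta = 10, central_theta = 6, parietal_theta = 6,
    occipital_theta = 6, temporal_theta = 10,
    frontal_alpha = 8, central_alpha = 4, parietal_alpha = 5,
    occipital_alpha = 6, temporal_alpha = 8,
    frontal_beta = 5, central_beta = 6, parietal_beta = 3,
    occipital_beta = 6, temporal_beta = 5
  )
  key <- paste(tab$region, tab$band, sep = "_")
  tab$normal <- unname(normal[key])
  tab$sickness <- tab$normal + contrast * (unname(sickness[key]) - tab$normal)
  tab
}

#' Simulation configuration
#'
#' Study-shaped defaults: 25 subjects x 20 videos, two minutes of EEG per
#' state per video, 500 Hz, the 8 analysis channels plus both mastoids.
#'
#' @param n_subjects,n_videos Corpus shape.
#' @param duration_s Seconds of EEG per state per (subject, video).
#' @param fs Sampling rate, Hz.
#' @param channels Channel names; every one must map to a region via
#'   [channel_region()].
#' @param band_amplitude_table See [default_band_amplitudes()].
#' @param pink_noise_sd,white_noise_sd Background noise levels, microvolt.
#' @param onset_s Latent sickness onset time for transition recordings.
#' @param onset_slope Logistic slope (1/s) of the latent ramp.
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 25, n_videos = 20, duration_s = 120,
                       fs = 500,
                       channels = c("FP1", "FP2", "C3", "C4", "P3", "P4",
                                    "O1", "O2", "M1", "M2"),
                       band_amplitude_table = default_band_amplitudes(),
                       pink_noise_sd = 2, white_noise_sd = 1,
                       onset_s = 56, onset_slope = 0.25, seed = 1) {
  stopifnot(fs > 0, duration_s > 0)
  if (n_subjects < 1 || n_videos < 1) {
    stop("n_subjects and n_videos must be at least 1")
  }
  channel_region(channels)  # errors on unmapped channels
  if (any(band_amplitude_table$normal < 0) ||
      any(band_amplitude_table$sickness < 0)) {
    stop("band amplitudes must be nonnegative")
  }
  structure(
    list(n_subjects = n_subjects, n_videos = n_videos,
         duration_s = duration_s, fs = fs, channels = channels,
         band_amplitude_table = band_amplitude_table,
         pink_noise_sd = pink_noise_sd, white_noise_sd = white_noise_sd,
         onset_s = onset_s, onset_slope = onset_slope, seed = seed),
    class = "sim_config"
  )
}

#' Latent sickness trajectory
#'
#' Nondecreasing logistic ramp from 0 towards `level`, reaching half its
#' height at `onset_s`.
#'
#' @param t Time points, seconds.
#' @param onset_s Onset (half-maximum) time, seconds.
#' @param slope Logistic slope, 1/s.
#' @param level Asymptotic level in `[0, 1]`.
#' @return Numeric vector of levels in `[0, level]`.
#' @export
latent_trajectory <- function(t, onset_s = 56, slope = 0.25, level = 1) {
  stopifnot(level >= 0, level <= 1, slope > 0)
  level * plogis(slope * (t - onset_s))
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise,
# rescaled to the requested standard deviation.
pink_noise <- function(n, sd_uv) {
  if (sd_uv <= 0) return(numeric(n))
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)          # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  sp <- sp * shape
  x <- Re(fft(sp, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_uv / sd(x)
}

# Sum of `k` random-frequency tones inside [low, high) Hz with total
# power equal to a single tone of amplitude `amp`.
band_tones <- function(n, fs, low, high, amp, k = 3) {
  if (amp <= 0) return(numeric(n))
  t <- seq(0, by = 1 / fs, length.out = n)
  margin <- 0.05 * (high - low)
  freqs <- runif(k, low + margin, high - margin)
  phases <- runif(k, 0, 2 * pi)
  x <- numeric(n)
  for (i in seq_len(k)) {
    x <- x + (amp / sqrt(k)) * sin(2 * pi * freqs[i] * t + phases[i])
  }
  x
}

# Effective amplitude table for a state at a given severity: sickness
# amplitudes are interpolated between the normal and full-sickness
# columns.
effective_amplitudes <- function(tab, state, severity) {
  if (state == "normal") return(stats::setNames(tab$normal,
                                                paste(tab$region, tab$band)))
  stats::setNames(tab$normal + severity * (tab$sickness - tab$normal),
                  paste(tab$region, tab$band))
}

#' Simulate one EEG recording
#'
#' Each non-mastoid channel is a sum over the four rhythm bands of
#' random-phase tones with the region/band/state amplitude from the
#' configuration table, plus pink and white noise. Mastoid channels carry
#' reference noise only.
#'
#' @param config A [sim_config()].
#' @param state `"normal"` or `"sickness"`.
#' @param severity Sickness severity in `[0, 1]`; scales the amplitude
#'   contrast of the sickness state. Ignored for `"normal"`.
#' @param seed Integer seed; identical `(config, state, severity, seed)`
#'   reproduce the recording exactly.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(config, state = c("normal", "sickness"),
                               severity = 1, seed = config$seed) {
  state <- match.arg(state)
  stopifnot(severity >= 0, severity <= 1)
  n <- round(config$duration_s * config$fs)
  regions <- channel_region(config$channels)
  amps <- effective_amplitudes(config$band_amplitude_table, state, severity)
  bands <- band_specs()
  with_seed(seed, {
    data <- matrix(0, length(config$channels), n)
    for (ci in seq_along(config$channels)) {
      x <- numeric(n)
      if (regions[ci] != "mastoid") {
        for (bi in seq_len(nrow(bands))) {
          a <- amps[paste(regions[ci], bands$band[bi])]
          x <- x + band_tones(n, config$fs, bands$low_hz[bi],
                              bands$high_hz[bi], a)
        }
      }
      x <- x + pink_noise(n, config$pink_noise_sd)
      if (config$white_noise_sd > 0) {
        x <- x + rnorm(n, sd = config$white_noise_sd)
      }
      data[ci, ] <- x
    }
    eeg_recording(data, config$fs, config$channels)
  })
}

#' Simulate a recording with a sickness onset
#'
#' Blends a normal-state and a sickness-state signal sample-by-sample
#' with the latent trajectory `m(t)`, emulating a subject who becomes
#' motion-sick partway through a session.
#'
#' @param config A [sim_config()].
#' @param severity Severity reached after the onset, in `[0, 1]`.
#' @param onset_s,slope Passed to [latent_trajectory()].
#' @param seed Integer seed.
#' @return A list with `recording` (an [eeg_recording()]) and
#'   `trajectory` (the latent level at every sample).
#' @export
simulate_transition_recording <- function(config, severity = 1,
                                          onset_s = config$onset_s,
                                          slope = config$onset_slope,
                                          seed = config$seed) {
  n <- round(config$duration_s * config$fs)
  t <- seq(0, by = 1 / config$fs, length.out = n)
  m <- latent_trajectory(t, onset_s, slope, level = 1)
  regions <- channel_region(config$channels)
  amps_n <- effective_amplitudes(config$band_amplitude_table, "normal", 0)
  amps_s <- effective_amplitudes(config$band_amplitude_table, "sickness",
                                 severity)
  bands <- band_specs()
  rec <- with_seed(seed, {
    data <- matrix(0, length(config$channels), n)
    for (ci in seq_along(config$channels)) {
      x <- numeric(n)
      if (regions[ci] != "mastoid") {
        xn <- numeric(n)
        xs <- numeric(n)
        for (bi in seq_len(nrow(bands))) {
          lo <- bands$low_hz[bi]; hi <- bands$high_hz[bi]
          xn <- xn + band_tones(n, config$fs, lo, hi,
                                amps_n[paste(regions[ci], bands$band[bi])])
          xs <- xs + band_tones(n, config$fs, lo, hi,
                                amps_s[paste(regions[ci], bands$band[bi])])
        }
        x <- (1 - m) * xn + m * xs
      }
      x <- x + pink_noise(n, config$pink_noise_sd)
      if (config$white_noise_sd > 0) {
        x <- x + rnorm(n, sd = config$white_noise_sd)
      }
      data[ci, ] <- x
    }
    eeg_recording(data, config$fs, config$channels)
  })
  list(recording = rec, trajectory = severity * m)
}

#' Simulate a 16-item SSQ response
#'
#' Item scores are drawn from a binomial(3, p) distribution whose success
#' probability grows linearly with the latent end-of-session sickness
#' level, giving an ordered categorical response whose mean is strictly
#' increasing in `m_end`. `m_end = 0` forces an all-zero response.
#'
#' @param m_end Latent sickness level at the end of the session, `[0, 1]`.
#' @param seed Integer seed.
#' @param item_weights Per-item susceptibility in `[0, 1]` (length 16);
#'   `rep(1, 16)` makes `m_end = 1` deterministic (all items 3).
#' @return Integer vector of 16 item scores in 0..3.
#' @export
simulate_ssq <- function(m_end, seed = 1,
                         item_weights = seq(0.95, 0.65,
                                            length.out = 16)) {
  if (!is.numeric(m_end) || length(m_end) != 1 || m_end < 0 || m_end > 1) {
    stop("`m_end` must be a single value in [0, 1]")
  }
  stopifnot(length(item_weights) == 16, all(item_weights >= 0),
            all(item_weights <= 1))
  with_seed(seed, {
    as.integer(rbinom(16, size = 3, prob = m_end * item_weights))
  })
}

#' Simulate a labelled EEG + SSQ corpus
#'
#' For every (subject, video) pair one normal and one sickness recording
#' of `config$duration_s` seconds are generated; the sickness severity
#' varies across videos (ramp) and subjects (jitter), and each sickness
#' recording's SSQ response is drawn at that severity. Recordings are run
#' through the standard preprocessing chain (band-pass, PCA artifact
#' check, mastoid re-reference, 8-channel selection) and cut into
#' `window_s`-second epochs labelled 0 (normal) / 1 (sickness).
#'
#' @param config A [sim_config()].
#' @param window_s Epoch width in seconds.
#' @param preprocess Apply the preprocessing chain before epoching.
#' @param keep_recordings Also return the raw recordings (memory-heavy).
#' @return A `vims_dataset`: list with `epochs` (labelled [epoch_set()]
#'   whose `origin` carries subject, video, state, severity), `ssq`
#'   (data.frame subject_id, video_id, item_1..item_16, severity), and
#'   the generating `config` / `window_s`.
#' @export
simulate_dataset <- function(config, window_s = 10, preprocess = TRUE,
                             keep_recordings = FALSE) {
  ns <- config$n_subjects
  nv <- config$n_videos
  plan <- with_seed(config$seed, {
    video_base <- seq(0.45, 0.95, length.out = nv)
    sev <- matrix(0, ns, nv)
    for (i in seq_len(ns)) {
      sev[i, ] <- pmin(1, pmax(0.35, video_base + rnorm(nv, sd = 0.08)))
    }
    seeds <- matrix(sample.int(.Machine$integer.max, ns * nv * 3), ncol = 3)
    list(sev = sev, seeds = seeds)
  })
  sets <- vector("list", ns * nv * 2)
  recs <- if (keep_recordings) list() else NULL
  ssq <- NULL
  k <- 0
  row <- 0
  for (i in seq_len(ns)) {
    for (v in seq_len(nv)) {
      row <- row + 1
      sev <- plan$sev[i, v]
      rec_n <- simulate_recording(config, "normal",
                                  seed = plan$seeds[row, 1])
      rec_s <- simulate_recording(config, "sickness", severity = sev,
                                  seed = plan$seeds[row, 2])
      if (keep_recordings) {
        recs[[sprintf("s%02d_v%02d_normal", i, v)]] <- rec_n
        recs[[sprintf("s%02d_v%02d_sickness", i, v)]] <- rec_s
      }
      if (preprocess) {
        rec_n <- preprocess_recording(rec_n)
        rec_s <- preprocess_recording(rec_s)
      }
      es_n <- segment_windows(rec_n, window_s)
      es_s <- segment_windows(rec_s, window_s)
      for (es in list(list(es_n, 0L, "normal"), list(es_s, 1L, "sickness"))) {
        ne <- n_epochs(es[[1]])
        es[[1]]$label <- rep(es[[3]] == "sickness", ne) * 1L
        es[[1]]$origin <- data.frame(
          subject_id = rep(i, ne), video_id = rep(v, ne),
          state = rep(es[[3]], ne),
          severity = rep(if (es[[3]] == "sickness") sev else 0, ne),
          offset_s = es[[1]]$origin$offset_s
        )
        k <- k + 1
        sets[[k]] <- es[[1]]
      }
      items <- simulate_ssq(sev, seed = plan$seeds[row, 3])
      ssq_row <- data.frame(subject_id = i, video_id = v, severity = sev)
      ssq_row[paste0("item_", 1:16)] <- as.list(items)
      ssq <- rbind(ssq, ssq_row)
    }
  }
  out <- list(epochs = bind_epochs(sets[seq_len(k)]), ssq = ssq,
              config = config, window_s = window_s)
  if (keep_recordings) out$recordings <- recs
  class(out) <- "vims_dataset"
  out
}

#' @export
print.vims_dataset <- function(x, ...) {
  cat(sprintf("<vims_dataset> %d subjects x %d videos, %g s per state\n",
              x$config$n_subjects, x$config$n_videos, x$config$duration_s))
  print(x$epochs)
  invisible(x)
}
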