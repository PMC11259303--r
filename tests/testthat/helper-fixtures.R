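# Shared fixtures: tiny simulation configs, spectral oracles, and a
# lazily built acceptance-scale corpus reused by the end-to-end tests.

eight_channels <- c("FP1", "FP2", "C3", "C4", "P3", "P4", "O1", "O2")
ten_channels <- c(eight_channels, "M1", "M2")

# Independent periodogram band-power oracle (plain FFT, no package code).
band_power_frac <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lo & f < hi]) / sum(p)
}

tiny_config <- function(...) {
  sim_config(n_subjects = 2, n_videos = 2, duration_s = 20, seed = 5, ...)
}

# Silent-background config: one single band amplitude on one region.
single_band_config <- function(region, band, amp, duration_s = 20) {
  tab <- default_band_amplitudes()
  tab$normal <- 0
  tab$sickness <- 0
  tab$normal[tab$region == region & tab$band == band] <- amp
  sim_config(n_subjects = 1, n_videos = 1, duration_s = duration_s,
             band_amplitude_table = tab, pink_noise_sd = 0,
             white_noise_sd = 0, seed = 9)
}

# Acceptance-scale corpus (~1080 ten-second epochs over 9 subjects),
# built once per test run and shared between the end-to-end tests.
.corpus_cache <- new.env(parent = emptyenv())

acceptance_corpus <- function(contrast = 1, seed = 11) {
  key <- paste0("c", contrast, "_s", seed)
  if (is.null(.corpus_cache[[key]])) {
    cfg <- sim_config(
      n_subjects = 9, n_videos = 6, duration_s = 100,
      band_amplitude_table = default_band_amplitudes(contrast),
      seed = seed)
    ds <- simulate_dataset(cfg, window_s = 10)
    feats <- extract_features_epochset(ds$epochs)
    .corpus_cache[[key]] <- list(config = cfg, ds = ds, feats = feats)
  }
  .corpus_cache[[key]]
}

.model_cache <- new.env(parent = emptyenv())

acceptance_classifier <- function() {
  if (is.null(.model_cache$classifier)) {
    corp <- acceptance_corpus()
    .model_cache$classifier <- train_classifier(
      corp$feats, cfg = train_config(seed = 11))
  }
  .model_cache$classifier
}

acceptance_predictor <- function() {
  if (is.null(.model_cache$predictor)) {
    corp <- acceptance_corpus()
    scored <- score_ssq_table(corp$ds$ssq)
    key <- paste(scored$subject_id, scored$video_id)
    tot <- scored$total_norm[match(paste(corp$feats$origin$subject_id,
                                         corp$feats$origin$video_id), key)]
    targets <- ifelse(corp$feats$label == 1, tot, 0)
    .model_cache$predictor <- list(
      model = train_predictor(corp$feats, targets,
                              cfg = train_config(seed = 11)),
      targets = targets)
  }
  .model_cache$predictor
}
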