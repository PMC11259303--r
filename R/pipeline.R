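# Stage runner: ties simulation, preprocessing, feature extraction, SSQ
# scoring, training, prediction and evaluation into reproducible
# filesystem stages under one run directory. Each stage writes its
# artifacts plus a manifest (resolved config, seed, package version) so a
# run can be recreated exactly.

run_manifest <- function(run_dir, cfg, stage) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("vimseeg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(run_dir, paste0("manifest_", stage,
                                                       ".yaml")))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic corpus: epochs, SSQ table), `features`
#' (wavelet-packet feature tensors), `score-ssq` (scored SSQ CSV),
#' `train-classifier`, `train-predictor`, `predict` (sliding-window
#' trajectory on a transition recording), `evaluate` (held-out test
#' metrics as JSON). Stages read the artifacts of earlier stages from
#' `run_dir` and never mutate them. `preprocess` runs inside `simulate`
#' for synthetic corpora but is also available standalone for a
#' recording file.
#'
#' @param name Stage name.
#' @param config A [validate_config()] result (or anything it accepts).
#' @param run_dir Artifact directory (created if missing).
#' @param input Optional input file for `preprocess` / `predict` (an EDF
#'   or CSV recording).
#' @param verbose Log per-stage progress.
#' @return Invisibly, the paths written by the stage.
#' @export
run_command <- function(name = c("simulate", "preprocess", "features",
                                 "score-ssq", "train-classifier",
                                 "train-predictor", "predict", "evaluate"),
                        config = NULL, run_dir = "vimseeg_run",
                        input = NULL, verbose = TRUE) {
  name <- match.arg(name)
  cfg <- validate_config(config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- switch(
    name,
    "simulate" = {
      sc <- config_sim(cfg)
      ds <- simulate_dataset(sc, window_s = cfg$preprocess$window_s)
      p1 <- file.path(run_dir, "epochs.rds")
      p2 <- file.path(run_dir, "ssq.csv")
      saveRDS(ds$epochs, p1)
      write.csv(ds$ssq, p2, row.names = FALSE)
      c(p1, p2)
    },
    "preprocess" = {
      if (is.null(input)) stop("preprocess needs an input recording file")
      rec <- read_recording(input)
      rec <- preprocess_recording(
        rec, low_hz = cfg$preprocess$low_hz,
        high_hz = cfg$preprocess$high_hz,
        channels = cfg$preprocess$channels,
        reference = cfg$preprocess$reference,
        var_threshold = cfg$preprocess$pca_var_threshold,
        kurt_threshold = cfg$preprocess$pca_kurtosis_threshold)
      p <- file.path(run_dir, "preprocessed.csv")
      write_recording_csv(rec, p)
      p
    },
    "features" = {
      es <- readRDS(file.path(run_dir, "epochs.rds"))
      feats <- extract_features_epochset(
        es, level = cfg$features$wpt_level,
        frames_per_s = cfg$features$frames_per_s)
      p <- file.path(run_dir, "features.rds")
      saveRDS(feats, p)
      p
    },
    "score-ssq" = {
      ssq <- read.csv(file.path(run_dir, "ssq.csv"))
      scored <- score_ssq_table(ssq)
      p <- file.path(run_dir, "ssq_scored.csv")
      write.csv(scored, p, row.names = FALSE)
      p
    },
    "train-classifier" = {
      feats <- readRDS(file.path(run_dir, "features.rds"))
      tc <- train_config(window_s = cfg$preprocess$window_s,
                         epochs = cfg$train$epochs, batch = cfg$train$batch,
                         lr = cfg$train$lr, beta1 = cfg$train$beta1,
                         beta2 = cfg$train$beta2,
                         weight_decay = cfg$train$weight_decay,
                         hidden = cfg$train$hidden,
                         frames_per_s = cfg$features$frames_per_s,
                         seed = cfg$seed)
      model <- train_classifier(feats, cfg = tc)
      p1 <- file.path(run_dir, "classifier.rds")
      p2 <- file.path(run_dir, "classifier_history.csv")
      saveRDS(model, p1)
      write.csv(model$history, p2, row.names = FALSE)
      c(p1, p2)
    },
    "train-predictor" = {
      feats <- readRDS(file.path(run_dir, "features.rds"))
      scored <- score_ssq_table(read.csv(file.path(run_dir, "ssq.csv")))
      key <- paste(scored$subject_id, scored$video_id)
      tot <- scored$total_norm[match(paste(feats$origin$subject_id,
                                           feats$origin$video_id), key)]
      targets <- ifelse(feats$label == 1, tot, 0)
      tc <- train_config(window_s = cfg$preprocess$window_s,
                         epochs = cfg$train$epochs, batch = cfg$train$batch,
                         lr = cfg$train$lr, hidden = cfg$train$hidden,
                         frames_per_s = cfg$features$frames_per_s,
                         seed = cfg$seed)
      model <- train_predictor(feats, targets, cfg = tc)
      p1 <- file.path(run_dir, "predictor.rds")
      p2 <- file.path(run_dir, "predictor_history.csv")
      saveRDS(model, p1)
      write.csv(model$history, p2, row.names = FALSE)
      c(p1, p2)
    },
    "predict" = {
      model <- readRDS(file.path(run_dir, "predictor.rds"))
      if (is.null(input)) {
        sc <- config_sim(cfg)
        tr <- simulate_transition_recording(sc, seed = cfg$seed + 7)
        rec <- preprocess_recording(tr$recording)
      } else {
        rec <- read_recording(input)
        if (!setequal(rec$channels, cfg$preprocess$channels)) {
          rec <- preprocess_recording(rec)
        }
      }
      traj <- predict_timeseries(model, rec,
                                 level = cfg$features$wpt_level)
      p <- file.path(run_dir, "trajectory.csv")
      write.csv(traj, p, row.names = FALSE)
      p
    },
    "evaluate" = {
      feats <- readRDS(file.path(run_dir, "features.rds"))
      model <- readRDS(file.path(run_dir, "classifier.rds"))
      te <- model$split$test
      prob <- predict(model, feats$x[, , te, drop = FALSE])
      pred <- as.integer(prob > cfg$evaluate$threshold)
      rep <- eval_report(labels = feats$label[te], preds = pred,
                         positive = cfg$evaluate$positive)
      m <- rep$classification
      p1 <- file.path(run_dir, "evaluation.json")
      p2 <- file.path(run_dir, "confusion.csv")
      jsonlite::write_json(
        list(acc = m$acc, sen = m$sen, spe = m$spe, n = length(te),
             positive = m$positive),
        p1, auto_unbox = TRUE, digits = NA)
      write.csv(as.data.frame(rep$confusion$table), p2)
      c(p1, p2)
    }
  )
  run_manifest(run_dir, cfg, name)
  stage_log(verbose, "%s finished in %.1f s -> %s", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            paste(basename(paths), collapse = ", "))
  invisible(paths)
}
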