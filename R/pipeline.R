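#' Pipeline configuration
#'
#' Assembles and validates every tunable of the end-to-end pipeline in one
#' list: cohort simulation, preprocessing widths, network parameters,
#' classifier cost and the sweep grid. `target_len` must equal `m * n` and
#' the network constraints are revalidated here, so a bad configuration fails
#' at load time, not mid-run.
#'
#' @param ... Overrides of the defaults (see the function body for names), or
#'   a single `file` argument naming a JSON file of overrides.
#' @param file Optional path to a JSON config file; entries override
#'   defaults, and explicit `...` arguments override the file.
#' @return A validated list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(n_subjects = 5, records_per_subject = 4)
#' cfg$target_len
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    # cohort
    n_subjects = 20, records_per_subject = 20, duration = 10, fs = 500,
    n_leads = 1, rr_jitter_sd = 0.02,
    baseline_wander_amp = 0.1, baseline_wander_freq = 0.3,
    white_noise_sd = 0.02, spike_rate = 0.2, spike_amp = 0.5,
    # preprocessing
    target_len = 784, m = 28, n = 28,
    baseline_width = 500, smooth_width = 10, window = 400,
    refractory = 0.3, rel_threshold = 0.5,
    # network (Table-style names)
    k1 = 7, k2 = 7, L1 = 8, L2 = 8, h1 = 7, h2 = 7, R = 0.5,
    pad_before_blocks = TRUE,
    # classifier / sweep
    C = 1.0, l2_normalize = FALSE,
    sweep_h = c(6, 8), sweep_k = c(3, 5, 7), sweep_L = c(3, 5, 8),
    sweep_R = c(0.5, 0.6),
    seed = 1
  )
  if (!is.null(file)) {
    loaded <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(loaded)] <- loaded
  }
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) abort(paste("unknown config keys:",
                                 paste(bad, collapse = ", ")))
    cfg[names(overrides)] <- overrides
  }
  if (cfg$target_len != cfg$m * cfg$n)
    abort("target_len must equal m * n")
  pcanet_params(cfg$k1, cfg$k2, cfg$L1, cfg$L2, cfg$h1, cfg$h2, cfg$R,
                cfg$pad_before_blocks)   # revalidate constraints
  noise_spec(cfg$baseline_wander_amp, cfg$baseline_wander_freq,
             cfg$white_noise_sd, cfg$spike_rate, cfg$spike_amp)
  structure(cfg, class = "pipeline_config")
}

config_noise <- function(cfg) {
  noise_spec(cfg$baseline_wander_amp, cfg$baseline_wander_freq,
             cfg$white_noise_sd, cfg$spike_rate, cfg$spike_amp)
}

config_params <- function(cfg) {
  pcanet_params(cfg$k1, cfg$k2, cfg$L1, cfg$L2, cfg$h1, cfg$h2, cfg$R,
                cfg$pad_before_blocks)
}

log_run <- function(out_dir, command, seed, cfg) {
  line <- data.frame(command = command, seed = seed,
                     config_hash = rlang::hash(unclass(cfg)))
  lf <- file.path(out_dir, "run_log.tsv")
  write.table(line, lf, sep = "\t", row.names = FALSE, quote = FALSE,
              col.names = !file.exists(lf), append = file.exists(lf))
}

read_beats <- function(out_dir) {
  bf <- file.path(out_dir, "beats.tsv")
  if (!file.exists(bf))
    abort("no beat vectors found: run the 'preprocess' stage first")
  df <- read.table(bf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  beat_cols <- grepl("^b[0-9]+$", names(df))
  tibble::tibble(record_id = df$record_id, subject_id = df$subject_id,
                 split = df$split,
                 beat = lapply(seq_len(nrow(df)),
                               function(i) as.numeric(df[i, beat_cols])))
}

#' Run one stage of the identification pipeline
#'
#' Stages write plain-text artifacts under `out_dir` and log their
#' parameters, so a full run is `simulate`, `preprocess`, `train`,
#' `evaluate` (and optionally `sweep`) with the same config and seed;
#' identical config and seed reproduce identical artifacts.
#'
#' * `simulate` — write a synthetic cohort (`cohort/` + manifest);
#' * `preprocess` — beat vectors for every record (`beats.tsv`);
#' * `train` — fit the filter banks on the train split, extract features,
#'   train the classifier (`model.rds`);
#' * `evaluate` — test-split accuracy (`accuracy.tsv`) and per-class
#'   one-vs-rest confusion counts (`confusion.tsv`);
#' * `sweep` — grid accuracies (`sweep.tsv`).
#'
#' @param command One of `"simulate"`, `"preprocess"`, `"train"`,
#'   `"evaluate"`, `"sweep"`.
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory.
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list of the paths written (for `evaluate`, also the
#'   accuracy).
#' @export
run_pipeline <- function(command, config = pipeline_config(),
                         out_dir = "eecgnet-out", seed = NULL) {
  command <- match.arg(command,
                       c("simulate", "preprocess", "train", "evaluate",
                         "sweep"))
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_run(out_dir, command, seed, config)

  if (command == "simulate") {
    cohort <- generate_cohort(config$n_subjects, config$records_per_subject,
                              config$duration, config$fs, config_noise(config),
                              config$n_leads, seed = seed,
                              rr_jitter_sd = config$rr_jitter_sd)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    message(sprintf("simulate: %d records -> %s/cohort", nrow(cohort),
                    out_dir))
    return(invisible(list(cohort = file.path(out_dir, "cohort"))))
  }

  if (command == "preprocess") {
    cohort <- read_cohort(file.path(out_dir, "cohort"))
    pp <- preprocess_cohort(cohort, config$target_len,
                            baseline_width = config$baseline_width,
                            smooth_width = config$smooth_width,
                            window = config$window,
                            refractory = config$refractory,
                            rel_threshold = config$rel_threshold)
    beats <- do.call(rbind, pp$beat)
    colnames(beats) <- paste0("b", seq_len(ncol(beats)))
    out <- data.frame(record_id = pp$record_id, subject_id = pp$subject_id,
                      split = pp$split, beats, check.names = FALSE)
    bf <- file.path(out_dir, "beats.tsv")
    write.table(out, bf, sep = "\t", row.names = FALSE, quote = FALSE)
    message(sprintf("preprocess: %d beat vectors of length %d -> %s",
                    nrow(out), config$target_len, bf))
    return(invisible(list(beats = bf)))
  }

  if (command == "sweep") {
    pp <- read_beats(out_dir)
    res <- sweep_eecgnet(pp, config$m, config$n,
                         h = config$sweep_h, k = config$sweep_k,
                         L = config$sweep_L, R = config$sweep_R,
                         C = config$C,
                         pad_before_blocks = config$pad_before_blocks)
    sf <- file.path(out_dir, "sweep.tsv")
    write.table(as.data.frame(res), sf, sep = "\t", row.names = FALSE,
                quote = FALSE)
    message(sprintf("sweep: %d grid points -> %s", nrow(res), sf))
    return(invisible(list(sweep = sf)))
  }

  params <- config_params(config)
  pp <- read_beats(out_dir)
  train <- pp[pp$split == "train", ]
  test <- pp[pp$split == "test", ]

  if (command == "train") {
    imgs <- cohort_images(train, config$m, config$n)
    fit <- eecgnet_fit(imgs, params)
    feats <- eecgnet_transform(fit, imgs)
    clf <- train_classifier(feats, train$subject_id, C = config$C,
                            l2_normalize = config$l2_normalize)
    mf <- file.path(out_dir, "model.rds")
    saveRDS(list(network = fit, classifier = clf), mf)
    message(sprintf("train: %d images, feature length %d -> %s",
                    length(imgs), ncol(feats), mf))
    return(invisible(list(model = mf)))
  }

  # evaluate
  mf <- file.path(out_dir, "model.rds")
  if (!file.exists(mf))
    abort("no trained model found: run the 'train' stage first")
  model <- readRDS(mf)
  imgs <- cohort_images(test, config$m, config$n)
  feats <- eecgnet_transform(model$network, imgs)
  pred <- predict(model$classifier, feats)
  acc <- accuracy(pred, test$subject_id)
  af <- file.path(out_dir, "accuracy.tsv")
  write.table(data.frame(n_test = nrow(test), accuracy = acc), af,
              sep = "\t", row.names = FALSE, quote = FALSE)
  cf <- file.path(out_dir, "confusion.tsv")
  write.table(as.data.frame(confusion_counts(pred, test$subject_id)), cf,
              sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("evaluate: accuracy %.2f%% on %d test records -> %s",
                  acc, nrow(test), af))
  invisible(list(accuracy_file = af, confusion = cf, accuracy = acc))
}
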