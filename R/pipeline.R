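# End-to-end experiment orchestration: data -> pretrain S -> train GAN
# and SpineGAN -> generate synthetic sets -> train classifiers on real
# and synthetic -> generative metrics; seeded, logged, resumable.

#' Experiment configuration
#'
#' Bundles every stage's configuration.  All module-level seeds derive
#' deterministically from `seed` via [stage_seed()].  The SpineGAN arm's
#' GAN configuration is forced to differ from the plain arm only in
#' `gamma > 0` and the use of the pretrained network S, so the
#' comparison isolates the guidance term.
#'
#' @param data either a list `list(kind = "phantom", n_normal, n_abnormal,
#'   cfg = phantom_config())` or `list(kind = "dicom", directory,
#'   label_table)`.
#' @param ingest an [ingest_config()] (used for the split, and for DICOM
#'   preprocessing in dicom mode).
#' @param gan a [gan_config()] shared by both arms; the SpineGAN arm
#'   uses `spinegan_gamma`.
#' @param spinegan_gamma positive guidance weight for the SpineGAN arm.
#' @param sampling_n synthetic images per generator arm.
#' @param class_scheme synthetic class composition (see
#'   [sampling_config()]).
#' @param classifier a [classifier_config()] shared by all arms.
#' @param clf_seeds classifier seeds the endpoint is averaged over.
#' @param metrics_k neighbourhood size for precision/recall.
#' @param metrics_n images per side used for the generative metrics.
#' @param seed global seed.
#' @param output_dir directory for checkpoints and the report.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(data = list(kind = "phantom", n_normal = 458L,
                                          n_abnormal = 292L,
                                          cfg = phantom_config()),
                              ingest = ingest_config(target_side = 64L,
                                                     min_dim_threshold = 1L),
                              gan = gan_config(),
                              spinegan_gamma = 1.0,
                              sampling_n = 2000L,
                              class_scheme = "match_real_prior",
                              classifier = classifier_config(),
                              clf_seeds = 1:3,
                              metrics_k = 3L, metrics_n = 300L,
                              seed = 1L,
                              output_dir = tempfile("slx_")) {
  structure(list(data = data, ingest = ingest, gan = gan,
                 spinegan_gamma = spinegan_gamma,
                 sampling_n = as.integer(sampling_n),
                 class_scheme = class_scheme, classifier = classifier,
                 clf_seeds = as.integer(clf_seeds),
                 metrics_k = as.integer(metrics_k),
                 metrics_n = as.integer(metrics_n),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' @param cfg an [experiment_config()].
#' @return character vector of violations; empty iff the configuration
#'   is valid.
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  if (!inherits(cfg, "experiment_config")) {
    return("not an experiment_config object")
  }
  if (!cfg$data$kind %in% c("phantom", "dicom")) {
    say("data$kind: must be 'phantom' or 'dicom'")
  }
  if (cfg$data$kind == "phantom") {
    if ((cfg$data$n_normal %||% 0) + (cfg$data$n_abnormal %||% 0) < 2) {
      say("data: phantom cohort needs n_normal + n_abnormal >= 2")
    }
  } else if (is.null(cfg$data$directory)) {
    say("data$directory: required in dicom mode")
  }
  if (cfg$ingest$split_fraction <= 0 || cfg$ingest$split_fraction >= 1) {
    say("ingest$split_fraction: must lie strictly between 0 and 1")
  }
  if (!is.null(cfg$spinegan_gamma) && cfg$spinegan_gamma <= 0) {
    say("spinegan_gamma: spinegan arm requires gamma > 0")
  }
  if (cfg$gan$total_images_shown < cfg$gan$batch_size) {
    say("gan$total_images_shown: must be at least one batch")
  }
  if (cfg$sampling_n < 1) say("sampling_n: must be at least 1")
  if (length(cfg$clf_seeds) < 1) say("clf_seeds: need at least one seed")
  if (cfg$metrics_k < 1) say("metrics_k: must be at least 1")
  v
}

# run `fn` unless a checkpoint exists; persist the result
run_stage <- function(name, dir, resume, verbose, fn) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (resume && file.exists(path)) {
    if (verbose) message(sprintf("[%s] restored from checkpoint", name))
    return(readRDS(path))
  }
  t0 <- proc.time()[["elapsed"]]
  out <- fn()
  saveRDS(out, path)
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  out
}

#' Run a full synthetic-learning experiment
#'
#' Executes the pipeline end to end and returns the report: per arm
#' (real, GAN-synthetic, SpineGAN-synthetic) the test AUC averaged over
#' classifier seeds, per generator the generative metrics
#' (FID, precision, recall), and the label-fidelity rate (agreement of a
#' reference classifier with the conditioning labels of the synthetic
#' images).  Every stage's artifact is persisted under
#' `cfg$output_dir`; a rerun with `resume = TRUE` skips completed
#' stages and reproduces identical numbers.
#'
#' @param cfg an [experiment_config()] (validated first; violations
#'   abort).
#' @param resume reuse existing stage checkpoints.
#' @param verbose log stage completions.
#' @return an object of class `sl_report`.
#' @export
run_experiment <- function(cfg, resume = TRUE, verbose = TRUE) {
  viol <- validate_config(cfg)
  if (length(viol)) {
    stop("invalid experiment configuration:\n  ",
         paste(viol, collapse = "\n  "))
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  st <- function(name, fn) {
    tryCatch(run_stage(name, cfg$output_dir, resume, verbose, fn),
             error = function(e) {
               stop(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
  }

  data_split <- st("data", function() {
    if (cfg$data$kind == "phantom") {
      ds <- generate_cohort(cfg$data$n_normal, cfg$data$n_abnormal,
                            cfg$data$cfg,
                            seed = stage_seed(cfg$seed, "phantom"))
    } else {
      lk <- if (is.character(cfg$data$label_table)) {
        read_label_table(cfg$data$label_table)
      } else {
        cfg$data$label_table
      }
      ds <- ingest_directory(cfg$data$directory, lk, cfg$ingest)$dataset
    }
    icfg <- cfg$ingest
    icfg$split_seed <- stage_seed(cfg$seed, "split")
    split_dataset(ds, icfg)
  })
  train <- data_split$train
  test <- data_split$test
  test_hash <- param_hash(dataset_pixel_matrix(test))

  s_net <- st("pretrain_s", function() {
    ccfg <- cfg$classifier
    ccfg$augment <- NULL
    ccfg$seed <- stage_seed(cfg$seed, "pretrain_s")
    pretrain_label_network(train, ccfg)
  })

  gan_plain <- st("gan_plain", function() {
    gcfg <- cfg$gan
    gcfg$gamma <- 0
    gcfg$seed <- stage_seed(cfg$seed, "gan_plain")
    train_gan(train, gcfg)
  })

  gan_spine <- st("gan_spine", function() {
    gcfg <- cfg$gan
    gcfg$gamma <- cfg$spinegan_gamma
    gcfg$seed <- stage_seed(cfg$seed, "gan_spine")
    train_gan(train, gcfg, s = s_net)
  })
  generators <- list(gan_synthetic = gan_plain,
                     spinegan_synthetic = gan_spine)

  experiment <- st("classifiers", function() {
    synthetic_learning_experiment(
      train, test, generators, n_synthetic = cfg$sampling_n,
      cfg = cfg$classifier, seeds = cfg$clf_seeds,
      class_scheme = cfg$class_scheme)
  })

  metrics <- st("metrics", function() {
    n_side <- min(cfg$metrics_n, length(test))
    real_ref <- test[seq_len(n_side)]
    synth <- lapply(generators, function(g) {
      generate_synthetic_dataset(
        g, sampling_config(cfg$metrics_n, class_scheme = cfg$class_scheme,
                           seed = stage_seed(cfg$seed, "metrics_sample")))
    })
    metrics_report(real_ref, synth, k = cfg$metrics_k)
  })

  fidelity <- st("label_fidelity", function() {
    rows <- list()
    for (seed in cfg$clf_seeds) {
      c2 <- cfg$classifier
      c2$augment <- NULL
      c2$seed <- stage_seed(seed, "fidelity_ref")
      ref <- train_classifier(train, c2)
      for (arm in names(generators)) {
        syn <- generate_synthetic_dataset(
          generators[[arm]],
          sampling_config(cfg$metrics_n, class_scheme = "balanced",
                          seed = stage_seed(seed,
                                            paste0("fid_sample_", arm))))
        p <- predict_probabilities(ref, syn)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, seed = seed,
          agreement = mean(as.integer(p >= 0.5) ==
                             dataset_binary_labels(syn)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  report <- structure(list(
    summary = experiment$summary, runs = experiment$runs,
    metrics = metrics, label_fidelity = fidelity,
    n_train = length(train), n_test = length(test),
    test_set_hash = test_hash, seed = cfg$seed,
    config = cfg
  ), class = "sl_report")
  saveRDS(report, file.path(cfg$output_dir, "report.rds"))
  write_report_text(report, file.path(cfg$output_dir, "report.txt"))
  report
}

write_report_text <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("seed\t%d", report$seed),
    sprintf("n_train\t%d", report$n_train),
    sprintf("n_test\t%d", report$n_test),
    sprintf("test_set_hash\t%s", report$test_set_hash),
    "", "arm\tauc_mean\tauc_sd"), con)
  utils::write.table(report$summary, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines("", con)
  utils::write.table(report$metrics, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("", con)
  utils::write.table(report$label_fidelity, con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @export
print.sl_report <- function(x, ...) {
  cat("Synthetic-learning experiment report\n")
  cat(sprintf("  train %d / test %d (test hash %s)\n", x$n_train, x$n_test,
              substr(x$test_set_hash, 1, 8)))
  cat("\nClassification endpoint (AUC on shared real test set):\n")
  print(x$summary, row.names = FALSE)
  cat("\nGenerative metrics:\n")
  print(x$metrics, row.names = FALSE)
  cat("\nLabel fidelity (reference-classifier agreement with conditioning labels):\n")
  agg <- tapply(x$label_fidelity$agreement, x$label_fidelity$arm, mean)
  print(round(agg, 4))
  invisible(x)
}
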