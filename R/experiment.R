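#' Run one augmentation experiment end to end
#'
#' Wires the modules into the standard workflow: generate (or accept) an
#' amino-acid dataset, split it by edit distance from wild type, truncate the
#' training fraction with label stratification, prepare train/validation/test
#' sequences under the requested condition, train a reference model, predict
#' on the replicated test sets and aggregate the metric. Every random draw
#' flows from seeds recorded in the returned manifest; rerunning the same
#' config reproduces all numbers exactly.
#'
#' Conditions:
#' \describe{
#'   \item{`aa_baseline`}{train on the amino-acid sequences (scheme
#'     `aa_unigram`).}
#'   \item{`dna_baseline`}{reverse translate once per sequence, no
#'     augmentation; codon sampling per `sampling`.}
#'   \item{`offline`}{offline NTA with `method` (`"iterative"`/`"random"`)
#'     and factor `n_aug`.}
#'   \item{`online`}{random reverse translation plus per-batch probabilistic
#'     augmentation (`t_aug`, `num_subs`), fixed epochs.}
#' }
#'
#' @param config Nested list; see the package vignette. Recognized sections:
#'   `dataset` (either `preset = "gb1_like"`/`"cdrh3_like"` with
#'   `n_variants`, `max_ed`, `noise_sd`, or an `nta_dataset` under `data`),
#'   `split` (`ed_threshold`, `valid_fraction`), `fraction`, `condition`
#'   (`type`, `method`, `n_aug`, `t_aug`, `num_subs`), `table`
#'   (`"natural"`/`"balanced"`/`"shuffled"`), `scheme`, `model` (`family`,
#'   `preset`), `train` (`epochs`, `patience`, `batch_size`, `lr`,
#'   `class_weighted_sampling`), `seed`, and optional `out_dir`. For
#'   classification an optional `imbalance` section (`positive_ratio`)
#'   down-samples positives in the train and validation splits; an
#'   imbalanced offline condition then augments the minority class only,
#'   reverse translating the majority class once per record.
#' @return A list of class `nta_run`: `metric` (an `nta_metric_result` over
#'   the 5 test replicates for this single seed), `per_replicate`,
#'   `valid_metric`, `train_result`, `manifest`.
#' @export
run_experiment <- function(config) {
  config <- validate_run_config(config)
  seed <- config$seed
  table <- resolve_table(config$table, seed)
  ds <- resolve_dataset(config$dataset, seed)
  task <- dataset_meta(ds)$task

  ds <- split_by_edit_distance(
    ds, config$dataset$wild_type, config$split$ed_threshold,
    valid_fraction = config$split$valid_fraction, seed = seed + 11L
  )
  train_aa <- ds[ds$set == "train", ]
  valid_aa <- ds[ds$set == "valid", ]
  test_aa <- as_labeled_dataset(ds[ds$set == "test", ], "amino_acid", task)
  if (config$fraction < 1) {
    train_aa <- stratified_truncate(
      as_labeled_dataset(train_aa, "amino_acid", task),
      config$fraction, seed = seed + 13L
    )
  } else {
    train_aa <- as_labeled_dataset(train_aa, "amino_acid", task)
  }
  valid_aa <- as_labeled_dataset(valid_aa, "amino_acid", task)
  if (!is.null(config$imbalance)) {
    if (task != "classification") {
      abort_ntaug("Config field `imbalance`: needs a classification dataset.",
                  "config_error")
    }
    train_aa <- impose_class_imbalance(
      train_aa, config$imbalance$positive_ratio, seed = seed + 41L
    )
    valid_aa <- impose_class_imbalance(
      valid_aa, config$imbalance$positive_ratio, seed = seed + 43L
    )
  }

  cond <- config$condition
  sampling <- if (identical(cond$method, "iterative")) "deterministic" else "random"
  online_cfg <- NULL
  if (cond$type == "aa_baseline") {
    scheme <- "aa_unigram"
    train_set <- train_aa
    valid_set <- valid_aa
    test_reps <- make_test_replicates_aa(test_aa)
  } else {
    scheme <- config$scheme
    rt <- function(d, s) reverse_translate_dataset(d, table, sampling, s)
    train_set <- switch(cond$type,
      dna_baseline = rt(train_aa, seed + 17L),
      offline = {
        acfg <- aug_config(cond$n_aug, method = cond$method, table = table,
                           seed = seed + 17L)
        # imbalanced classification: augment the minority class only
        if (task == "classification" &&
            sum(train_aa$label == 1) != sum(train_aa$label == 0)) {
          suppressWarnings(augment_minority_class(train_aa, acfg))
        } else {
          suppressWarnings(augment_dataset_offline(train_aa, acfg))
        }
      },
      online = rt(train_aa, seed + 17L)
    )
    if (cond$type == "online") {
      online_cfg <- online_aug_config(
        t_aug = cond$t_aug, num_subs = cond$num_subs,
        table = table, seed = seed + 19L
      )
    }
    valid_set <- rt(valid_aa, seed + 23L)
    test_reps <- make_test_replicates(test_aa, table, mode = sampling,
                                      base_seed = seed + 29L, k = 5L)
  }

  vocab <- build_vocabulary(scheme)
  mcfg <- model_config(config$model$family, task, config$model$preset, scheme)
  model <- build_model(mcfg, vocab, seed = seed + 31L)
  tc <- train_config(
    mode = if (cond$type == "online") "online" else "offline",
    epochs = config$train$epochs, patience = config$train$patience,
    batch_size = config$train$batch_size, lr = config$train$lr,
    seed = seed + 37L, online_cfg = online_cfg,
    class_weighted_sampling = isTRUE(config$train$class_weighted_sampling)
  )
  tr <- train_model(model, train_set, valid_set, tc)

  per_rep <- vapply(test_reps$replicates, function(rep_ds) {
    pred <- predict_model(tr$model, rep_ds)
    if (task == "regression") {
      spearman_rho(pred, rep_ds$label)
    } else {
      mcc(as.numeric(pred > 0.5), rep_ds$label)
    }
  }, numeric(1))
  metric_name <- if (task == "regression") "spearman_rho" else "mcc"
  metric <- aggregate_metrics(matrix(per_rep, nrow = 1), metric = metric_name)

  manifest <- list(
    config = config[setdiff(names(config), "dataset_data")],
    seed = seed,
    n_train = nrow(train_set), n_valid = nrow(valid_set),
    n_test = nrow(test_aa),
    package_version = as.character(utils::packageVersion("ntaug"))
  )
  result <- structure(
    list(metric = metric, per_replicate = per_rep,
         valid_metric = tr$history$valid_metric[tr$best_epoch],
         train_result = tr, manifest = manifest),
    class = "nta_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(result, train_set, config)
  result
}

make_test_replicates_aa <- function(test_aa, k = 5L) {
  list(replicates = replicate(k, test_aa, simplify = FALSE))
}

reverse_translate_dataset <- function(ds, table, sampling, seed) {
  meta <- dataset_meta(ds)
  nts <- if (sampling == "deterministic") {
    vapply(ds$sequence, reverse_translate, character(1), table = table,
           USE.NAMES = FALSE)
  } else {
    with_seed(seed, vapply(
      ds$sequence,
      function(s) reverse_translate(s, table, mode = "random"),
      character(1), USE.NAMES = FALSE
    ))
  }
  out <- ds
  out$sequence <- nts
  as_labeled_dataset(out, alphabet = "nucleotide", task = meta$task)
}

resolve_table <- function(name, seed) {
  switch(name,
    natural = natural_codon_table(),
    balanced = balanced_codon_table(seed),
    shuffled = shuffled_codon_table(seed),
    abort_ntaug(sprintf("Unknown codon table '%s'.", name), "config_error")
  )
}

resolve_dataset <- function(dcfg, seed) {
  if (!is.null(dcfg$data)) return(dcfg$data)
  spec <- switch(dcfg$preset,
    gb1_like = gb1_like_spec(seed = seed,
                             noise_sd = dcfg$noise_sd %||% 0.1),
    cdrh3_like = cdrh3_like_spec(seed = seed,
                                 noise_sd = dcfg$noise_sd %||% 0.1),
    abort_ntaug(sprintf("Unknown dataset preset '%s'.", dcfg$preset),
                "config_error")
  )
  if (inherits(spec, "binder_spec")) {
    generate_binder_dataset(spec, dcfg$n_variants, dcfg$max_ed)
  } else {
    generate_landscape(spec, dcfg$n_variants, dcfg$max_ed)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and normalize a run configuration
#'
#' Fills defaults and rejects contradictory settings (e.g. an offline
#' condition carrying online hyperparameters).
#'
#' @param config A nested list as accepted by [run_experiment()].
#' @return The normalized config.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) abort_ntaug("Config must be a list.", "config_error")
  fail <- function(path, msg) {
    abort_ntaug(sprintf("Config field `%s`: %s", path, msg), "config_error")
  }
  config$seed <- as.integer(config$seed %||% 0L)
  config$table <- config$table %||% "natural"
  config$scheme <- config$scheme %||% "nt_trigram"
  config$fraction <- config$fraction %||% 1
  if (config$fraction <= 0 || config$fraction > 1) {
    fail("fraction", "must lie in (0, 1].")
  }
  if (is.null(config$dataset)) fail("dataset", "is required.")
  if (is.null(config$dataset$data)) {
    config$dataset$preset <- config$dataset$preset %||% "gb1_like"
    config$dataset$n_variants <- config$dataset$n_variants %||% 3000L
    config$dataset$max_ed <- config$dataset$max_ed %||% 4L
  }
  if (is.null(config$dataset$wild_type)) {
    config$dataset$wild_type <- switch(
      config$dataset$preset %||% "custom",
      gb1_like = gb1_like_spec()$wild_type,
      cdrh3_like = cdrh3_like_spec()$wild_type,
      fail("dataset.wild_type", "is required for custom data.")
    )
  }
  config$split <- config$split %||% list()
  config$split$ed_threshold <- config$split$ed_threshold %||% 3L
  config$split$valid_fraction <- config$split$valid_fraction %||% 0.2
  cond <- config$condition %||% list(type = "dna_baseline")
  if (is.null(cond$type) ||
      !cond$type %in% c("aa_baseline", "dna_baseline", "offline", "online")) {
    fail("condition.type", "must be aa_baseline/dna_baseline/offline/online.")
  }
  if (cond$type == "offline") {
    if (is.null(cond$n_aug)) fail("condition.n_aug", "is required for offline NTA.")
    cond$method <- cond$method %||% "random"
    if (!is.null(cond$t_aug) || !is.null(cond$num_subs)) {
      fail("condition", "offline augmentation cannot carry online hyperparameters.")
    }
  } else if (cond$type == "online") {
    cond$method <- "random"
    cond$t_aug <- cond$t_aug %||% 0.5
    cond$num_subs <- cond$num_subs %||% 0.25
    if (!is.null(cond$n_aug)) {
      fail("condition", "online augmentation cannot carry n_aug.")
    }
  } else {
    cond$method <- cond$method %||% "random"
  }
  config$condition <- cond
  config$model <- config$model %||% list()
  config$model$family <- config$model$family %||% "cnn"
  config$model$preset <- config$model$preset %||% "desk"
  config$train <- config$train %||% list()
  config$train$epochs <- config$train$epochs %||% 30L
  config$train$patience <- config$train$patience %||% 10L
  config$train$batch_size <- config$train$batch_size %||% 32L
  config$train$lr <- config$train$lr %||% 1e-3
  config
}

#' @rdname validate_run_config
#' @param path Path to a YAML file holding the nested configuration.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

write_run_artifacts <- function(result, train_set, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(train_set, file.path(config$out_dir, "train_set.csv"))
  utils::write.csv(result$train_result$history,
                   file.path(config$out_dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      metric = result$metric$metric,
      per_replicate = result$per_replicate,
      mean = result$metric$mean,
      sd = result$metric$sd,
      valid_metric = result$valid_metric
    ),
    file.path(config$out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(result$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out_dir)
}

#' Run a grid of experiments
#'
#' One run per (fraction, condition) cell per seed; rows of the summary
#' aggregate the per-seed replicate means into mean, sd and 95% CI.
#'
#' @param base_config Config shared by all cells (see [run_experiment()]).
#' @param fractions Numeric vector of training fractions.
#' @param conditions Named list of condition lists.
#' @param seeds Integer vector of seeds.
#' @return A list with `summary` (tibble: one row per cell) and `runs`
#'   (nested list of `nta_run`s).
#' @export
run_grid <- function(base_config, fractions, conditions, seeds) {
  if (!length(fractions) || !length(conditions) || !length(seeds)) {
    abort_ntaug("Grid sweeps must be non-empty.", "config_error")
  }
  if (is.null(names(conditions))) {
    names(conditions) <- paste0("condition", seq_along(conditions))
  }
  runs <- list()
  rows <- list()
  for (f in fractions) {
    for (cn in names(conditions)) {
      vals <- list()
      for (s in seeds) {
        cfg <- base_config
        cfg$fraction <- f
        cfg$condition <- conditions[[cn]]
        cfg$seed <- s
        key <- sprintf("f%s_%s_seed%d", format(f), cn, s)
        run <- run_experiment(cfg)
        runs[[key]] <- run
        vals[[length(vals) + 1L]] <- run$per_replicate
      }
      agg <- aggregate_metrics(do.call(rbind, vals),
                               metric = runs[[length(runs)]]$metric$metric)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fraction = f, condition = cn, metric = agg$metric,
        mean = agg$mean, sd = agg$sd, n_seeds = agg$n_seeds,
        ci_low = if (is.null(agg$ci95)) NA_real_ else agg$ci95[1],
        ci_high = if (is.null(agg$ci95)) NA_real_ else agg$ci95[2]
      )
    }
  }
  list(summary = do.call(rbind, rows), runs = runs)
}
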