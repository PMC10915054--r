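#' Run the full classification pipeline on a cohort
#'
#' End-to-end orchestration: segment every frame, extract the thermal
#' feature table, screen features with the Kolmogorov-Smirnov test, split
#' into training and validation subsets (stratified 75/25 by default),
#' tune and train both the random-forest and multilayer-perceptron
#' pipelines on the screened features, and evaluate both on the held-out
#' validation rows. Screening runs on the full labeled table by default
#' (feature removal before the split); set `screen_after_split = TRUE` for
#' the leakage-free variant. Every stochastic stage derives its seed from
#' `seed`, so a rerun with the same inputs and seed is bit-identical.
#'
#' @param cohort Tibble with `sample_id`, `treatment` and a `frame` list
#'   column (e.g. from [generate_cohort()] or [read_cohort()]), or an
#'   already-extracted feature table (no `frame` column).
#' @param seed Global integer seed.
#' @param alpha Screening significance threshold.
#' @param train_fraction Training proportion of the split.
#' @param screen_after_split Screen on training rows only.
#' @param search_iterations Random-search draws per model.
#' @param models Which pipelines to run.
#' @param use_truth_mask,strict Passed to [extract_feature_table()].
#' @param out_dir Optional directory; when given, the feature table, screen
#'   results, per-class reports, confusion matrices, comparison summary and
#'   resolved configuration are written there as CSV/JSON.
#' @return A `thermoleaf_run` list: `feature_table`, `screen`,
#'   `kept_features`, `split`, `pipelines`, `reports`, `predictions`,
#'   `comparison`, `config`.
#' @export
run_pipeline <- function(cohort, seed = 1L, alpha = 0.05, train_fraction = 0.75,
                         screen_after_split = FALSE, search_iterations = 25L,
                         models = c("rf", "mlp"), use_truth_mask = FALSE,
                         strict = FALSE, out_dir = NULL) {
  models <- match.arg(models, c("rf", "mlp"), several.ok = TRUE)
  feature_table <- if ("frame" %in% names(cohort)) {
    extract_feature_table(cohort, use_truth_mask = use_truth_mask, strict = strict)
  } else {
    cohort
  }
  if (nrow(feature_table) < 8L) {
    rlang::abort("fewer than 8 usable samples after extraction",
                 class = "thermoleaf_validation_error")
  }
  split <- split_dataset(feature_table$treatment, train_fraction = train_fraction,
                         seed = seed)
  screen <- screen_features(
    feature_table, alpha = alpha,
    after_split_idx = if (screen_after_split) split$train else NULL
  )
  kept <- screen$feature[screen$discriminating]
  if (length(kept) == 0L) {
    rlang::warn("no feature passed screening; falling back to all features")
    kept <- screen$feature
  }
  train_tbl <- feature_table[split$train, ]
  valid_tbl <- feature_table[split$validation, ]
  # stratified k-fold needs at least k members of the rarer class
  folds <- min(10L, min(table(train_tbl$treatment)))
  pipelines <- purrr::map(rlang::set_names(models), function(m) {
    cfg <- pipeline_config(model = m, search_iterations = search_iterations,
                           cv_folds = folds,
                           seed = seed + match(m, c("rf", "mlp")))
    cfg$k_features <- min(cfg$k_features, length(kept))
    tune_and_train(train_tbl, cfg, features = kept)
  })
  reports <- purrr::map(pipelines, evaluate_pipeline, data = valid_tbl)
  predictions <- purrr::imap(pipelines, function(p, m) {
    tibble::tibble(
      sample_id = valid_tbl$sample_id, model = m,
      treatment = valid_tbl$treatment,
      predicted = predict(p, valid_tbl)
    )
  }) |> dplyr::bind_rows()
  comparison <- if (length(reports) == 2L) {
    compare_models(reports[[1]], reports[[2]])
  } else NULL
  run <- structure(
    list(feature_table = feature_table, screen = screen, kept_features = kept,
         split = split, pipelines = pipelines, reports = reports,
         predictions = predictions, comparison = comparison,
         config = list(seed = seed, alpha = alpha, train_fraction = train_fraction,
                       screen_after_split = screen_after_split,
                       search_iterations = search_iterations, models = models)),
    class = "thermoleaf_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.thermoleaf_run <- function(x, ...) {
  cat(sprintf("<thermoleaf_run> %d samples, kept features: %s\n",
              nrow(x$feature_table), paste(x$kept_features, collapse = ", ")))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Write the artifacts of a pipeline run to a directory
#'
#' @param run A `thermoleaf_run` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$feature_table, file.path(dir, "feature_table.csv"), progress = FALSE)
  readr::write_csv(run$screen, file.path(dir, "screen_results.csv"), progress = FALSE)
  readr::write_csv(run$predictions, file.path(dir, "predictions.csv"), progress = FALSE)
  for (m in names(run$reports)) {
    r <- run$reports[[m]]
    readr::write_csv(generics::tidy(r), file.path(dir, sprintf("report_%s.csv", m)),
                     progress = FALSE)
    utils::write.csv(r$confusion, file.path(dir, sprintf("confusion_%s.csv", m)))
  }
  if (!is.null(run$comparison)) {
    readr::write_csv(run$comparison$summary, file.path(dir, "comparison.csv"),
                     progress = FALSE)
  }
  writeLines(
    vapply(names(run$config), function(k) {
      sprintf("%s: %s", k, paste(run$config[[k]], collapse = ","))
    }, character(1)),
    file.path(dir, "config.txt")
  )
  invisible(dir)
}

#' Read a cohort of thermal CSVs via a manifest
#'
#' @param manifest_path Path to a manifest CSV (see [load_manifest()]);
#'   relative `path` entries resolve against the manifest's directory.
#' @param ... Passed to [parse_thermal_csv()].
#' @return A cohort tibble (`sample_id`, `treatment`, `frame` list column).
#' @export
read_cohort <- function(manifest_path, ...) {
  manifest <- load_manifest(manifest_path)
  base <- dirname(manifest_path)
  frames <- purrr::pmap(manifest, function(sample_id, path, genotype, treatment,
                                           timepoint, drought_stage, replicate) {
    p <- if (file.exists(path)) path else file.path(base, path)
    parse_thermal_csv(p, sample_id = sample_id, genotype = genotype,
                      treatment = treatment, timepoint = timepoint,
                      drought_stage = drought_stage, ...)
  })
  tibble::tibble(sample_id = manifest$sample_id, treatment = manifest$treatment,
                 frame = frames)
}
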