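#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()]: statistic is the supremum gap
#' between the two empirical CDFs, two-sided alternative, p-value from the
#' asymptotic Kolmogorov distribution by default (set `exact = TRUE` for the
#' exact small-sample method).
#'
#' @param a,b Numeric samples, each of size at least 3.
#' @param exact Use the exact p-value method.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (length(a) < 3L || length(b) < 3L) {
    rlang::abort("each sample must have at least 3 values",
                 class = "thermoleaf_insufficient_data_error")
  }
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided", exact = exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Screen features for treatment discrimination
#'
#' Runs a two-sample Kolmogorov-Smirnov test on each feature column,
#' comparing its distribution between the WW and DD groups. A feature is
#' kept (`discriminating = TRUE`) when its p-value falls below `alpha`: a
#' feature whose distributions cannot be told apart carries no class signal
#' and is dropped before classification. Screening runs on the full labeled
#' table by default, matching the pipeline order in which feature removal
#' precedes the train/validation split; `after_split_idx` restricts
#' screening to the given (training) rows for a leakage-free variant. No
#' multiple-testing correction is applied.
#'
#' @param table Feature tibble with a `treatment` column (`WW`/`DD`) and
#'   numeric feature columns.
#' @param features Feature column names; defaults to the nine thermal
#'   indicators present in `table`.
#' @param alpha Significance threshold, 0.05 by default.
#' @param after_split_idx Optional integer row indices (training rows) to
#'   screen on instead of the full table.
#' @return A tibble ordered by ascending p-value: `feature`,
#'   `ks_statistic`, `p_value`, `discriminating`, `n_ww`, `n_dd`, `alpha`.
#' @export
screen_features <- function(table, features = NULL, alpha = 0.05,
                            after_split_idx = NULL) {
  if (!is.null(after_split_idx)) table <- table[after_split_idx, , drop = FALSE]
  if (is.null(features)) features <- intersect(thermal_feature_names(), names(table))
  stopifnot(length(features) > 0, "treatment" %in% names(table))
  classes <- unique(table$treatment)
  if (!all(c("WW", "DD") %in% classes)) {
    rlang::abort("both WW and DD must be present to screen features",
                 class = "thermoleaf_validation_error")
  }
  ww <- table[table$treatment == "WW", , drop = FALSE]
  dd <- table[table$treatment == "DD", , drop = FALSE]
  res <- purrr::map(features, function(f) {
    ks <- ks_two_sample(ww[[f]], dd[[f]])
    tibble::tibble(
      feature = f, ks_statistic = ks$statistic, p_value = ks$p_value,
      discriminating = ks$p_value < alpha,
      n_ww = nrow(ww), n_dd = nrow(dd), alpha = alpha
    )
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$p_value)
}
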