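#' Join classifier predictions with physiological measurements
#'
#' Inner-joins per-sample predictions with a physiology table (volumetric
#' soil water content %, PSII efficiency, leaf water potential) and tags
#' each row with its outcome: `DD_DD`, `DD_WW`, `WW_DD`, `WW_WW` (true
#' label, then predicted). Unmatched sample ids on either side are dropped
#' with a warning.
#'
#' @param predictions Tibble with `sample_id`, `treatment` (true label) and
#'   `predicted` columns.
#' @param physio Tibble with `sample_id`, `soil_vwc` (0-100 %), `psii_eff`
#'   (0-1), `leaf_wp` (MPa, non-positive). Columns other than `sample_id`
#'   may be missing; present ones are validated.
#' @return A joined tibble with an `outcome` column.
#' @export
join_predictions_physio <- function(predictions, physio) {
  stopifnot(all(c("sample_id", "treatment", "predicted") %in% names(predictions)))
  dup <- physio$sample_id[duplicated(physio$sample_id)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicated sample_id in physiology table: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "thermoleaf_validation_error")
  }
  if ("soil_vwc" %in% names(physio) &&
      any(physio$soil_vwc < 0 | physio$soil_vwc > 100, na.rm = TRUE)) {
    rlang::abort("soil_vwc must lie in [0, 100] %", class = "thermoleaf_validation_error")
  }
  if ("psii_eff" %in% names(physio) &&
      any(physio$psii_eff < 0 | physio$psii_eff > 1, na.rm = TRUE)) {
    rlang::abort("psii_eff must lie in [0, 1]", class = "thermoleaf_validation_error")
  }
  if ("leaf_wp" %in% names(physio) && any(physio$leaf_wp > 0, na.rm = TRUE)) {
    rlang::abort("leaf_wp must be non-positive (MPa)", class = "thermoleaf_validation_error")
  }
  unmatched <- setdiff(predictions$sample_id, physio$sample_id)
  if (length(unmatched) > 0) {
    rlang::warn(sprintf("%d prediction(s) without physiology rows: %s",
                        length(unmatched), paste(unmatched, collapse = ", ")))
  }
  joined <- dplyr::inner_join(predictions, physio, by = "sample_id")
  if (nrow(joined) == 0) {
    rlang::abort("no sample_id overlap between predictions and physiology table",
                 class = "thermoleaf_validation_error")
  }
  dplyr::mutate(joined, outcome = paste(.data$treatment, .data$predicted, sep = "_"))
}

#' Flag physiologically anomalous samples per treatment group
#'
#' For each trait, a sample is flagged when its value falls outside the
#' Tukey fences (`multiplier` times the IQR beyond the quartiles) of its
#' own treatment group — the same robust fence rule used throughout the
#' pipeline. Misclassified leaves in practice often show such outlier
#' physiology (e.g. a dry-down plant whose soil never dried); the output is
#' purely associational and asserts no causality.
#'
#' @param joined Tibble from [join_predictions_physio()].
#' @param traits Trait columns to test; defaults to those present among
#'   `soil_vwc`, `psii_eff`, `leaf_wp`.
#' @param multiplier Fence multiplier, 1.5 by default.
#' @param min_group Minimum rows per treatment group for a trait to be
#'   testable; undersized groups are skipped with a warning.
#' @return `joined` plus `physio_outlier` (logical) and `which_traits`
#'   (comma-separated flagged traits, `""` when none).
#' @export
flag_physio_outliers <- function(joined, traits = NULL, multiplier = 1.5,
                                 min_group = 4L) {
  if (is.null(traits)) traits <- intersect(c("soil_vwc", "psii_eff", "leaf_wp"), names(joined))
  stopifnot(length(traits) > 0, "treatment" %in% names(joined))
  flags <- matrix(FALSE, nrow(joined), length(traits),
                  dimnames = list(NULL, traits))
  for (tr in traits) {
    for (grp in unique(joined$treatment)) {
      rows <- which(joined$treatment == grp & !is.na(joined[[tr]]))
      if (length(rows) < min_group) {
        rlang::warn(sprintf("trait %s skipped for group %s: only %d rows (< %d)",
                            tr, grp, length(rows), min_group))
        next
      }
      v <- joined[[tr]][rows]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      flags[rows, tr] <- v < q[1] - multiplier * iqr | v > q[2] + multiplier * iqr
    }
  }
  joined$physio_outlier <- rowSums(flags) > 0
  joined$which_traits <- apply(flags, 1L, function(r) paste(traits[r], collapse = ","))
  joined
}

#' Flag rates by classification outcome
#'
#' Summarizes [flag_physio_outliers()] output: the fraction of
#' physiological outliers among correctly and incorrectly classified
#' samples, and per outcome tag.
#'
#' @param diagnosed Tibble from [flag_physio_outliers()].
#' @return A list with `by_outcome` and `by_correctness` tibbles.
#' @export
summarize_mislabels <- function(diagnosed) {
  by_outcome <- diagnosed |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(n = dplyr::n(), flagged = sum(.data$physio_outlier),
                     flag_rate = mean(.data$physio_outlier), .groups = "drop")
  by_correctness <- diagnosed |>
    dplyr::mutate(correct = .data$treatment == .data$predicted) |>
    dplyr::group_by(.data$correct) |>
    dplyr::summarise(n = dplyr::n(), flagged = sum(.data$physio_outlier),
                     flag_rate = mean(.data$physio_outlier), .groups = "drop")
  list(by_outcome = by_outcome, by_correctness = by_correctness)
}
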