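#' Remove temperature outliers with a Tukey fence
#'
#' Single-pass robust filter: values outside
#' `[q1 - multiplier * IQR, q3 + multiplier * IQR]` of the input sample are
#' dropped (strict inequality, so with a zero IQR equal values are all
#' retained). Applied to the masked temperatures before feature extraction,
#' this absorbs contamination from small leaf-mask misalignments — a thin
#' ring of backdrop pixels leaking into the mask is fenced out as long as it
#' stays a minority.
#'
#' @param temps Numeric vector of temperatures, at least 4 values.
#' @param multiplier Fence multiplier, 1.5 by default.
#' @return The retained values, in input order.
#' @export
filter_outliers <- function(temps, multiplier = 1.5) {
  if (length(temps) < 4L) {
    rlang::abort(sprintf("need at least 4 values to fence outliers, got %d", length(temps)),
                 class = "thermoleaf_insufficient_data_error")
  }
  q <- stats::quantile(temps, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  temps[temps >= lo & temps <= hi]
}

#' Extract statistical thermal indicators from a masked leaf
#'
#' Computes the nine indicators — mean, standard deviation, median, 25th and
#' 75th percentiles, interquartile range, max, min, and temperature range —
#' over the temperatures under the leaf mask, after a single-pass
#' [filter_outliers()] fence. Quantiles use linear interpolation (type 7);
#' the standard deviation is the sample (n-1) convention by default.
#'
#' @param frame A [thermal_frame()].
#' @param mask A [leaf_mask()] aligned to `frame`.
#' @param multiplier Outlier-fence multiplier.
#' @param min_pixels Minimum masked pixel count after filtering.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return A one-row tibble with columns `mean`, `std`, `median`, `p25`,
#'   `p75`, `iqr`, `max`, `min`, `range`, `n_pixels_used`,
#'   `n_outliers_removed`.
#' @export
extract_features <- function(frame, mask, multiplier = 1.5, min_pixels = 10L,
                             sd_type = c("sample", "population")) {
  sd_type <- rlang::arg_match(sd_type)
  vals <- frame$values
  mv <- if (inherits(mask, "leaf_mask")) mask$values else mask
  stopifnot(identical(dim(vals), dim(mv)))
  temps <- vals[mv]
  if (length(temps) < 4L) {
    rlang::abort(
      sprintf("only %d masked pixels; need at least 4", length(temps)),
      class = "thermoleaf_insufficient_data_error"
    )
  }
  kept <- filter_outliers(temps, multiplier = multiplier)
  if (length(kept) < min_pixels) {
    rlang::abort(
      sprintf("%d pixels after outlier filtering (floor %d; %d before)",
              length(kept), min_pixels, length(temps)),
      class = "thermoleaf_insufficient_data_error"
    )
  }
  q <- stats::quantile(kept, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- stats::sd(kept)
  if (sd_type == "population") s <- s * sqrt((length(kept) - 1) / length(kept))
  tibble::tibble(
    mean = mean(kept), std = s, median = q[2], p25 = q[1], p75 = q[3],
    iqr = q[3] - q[1], max = max(kept), min = min(kept),
    range = max(kept) - min(kept),
    n_pixels_used = length(kept),
    n_outliers_removed = length(temps) - length(kept)
  )
}

#' Names of the thermal feature columns
#' @return Character vector of the nine indicator names.
#' @export
thermal_feature_names <- function() {
  c("mean", "std", "median", "p25", "p75", "iqr", "max", "min", "range")
}

#' Build the per-sample feature table for a cohort
#'
#' Segments each frame (or uses a provided mask column) and extracts the
#' thermal indicators, returning one row per sample joined with its labels.
#' Samples whose segmentation or extraction fails are dropped with a
#' warning (set `strict = TRUE` to fail fast instead), mirroring
#' quality-control attrition in real campaigns.
#'
#' @param cohort Tibble with `sample_id`, `treatment` and a `frame` list
#'   column; an optional `mask` list column bypasses segmentation.
#' @param use_truth_mask Use the `truth_mask` column instead of segmenting
#'   (synthetic cohorts only).
#' @param strict Fail on the first per-sample error.
#' @param ... Passed to [segment_leaf()] and [extract_features()].
#' @return A tibble: `sample_id`, `treatment`, the nine feature columns,
#'   `n_pixels_used`, `n_outliers_removed`.
#' @export
extract_feature_table <- function(cohort, use_truth_mask = FALSE, strict = FALSE, ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% names(formals(segment_leaf))]
  feat_args <- dots[names(dots) %in% names(formals(extract_features))]
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    fr <- cohort$frame[[i]]
    res <- tryCatch({
      mk <- if (use_truth_mask) {
        cohort$truth_mask[[i]]
      } else if ("mask" %in% names(cohort)) {
        cohort$mask[[i]]
      } else {
        do.call(segment_leaf, c(list(fr), seg_args))
      }
      do.call(extract_features, c(list(fr, mk), feat_args))
    }, error = function(e) {
      if (strict) rlang::abort(
        sprintf("sample %s: %s", cohort$sample_id[i], conditionMessage(e)),
        parent = e
      )
      rlang::warn(sprintf("dropping sample %s: %s", cohort$sample_id[i],
                          conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(sample_id = cohort$sample_id[i], treatment = cohort$treatment[i]),
      res
    )
  })
  dplyr::bind_rows(rows)
}
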