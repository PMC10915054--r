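#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classification report into per-class metrics
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per class: precision, recall, F1, support.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$per_class, model = x$model, .before = 1)
}

#' One-row summary of a classification report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble: accuracy, correct count, n_validation.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(model = x$model, accuracy = x$accuracy,
                 correct = sum(diag(x$confusion)), n_validation = x$n_validation)
}

#' Tidy a fitted pipeline's random-search log
#'
#' @param x A `thermoleaf_pipeline`.
#' @param ... Unused.
#' @return The search log tibble, best configuration first.
#' @export
tidy.thermoleaf_pipeline <- function(x, ...) x$search_log

#' One-row summary of a fitted pipeline
#'
#' @param x A `thermoleaf_pipeline`.
#' @param ... Unused.
#' @return A tibble with the model, CV accuracy and best hyperparameters.
#' @export
glance.thermoleaf_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model = x$config$model, cv_accuracy = x$cv_accuracy,
                   n_selected = length(x$selected_features)),
    x$best_hyperparameters
  )
}

matrix_to_long <- function(m, value_name) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  ) |> dplyr::rename(!!value_name := "value")
}

#' Plot a thermal frame as a temperature raster
#'
#' @param object A [thermal_frame()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermal_frame <- function(object, ...) {
  d <- matrix_to_long(object$values, "temp")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$temp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "degC") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a leaf mask
#'
#' @param object A [leaf_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leaf_mask <- function(object, ...) {
  d <- matrix_to_long(object$values * 1, "on")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$on > 0)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "darkgreen"),
                               name = "leaf") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of the 2x2 confusion matrix with counts.
#' @export
autoplot.eval_report <- function(object, ...) {
  conf <- object$confusion
  d <- tidyr::expand_grid(truth = rownames(conf), predicted = colnames(conf)) |>
    dplyr::mutate(count = purrr::map2_int(.data$truth, .data$predicted,
                                          function(t, p) conf[t, p]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(conf))) +
    ggplot2::labs(title = if (is.na(object$model)) NULL else toupper(object$model),
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot feature screening results
#'
#' @param screen Tibble from [screen_features()].
#' @return A ggplot of per-feature KS p-values against the alpha threshold.
#' @export
plot_screen <- function(screen) {
  ggplot2::ggplot(screen,
                  ggplot2::aes(x = stats::reorder(.data$feature, -.data$p_value),
                               y = .data$p_value, fill = .data$discriminating)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = screen$alpha[1], linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "KS p-value") +
    ggplot2::theme_minimal()
}
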