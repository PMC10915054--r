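#' Stratified train/validation split
#'
#' Splits `n` samples into a training ("T") and validation ("V") set with
#' `|T| = floor(train_fraction * n)`, stratified by class so both labels
#' appear on each side. With 419 samples and the default 0.75 fraction this
#' gives the canonical 314 / 105 partition.
#'
#' @param labels Character or factor vector of class labels (one per
#'   sample), or a single integer `n` for an unstratified split.
#' @param train_fraction Proportion assigned to training, default 0.75.
#' @param seed Integer seed; the split is deterministic per seed.
#' @param stratified Stratify by class (default `TRUE`; ignored when
#'   `labels` is a count).
#' @return A list with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(labels, train_fraction = 0.75, seed = 1L,
                          stratified = TRUE) {
  if (length(labels) == 1L && is.numeric(labels)) {
    n <- as.integer(labels)
    stratified <- FALSE
    labels <- rep("all", n)
  } else {
    n <- length(labels)
  }
  stopifnot(n >= 4L, train_fraction > 0, train_fraction < 1)
  n_train <- as.integer(floor(train_fraction * n))
  train_idx <- withr::with_seed(seed, {
    if (!stratified) {
      sort(sample.int(n, n_train))
    } else {
      labels <- as.character(labels)
      classes <- sort(unique(labels))
      per <- table(labels)[classes]
      # proportional allocation; leftover train slots go to the classes
      # with the largest fractional remainders
      exact <- as.numeric(per) * train_fraction
      base <- floor(exact)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        cut <- order(exact - base)[seq_len(-rem)]
        base[cut] <- base[cut] - 1
      }
      idx <- unlist(purrr::map2(classes, base, function(cl, k) {
        pool <- which(labels == cl)
        if (k < 1 || k >= length(pool)) {
          rlang::abort(
            sprintf("class %s would be absent from one side of the split", cl),
            class = "thermoleaf_validation_error"
          )
        }
        sample(pool, k)
      }))
      sort(idx)
    }
  })
  list(train = train_idx, validation = setdiff(seq_len(n), train_idx))
}

#' Fit and apply per-feature standardization
#'
#' Scales each feature to zero mean and unit standard deviation, with the
#' mean and sd fitted on the training rows only; validation rows are
#' transformed with the training parameters. A zero-variance training
#' column cannot be scaled and is passed through centered with a warning.
#'
#' @param train Data frame / tibble of numeric training features.
#' @return An object of class `thermoleaf_scaler`; apply it with
#'   [apply_scaler()].
#' @export
fit_scaler <- function(train) {
  train <- as.data.frame(train)
  center <- vapply(train, mean, numeric(1))
  scale_ <- vapply(train, stats::sd, numeric(1))
  zero <- !is.finite(scale_) | scale_ == 0
  if (any(zero)) {
    rlang::warn(sprintf("zero-variance feature(s) passed through centered: %s",
                        paste(names(train)[zero], collapse = ", ")))
    scale_[zero] <- 1
  }
  structure(list(center = center, scale = scale_, zero_variance = names(train)[zero]),
            class = "thermoleaf_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `thermoleaf_scaler`.
#' @param newdata Data frame with the same feature columns.
#' @return `apply_scaler()`: a tibble of standardized features.
#' @export
apply_scaler <- function(scaler, newdata) {
  stopifnot(inherits(scaler, "thermoleaf_scaler"))
  newdata <- as.data.frame(newdata)[names(scaler$center)]
  out <- purrr::imap(newdata, function(col, nm) {
    (col - scaler$center[[nm]]) / scaler$scale[[nm]]
  })
  tibble::as_tibble(out)
}

#' Mutual information between a numeric feature and a class label
#'
#' Plug-in estimate: the feature is discretized into (at most) `bins`
#' equal-frequency bins and the mutual information of the binned feature
#' with the label is computed in nats. A tiny seeded jitter
#' (1e-10 relative) breaks discretization ties so the estimate is
#' deterministic per seed even with heavily tied data.
#'
#' @param x Numeric feature vector.
#' @param y Class label vector.
#' @param bins Maximum number of equal-frequency bins.
#' @param seed Integer seed for the tie-breaking jitter.
#' @return Estimated mutual information in nats (non-negative).
#' @export
mutual_information <- function(x, y, bins = 10L, seed = 1L) {
  stopifnot(length(x) == length(y))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  x <- withr::with_seed(seed, x + stats::rnorm(length(x), 0, 1e-10 * s))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1), type = 7))
  if (length(br) < 2L) return(0)
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Select the most informative features by mutual information
#'
#' Ranks features by estimated mutual information with the class label
#' (training rows only) and returns the names of the top `k`; ties break
#' toward the earlier column.
#'
#' @param train Tibble of numeric training features.
#' @param labels Class labels for the training rows.
#' @param k Number of features to keep.
#' @param seed Seed for the MI estimator.
#' @return Character vector of `k` selected feature names, in rank order.
#' @export
select_features_mi <- function(train, labels, k, seed = 1L) {
  feats <- names(train)
  if (k > length(feats)) {
    rlang::abort(sprintf("k = %d exceeds the %d available features", k, length(feats)),
                 class = "thermoleaf_validation_error")
  }
  mi <- vapply(seq_along(feats), function(i) {
    mutual_information(train[[i]], labels, seed = seed + i)
  }, numeric(1))
  feats[order(-mi, seq_along(feats))][seq_len(k)]
}

#' Pipeline configuration
#'
#' Collects the tunable knobs of one classification pipeline. Defaults are
#' the selected working point: for the random forest, 3
#' mutual-information-selected features, minimum 5 samples per tree leaf,
#' maximum tree depth 5; for the multilayer perceptron, 7 selected features
#' and a single hidden layer of 50 neurons trained with L2 weight decay and
#' no learning-rate scheduling. The random forest grows 100 trees by
#' default (configurable). Tree depth is enforced through the maximum
#' number of terminal nodes (`2^max_depth`).
#'
#' @param model `"rf"` or `"mlp"`.
#' @param k_features Number of features kept by mutual-information
#'   selection; `NULL` picks the model default (3 for rf, 7 for mlp).
#' @param rf_min_samples_leaf,rf_max_depth,rf_n_trees Random-forest knobs.
#' @param mlp_hidden_size,mlp_decay,mlp_max_iter Perceptron knobs.
#' @param cv_folds Stratified cross-validation folds for tuning.
#' @param search_iterations Random-search draws from the hyperparameter
#'   grid.
#' @param seed Integer seed for search, folding and model fits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(model = c("rf", "mlp"), k_features = NULL,
                            rf_min_samples_leaf = 5L, rf_max_depth = 5L,
                            rf_n_trees = 100L,
                            mlp_hidden_size = 50L, mlp_decay = 1e-4,
                            mlp_max_iter = 500L,
                            cv_folds = 10L, search_iterations = 25L,
                            seed = 1L) {
  model <- rlang::arg_match(model)
  if (is.null(k_features)) k_features <- if (model == "rf") 3L else 7L
  stopifnot(k_features >= 1L, cv_folds >= 2L, search_iterations >= 1L)
  structure(
    list(model = model, k_features = as.integer(k_features),
         rf_min_samples_leaf = as.integer(rf_min_samples_leaf),
         rf_max_depth = as.integer(rf_max_depth),
         rf_n_trees = as.integer(rf_n_trees),
         mlp_hidden_size = as.integer(mlp_hidden_size),
         mlp_decay = mlp_decay, mlp_max_iter = as.integer(mlp_max_iter),
         cv_folds = as.integer(cv_folds),
         search_iterations = as.integer(search_iterations),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Default random-search space for a pipeline
#'
#' The grid the random search samples from; it contains the default working
#' point of each model. Override by passing a data frame of the same shape
#' to [tune_and_train()].
#'
#' @param config A [pipeline_config()].
#' @return A tibble, one row per candidate hyperparameter combination.
#' @export
default_search_space <- function(config) {
  if (config$model == "rf") {
    tidyr::expand_grid(
      k_features = c(3L, 5L, 7L, 9L),
      rf_max_depth = c(3L, 5L, 7L, 10L),
      rf_min_samples_leaf = c(2L, 5L, 10L),
      rf_n_trees = c(100L, 300L)
    )
  } else {
    tidyr::expand_grid(
      k_features = c(3L, 5L, 7L, 9L),
      mlp_hidden_size = c(25L, 50L, 100L),
      mlp_decay = c(1e-4, 1e-3)
    )
  }
}

make_stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  by_fold <- split(labels, factor(fold, levels = seq_len(k)))
  if (any(vapply(by_fold, function(l) length(unique(l)) < 2L, logical(1)))) {
    rlang::abort("a cross-validation fold would be empty or single-class; reduce cv_folds",
                 class = "thermoleaf_validation_error")
  }
  fold
}

fit_model <- function(x, y, config, hp, seed) {
  # x: standardized selected features (data.frame); y: factor DD/WW
  df <- data.frame(x, .y = y, check.names = FALSE)
  withr::with_seed(seed, {
    if (config$model == "rf") {
      randomForest::randomForest(
        x = as.matrix(x), y = y,
        ntree = hp$rf_n_trees,
        nodesize = hp$rf_min_samples_leaf,
        maxnodes = min(2L^hp$rf_max_depth, nrow(x))
      )
    } else {
      nnet::nnet(.y ~ ., data = df, size = hp$mlp_hidden_size,
                 decay = hp$mlp_decay, maxit = config$mlp_max_iter,
                 MaxNWts = 10000L, trace = FALSE)
    }
  })
}

predict_model <- function(model, x, levels_) {
  if (inherits(model, "randomForest")) {
    as.character(stats::predict(model, as.matrix(x)))
  } else {
    p <- as.numeric(stats::predict(model, data.frame(x, check.names = FALSE)))
    # nnet binary output is P(second factor level)
    ifelse(p > 0.5, levels_[2], levels_[1])
  }
}

config_hp <- function(config) {
  if (config$model == "rf") {
    tibble::tibble(k_features = config$k_features,
                   rf_max_depth = config$rf_max_depth,
                   rf_min_samples_leaf = config$rf_min_samples_leaf,
                   rf_n_trees = config$rf_n_trees)
  } else {
    tibble::tibble(k_features = config$k_features,
                   mlp_hidden_size = config$mlp_hidden_size,
                   mlp_decay = config$mlp_decay)
  }
}

#' Tune and train a classification pipeline
#'
#' Random-search hyperparameter optimization under stratified k-fold
#' cross-validation on the training subset, then a final refit of the best
#' configuration on all training rows. Within each fold, standardization
#' and mutual-information feature selection are refitted on the fold's
#' training rows only, so CV scores are leakage-free; the final pipeline
#' refits both on the full training subset. Fully deterministic per seed.
#'
#' @param data Tibble with a `treatment` column (`WW`/`DD`) and feature
#'   columns; typically `feature_table[split$train, ]`.
#' @param config A [pipeline_config()].
#' @param features Candidate feature columns (default: the thermal
#'   indicators present, intersected with any screened set you pass).
#' @param search_space Candidate grid; default [default_search_space()].
#'   Collapse it to one row to skip searching.
#' @return A `thermoleaf_pipeline` object: scaler, selected features,
#'   fitted model, best hyperparameters, CV accuracy, and the full search
#'   log (`$search_log`).
#' @export
tune_and_train <- function(data, config = pipeline_config(), features = NULL,
                           search_space = NULL) {
  if (is.null(features)) features <- intersect(thermal_feature_names(), names(data))
  stopifnot("treatment" %in% names(data), length(features) >= 1L)
  y <- factor(data$treatment, levels = c("DD", "WW"))
  if (nlevels(droplevels(y)) < 2L) {
    rlang::abort("training data must contain both classes",
                 class = "thermoleaf_validation_error")
  }
  x_all <- data[features]
  if (is.null(search_space)) search_space <- default_search_space(config)
  search_space <- search_space[search_space$k_features <= length(features), , drop = FALSE]
  stopifnot(nrow(search_space) > 0)
  n_draw <- min(config$search_iterations, nrow(search_space))
  cand <- withr::with_seed(config$seed, {
    search_space[sample.int(nrow(search_space), n_draw), , drop = FALSE]
  })
  fold <- make_stratified_folds(y, config$cv_folds, seed = config$seed + 1L)

  cv_accuracy <- function(hp) {
    accs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f; te <- !tr
      scaler <- suppressWarnings(fit_scaler(x_all[tr, ]))
      xtr <- apply_scaler(scaler, x_all[tr, ])
      sel <- select_features_mi(xtr, y[tr], k = hp$k_features,
                                seed = config$seed + 7L)
      fit <- fit_model(xtr[sel], y[tr], config, hp, seed = config$seed + 13L + f)
      pred <- predict_model(fit, apply_scaler(scaler, x_all[te, ])[sel],
                            levels(y))
      mean(pred == as.character(y[te]))
    }, numeric(1))
    mean(accs)
  }

  scores <- vapply(seq_len(nrow(cand)), function(i) cv_accuracy(cand[i, ]), numeric(1))
  best_i <- which.max(scores)
  best_hp <- cand[best_i, ]

  scaler <- suppressWarnings(fit_scaler(x_all))
  x_std <- apply_scaler(scaler, x_all)
  sel <- select_features_mi(x_std, y, k = best_hp$k_features, seed = config$seed + 7L)
  final <- fit_model(x_std[sel], y, config, best_hp, seed = config$seed + 29L)

  structure(
    list(config = config, features = features, scaler = scaler,
         selected_features = sel, model = final,
         best_hyperparameters = best_hp, cv_accuracy = scores[best_i],
         search_log = dplyr::arrange(
           dplyr::bind_cols(cand, tibble::tibble(cv_accuracy = scores)),
           dplyr::desc(.data$cv_accuracy)
         ),
         levels = levels(y)),
    class = "thermoleaf_pipeline"
  )
}

#' @export
print.thermoleaf_pipeline <- function(x, ...) {
  cat(sprintf("<thermoleaf_pipeline> %s: CV accuracy %.3f, features [%s]\n",
              toupper(x$config$model), x$cv_accuracy,
              paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' Predict treatment labels with a fitted pipeline
#'
#' @param object A `thermoleaf_pipeline` from [tune_and_train()].
#' @param newdata Tibble with the pipeline's feature columns.
#' @param ... Unused.
#' @return Character vector of predicted labels (`DD`/`WW`).
#' @export
predict.thermoleaf_pipeline <- function(object, newdata, ...) {
  x <- apply_scaler(object$scaler, newdata[object$features])
  predict_model(object$model, x[object$selected_features], object$levels)
}

#' Evaluate a fitted pipeline on a validation subset
#'
#' Builds the classification report: a 2x2 confusion matrix (rows true,
#' columns predicted, DD first), per-class precision / recall / F1 /
#' support, and overall accuracy.
#'
#' @param pipeline A `thermoleaf_pipeline`.
#' @param data Validation tibble with `treatment` and the feature columns.
#' @return An `eval_report` object.
#' @export
evaluate_pipeline <- function(pipeline, data) {
  stopifnot(nrow(data) > 0)
  truth <- factor(data$treatment, levels = pipeline$levels)
  if (nlevels(droplevels(truth)) < 2L) {
    rlang::abort("validation data must contain both classes",
                 class = "thermoleaf_validation_error")
  }
  pred <- factor(predict(pipeline, data), levels = pipeline$levels)
  eval_report(truth, pred, model = pipeline$config$model)
}

#' Build a classification report from true and predicted labels
#'
#' @param truth,pred Factors (or characters) with levels `DD`, `WW`.
#' @param model Optional model tag carried in the report.
#' @return An `eval_report`: `confusion` (2x2 matrix, rows true), and
#'   tibbles accessible via [generics::tidy()] / [generics::glance()].
#' @export
eval_report <- function(truth, pred, model = NA_character_) {
  lev <- c("DD", "WW")
  truth <- factor(as.character(truth), levels = lev)
  pred <- factor(as.character(pred), levels = lev)
  conf <- table(truth = truth, predicted = pred)
  per_class <- purrr::map(lev, function(cl) {
    tp <- conf[cl, cl]
    p_denom <- sum(conf[, cl])
    r_denom <- sum(conf[cl, ])
    precision <- if (p_denom > 0) tp / p_denom else 0
    recall <- if (r_denom > 0) tp / r_denom else 0
    f1 <- f1_score(precision, recall)
    tibble::tibble(class = cl, precision = precision, recall = recall,
                   f1 = f1, support = as.integer(r_denom))
  })
  structure(
    list(confusion = unclass(conf), per_class = dplyr::bind_rows(per_class),
         accuracy = sum(diag(conf)) / sum(conf),
         n_validation = as.integer(sum(conf)), model = model),
    class = "eval_report"
  )
}

#' F1 score from precision and recall
#'
#' `2 * P * R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Numeric in \[0, 1\].
#' @return The harmonic mean of precision and recall.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s accuracy %.0f%% on %d validation samples\n",
              if (is.na(x$model)) "" else paste0(" ", toupper(x$model), ":"),
              100 * x$accuracy, x$n_validation))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %s: precision %.2f, recall %.2f, F1 %.2f, support %d\n",
                pc$class[i], pc$precision[i], pc$recall[i], pc$f1[i], pc$support[i]))
  }
  cat("  confusion (rows true, cols predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Compare two classification reports
#'
#' Side-by-side per-class metrics, total correct counts and the accuracy
#' delta (second minus first). Reports with different validation sizes are
#' allowed and flagged.
#'
#' @param report_a,report_b `eval_report` objects.
#' @return A list with `per_class` (long tibble), `summary` (one row per
#'   model), `delta_correct`, `delta_accuracy_points`, `same_support`.
#' @export
compare_models <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "eval_report"), inherits(report_b, "eval_report"))
  tag <- function(r, d) if (is.na(r$model)) d else toupper(r$model)
  ta <- tag(report_a, "A"); tb <- tag(report_b, "B")
  per_class <- dplyr::bind_rows(
    dplyr::mutate(report_a$per_class, model = ta, .before = 1),
    dplyr::mutate(report_b$per_class, model = tb, .before = 1)
  )
  summary <- tibble::tibble(
    model = c(ta, tb),
    correct = c(sum(diag(report_a$confusion)), sum(diag(report_b$confusion))),
    n_validation = c(report_a$n_validation, report_b$n_validation),
    accuracy = c(report_a$accuracy, report_b$accuracy)
  )
  list(
    per_class = per_class, summary = summary,
    delta_correct = summary$correct[2] - summary$correct[1],
    delta_accuracy_points = 100 * (summary$accuracy[2] - summary$accuracy[1]),
    same_support = report_a$n_validation == report_b$n_validation
  )
}
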