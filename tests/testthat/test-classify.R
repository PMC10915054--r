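test_that("the 75/25 split reproduces the canonical sizes and is deterministic", {
  labels <- rep(c("WW", "DD"), c(212, 207))
  sp <- split_dataset(labels, seed = 1)
  expect_equal(length(sp$train), 314L)
  expect_equal(length(sp$validation), 105L)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_len(419))
  # stratification keeps both classes on both sides
  expect_setequal(unique(labels[sp$train]), c("WW", "DD"))
  expect_setequal(unique(labels[sp$validation]), c("WW", "DD"))

  sp2 <- split_dataset(labels, seed = 1)
  expect_identical(sp, sp2)

  tiny <- split_dataset(4, train_fraction = 0.75, seed = 2)
  expect_equal(length(tiny$train), 3L)
  expect_equal(length(tiny$validation), 1L)
})

test_that("standardization fits on training rows and transfers to validation", {
  tr <- tibble::tibble(a = c(1, 2, 3), b = c(10, 20, 30))
  sc <- fit_scaler(tr)
  z <- apply_scaler(sc, tr)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(vapply(z, sd, numeric(1)), c(a = 1, b = 1))
  # a validation value at the training mean maps to zero
  expect_equal(apply_scaler(sc, tibble::tibble(a = 2, b = 20))$a, 0)
  # zero-variance column passes through centered, with a warning
  expect_warning(sc2 <- fit_scaler(tibble::tibble(a = c(1, 2, 3), k = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(apply_scaler(sc2, tibble::tibble(a = 1, k = 5))$k, 0)
})

test_that("mutual information ranks informative features first", {
  withr::local_seed(5)
  y <- rep(c("A", "B"), each = 100)
  strong <- rnorm(200, ifelse(y == "A", 0, 3))
  noise <- rnorm(200)
  expect_gt(mutual_information(strong, y), mutual_information(noise, y))
  expect_equal(mutual_information(rep(1, 200), y), 0)

  tr <- tibble::tibble(strong = strong, noise = noise)
  expect_equal(select_features_mi(tr, y, k = 1), "strong")
  expect_setequal(select_features_mi(tr, y, k = 2), c("strong", "noise"))
  expect_error(select_features_mi(tr, y, k = 3),
               class = "thermoleaf_validation_error")
})

test_that("offset-carrying features win selection across repeated cohorts", {
  wins <- 0
  for (rep in 1:50) {
    tbl <- make_tabular_cohort(40, offset = 3, seed = 2000 + rep)
    sel <- select_features_mi(tbl[thermal_feature_names()], tbl$treatment,
                              k = 2, seed = rep)
    if (setequal(sel, c("mean", "median"))) wins <- wins + 1
  }
  expect_gte(wins / 50, 0.95)
})

test_that("a collapsed search space returns its single point, deterministically", {
  tbl <- make_tabular_cohort(40, offset = 3, seed = 6)
  point <- tibble::tibble(k_features = 3L, rf_max_depth = 5L,
                          rf_min_samples_leaf = 5L, rf_n_trees = 50L)
  cfg <- pipeline_config("rf", cv_folds = 5L, search_iterations = 10L, seed = 9L)
  fit <- tune_and_train(tbl, cfg, search_space = point)
  expect_equal(fit$best_hyperparameters$rf_max_depth, 5L)
  expect_equal(fit$best_hyperparameters$rf_n_trees, 50L)
  expect_length(fit$selected_features, 3L)

  fit2 <- tune_and_train(tbl, cfg, search_space = point)
  expect_identical(fit$best_hyperparameters, fit2$best_hyperparameters)
  expect_identical(fit$cv_accuracy, fit2$cv_accuracy)
  expect_identical(predict(fit, tbl), predict(fit2, tbl))
})

test_that("a well-separated cohort cross-validates above 0.95", {
  tbl <- make_tabular_cohort(60, offset = 5, seed = 10, noise = 0.5)
  cfg <- pipeline_config("rf", cv_folds = 10L, search_iterations = 4L, seed = 3L)
  fit <- tune_and_train(tbl, cfg)
  expect_gte(fit$cv_accuracy, 0.95)
})

test_that("the MLP pipeline trains and evaluates end to end", {
  tbl <- make_tabular_cohort(40, offset = 4, seed = 13, noise = 0.8)
  sp <- split_dataset(tbl$treatment, seed = 4)
  cfg <- pipeline_config("mlp", cv_folds = 4L, search_iterations = 2L, seed = 5L)
  fit <- tune_and_train(tbl[sp$train, ], cfg)
  rep_ <- evaluate_pipeline(fit, tbl[sp$validation, ])
  expect_s3_class(rep_, "eval_report")
  expect_gte(rep_$accuracy, 0.8)
  expect_equal(glance(fit)$model, "mlp")
})

test_that("report arithmetic is internally consistent for random predictions", {
  withr::local_seed(20)
  for (rep in 1:20) {
    n <- sample(20:120, 1)
    truth <- sample(c("DD", "WW"), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.3, sample(c("DD", "WW"), n, replace = TRUE), truth)
    r <- eval_report(truth, pred)
    expect_equal(sum(r$confusion), r$n_validation)
    expect_equal(r$accuracy, sum(diag(r$confusion)) / r$n_validation)
    expect_equal(sum(r$per_class$support), r$n_validation)
    for (i in 1:2) {
      pc <- r$per_class[i, ]
      expect_equal(pc$f1, f1_score(pc$precision, pc$recall))
    }
  }
})

test_that("printed report metrics reproduce the worked examples", {
  # 37 WW and 45 DD correct of 105 validation leaves -> 78% accuracy
  truth <- rep(c("WW", "DD"), c(53, 52))
  pred <- c(rep("WW", 37), rep("DD", 16), rep("DD", 45), rep("WW", 7))
  r <- eval_report(truth, pred)
  expect_equal(round(100 * r$accuracy), 78)
  expect_equal(sum(diag(r$confusion)), 82)

  # F1 from printed precision/recall pairs
  expect_equal(round(f1_score(0.74, 0.87), 2), 0.80)
  expect_equal(round(f1_score(0.78, 0.71), 2), 0.74)
  expect_equal(round(f1_score(0.84, 0.70), 2), 0.76)

  # perfect predictions
  rp <- eval_report(c("DD", "WW", "DD"), c("DD", "WW", "DD"))
  expect_equal(rp$accuracy, 1)
  expect_equal(rp$confusion["DD", "WW"] + rp$confusion["WW", "DD"], 0)
})

test_that("model comparison reports deltas and support mismatches", {
  truth <- rep(c("WW", "DD"), c(54, 51))
  pred_rf <- c(rep("WW", 40), rep("DD", 14), rep("DD", 38), rep("WW", 13))
  r_rf <- eval_report(truth, pred_rf, model = "rf")
  truth2 <- rep(c("WW", "DD"), c(53, 52))
  pred_mlp <- c(rep("WW", 37), rep("DD", 16), rep("DD", 45), rep("WW", 7))
  r_mlp <- eval_report(truth2, pred_mlp, model = "mlp")

  cmp <- compare_models(r_rf, r_mlp)
  expect_equal(cmp$summary$correct, c(78, 82))
  expect_equal(cmp$delta_correct, 4)
  expect_equal(round(cmp$delta_accuracy_points, 1), 3.8)
  expect_true(cmp$same_support)   # both reports use 105 leaves

  same <- compare_models(r_rf, r_rf)
  expect_equal(same$delta_correct, 0)
  expect_equal(same$delta_accuracy_points, 0)
})

test_that("training refuses single-class data and impossible folds", {
  tbl <- make_tabular_cohort(10, offset = 1, seed = 2)
  expect_error(tune_and_train(dplyr::filter(tbl, treatment == "WW"),
                              pipeline_config("rf")),
               class = "thermoleaf_validation_error")
  expect_error(
    tune_and_train(tbl[c(1:10, 11), ], pipeline_config("rf", cv_folds = 10L)),
    class = "thermoleaf_validation_error"
  )
})
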