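small_grid <- function() tibble::tibble(mtry = "third", min_leaf = 1L)

test_that("regression metrics follow their standard definitions", {
  m <- evaluate_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(r2 = 1, rmse = 0, mae = 0))
  m2 <- evaluate_metrics(c(0, 2), c(1, 1))
  expect_equal(unlist(m2), c(r2 = 0, rmse = 1, mae = 1))
  y <- c(1, 4, 2, 5)
  m3 <- evaluate_metrics(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)
  expect_warning(m4 <- evaluate_metrics(c(2, 2), c(1, 3)), "zero-variance")
  expect_true(is.na(m4$r2))
  expect_error(evaluate_metrics(1:3, 1:2), "equal nonzero length")
})

test_that("the forest learns a perfectly learnable signal", {
  withr::with_seed(10, {
    x <- matrix(runif(300 * 6), ncol = 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- x[, 4]
  })
  fit <- train_rfr(x, y, train_config(
    n_trees = 60, cv_folds = 10, n_repeats = 1,
    grid = tibble::tibble(mtry = "all", min_leaf = 1L), seed = 2))
  expect_gte(glance(fit)$r2_test, 0.99)
  expect_gte(glance(fit)$r2_train, glance(fit)$r2_test - 0.01)
})

test_that("pure-noise targets are not fit", {
  withr::with_seed(11, {
    x <- matrix(rbinom(500 * 10, 1, 0.5), ncol = 10,
                dimnames = list(NULL, paste0("b", 1:10)))
    y <- rnorm(500)
  })
  fit <- train_rfr(x, y, train_config(n_trees = 60, cv_folds = 10,
                                      n_repeats = 1, grid = small_grid(),
                                      seed = 3))
  expect_lte(glance(fit)$r2_test, 0.2)
})

test_that("grid search selects by cross-validated MSE", {
  d <- generate_ml_dataset(seed = 12, n = 150, noise_sd = 0.05,
                           signal_kind = "orbital_linear")
  grid <- tibble::tibble(mtry = c("all", "all"), min_leaf = c(1L, 60L))
  fit <- train_rfr(d$features, d$targets,
                   train_config(n_trees = 40, cv_folds = 5, n_repeats = 1,
                                grid = grid, seed = 4))
  expect_equal(nrow(tidy(fit)), 2L)
  # a leaf as large as half the data must lose to the default
  expect_equal(fit$selected$min_leaf, 1L)
  expect_equal(tidy(fit)$cv_mse[1], min(tidy(fit)$cv_mse))
})

test_that("training demands enough rows, sane targets, and matched lengths", {
  x <- matrix(runif(60), ncol = 2)
  expect_error(train_rfr(x, rnorm(30), train_config(cv_folds = 10)),
               "at least 100 samples")
  expect_error(train_rfr(x, rep(1, 30),
                         train_config(cv_folds = 3, grid = small_grid())),
               "degenerate target")
  expect_error(rf_regressor(x, rep(1, 30)), "degenerate target")
  expect_error(train_rfr(x, rnorm(29), train_config()), "disagree")
})

test_that("worst-of-repeats reports the minimum and is reproducible", {
  d <- generate_ml_dataset(seed = 13, n = 140, noise_sd = 0.2,
                           signal_kind = "orbital_linear")
  cfg <- train_config(n_trees = 30, cv_folds = 10, n_repeats = 3,
                      grid = small_grid(), seed = 5)
  rep1 <- worst_of_repeats(d$features, d$targets, cfg)
  expect_equal(nrow(tidy(rep1)), 3L)
  expect_true(all(glance(rep1)$r2_test <= tidy(rep1)$r2_test))
  expect_lte(glance(rep1)$r2_test, mean(tidy(rep1)$r2_test))
  # bit-identical reports across runs with the same master seed
  rep2 <- worst_of_repeats(d$features, d$targets, cfg)
  expect_identical(tidy(rep1), tidy(rep2))
  # a single repeat reduces to train_rfr at the same seed
  cfg1 <- train_config(n_trees = 30, cv_folds = 10, n_repeats = 1,
                       grid = small_grid(), seed = 5)
  solo <- train_rfr(d$features, d$targets, cfg1)
  expect_equal(glance(worst_of_repeats(d$features, d$targets, cfg1)),
               glance(solo))
})

test_that("TreeSHAP matches brute-force Shapley enumeration", {
  withr::with_seed(21, {
    x <- matrix(runif(70 * 4), ncol = 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- 2 * x[, 1] + (x[, 2] > 0.5) - x[, 3] * x[, 1] + rnorm(70, 0, 0.1)
  })
  fit <- rf_regressor(x, y, n_trees = 6, min_leaf = 4, seed = 8)
  phi <- shap_values(fit, x[1:4, , drop = FALSE])
  for (i in 1:4) {
    expect_equal(as.numeric(phi[i, ]), brute_shap(fit, x[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("SHAP attributions are locally accurate and rank planted signals first", {
  d <- generate_ml_dataset(seed = 14, n = 150, noise_sd = 0.05,
                           signal_kind = "orbital_linear")
  fit <- train_rfr(d$features, d$targets,
                   train_config(n_trees = 50, cv_folds = 10, n_repeats = 1,
                                grid = small_grid(), seed = 6))
  xs <- d$features[1:40, ]
  imp <- shap_importance(fit, xs)
  expect_equal(imp$feature[1], "homo_up")
  phi <- attr(imp, "shap")
  pred <- predict(fit$model, xs)
  expect_lt(max(abs(attr(phi, "base_value") + rowSums(phi) - pred)), 1e-6)
  expect_error(shap_importance(lm(d$targets ~ 1), xs), "unsupported model")
})

test_that("no feature dominates SHAP importances of a pure-noise model", {
  withr::with_seed(22, {
    x <- matrix(runif(300 * 10), ncol = 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rnorm(300)
  })
  fit <- rf_regressor(x, y, n_trees = 60, seed = 9)
  imp <- shap_importance(fit, x[1:80, , drop = FALSE])
  expect_lt(max(imp$mean_abs_shap), 3 * median(imp$mean_abs_shap))
})

test_that("the forest agrees with an independent implementation on planted data", {
  d <- generate_ml_dataset(seed = 15, n = 250, noise_sd = 0.05,
                           signal_kind = "orbital_linear")
  tr <- 1:200
  te <- 201:250
  fit <- rf_regressor(d$features[tr, ], d$targets[tr], n_trees = 80,
                      mtry = "all", seed = 10)  # sklearn regression default
  mine <- evaluate_metrics(d$targets[te], predict(fit, d$features[te, ]))$r2
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(d$features, target = d$targets), csv)
  out <- withr::local_tempfile()
  code <- paste(
    "import sys, pandas as pd",
    "from sklearn.ensemble import RandomForestRegressor",
    "df = pd.read_csv(sys.argv[1])",
    "X, y = df.drop(columns=['target']), df['target']",
    "m = RandomForestRegressor(n_estimators=80, random_state=0)",
    "m.fit(X[:200], y[:200])",
    "open(sys.argv[2], 'w').write(str(m.score(X[200:], y[200:])))",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code), csv, out))
  expect_equal(status, 0L)
  theirs <- as.numeric(readLines(out, warn = FALSE))
  expect_gte(mine, 0.9)
  expect_gte(theirs, 0.9)
  expect_equal(mine, theirs, tolerance = 0.05)
})

test_that("prediction enforces the feature manifest", {
  withr::with_seed(30, {
    x <- matrix(runif(200), ncol = 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- x[, 1] + rnorm(50, 0, 0.1)
  })
  fit <- rf_regressor(x, y, n_trees = 20, seed = 11)
  # reordered columns are re-aligned by name
  expect_equal(predict(fit, x[, 4:1]), predict(fit, x))
  bad <- x[, 1:3]
  colnames(bad) <- c("f1", "f2", "g9")
  expect_error(predict(fit, bad), "feature manifest mismatch")
})
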