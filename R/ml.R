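#' Training configuration for the surrogate-model protocol
#'
#' Encodes the published training regimen: 200-tree random forests,
#' hyperparameters grid-searched by 10-fold cross-validation on the
#' training portion (minimizing MSE), an 80/20 shuffled train/test
#' split, and the assessment repeated five times with the worst result
#' reported. The default grid spans the feature-subsampling rule and
#' minimum leaf size; remaining hyperparameters stay at their
#' defaults.
#'
#' @param n_trees Trees per forest (default 200).
#' @param cv_folds Cross-validation folds (default 10).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param n_repeats Assessment repetitions (default 5).
#' @param grid Data frame of hyperparameter combinations with columns
#'   `mtry` (count or `"sqrt"`/`"third"`/`"all"`) and `min_leaf`.
#' @param seed Master seed; every split, fold assignment and forest
#'   derives from it deterministically.
#' @param share_search If `TRUE`, the hyperparameter search runs once
#'   and is reused across repeats; by default each repeat re-searches.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_trees = 200L, cv_folds = 10L, test_fraction = 0.2,
                         n_repeats = 5L, grid = default_hyper_grid(),
                         seed = 1L, share_search = FALSE) {
  stopifnot(n_trees >= 1L, cv_folds >= 2L,
            test_fraction > 0, test_fraction < 1, n_repeats >= 1L,
            is.data.frame(grid), all(c("mtry", "min_leaf") %in% names(grid)),
            nrow(grid) >= 1L)
  structure(
    list(n_trees = as.integer(n_trees), cv_folds = as.integer(cv_folds),
         test_fraction = test_fraction, n_repeats = as.integer(n_repeats),
         grid = as_tibble(grid), seed = as.integer(seed),
         share_search = isTRUE(share_search)),
    class = "train_config"
  )
}

#' @rdname train_config
#' @export
default_hyper_grid <- function() {
  tidyr::expand_grid(mtry = c("sqrt", "third", "all"),
                     min_leaf = c(1L, 2L, 5L))
}

#' Regression metrics
#'
#' `R2 = 1 - SS_res / SS_tot`, root-mean-squared error, and mean
#' absolute error. A zero-variance truth vector leaves R2 undefined:
#' it is returned as `NA` with a warning.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A one-row tibble with `r2`, `rmse`, `mae`.
#' @examples
#' evaluate_metrics(c(0, 2), c(1, 1)) # r2 0, rmse 1, mae 1
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  stopifnot(is.numeric(y_true), is.numeric(y_pred))
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    abort("`y_true` and `y_pred` must have equal nonzero length")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  ss_res <- sum((y_true - y_pred)^2)
  r2 <- if (ss_tot == 0) {
    warn("zero-variance `y_true`: R2 is undefined (returned as NA)")
    NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  tibble(r2 = r2, rmse = sqrt(mean((y_true - y_pred)^2)),
         mae = mean(abs(y_true - y_pred)))
}

# k-fold CV MSE of one hyperparameter combination on (x, y).
.cv_mse <- function(x, y, combo, config, fold_id, seed) {
  errs <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold_id != f
    fit <- rf_regressor(x[tr, , drop = FALSE], y[tr],
                        n_trees = config$n_trees, mtry = combo$mtry,
                        min_leaf = combo$min_leaf, seed = seed + f)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    errs[f] <- mean((y[!tr] - pred)^2)
  }
  mean(errs)
}

#' Train a random-forest surrogate with the published protocol
#'
#' Shuffles the data, holds out `test_fraction` of it, grid-searches
#' hyperparameters by k-fold cross-validated MSE on the training
#' portion, refits the winning combination on the full training
#' portion, and reports held-out metrics together with the train-set
#' and out-of-bag R2.
#'
#' @param features Feature matrix or data frame.
#' @param targets Numeric response.
#' @param config A [train_config()].
#' @param search Optional pre-selected hyperparameters (a one-row data
#'   frame) to skip the search, used by [worst_of_repeats()] when
#'   `share_search = TRUE`.
#' @return An object of class `rfr_fit`: list with `model`
#'   (an [rf_regressor()]), `metrics` (one-row tibble: r2_train,
#'   r2_test, r2_oob, rmse, mae, n_train, n_test), `cv` (grid-search
#'   table), and `selected` (winning hyperparameters).
#' @export
train_rfr <- function(features, targets, config = train_config(),
                      search = NULL) {
  stopifnot(inherits(config, "train_config"))
  x <- .as_feature_matrix(features)
  y <- as.numeric(targets)
  if (nrow(x) != length(y)) abort("features and targets disagree in length")
  if (length(y) < 10L * config$cv_folds) {
    abort(sprintf("need at least %d samples for %d-fold cross-validation",
                  10L * config$cv_folds, config$cv_folds))
  }
  if (var(y) == 0) abort("degenerate target: zero variance")

  with_seed(config$seed, {
    ord <- sample.int(length(y))
    n_test <- max(1L, round(config$test_fraction * length(y)))
    test_idx <- ord[seq_len(n_test)]
    train_idx <- ord[-seq_len(n_test)]
    xt <- x[train_idx, , drop = FALSE]
    yt <- y[train_idx]
    fold_id <- rep_len(seq_len(config$cv_folds), length(yt))[
      sample.int(length(yt))]
    # headroom below .Machine$integer.max for per-fold/per-combo offsets
    forest_seed <- sample.int(2000000000L, 1L)

    cv_tab <- NULL
    if (is.null(search)) {
      cv_tab <- config$grid
      cv_tab$cv_mse <- purrr::map_dbl(seq_len(nrow(cv_tab)), function(i) {
        .cv_mse(xt, yt, cv_tab[i, ], config, fold_id, forest_seed + 1000L * i)
      })
      selected <- cv_tab[which.min(cv_tab$cv_mse), c("mtry", "min_leaf")]
    } else {
      selected <- as_tibble(search)[, c("mtry", "min_leaf")]
    }

    model <- rf_regressor(xt, yt, n_trees = config$n_trees,
                          mtry = selected$mtry[[1L]],
                          min_leaf = selected$min_leaf[[1L]],
                          seed = forest_seed)
    pred_test <- predict(model, x[test_idx, , drop = FALSE])
    pred_train <- predict(model, xt)
    test_m <- evaluate_metrics(y[test_idx], pred_test)
    train_m <- evaluate_metrics(yt, pred_train)
    metrics <- tibble(
      r2_train = train_m$r2, r2_test = test_m$r2, r2_oob = model$r2_oob,
      rmse = test_m$rmse, mae = test_m$mae,
      n_train = length(train_idx), n_test = n_test)
    structure(
      list(model = model, metrics = metrics, cv = cv_tab,
           selected = selected, config = config),
      class = "rfr_fit"
    )
  })
}

#' @export
print.rfr_fit <- function(x, ...) {
  cat(sprintf("<rfr_fit> %d trees, mtry=%s, min_leaf=%s\n",
              x$model$n_trees, x$selected$mtry[[1L]], x$selected$min_leaf[[1L]]))
  print(x$metrics)
  invisible(x)
}

#' @method glance rfr_fit
#' @export
glance.rfr_fit <- function(x, ...) x$metrics

#' @method tidy rfr_fit
#' @export
tidy.rfr_fit <- function(x, ...) {
  x$cv %||% dplyr::mutate(x$selected, cv_mse = NA_real_)
}

#' Worst-of-repeats model assessment
#'
#' Repeats the full shuffle/split/search/train/test cycle
#' `config$n_repeats` times with independent shuffles and reports the
#' repeat with the lowest held-out R2 (ties broken toward the higher
#' RMSE) -- a conservative performance statement. With
#' `share_search = TRUE` the hyperparameter search from the first
#' repeat is reused.
#'
#' @inheritParams train_rfr
#' @return An object of class `rfr_repeats`: list with `fits` (all
#'   repeats), `worst` (index), `per_repeat` (metrics tibble), and the
#'   worst repeat's `rfr_fit` under `$report`.
#' @export
worst_of_repeats <- function(features, targets, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  fits <- vector("list", config$n_repeats)
  search <- NULL
  for (i in seq_len(config$n_repeats)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + 1009L * (i - 1L)) %% 2000000000L
    fits[[i]] <- train_rfr(features, targets, cfg_i, search = search)
    if (config$share_search && is.null(search)) search <- fits[[i]]$selected
  }
  per_repeat <- dplyr::bind_rows(purrr::map(fits, glance))
  per_repeat$repeat_id <- seq_len(config$n_repeats)
  worst <- order(per_repeat$r2_test, -per_repeat$rmse)[1L]
  structure(
    list(fits = fits, worst = worst, per_repeat = per_repeat,
         report = fits[[worst]], config = config),
    class = "rfr_repeats"
  )
}

#' @export
print.rfr_repeats <- function(x, ...) {
  cat(sprintf("<rfr_repeats> %d repeats; worst repeat: %d\n",
              nrow(x$per_repeat), x$worst))
  print(x$per_repeat)
  invisible(x)
}

#' @method tidy rfr_repeats
#' @export
tidy.rfr_repeats <- function(x, ...) x$per_repeat

#' @method glance rfr_repeats
#' @export
glance.rfr_repeats <- function(x, ...) glance(x$report)

#' SHAP feature-importance ranking
#'
#' TreeSHAP attributions (see [shap_values()]) summarized as the mean
#' absolute attribution per feature, ranked. The per-sample attribution
#' matrix is attached as attribute `"shap"` (with its `"base_value"`).
#'
#' @param model An `rfr_fit`, `rfr_repeats`, or `rf_regressor`.
#' @param features Samples to attribute (matrix or data frame).
#' @return A tibble with `feature`, `mean_abs_shap`, `rank`.
#' @export
shap_importance <- function(model, features) {
  if (inherits(model, "rfr_repeats")) model <- model$report
  if (inherits(model, "rfr_fit")) model <- model$model
  if (!inherits(model, "rf_regressor")) {
    abort("unsupported model type: expected rf_regressor / rfr_fit / rfr_repeats")
  }
  phi <- shap_values(model, features)
  out <- tibble(feature = colnames(phi),
                mean_abs_shap = colMeans(abs(phi)))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_abs_shap))
  out$rank <- seq_len(nrow(out))
  attr(out, "shap") <- phi
  out
}
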