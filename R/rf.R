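# Feature matrices: accept a data frame or matrix, keep the manifest of
# column names so serving-time inputs can be checked against it.
.as_feature_matrix <- function(x, manifest = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) abort("features must be a matrix or data frame")
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  if (!is.null(manifest)) {
    if (!identical(colnames(x), manifest)) {
      if (all(manifest %in% colnames(x))) {
        x <- x[, manifest, drop = FALSE]
      } else {
        abort(paste0("feature manifest mismatch: model was trained on [",
                     paste(head(manifest, 3L), collapse = ", "),
                     ", ...] but input provides [",
                     paste(head(colnames(x), 3L), collapse = ", "), ", ...]"))
      }
    }
  }
  x
}

.resolve_mtry <- function(mtry, p) {
  if (is.numeric(mtry)) {
    m <- as.integer(mtry)
  } else {
    m <- switch(match.arg(mtry, c("sqrt", "third", "all")),
                sqrt = floor(sqrt(p)), third = floor(p / 3), all = p)
  }
  max(1L, min(as.integer(m), p))
}

#' Random-forest regressor
#'
#' A bagged CART ensemble for regression, grown on bootstrap samples
#' with variance-reduction splits, a per-node random feature subset,
#' and out-of-bag (OOB) scoring. The implementation is the package's
#' own (compiled) and is fully deterministic in `seed`; fitted models
#' are plain R lists and serialize with `saveRDS()`.
#'
#' @param x Feature matrix or data frame (rows = samples).
#' @param y Numeric response.
#' @param n_trees Number of trees (default 200).
#' @param mtry Features tried per split: a count, or one of `"sqrt"`
#'   (default, `floor(sqrt(p))`), `"third"` (`floor(p/3)`), `"all"`.
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param max_depth Maximum tree depth; `0` (default) means unlimited.
#' @param seed Integer seed for bootstrap and feature sampling.
#'
#' @return An object of class `rf_regressor` with components `trees`,
#'   `feature_names`, `oob_prediction`, `r2_oob`, and the
#'   hyperparameters used.
#' @examples
#' x <- matrix(runif(600), ncol = 3)
#' fit <- rf_regressor(x, x[, 1] + 0.1 * x[, 2], n_trees = 50, seed = 1)
#' fit$r2_oob
#' @export
rf_regressor <- function(x, y, n_trees = 200L, mtry = "sqrt", min_leaf = 1L,
                         max_depth = 0L, seed = 1L) {
  x <- .as_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) abort("length(y) must equal nrow(x)")
  if (any(!is.finite(y)) || any(!is.finite(x))) {
    abort("features and response must be finite")
  }
  if (var(y) == 0) abort("degenerate target: response has zero variance")
  m <- .resolve_mtry(mtry, ncol(x))
  fit <- .rf_fit_cpp(x, y, as.integer(n_trees), m, as.integer(min_leaf),
                     as.integer(max_depth), as.integer(seed))
  oob <- fit$oob_prediction
  ok <- is.finite(oob)
  r2_oob <- if (sum(ok) >= 2L && var(y[ok]) > 0) {
    1 - sum((y[ok] - oob[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  } else {
    NA_real_
  }
  structure(
    list(trees = fit$trees, feature_names = colnames(x),
         oob_prediction = oob, r2_oob = r2_oob,
         n_trees = as.integer(n_trees), mtry = m,
         min_leaf = as.integer(min_leaf), max_depth = as.integer(max_depth),
         seed = as.integer(seed), n_train = nrow(x)),
    class = "rf_regressor"
  )
}

#' @export
print.rf_regressor <- function(x, ...) {
  cat(sprintf("<rf_regressor> %d trees, mtry %d of %d features, min_leaf %d\n",
              x$n_trees, x$mtry, length(x$feature_names), x$min_leaf))
  cat(sprintf("  trained on %d samples, R2_oob = %.4f\n", x$n_train, x$r2_oob))
  invisible(x)
}

#' Predict from a random-forest regressor
#'
#' @param object An `rf_regressor`.
#' @param newdata Feature matrix or data frame; columns are matched to
#'   the training manifest by name and must all be present.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rf_regressor <- function(object, newdata, ...) {
  x <- .as_feature_matrix(newdata, manifest = object$feature_names)
  as.numeric(.rf_predict_cpp(object$trees, x))
}

#' TreeSHAP attributions for a forest
#'
#' Exact Shapley values of each tree's conditional-expectation value
#' function (cover-weighted expectations over the unobserved branch),
#' averaged over the ensemble. Satisfies local accuracy: for every
#' sample, `base_value + sum(phi)` equals the forest prediction.
#'
#' @param object An `rf_regressor`.
#' @param newdata Samples to explain (matrix or data frame).
#' @return A matrix (samples x features) of attributions with
#'   attribute `base_value`.
#' @export
shap_values <- function(object, newdata) {
  if (!inherits(object, "rf_regressor")) {
    abort("unsupported model type: TreeSHAP needs an rf_regressor tree ensemble")
  }
  x <- .as_feature_matrix(newdata, manifest = object$feature_names)
  res <- .rf_shap_cpp(object$trees, x)
  phi <- res$phi
  dimnames(phi) <- list(rownames(x), object$feature_names)
  attr(phi, "base_value") <- res$base_value
  phi
}
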