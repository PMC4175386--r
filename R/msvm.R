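#' Fit a multiclass support vector machine
#'
#' The package's central modelling interface: fits a K-class soft-margin
#' kernel SVM by binary decomposition (one-against-one voting by
#' default; see [train_multiclass()] for the strategies) and returns a
#' classed fit with the usual `print`, `summary`, `predict` and `coef`
#' methods.
#'
#' @param x a numeric matrix / [feature_table] of predictors, or a
#'   formula.
#' @param ... passed on between methods.
#' @return An object of class `msvm`: the underlying `multiclass_svm`
#'   plus the call, class counts and training accuracy.
#' @examples
#' d <- synth_blobs(n_classes = 3, n_per_class = 15, seed = 1)
#' fit <- msvm(d$table, d$labels, C = 10, gamma = 1)
#' fit
#' table(predict(fit, d$table), d$labels$labels)
#' @export
msvm <- function(x, ...) UseMethod("msvm")

#' @rdname msvm
#' @param y class labels (integer codes `1..K`, factor, or a
#'   [label_vector]).
#' @param kernel kernel kind, one of `"rbf"`, `"linear"`,
#'   `"polynomial"`, `"sigmoid"`.
#' @param C soft-margin penalty, default 1.
#' @param gamma kernel scale parameter, default 1.
#' @param coef_r,degree_m additive constant and degree for the
#'   polynomial/sigmoid kernels.
#' @param strategy multiclass decomposition, `"OAO"` (default), `"OAA"`
#'   or `"DAG"`.
#' @param tolerance dual-solver tolerance.
#' @export
msvm.default <- function(x, y, kernel = c("rbf", "linear", "polynomial",
                                          "sigmoid"),
                         C = 1, gamma = 1, coef_r = 0, degree_m = 3L,
                         strategy = c("OAO", "OAA", "DAG"),
                         tolerance = 1e-6, ...) {
  kernel <- match.arg(kernel)
  strategy <- match.arg(strategy)
  cfg <- svm_config(kernel_spec(kernel, gamma = gamma, coef_r = coef_r,
                                degree_m = degree_m),
                    C = C, tolerance = tolerance)
  xm <- as_matrix_x(x)
  yv <- as_labels_y(y)
  core <- train_multiclass(xm, yv, cfg, strategy)
  pred <- predict_multiclass(core, xm)
  structure(
    list(core = core, config = cfg, strategy = strategy,
         class_counts = table(yv),
         feature_ids = if (inherits(x, "feature_table")) x$feature_ids
                       else colnames(xm),
         train_accuracy = mean(pred == yv),
         call = match.call()),
    class = "msvm"
  )
}

#' @rdname msvm
#' @param formula a model formula `class ~ .` (or explicit predictors).
#' @param data a data frame holding predictors and the class column.
#' @export
msvm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  xm <- stats::model.matrix(attr(mf, "terms"), mf)
  xm <- xm[, colnames(xm) != "(Intercept)", drop = FALSE]
  fit <- msvm.default(xm, y, ...)
  fit$call <- match.call()
  fit
}

#' @export
#' @param x an `msvm` fit (for `formula`, the formula argument).
#' @rdname msvm
print.msvm <- function(x, ...) {
  cat("Multiclass SVM fit\n")
  cat(sprintf("  strategy: %s   classes: %d   binary machines: %d\n",
              x$strategy, length(x$core$class_codes),
              length(x$core$binary_models)))
  cat(sprintf("  kernel: %s  C=%g", x$config$kernel$kind, x$config$C))
  if (x$config$kernel$kind != "linear") {
    cat(sprintf("  gamma=%g", x$config$kernel$gamma))
  }
  cat(sprintf("\n  training accuracy: %.4f\n", x$train_accuracy))
  invisible(x)
}

#' @export
summary.msvm <- function(object, ...) {
  nsv <- vapply(object$core$binary_models,
                function(m) length(m$alpha), integer(1))
  out <- list(fit = object, n_sv = nsv)
  class(out) <- "summary.msvm"
  out
}

#' @export
print.summary.msvm <- function(x, ...) {
  print(x$fit)
  cat("  class counts:\n")
  print(x$fit$class_counts)
  cat(sprintf("  support vectors per machine: %s\n",
              paste(x$n_sv, collapse = ", ")))
  invisible(x)
}

#' @export
predict.msvm <- function(object, newdata, ...) {
  predict_multiclass(object$core, newdata)
}

#' Linear feature weights of a fitted multiclass SVM
#'
#' For a linear-kernel fit, returns the weight vector
#' \eqn{w = \sum_i y_i \alpha_i x_i} of every binary machine (one row
#' per machine), the quantity whose squared components drive SVM-RFE.
#'
#' @param object an `msvm` fit with a linear kernel.
#' @param ... unused.
#' @return Numeric matrix, machines in rows, features in columns.
#' @export
coef.msvm <- function(object, ...) {
  w <- t(vapply(object$core$binary_models, compute_feature_weights,
                numeric(object$core$binary_models[[1L]]$n_features)))
  rn <- vapply(object$core$binary_models, function(m) {
    if (!is.null(m$target)) paste0(m$target, "/rest")
    else paste(m$pair, collapse = "/")
  }, character(1))
  dimnames(w) <- list(rn, object$feature_ids)
  w
}
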