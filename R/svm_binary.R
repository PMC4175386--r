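#' SVM training configuration
#'
#' Bundles the soft-margin penalty `C`, the kernel, and the dual-solver
#' tolerance. Larger `C` penalises margin violations more strongly;
#' `C = 1e6` effectively recovers the hard-margin machine on separable
#' data.
#'
#' @param kernel a [kernel_spec]. Default RBF with gamma = 1.
#' @param C positive soft-margin penalty. Default 1.
#' @param tolerance positive dual-solver termination tolerance.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(kernel = kernel_spec("rbf"), C = 1,
                       tolerance = 1e-6) {
  if (!inherits(kernel, "kernel_spec")) stopf("`kernel` must be a kernel_spec")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stopf("C must be > 0")
  if (!is.numeric(tolerance) || tolerance <= 0) stopf("tolerance must be > 0")
  structure(list(kernel = kernel, C = C, tolerance = tolerance),
            class = "svm_config")
}

#' @export
print.svm_config <- function(x, ...) {
  cat(sprintf("<svm_config> C=%g, kernel=%s", x$C, x$kernel$kind))
  if (x$kernel$kind != "linear") cat(sprintf(" gamma=%g", x$kernel$gamma))
  cat("\n")
  invisible(x)
}

#' Train a binary soft-margin kernel SVM
#'
#' Solves the dual problem
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i
#'   \alpha_j y_i y_j K(x_i, x_j), \quad 0 \le \alpha_i \le C, \quad
#'   \sum_i \alpha_i y_i = 0}
#' and returns the support expansion. The quadratic program is solved by
#' libsvm (via \pkg{e1071}); the support coefficients, vectors, labels
#' and bias are extracted into a plain `binary_svm` object so that
#' decision values, feature weights and feasibility checks are computed
#' by this package, independent of the solver's predict path.
#'
#' @param x numeric matrix (or [feature_table]) of training instances.
#' @param y labels in `{-1, +1}`, both classes present.
#' @param config an [svm_config].
#' @return An object of class `binary_svm` with elements `alpha`
#'   (support coefficients, `0 < alpha_i <= C`), `sv` (support vectors),
#'   `sv_labels` (+1/-1), `bias`, `kernel`, `C`, `n_features`.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- train_binary_svm(x, c(-1, 1),
#'                       svm_config(kernel_spec("linear"), C = 1000))
#' decision_value(m, matrix(c(-1, 1), ncol = 1))
#' @export
train_binary_svm <- function(x, y, config = svm_config()) {
  x <- as_matrix_x(x)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stopf("labels must be in {-1, +1}")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (length(y) != nrow(x)) stopf("%d labels for %d rows", length(y), nrow(x))
  ks <- config$kernel
  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(1, -1)),
    scale = FALSE, type = "C-classification",
    kernel = switch(ks$kind, linear = "linear", polynomial = "polynomial",
                    rbf = "radial", sigmoid = "sigmoid"),
    cost = config$C,
    gamma = if (ks$kind == "linear") 1 else ks$gamma,
    coef0 = ks$coef_r, degree = ks$degree_m,
    tolerance = min(config$tolerance, 1e-3), cachesize = 64
  )
  # libsvm orients coefs/rho so a positive decision value means the class
  # occurring first in the training data (fit$levels[fit$labels[1]]);
  # normalise so positive always means class +1
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  if (as.numeric(as.character(fit$levels[fit$labels[1L]])) == -1) {
    coefs <- -coefs
    rho <- -rho
  }
  structure(
    list(alpha = abs(coefs),
         sv = unname(as.matrix(fit$SV)),
         sv_labels = as.numeric(sign(coefs)),
         bias = -rho,
         kernel = ks, C = config$C, n_features = ncol(x)),
    class = "binary_svm"
  )
}

#' Decision values of a binary SVM
#'
#' Evaluates \eqn{f(x) = \sum_i y_i \alpha_i K(x, x_i) + b}; the
#' predicted label is `sign(f(x))` with positive meaning class `+1`.
#'
#' @param model a `binary_svm` from [train_binary_svm()].
#' @param x numeric matrix (or single vector) of query points.
#' @return Numeric vector of decision values, one per query row.
#' @export
decision_value <- function(model, x) {
  if (!inherits(model, "binary_svm")) stopf("`model` must be a binary_svm")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as_matrix_x(x)
  if (ncol(x) != model$n_features) {
    stopf("query has %d features, model expects %d", ncol(x),
          model$n_features)
  }
  k <- kernel_cross(model$kernel, x, model$sv)
  drop(k %*% (model$alpha * model$sv_labels)) + model$bias
}

#' @export
print.binary_svm <- function(x, ...) {
  cat(sprintf("<binary_svm> %d support vectors, C=%g, kernel=%s, bias=%.4g\n",
              length(x$alpha), x$C, x$kernel$kind, x$bias))
  invisible(x)
}

#' Check dual feasibility of a trained binary SVM
#'
#' Verifies the box constraints `0 <= alpha_i <= C` and the equality
#' constraint `sum(alpha_i y_i) = 0` within a tolerance.
#'
#' @param model a `binary_svm`.
#' @param tol nonnegative slack, default `1e-6` scaled by `C`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_dual_feasibility <- function(model, tol = 1e-6) {
  slack <- tol * max(1, model$C)
  if (any(model$alpha < -slack)) stopf("negative alpha")
  if (any(model$alpha > model$C + slack)) {
    stopf("alpha exceeds box bound C=%g by %g", model$C,
          max(model$alpha) - model$C)
  }
  eq <- abs(sum(model$alpha * model$sv_labels))
  if (eq > slack * length(model$alpha)) {
    stopf("equality constraint violated: |sum alpha*y| = %g", eq)
  }
  invisible(TRUE)
}

# JSON (de)serialisation of the documented model layout --------------------

#' Serialise / restore a binary SVM model
#'
#' The JSON layout stores `alpha`, `sv` (row-major matrix), `sv_labels`,
#' `bias`, `C` and the kernel spec, so models round-trip across sessions
#' without reference to the solver.
#'
#' @param model a `binary_svm`.
#' @param path file path for the JSON document.
#' @return `write_binary_svm` returns `path` invisibly;
#'   `read_binary_svm` returns the restored `binary_svm`.
#' @export
write_binary_svm <- function(model, path) {
  obj <- list(alpha = model$alpha, sv = model$sv,
              sv_labels = model$sv_labels, bias = model$bias, C = model$C,
              kernel = unclass(model$kernel), n_features = model$n_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binary_svm
#' @export
read_binary_svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- kernel_spec(obj$kernel$kind, gamma = obj$kernel$gamma,
                    coef_r = obj$kernel$coef_r,
                    degree_m = obj$kernel$degree_m)
  structure(
    list(alpha = as.numeric(obj$alpha), sv = as.matrix(obj$sv),
         sv_labels = as.numeric(obj$sv_labels), bias = as.numeric(obj$bias),
         kernel = ks, C = as.numeric(obj$C),
         n_features = as.integer(obj$n_features)),
    class = "binary_svm"
  )
}
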