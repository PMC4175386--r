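#' Kernel specification
#'
#' The four standard SVM kernels. Conventions:
#' \describe{
#'   \item{linear}{\eqn{K(x,y) = x \cdot y}}
#'   \item{polynomial}{\eqn{K(x,y) = (\gamma\, x \cdot y + r)^m}}
#'   \item{rbf}{\eqn{K(x,y) = \exp(-\gamma \|x-y\|^2)}}
#'   \item{sigmoid}{\eqn{K(x,y) = \tanh(\gamma\, x \cdot y + r)}}
#' }
#' The RBF kernel is parameterised directly by `gamma` (not by a
#' bandwidth sigma): this is the convention under which tuning grids
#' such as gamma in 2.4..12 are meaningful, and it matches libsvm.
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param gamma positive scale parameter (ignored for linear).
#' @param coef_r additive constant r for polynomial/sigmoid. Default 0.
#' @param degree_m positive integer polynomial degree. Default 3.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = 1, coef_r = 0, degree_m = 3L) {
  kind <- match.arg(kind)
  if (kind != "linear" && (!is.numeric(gamma) || gamma <= 0)) {
    stopf("gamma must be > 0 for the %s kernel", kind)
  }
  if (!is_count(degree_m)) stopf("degree_m must be a positive integer")
  structure(list(kind = kind, gamma = gamma, coef_r = coef_r,
                 degree_m = as.integer(degree_m)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
    linear = "",
    rbf = sprintf(" (gamma=%g)", x$gamma),
    polynomial = sprintf(" (gamma=%g, r=%g, m=%d)", x$gamma, x$coef_r,
                         x$degree_m),
    sigmoid = sprintf(" (gamma=%g, r=%g)", x$gamma, x$coef_r))
  cat(sprintf("<kernel_spec> %s%s\n", x$kind, extra))
  invisible(x)
}

#' Evaluate a kernel on two vectors
#'
#' @param spec a [kernel_spec].
#' @param x,y numeric vectors of equal length.
#' @return The scalar kernel value.
#' @examples
#' kernel_eval(kernel_spec("linear"), c(1, 2), c(3, 4)) # 11
#' @export
kernel_eval <- function(spec, x, y) {
  if (length(x) != length(y)) {
    stopf("dimension mismatch: %d vs %d", length(x), length(y))
  }
  drop(kernel_cross(spec, matrix(x, 1L), matrix(y, 1L)))
}

# Cross-kernel matrix K[i, j] = K(a_i, b_j) for row-matrices a, b.
kernel_cross <- function(spec, a, b) {
  if (ncol(a) != ncol(b)) {
    stopf("dimension mismatch: %d vs %d columns", ncol(a), ncol(b))
  }
  switch(spec$kind,
    linear = a %*% t(b),
    polynomial = (spec$gamma * (a %*% t(b)) + spec$coef_r)^spec$degree_m,
    sigmoid = tanh(spec$gamma * (a %*% t(b)) + spec$coef_r),
    rbf = {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
      exp(-spec$gamma * pmax(d2, 0))
    })
}

#' Gram matrix of a sample under a kernel
#'
#' @param spec a [kernel_spec].
#' @param x numeric matrix, one instance per row.
#' @return The symmetric `nrow(x)` x `nrow(x)` kernel matrix.
#' @export
kernel_matrix <- function(spec, x) {
  x <- as_matrix_x(x)
  k <- kernel_cross(spec, x, x)
  (k + t(k)) / 2
}
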