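#' Linear feature weights of a binary SVM
#'
#' For a linear-kernel machine the decision function is
#' \eqn{f(x) = w \cdot x + b} with \eqn{w = \sum_k \alpha_k y_k x_k};
#' this returns that `w`. Weights are undefined for nonlinear kernels,
#' so those are an error: rank with the linear kernel (the package's
#' RFE always does) and tune the nonlinear classifier afterwards.
#'
#' @param model a `binary_svm` trained with the linear kernel.
#' @return Numeric weight vector, one entry per feature.
#' @export
compute_feature_weights <- function(model) {
  if (!inherits(model, "binary_svm")) stopf("`model` must be a binary_svm")
  if (model$kernel$kind != "linear") {
    stopf(paste("feature weights are defined only for the linear kernel;",
                "run the RFE ranking in linear mode"))
  }
  drop(t(model$sv) %*% (model$alpha * model$sv_labels))
}

#' Squared-weight ranking criterion
#'
#' The RFE importance of feature i is \eqn{c_i = w_i^2}: invariant to
#' the sign of the weight and proportional to the sensitivity of the
#' margin to removing the feature.
#'
#' @param w numeric weight vector.
#' @return Nonnegative criterion vector `w^2`.
#' @export
ranking_criterion <- function(w) as.numeric(w)^2

#' Aggregate ranking criteria across binary machines
#'
#' A multiclass decomposition yields one weight vector per binary
#' machine; the multiclass RFE criterion is the elementwise sum of the
#' per-machine squared weights.
#'
#' @param criteria list of equal-length nonnegative criterion vectors.
#' @return Single criterion vector, the elementwise sum.
#' @export
aggregate_multiclass_criteria <- function(criteria) {
  if (!length(criteria)) stopf("empty criterion list")
  d <- lengths(criteria)
  if (length(unique(d)) != 1L) {
    stopf("criterion dimension mismatch: %s", paste(unique(d), collapse = ", "))
  }
  Reduce(`+`, lapply(criteria, as.numeric))
}

#' SVM recursive feature elimination
#'
#' Backward elimination over the full feature set: at each iteration a
#' linear-kernel multiclass SVM is retrained on the surviving features,
#' every feature is scored by the aggregated squared weight criterion,
#' and the single lowest-scoring feature (ties to the lowest column
#' index) is removed and prepended to the ranked list. The loop runs
#' until no features remain, so the result is a complete ranking:
#' `ranked_ids[1]` is the most important (last-surviving) feature.
#'
#' The internal machines always use the linear kernel (the weight
#' criterion is linear-only); `C` defaults to 1 and is deliberately not
#' tuned here — parameter tuning happens after ranking, on the final
#' classifier.
#'
#' @param x numeric matrix or [feature_table].
#' @param y labels ([label_vector] or integer codes).
#' @param C soft-margin penalty of the internal linear machines.
#' @param strategy multiclass decomposition used internally, default
#'   `"OAO"`.
#' @param tolerance dual-solver tolerance.
#' @return An object of class `svm_rfe`: `ranked_ids` (descending
#'   importance), `elimination_order` (removal order; its reverse equals
#'   `ranked_ids`), and `per_iteration`, a list of
#'   `list(remaining, criterion)` audit records.
#' @examples
#' d <- synth_planted(n = 60, n_features = 5, informative = c(1, 2),
#'                    seed = 1)
#' r <- svm_rfe(d$table, d$labels)
#' r$ranked_ids
#' @export
svm_rfe <- function(x, y, C = 1, strategy = c("OAO", "OAA"),
                    tolerance = 1e-6) {
  strategy <- match.arg(strategy)
  xm <- as_matrix_x(x)
  yv <- as_labels_y(y)
  ids <- if (inherits(x, "feature_table")) x$feature_ids
         else if (!is.null(colnames(xm))) colnames(xm)
         else paste0("V", seq_len(ncol(xm)))
  if (ncol(xm) < 1L) stopf("need at least one feature")
  cfg <- svm_config(kernel_spec("linear"), C = C, tolerance = tolerance)

  remaining <- seq_len(ncol(xm))
  elim <- character(0)
  audit <- list()
  iter <- 0L
  while (length(remaining) > 0L) {
    iter <- iter + 1L
    mc <- tryCatch(
      train_multiclass(xm[, remaining, drop = FALSE], yv, cfg, strategy),
      error = function(e) {
        stopf("RFE training failed at iteration %d (remaining: %s): %s",
              iter, paste(ids[remaining], collapse = ","),
              conditionMessage(e))
      })
    crit <- aggregate_multiclass_criteria(
      lapply(mc$binary_models,
             function(m) ranking_criterion(compute_feature_weights(m))))
    audit[[iter]] <- list(remaining = ids[remaining],
                          criterion = as.numeric(crit))
    worst <- remaining[which.min(crit)]
    elim <- c(elim, ids[worst])
    remaining <- setdiff(remaining, worst)
  }
  structure(list(ranked_ids = rev(elim), elimination_order = elim,
                 per_iteration = audit, strategy = strategy, C = C),
            class = "svm_rfe")
}

#' @export
print.svm_rfe <- function(x, ...) {
  cat(sprintf("<svm_rfe> %d features ranked (%s, linear kernel, C=%g)\n",
              length(x$ranked_ids), x$strategy, x$C))
  cat("ranking:", paste(x$ranked_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.svm_rfe <- function(x, ...) {
  n <- lengths(lapply(x$per_iteration, `[[`, "remaining"))
  mins <- vapply(x$per_iteration, function(it) min(it$criterion), numeric(1))
  graphics::plot(n, mins, type = "b", log = "",
                 xlab = "features remaining",
                 ylab = "minimum criterion (w^2)",
                 main = "SVM-RFE elimination path", ...)
  invisible(x)
}

#' Select the top-k features of a ranking
#'
#' @param ranking an `svm_rfe` object.
#' @param k number of features to keep, `1 <= k <= length(ranked_ids)`.
#' @return Character vector: the first `k` ranked feature ids, in rank
#'   order.
#' @export
select_top_k <- function(ranking, k) {
  if (!inherits(ranking, "svm_rfe")) stopf("`ranking` must be an svm_rfe")
  n <- length(ranking$ranked_ids)
  if (!is_count(k) || k > n) stopf("k must be in 1..%d, got %s", n, k)
  ranking$ranked_ids[seq_len(k)]
}

#' Write a feature ranking to disk
#'
#' Emits a two-column TSV (`rank`, `feature_id`) plus, optionally, a
#' JSON audit of the per-iteration criterion vectors.
#'
#' @param ranking an `svm_rfe` object.
#' @param tsv_path path for the ranking TSV.
#' @param json_path optional path for the JSON audit.
#' @return `tsv_path`, invisibly.
#' @export
write_ranking <- function(ranking, tsv_path, json_path = NULL) {
  df <- data.frame(rank = seq_along(ranking$ranked_ids),
                   feature_id = ranking$ranked_ids)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(ranking$per_iteration, json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
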