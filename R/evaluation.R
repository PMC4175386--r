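#' Stratified k-fold assignment
#'
#' Randomly partitions instances into `k` folds class by class: each
#' class's instances are shuffled and dealt round-robin starting from a
#' random fold, so per-class fold counts never differ by more than one.
#' Classes with fewer than `k` members simply appear in that many folds
#' (never twice in one fold). Deterministic given `seed`.
#'
#' @param labels a [label_vector] or integer class codes.
#' @param k fold count, `2 <= k <=` instance count.
#' @param seed integer RNG seed for the shuffle.
#' @return An object of class `cv_plan`: `k`, `fold` (per-instance fold
#'   index in `1..k`), `seed`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  y <- as_labels_y(labels)
  n <- length(y)
  if (!is_count(k) || k < 2L) stopf("k must be an integer >= 2")
  if (k > n) stopf("k = %d exceeds the %d instances", k, n)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1L)
      fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> k=%d, %d instances, seed=%d\n", x$k,
              length(x$fold), x$seed))
  print(table(fold = x$fold))
  invisible(x)
}

#' Cross-validated accuracy of a multiclass SVM
#'
#' For each fold of the plan, trains on the remaining folds and scores
#' plain (instance-weighted) accuracy on the held-out fold; returns the
#' arithmetic mean of the per-fold accuracies. A training split that
#' lost a class entirely is an error naming the fold — reduce `k` in
#' that case.
#'
#' @param x training matrix or [feature_table].
#' @param labels [label_vector] or integer codes.
#' @param config an [svm_config].
#' @param strategy `"OAO"`, `"OAA"` or `"DAG"`.
#' @param plan a `cv_plan` from [stratified_kfold()].
#' @param per_fold if `TRUE`, return the vector of per-fold accuracies
#'   instead of their mean.
#' @return Mean accuracy fraction in `[0, 1]` (or the per-fold vector).
#' @export
cross_validate <- function(x, labels, config = svm_config(),
                           strategy = c("OAO", "OAA", "DAG"),
                           plan, per_fold = FALSE) {
  strategy <- match.arg(strategy)
  xm <- as_matrix_x(x)
  y <- as_labels_y(labels)
  if (length(y) != length(plan$fold)) {
    stopf("plan covers %d instances but data has %d", length(plan$fold),
          length(y))
  }
  classes <- sort(unique(y))
  folds <- sort(unique(plan$fold))
  acc <- vapply(folds, function(f) {
    tr <- plan$fold != f
    if (!all(classes %in% y[tr])) {
      miss <- setdiff(classes, y[tr])
      stopf("training split for fold %d lost class %s; reduce k", f,
            miss[1L])
    }
    model <- train_multiclass(xm[tr, , drop = FALSE], y[tr], config,
                              strategy)
    pred <- predict_multiclass(model, xm[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  if (per_fold) acc else mean(acc)
}

#' Repeated cross-validation
#'
#' Runs [cross_validate()] `n_repeats` times under re-randomised fold
#' splits with seeds `base_seed, base_seed + 1, ...`, yielding the
#' repeated accuracy observations consumed by the Taguchi SN analysis.
#'
#' @inheritParams cross_validate
#' @param k fold count.
#' @param n_repeats number of re-seeded repetitions.
#' @param base_seed seed of the first repetition.
#' @return Numeric vector of `n_repeats` accuracy fractions.
#' @export
repeated_cv <- function(x, labels, config = svm_config(),
                        strategy = c("OAO", "OAA", "DAG"),
                        k = 10L, n_repeats = 5L, base_seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is_count(n_repeats)) stopf("n_repeats must be a positive integer")
  y <- as_labels_y(labels)
  vapply(seq_len(n_repeats), function(r) {
    plan <- stratified_kfold(y, k = k, seed = base_seed + r - 1L)
    cross_validate(x, labels, config, strategy, plan)
  }, numeric(1))
}
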