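#' Deterministic synthetic multiclass dataset
#'
#' Generates an instances-by-features table with a controllable planted
#' structure, emulating the shape of small UCI classification
#' benchmarks. Informative features carry class-dependent means
#' separated (between-class sd) by `effect_size` noise-sd units; the
#' remaining features are pure class-independent noise (sd 1).
#' `value_mode` quantises the latent Gaussian values to match common
#' attribute codings:
#' \describe{
#'   \item{continuous}{raw Gaussian values.}
#'   \item{ordinal}{clinical-severity style 0-3 codes, fixed latent
#'     thresholds at -1, 0, 1.}
#'   \item{boolean}{0/1 by thresholding at 0.}
#' }
#' Class counts are realised exactly and outputs are bit-identical for a
#' fixed seed.
#'
#' @param class_counts integer vector of per-class instance counts
#'   (length K >= 2); class codes are `1..K` in this order.
#' @param n_features total number of features.
#' @param informative integer indices of the informative features.
#' @param effect_size class-mean separation in noise-sd units (>= 0).
#' @param value_mode `"continuous"` (default), `"ordinal"` or
#'   `"boolean"`.
#' @param seed integer RNG seed.
#' @return A list with `table` ([feature_table]), `labels`
#'   ([label_vector]), and `centers` (the K x n_features matrix of class
#'   means actually planted).
#' @examples
#' d <- synth_multiclass(c(20, 20, 20), n_features = 5,
#'                       informative = 1:2, effect_size = 2, seed = 1)
#' table(d$labels$labels)
#' @export
synth_multiclass <- function(class_counts, n_features,
                             informative = integer(0), effect_size = 2,
                             value_mode = c("continuous", "ordinal",
                                            "boolean"),
                             seed = 1L) {
  value_mode <- match.arg(value_mode)
  class_counts <- as.integer(class_counts)
  if (length(class_counts) < 2L || any(class_counts < 1L)) {
    stopf("need >= 2 classes with >= 1 instance each")
  }
  if (effect_size < 0) stopf("effect_size must be >= 0")
  informative <- as.integer(informative)
  if (length(informative) && (min(informative) < 1L ||
                              max(informative) > n_features)) {
    stopf("informative indices must lie in 1..%d", n_features)
  }
  K <- length(class_counts)
  n <- sum(class_counts)
  y <- rep(seq_len(K), class_counts)
  with_seed(seed, {
    centers <- matrix(0, K, n_features)
    for (j in informative) {
      raw <- rnorm(K)
      # centre and scale so the between-class sd is exactly effect_size
      s <- stats::sd(raw)
      centers[, j] <- if (s > 0) effect_size * (raw - mean(raw)) / s
                      else rep(0, K)
    }
    vals <- matrix(rnorm(n * n_features), n, n_features) + centers[y, ]
  })
  vals <- switch(value_mode,
    continuous = vals,
    ordinal = matrix(findInterval(vals, c(-1, 0, 1)), n, n_features),
    boolean = (vals > 0) + 0)
  list(table = feature_table(vals),
       labels = label_vector(y),
       centers = centers)
}

#' Dermatology-shaped synthetic dataset
#'
#' A convenience wrapper for a 358-instance, 6-class, 33-feature ordinal
#' (0-3 coded) table with the exact class counts of the preprocessed UCI
#' Dermatology dataset (111, 71, 60, 48, 48, 20).
#'
#' @param seed integer RNG seed.
#' @param informative indices of class-informative features.
#' @param effect_size class-mean separation in noise-sd units.
#' @return As [synth_multiclass()].
#' @export
synth_dermatology_like <- function(seed = 1L, informative = 1:12,
                                   effect_size = 2) {
  synth_multiclass(c(111L, 71L, 60L, 48L, 48L, 20L), n_features = 33L,
                   informative = informative, effect_size = effect_size,
                   value_mode = "ordinal", seed = seed)
}

#' Zoo-shaped synthetic dataset
#'
#' A 101-instance, 7-class, 16-feature boolean table with the exact
#' class counts of the UCI Zoo dataset (41, 20, 5, 13, 4, 8, 10) — note
#' class 5 has only 4 instances, which deliberately stresses stratified
#' cross-validation.
#'
#' @inheritParams synth_dermatology_like
#' @return As [synth_multiclass()].
#' @export
synth_zoo_like <- function(seed = 1L, informative = 1:8, effect_size = 3) {
  synth_multiclass(c(41L, 20L, 5L, 13L, 4L, 8L, 10L), n_features = 16L,
                   informative = informative, effect_size = effect_size,
                   value_mode = "boolean", seed = seed)
}

#' Planted-informative RFE recovery fixture
#'
#' Continuous dataset with a small set of informative features among
#' pure-noise features, the standard testbed for checking that SVM-RFE
#' ranks the planted features on top.
#'
#' @param n total instances, split evenly over `n_classes`.
#' @param n_features total features.
#' @param informative indices of the planted informative features.
#' @param n_classes number of classes, default 3.
#' @param effect_size class-mean separation, default 2.
#' @param seed integer RNG seed.
#' @return As [synth_multiclass()].
#' @export
synth_planted <- function(n = 200L, n_features = 10L, informative = c(1L, 2L),
                          n_classes = 3L, effect_size = 2, seed = 1L) {
  base <- n %/% n_classes
  counts <- rep(base, n_classes)
  counts[seq_len(n - base * n_classes)] <-
    counts[seq_len(n - base * n_classes)] + 1L
  synth_multiclass(counts, n_features = n_features,
                   informative = informative, effect_size = effect_size,
                   value_mode = "continuous", seed = seed)
}

#' Certified-separable Gaussian blobs
#'
#' Draws one spherical Gaussian blob per class at well-spread centers
#' and certifies pairwise linear separability by fitting an effectively
#' hard-margin linear SVM (C = 1e6) to every class pair and requiring
#' zero training errors. On failure the blobs are regenerated with 1.5x
#' the separation, up to 5 attempts, then an error is raised.
#'
#' @param n_classes number of blobs (>= 2).
#' @param n_per_class instances per blob.
#' @param dim feature dimension, default 2.
#' @param separation distance scale of the blob centers, default 4.
#' @param sd within-blob standard deviation, default 0.3.
#' @param seed integer RNG seed.
#' @return A list with `table`, `labels`, `centers`, and `separation`
#'   (the value that certified).
#' @export
synth_blobs <- function(n_classes = 3L, n_per_class = 20L, dim = 2L,
                        separation = 4, sd = 0.3, seed = 1L) {
  if (!is_count(n_classes) || n_classes < 2L) stopf("need >= 2 classes")
  sep <- separation
  for (attempt in seq_len(5L)) {
    out <- with_seed(seed + 1000L * (attempt - 1L), {
      theta <- 2 * pi * (seq_len(n_classes) - 1L) / n_classes
      centers <- matrix(0, n_classes, dim)
      centers[, 1L] <- sep * cos(theta)
      centers[, min(2L, dim)] <- centers[, min(2L, dim)] +
        if (dim >= 2L) sep * sin(theta) else 0
      y <- rep(seq_len(n_classes), each = n_per_class)
      vals <- centers[y, , drop = FALSE] +
        matrix(rnorm(length(y) * dim, sd = sd), ncol = dim)
      list(vals = vals, y = y, centers = centers)
    })
    if (blobs_separable(out$vals, out$y)) {
      return(list(table = feature_table(out$vals),
                  labels = label_vector(out$y),
                  centers = out$centers, separation = sep))
    }
    sep <- sep * 1.5
  }
  stopf("could not generate separable blobs after 5 attempts")
}

# Certify pairwise linear separability via a near-hard-margin linear SVM:
# zero training errors on every pair is a sufficient certificate.
blobs_separable <- function(vals, y) {
  cfg <- svm_config(kernel_spec("linear"), C = 1e6)
  for (i in unique(y)) {
    for (j in unique(y)) {
      if (j <= i) next
      idx <- y %in% c(i, j)
      m <- train_binary_svm(vals[idx, , drop = FALSE],
                            ifelse(y[idx] == i, 1, -1), cfg)
      f <- decision_value(m, vals[idx, , drop = FALSE])
      if (any(sign(f) != ifelse(y[idx] == i, 1, -1))) return(FALSE)
    }
  }
  TRUE
}
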