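cfg_rbf <- svm_config(kernel_spec("rbf", gamma = 1), C = 10)

test_that("model counts follow the decomposition formulas", {
  d <- blob3()
  oao <- train_multiclass(d$table, d$labels, cfg_rbf, "OAO")
  oaa <- train_multiclass(d$table, d$labels, cfg_rbf, "OAA")
  expect_length(oao$binary_models, 3L)          # 3*2/2
  expect_length(oaa$binary_models, 3L)          # K
  # K = 6 pairwise decomposition has 15 machines
  d6 <- synth_multiclass(rep(8, 6), n_features = 3, informative = 1:3,
                         effect_size = 4, seed = 4)
  m6 <- train_multiclass(d6$table, d6$labels, cfg_rbf, "OAO")
  expect_length(m6$binary_models, 15L)
  pairs <- t(vapply(m6$binary_models, `[[`, numeric(2), "pair"))
  expect_equal(nrow(unique(pairs)), 15L) # every pair exactly once
})

test_that("with K = 2 every strategy reduces to the single binary machine", {
  d <- synth_blobs(n_classes = 2, n_per_class = 10, seed = 1)
  preds <- lapply(c("OAO", "OAA", "DAG"), function(s) {
    m <- train_multiclass(d$table, d$labels, cfg_rbf, s)
    expect_length(m$binary_models, if (s == "OAA") 2L else 1L)
    predict_multiclass(m, d$table)
  })
  expect_equal(preds[[1]], preds[[2]])
  expect_equal(preds[[1]], preds[[3]])
})

test_that("all three strategies reach 100% on the separable blob fixture", {
  d <- blob3()
  for (s in c("OAO", "OAA", "DAG")) {
    m <- train_multiclass(d$table, d$labels, cfg_rbf, s)
    expect_equal(mean(predict_multiclass(m, d$table) == d$labels$labels), 1,
                 info = s)
  }
})

test_that("OAA argmax and tie-break follow the documented rule", {
  # stub OAA model whose machines return fixed decision values
  stub <- function(vals, targets) {
    models <- Map(function(v, k) {
      structure(list(alpha = v, sv = matrix(1), sv_labels = 1, bias = 0,
                     kernel = kernel_spec("linear"), C = 1, n_features = 1L,
                     target = k),
                class = "binary_svm")
    }, vals, targets)
    structure(list(strategy = "OAA", class_codes = sort(targets),
                   binary_models = models), class = "multiclass_svm")
  }
  # decision value at x = 1 equals alpha (single sv (1), y=+1, b=0)
  m <- stub(c(0.2, 1.5, -0.3), c(1, 2, 3))
  expect_equal(predict_oaa(m, matrix(1)), 2L)
  ties <- stub(c(0.7, 0.7, 0.7), c(1, 2, 3))
  expect_equal(predict_oaa(ties, matrix(1)), 1L)
  expect_error(predict_oao(m, matrix(1)), "OAO")
})

test_that("OAO votes are conserved and cyclic ties resolve deterministically", {
  d <- blob3()
  m <- train_multiclass(d$table, d$labels, cfg_rbf, "OAO")
  out <- predict_oao(m, d$table, votes = TRUE)
  expect_true(all(rowSums(out$votes) == 3L)) # K(K-1)/2 with K=3
  # constructed cyclic vote: 1 beats 2, 2 beats 3, 3 beats 1
  mk <- function(val, pair) {
    structure(list(alpha = abs(val), sv = matrix(1),
                   sv_labels = sign(val), bias = 0,
                   kernel = kernel_spec("linear"), C = 1, n_features = 1L,
                   pair = pair),
              class = "binary_svm")
  }
  cyc <- structure(list(strategy = "OAO", class_codes = 1:3,
                        binary_models = list(mk(0.5, c(1, 2)),
                                             mk(0.9, c(2, 3)),
                                             mk(-0.2, c(1, 3)))),
                   class = "multiclass_svm")
  out <- predict_oao(cyc, matrix(1), votes = TRUE)
  expect_equal(unname(out$votes[1, ]), c(1L, 1L, 1L))
  # tie-break: summed |f| is 0.7 (class 1), 1.4 (class 2), 1.1 (class 3)
  expect_equal(out$class, 2L)
})

test_that("DAG eliminates losers in K-1 evaluations", {
  d <- blob3()
  m <- train_multiclass(d$table, d$labels, cfg_rbf, "DAG")
  out <- predict_dag(m, d$table, count_evals = TRUE)
  expect_true(all(out$n_evals == 2L))
  expect_equal(mean(out$class == d$labels$labels), 1)
  # trace: all pairwise decisions favour class 3 => class 3 in 2 contests
  mk <- function(val, pair) {
    structure(list(alpha = abs(val), sv = matrix(1),
                   sv_labels = sign(val), bias = 0,
                   kernel = kernel_spec("linear"), C = 1, n_features = 1L,
                   pair = pair),
              class = "binary_svm")
  }
  fav3 <- structure(list(strategy = "DAG", class_codes = 1:3,
                         binary_models = list(mk(0.4, c(1, 2)),
                                              mk(-0.6, c(2, 3)),
                                              mk(-0.8, c(1, 3)))),
                    class = "multiclass_svm")
  out3 <- predict_dag(fav3, matrix(1), count_evals = TRUE)
  expect_equal(out3$class, 3L)
  expect_equal(out3$n_evals, 2L)
})

test_that("OAO and DAG agree when one class wins all its contests", {
  d <- blob3(seed = 11)
  oao <- train_multiclass(d$table, d$labels, cfg_rbf, "OAO")
  dag <- oao; dag$strategy <- "DAG"
  p_oao <- predict_oao(oao, d$table, votes = TRUE)
  p_dag <- predict_dag(dag, d$table)
  clean_sweep <- p_oao$votes[cbind(seq_len(nrow(d$table$values)),
                                   match(p_oao$class,
                                         oao$class_codes))] == 2L
  expect_true(any(clean_sweep))
  expect_equal(p_dag[clean_sweep], p_oao$class[clean_sweep])
})

test_that("strategies are equivariant under class relabeling", {
  d <- blob3(seed = 5)
  y <- d$labels$labels
  perm <- c(3L, 1L, 2L) # relabel: 1->3, 2->1, 3->2
  y2 <- perm[y]
  for (s in c("OAO", "OAA", "DAG")) {
    m1 <- train_multiclass(d$table$values, y, cfg_rbf, s)
    m2 <- train_multiclass(d$table$values, y2, cfg_rbf, s)
    p1 <- predict_multiclass(m1, d$table$values)
    p2 <- predict_multiclass(m2, d$table$values)
    expect_equal(perm[p1], p2, info = s)
  }
})

test_that("multiclass bundles serialise to JSON and back", {
  d <- blob3()
  m <- train_multiclass(d$table, d$labels, cfg_rbf, "OAO")
  tf <- tempfile(fileext = ".json")
  write_multiclass(m, tf)
  m2 <- read_multiclass(tf)
  expect_equal(predict_oao(m2, d$table), predict_oao(m, d$table))
})

test_that("zero-instance classes and bad strategies are rejected", {
  d <- blob3()
  expect_error(train_multiclass(d$table$values, rep(1L, 45), cfg_rbf),
               "2 classes")
  m <- train_multiclass(d$table, d$labels, cfg_rbf, "OAO")
  expect_error(predict_dag(m, d$table), "DAG")
})
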