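test_that("feature weights equal the support expansion of the linear machine", {
  # single support vector x=(2,0), y=+1, alpha=0.5 => w=(1,0)
  m <- structure(list(alpha = 0.5, sv = matrix(c(2, 0), 1), sv_labels = 1,
                      bias = 0, kernel = kernel_spec("linear"), C = 1,
                      n_features = 2L),
                 class = "binary_svm")
  expect_equal(compute_feature_weights(m), c(1, 0))
  # mirrored support vectors: w aligned with the class axis
  m2 <- structure(list(alpha = c(0.5, 0.5),
                       sv = rbind(c(1, 0), c(-1, 0)), sv_labels = c(1, -1),
                       bias = 0, kernel = kernel_spec("linear"), C = 1,
                       n_features = 2L),
                  class = "binary_svm")
  expect_equal(compute_feature_weights(m2), c(1, 0))
  m2$kernel <- kernel_spec("rbf")
  expect_error(compute_feature_weights(m2), "linear")
})

test_that("weights match the gradient of the linear decision function", {
  d <- gauss_pair(seed = 4)
  m <- train_binary_svm(d$x, d$y, linear_cfg(C = 10))
  w <- compute_feature_weights(m)
  x0 <- c(0.3, -0.2)
  h <- 1e-5
  num <- vapply(1:2, function(j) {
    e <- rep(0, 2); e[j] <- h
    (decision_value(m, x0 + e) - decision_value(m, x0 - e)) / (2 * h)
  }, numeric(1))
  expect_equal(num, w, tolerance = 1e-6)
})

test_that("ranking criterion is the elementwise square", {
  expect_equal(ranking_criterion(c(-2, 1)), c(4, 1))
  expect_equal(ranking_criterion(c(0, 0)), c(0, 0))
  w <- rnorm(5)
  expect_equal(order(ranking_criterion(w)), order(ranking_criterion(-w)))
})

test_that("multiclass criteria aggregate by elementwise sum", {
  expect_equal(aggregate_multiclass_criteria(list(c(1, 0), c(0, 1))), c(1, 1))
  expect_equal(aggregate_multiclass_criteria(list(c(2, 3))), c(2, 3))
  expect_error(aggregate_multiclass_criteria(list(1:2, 1:3)), "mismatch")
  # oracle: independent recomputation of sum over classifiers of w_i^2
  d <- blob3()
  m <- train_multiclass(d$table, d$labels, linear_cfg(), "OAO")
  ws <- lapply(m$binary_models, compute_feature_weights)
  agg <- aggregate_multiclass_criteria(lapply(ws, ranking_criterion))
  brute <- rowSums(vapply(ws, function(w) w^2, numeric(2)))
  expect_equal(agg, unname(brute))
})

test_that("svm_rfe returns a complete audited ranking", {
  d <- synth_planted(n = 90, n_features = 6, informative = c(2, 5),
                     seed = 1)
  r <- svm_rfe(d$table, d$labels)
  expect_setequal(r$ranked_ids, d$table$feature_ids) # permutation
  expect_equal(rev(r$elimination_order), r$ranked_ids)
  expect_length(r$per_iteration, 6L) # one removal per iteration
  sizes <- lengths(lapply(r$per_iteration, `[[`, "remaining"))
  expect_equal(sizes, 6:1)
})

test_that("a constant-zero feature is eliminated first and is inert", {
  d <- synth_planted(n = 60, n_features = 3, informative = c(1, 2),
                     seed = 2)
  vals <- d$table$values
  vals[, 3] <- 0
  tab <- feature_table(vals)
  r <- svm_rfe(tab, d$labels)
  expect_equal(r$elimination_order[1], "V3")
  # removing the zero column leaves decision values untouched
  cfg <- linear_cfg()
  y12 <- ifelse(d$labels$labels[d$labels$labels != 3] == 1, 1, -1)
  sub <- vals[d$labels$labels != 3, ]
  m_with <- train_binary_svm(sub, y12, cfg)
  m_without <- train_binary_svm(sub[, 1:2], y12, cfg)
  expect_equal(decision_value(m_with, sub),
               decision_value(m_without, sub[, 1:2]), tolerance = 1e-8)
})

test_that("single feature ranks trivially and top-k slices the ranking", {
  d <- synth_planted(n = 40, n_features = 1, informative = 1, seed = 3)
  r1 <- svm_rfe(d$table, d$labels)
  expect_equal(r1$ranked_ids, "V1")
  d2 <- synth_planted(n = 60, n_features = 5, informative = c(1, 2),
                      seed = 4)
  r <- svm_rfe(d2$table, d2$labels)
  expect_equal(select_top_k(r, 2), r$ranked_ids[1:2])
  expect_equal(select_top_k(r, 5), r$ranked_ids)
  expect_length(select_top_k(r, 1), 1L)
  expect_error(select_top_k(r, 6), "1..5")
  expect_error(select_top_k(r, 0), "1..5")
})

test_that("planted informative features are recovered on top", {
  d <- synth_planted(n = 200, n_features = 10, informative = c(1, 2),
                     effect_size = 2, seed = 5)
  r <- svm_rfe(d$table, d$labels)
  expect_setequal(select_top_k(r, 2), c("V1", "V2"))
})

test_that("ranking artifacts are written as TSV plus JSON audit", {
  d <- synth_planted(n = 60, n_features = 4, informative = 1, seed = 6)
  r <- svm_rfe(d$table, d$labels)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_ranking(r, tsv, js)
  back <- read.delim(tsv)
  expect_equal(back$feature_id, r$ranked_ids)
  expect_equal(back$rank, 1:4)
  audit <- jsonlite::read_json(js)
  expect_length(audit, 4L)
  expect_named(audit[[1]], c("remaining", "criterion"))
})
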