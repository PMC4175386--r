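test_that("the L9(3^2) design is the balanced full factorial in A-major order", {
  d <- build_design()
  expect_equal(dim(d), c(9L, 2L))
  expect_equal(d[1, ], c(A = 1L, B = 1L))
  expect_equal(d[6, ], c(A = 2L, B = 3L))
  expect_equal(as.integer(table(d[, "A"])), rep(3L, 3))
  expect_equal(as.integer(table(d[, "B"])), rep(3L, 3))
  expect_equal(nrow(unique(d)), 9L) # every pair once
})

test_that("sn_ltb matches the closed form and rejects invalid observations", {
  expect_equal(sn_ltb(rep(1, 5)), 0)
  y <- rep(0.8, 4)
  expect_equal(sn_ltb(y), 20 * log10(0.8))
  expect_equal(sn_ltb(c(0.5, 0.25)),
               -10 * log10(mean(c(1 / 0.25, 1 / 0.0625))))
  expect_error(sn_ltb(c(0.9, 0)), "positive")
  expect_error(sn_ltb(c(0.9, -0.1)), "positive")
  expect_error(sn_ltb(c(0.9, 1.2)), "\\(0, 1\\]")
  expect_error(sn_ltb(numeric(0)), "at least one")
})

test_that("sn_ltb is strictly increasing in every observation", {
  set.seed(1)
  for (rep in 1:25) {
    y <- runif(5, 0.3, 0.99)
    base <- sn_ltb(y)
    i <- sample.int(5, 1)
    y2 <- y
    y2[i] <- min(1, y[i] + runif(1, 0.001, 0.01))
    expect_gt(sn_ltb(y2), base)
  }
})

test_that("main_effects averages SN by level and flags the best level", {
  design <- build_design()
  # constant SN: all level means equal, zero differences, tie to level 1
  eff0 <- main_effects(design, rep(-1.5, 9))
  expect_equal(eff0$A$level_means, rep(-1.5, 3))
  expect_equal(eff0$A$difference, 0)
  expect_equal(eff0$B$best_level, 1L)
  expect_error(main_effects(design, 1:8), "9 design rows")
  # hand-computable SN column
  sn <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  eff <- main_effects(design, sn)
  expect_equal(eff$A$level_means, c(2, 5, 8))
  expect_equal(eff$B$level_means, c(4, 5, 6))
  expect_equal(eff$A$best_level, 3L)
})

test_that("balanced-design identity: level means average to the grand mean", {
  design <- build_design()
  set.seed(2)
  for (rep in 1:10) {
    sn <- rnorm(9)
    eff <- main_effects(design, sn)
    expect_equal(mean(eff$A$level_means), mean(sn))
    expect_equal(mean(eff$B$level_means), mean(sn))
  }
})

test_that("select_optimal decodes the argmax levels with tie to level 1", {
  la <- factor_levels("A(C)", c(10, 50, 100))
  lb <- factor_levels("B(gamma)", c(2.4, 5, 10))
  eff <- main_effects(build_design(), c(9, 1, 5, 1, 1, 1, 1, 1, 1))
  opt <- select_optimal(eff, la, lb)
  expect_equal(opt$C, 10)
  eff0 <- main_effects(build_design(), rep(0, 9))
  opt0 <- select_optimal(eff0, la, lb)
  expect_equal(unname(opt0$levels), c(1L, 1L))
  expect_equal(opt0$C, 10)
  expect_equal(opt0$gamma, 2.4)
  expect_error(factor_levels("A", c(1, 1, 2)), "3 distinct")
})

test_that("taguchi_tune over a monotone mock surface picks the top levels", {
  la <- factor_levels("A(C)", c(1, 2, 3))
  lb <- factor_levels("B(gamma)", c(1, 2, 3))
  surf <- function(C, gamma, seed) 0.5 + 0.04 * C + 0.01 * gamma
  ex <- taguchi_tune(levels_A = la, levels_B = lb, n_repeats = 2,
                     evaluator = surf)
  expect_equal(unname(ex$optimum$levels), c(3L, 3L))
  expect_equal(dim(ex$observations), c(9L, 2L))
  # constant evaluator: all SN equal, tie-break to (1, 1)
  ex0 <- taguchi_tune(levels_A = la, levels_B = lb, n_repeats = 3,
                      evaluator = function(C, gamma, seed) 0.9)
  expect_equal(unname(ex0$optimum$levels), c(1L, 1L))
  expect_true(all(abs(ex0$sn - ex0$sn[1]) < 1e-12))
})

test_that("additive mock surface: Taguchi optimum equals brute-force argmax", {
  la <- factor_levels("A(C)", c(2, 4, 8))
  lb <- factor_levels("B(gamma)", c(0.1, 1, 10))
  effA <- c(0.05, 0.12, 0.02)
  effB <- c(0.01, 0.09, 0.03)
  surf <- function(C, gamma, seed) {
    0.6 + effA[match(C, la$values)] + effB[match(gamma, lb$values)]
  }
  ex <- taguchi_tune(levels_A = la, levels_B = lb, n_repeats = 1,
                     evaluator = surf)
  cells <- expand.grid(a = 1:3, b = 1:3)
  brute <- cells[which.max(0.6 + effA[cells$a] + effB[cells$b]), ]
  expect_equal(unname(ex$optimum$levels), c(brute$a, brute$b))
  expect_equal(ex$optimum$C, la$values[brute$a])
  expect_equal(ex$optimum$gamma, lb$values[brute$b])
})

test_that("evaluator failures are reported with run and repeat indices", {
  la <- factor_levels("A(C)", c(1, 2, 3))
  lb <- factor_levels("B(gamma)", c(1, 2, 3))
  boom <- function(C, gamma, seed) if (C == 2) stop("nope") else 0.9
  expect_error(
    taguchi_tune(levels_A = la, levels_B = lb, n_repeats = 1,
                 evaluator = boom),
    "run 4, repeat 1")
})

test_that("taguchi artifacts mirror the orthogonal-array report layout", {
  la <- factor_levels("A(C)", c(1, 2, 3))
  lb <- factor_levels("B(gamma)", c(1, 2, 3))
  ex <- taguchi_tune(levels_A = la, levels_B = lb, n_repeats = 4,
                     evaluator = function(C, gamma, seed) 0.8 + 0.01 * C)
  df <- as.data.frame(ex)
  expect_equal(dim(df), c(9L, 3L + 4L + 2L)) # run, A, B, y1..y4, mean, sn
  runs <- tempfile(fileext = ".csv"); eff <- tempfile(fileext = ".csv")
  opt <- tempfile(fileext = ".json")
  write_taguchi(ex, runs, eff, opt)
  expect_equal(nrow(read.csv(runs)), 9L)
  expect_equal(read.csv(eff)$factor, c("A", "B"))
  back <- jsonlite::read_json(opt, simplifyVector = TRUE)
  expect_equal(back$C, ex$optimum$C)
})

test_that("bundled reference tuning tables load with their factor levels", {
  for (ds in c("dermatology", "zoo")) {
    t <- reference_tuning_table(ds)
    expect_equal(dim(t$observations), c(9L, 5L))
    expect_length(t$sn_printed, 9L)
    expect_s3_class(t$levels_A, "factor_levels")
  }
  expect_equal(reference_tuning_table("dermatology")$levels_B$values,
               c(2.4, 5, 10))
  expect_equal(reference_tuning_table("zoo")$levels_A$values, c(5, 10, 50))
})
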