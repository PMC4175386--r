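#' Factor level configuration
#'
#' One control factor of the parameter-design experiment: a name and
#' exactly three candidate numeric values (levels 1..3).
#'
#' @param name factor label, e.g. `"A(C)"` or `"B(gamma)"`.
#' @param values numeric vector of 3 distinct level values.
#' @return An object of class `factor_levels`.
#' @export
factor_levels <- function(name, values) {
  values <- as.numeric(values)
  if (length(values) != 3L || anyDuplicated(values)) {
    stopf("factor %s needs exactly 3 distinct level values", name)
  }
  structure(list(name = as.character(name), values = values),
            class = "factor_levels")
}

#' The L9(3^2) orthogonal design for two 3-level factors
#'
#' With two 3-level factors the nine-run orthogonal array coincides with
#' the full 3 x 3 factorial; it is generated directly in A-major run
#' order: (1,1), (1,2), (1,3), (2,1), ..., (3,3). Every level appears
#' exactly three times per column and every (A, B) pair exactly once.
#'
#' @return A 9 x 2 integer matrix of level indices with columns `A`, `B`.
#' @export
build_design <- function() {
  d <- cbind(A = rep(1:3, each = 3L), B = rep(1:3, times = 3L))
  storage.mode(d) <- "integer"
  d
}

#' Larger-the-better signal-to-noise ratio
#'
#' For repeated quality observations \eqn{y_1..y_n} (accuracy fractions
#' in (0, 1]), the larger-the-better SN ratio is
#' \deqn{SN = -10 \log_{10}\left(\frac{1}{n}\sum_i \frac{1}{y_i^2}\right)}
#' in decibels. It increases when any observation increases, and equals
#' \eqn{20\log_{10} y} for constant observations (0 at y = 1).
#'
#' @param observations numeric vector of accuracies in (0, 1].
#' @return The SN ratio in dB.
#' @examples
#' sn_ltb(c(0.9631, 0.9701, 0.9697, 0.9627, 0.9614)) # about -0.306
#' sn_ltb(rep(1, 5)) # 0
#' @export
sn_ltb <- function(observations) {
  y <- as.numeric(observations)
  if (!length(y)) stopf("need at least one observation")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stopf("observations must be positive (got %s)",
          paste(utils::head(y[!is.finite(y) | y <= 0], 3), collapse = ", "))
  }
  if (any(y > 1)) stopf("accuracy observations must lie in (0, 1]")
  -10 * log10(mean(1 / y^2))
}

#' Main-effects analysis of a 9-run experiment
#'
#' For each factor, the level mean is the arithmetic mean of the three
#' SN ratios observed at that level; the factor's range (`difference`)
#' is max level mean minus min level mean, and `best_level` is the level
#' with the maximal mean (ties to the lowest level index).
#'
#' @param design the 9 x 2 level matrix from [build_design()].
#' @param sn numeric vector of 9 SN ratios aligned with the design rows.
#' @return An object of class `taguchi_effects`: a list with one entry
#'   per factor (`A`, `B`), each holding `level_means` (length 3),
#'   `difference` and `best_level`.
#' @export
main_effects <- function(design, sn) {
  if (length(sn) != nrow(design)) {
    stopf("%d SN values for %d design rows", length(sn), nrow(design))
  }
  sn <- as.numeric(sn)
  out <- lapply(colnames(design), function(f) {
    lm <- vapply(1:3, function(l) mean(sn[design[, f] == l]), numeric(1))
    list(level_means = lm,
         difference = max(lm) - min(lm),
         best_level = which.max(lm))
  })
  names(out) <- colnames(design)
  structure(out, class = "taguchi_effects")
}

#' @export
print.taguchi_effects <- function(x, ...) {
  cat("Main effects (mean SN per level):\n")
  for (f in names(x)) {
    cat(sprintf("  %s: %s  diff=%.4f  best level=%d\n", f,
                paste(sprintf("%.4f", x[[f]]$level_means), collapse = "  "),
                x[[f]]$difference, x[[f]]$best_level))
  }
  invisible(x)
}

#' Decode the optimal parameter combination
#'
#' Picks, per factor, the level with the maximal mean SN ratio (higher
#' SN means better and more consistent accuracy) and decodes it to its
#' numeric parameter value.
#'
#' @param effects a `taguchi_effects` object from [main_effects()].
#' @param levels_A,levels_B [factor_levels] for factors A (the penalty
#'   C) and B (the kernel gamma).
#' @return Named list `list(C = , gamma = , levels = c(A, B))`.
#' @export
select_optimal <- function(effects, levels_A, levels_B) {
  la <- effects$A$best_level
  lb <- effects$B$best_level
  list(C = levels_A$values[la], gamma = levels_B$values[lb],
       levels = c(A = la, B = lb))
}

#' Run a Taguchi parameter-design experiment for (C, gamma)
#'
#' Executes the nine runs of the L9(3^2) design: each run decodes its
#' (C, gamma) levels, collects `n_repeats` accuracy observations from
#' the evaluator, and is summarised by its mean and larger-the-better SN
#' ratio. Main-effects analysis over the nine SN ratios then selects the
#' winning level of each factor.
#'
#' By default the evaluator is repeated stratified k-fold
#' cross-validation of an RBF-kernel multiclass SVM on `(x, y)`; the
#' r-th repeat of every run uses fold seed `base_seed + r - 1`, so runs
#' differ only in (C, gamma), not in fold randomness. A custom
#' `evaluator(C, gamma, seed)` returning an accuracy fraction may be
#' supplied instead (then `x` and `y` may be `NULL`).
#'
#' @param x,y training data (matrix/[feature_table] and labels), or
#'   `NULL` when `evaluator` is supplied.
#' @param levels_A [factor_levels] for the penalty C.
#' @param levels_B [factor_levels] for the kernel gamma.
#' @param k cross-validation fold count, default 10.
#' @param n_repeats repeated observations per run, default 5.
#' @param base_seed fold-split seed of the first repeat.
#' @param strategy multiclass decomposition for the default evaluator.
#' @param evaluator optional `function(C, gamma, seed)` -> accuracy.
#' @return An object of class `taguchi_experiment`: `design`,
#'   `levels_A`, `levels_B`, `observations` (9 x n_repeats), `means`,
#'   `sn`, `effects`, `optimum`, `seeds`.
#' @examples
#' surf <- function(C, gamma, seed) 0.5 + 0.04 * C + 0.01 * gamma
#' ex <- taguchi_tune(levels_A = factor_levels("A(C)", c(1, 2, 3)),
#'                    levels_B = factor_levels("B(gamma)", c(1, 2, 3)),
#'                    n_repeats = 2, evaluator = surf)
#' ex$optimum$levels
#' @export
taguchi_tune <- function(x = NULL, y = NULL, levels_A, levels_B,
                         k = 10L, n_repeats = 5L, base_seed = 1L,
                         strategy = c("OAO", "OAA", "DAG"),
                         evaluator = NULL) {
  strategy <- match.arg(strategy)
  if (!inherits(levels_A, "factor_levels") ||
      !inherits(levels_B, "factor_levels")) {
    stopf("levels_A and levels_B must be factor_levels objects")
  }
  if (!is_count(n_repeats)) stopf("n_repeats must be a positive integer")
  if (is.null(evaluator)) {
    if (is.null(x) || is.null(y)) stopf("need (x, y) or an evaluator")
    xm <- as_matrix_x(x)
    yv <- as_labels_y(y)
    evaluator <- function(C, gamma, seed) {
      cfg <- svm_config(kernel_spec("rbf", gamma = gamma), C = C)
      plan <- stratified_kfold(yv, k = k, seed = seed)
      cross_validate(xm, yv, cfg, strategy, plan)
    }
  }
  design <- build_design()
  seeds <- base_seed + seq_len(n_repeats) - 1L
  obs <- matrix(NA_real_, 9L, n_repeats)
  for (r in seq_len(9L)) {
    Cv <- levels_A$values[design[r, "A"]]
    gv <- levels_B$values[design[r, "B"]]
    for (j in seq_len(n_repeats)) {
      acc <- tryCatch(evaluator(Cv, gv, seeds[j]), error = function(e) {
        stopf("evaluator failed at run %d, repeat %d (C=%g, gamma=%g): %s",
              r, j, Cv, gv, conditionMessage(e))
      })
      obs[r, j] <- acc
    }
  }
  sn <- apply(obs, 1L, sn_ltb)
  effects <- main_effects(design, sn)
  structure(
    list(design = design, levels_A = levels_A, levels_B = levels_B,
         observations = obs, means = rowMeans(obs), sn = sn,
         effects = effects,
         optimum = select_optimal(effects, levels_A, levels_B),
         seeds = seeds, n_repeats = n_repeats),
    class = "taguchi_experiment"
  )
}

#' @export
print.taguchi_experiment <- function(x, ...) {
  cat("Taguchi L9(3^2) parameter-design experiment\n")
  cat(sprintf("  %s levels: %s\n", x$levels_A$name,
              paste(x$levels_A$values, collapse = ", ")))
  cat(sprintf("  %s levels: %s\n", x$levels_B$name,
              paste(x$levels_B$values, collapse = ", ")))
  print(as.data.frame(x))
  print(x$effects)
  cat(sprintf("  optimum: C=%g, gamma=%g (A%dB%d)\n", x$optimum$C,
              x$optimum$gamma, x$optimum$levels["A"], x$optimum$levels["B"]))
  invisible(x)
}

#' @export
summary.taguchi_experiment <- function(object, ...) print(object)

#' Tabulate a Taguchi experiment
#'
#' Returns the experiment as a data frame mirroring the conventional
#' orthogonal-array report: run number, the two level columns, the
#' repeated observations, their mean, and the SN ratio.
#'
#' @param x a `taguchi_experiment`.
#' @param ... unused.
#' @return A data frame with one row per run.
#' @export
as.data.frame.taguchi_experiment <- function(x, ...) {
  obs <- as.data.frame(x$observations)
  names(obs) <- paste0("y", seq_len(ncol(obs)))
  data.frame(run = 1:9, A = x$design[, "A"], B = x$design[, "B"],
             obs, mean = x$means, sn = x$sn)
}

#' Write Taguchi experiment artifacts
#'
#' Emits the runs table as CSV, the main-effects table as CSV, and the
#' decoded optimum as JSON.
#'
#' @param experiment a `taguchi_experiment`.
#' @param runs_csv,effects_csv,optimum_json output paths (any may be
#'   `NULL` to skip).
#' @return `experiment`, invisibly.
#' @export
write_taguchi <- function(experiment, runs_csv = NULL, effects_csv = NULL,
                          optimum_json = NULL) {
  if (!is.null(runs_csv)) {
    utils::write.csv(as.data.frame(experiment), runs_csv, row.names = FALSE)
  }
  if (!is.null(effects_csv)) {
    eff <- experiment$effects
    df <- do.call(rbind, lapply(names(eff), function(f) {
      data.frame(factor = f, level1 = eff[[f]]$level_means[1],
                 level2 = eff[[f]]$level_means[2],
                 level3 = eff[[f]]$level_means[3],
                 difference = eff[[f]]$difference,
                 best_level = eff[[f]]$best_level)
    }))
    utils::write.csv(df, effects_csv, row.names = FALSE)
  }
  if (!is.null(optimum_json)) {
    jsonlite::write_json(experiment$optimum, optimum_json,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(experiment)
}

#' Bundled reference tuning-experiment tables
#'
#' Loads the observation tables of two reference Taguchi tuning
#' experiments shipped with the package (repeated cross-validation
#' accuracies of an RBF multiclass SVM on the UCI Dermatology and Zoo
#' datasets, nine runs of five observations each), together with their
#' factor level configurations. These are the worked-example inputs for
#' [sn_ltb()], [main_effects()] and [select_optimal()].
#'
#' @param dataset `"dermatology"` or `"zoo"`.
#' @return A list with `observations` (9 x 5 matrix), `sn_printed`
#'   (the 9 SN ratios as reported, 4 d.p.), `levels_A`, `levels_B`.
#' @export
reference_tuning_table <- function(dataset = c("dermatology", "zoo")) {
  dataset <- match.arg(dataset)
  f <- system.file("extdata",
                   paste0(dataset, "_tuning_runs.csv"),
                   package = "svmtaguchi", mustWork = TRUE)
  runs <- utils::read.csv(f)
  lv <- utils::read.csv(system.file("extdata", "tuning_factor_levels.csv",
                                    package = "svmtaguchi", mustWork = TRUE))
  lv <- lv[lv$dataset == dataset, ]
  obs <- as.matrix(runs[, paste0("y", 1:5)])
  list(observations = unname(obs),
       sn_printed = runs$sn,
       levels_A = factor_levels("A(C)",
                                unlist(lv[lv$factor == "A", c("level1",
                                                              "level2",
                                                              "level3")])),
       levels_B = factor_levels("B(gamma)",
                                unlist(lv[lv$factor == "B", c("level1",
                                                              "level2",
                                                              "level3")])))
}
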