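#' Construct a feature table
#'
#' A `feature_table` is the package's tabular container: an
#' instances-by-features numeric matrix together with feature identifiers
#' and a logical mask marking cells that were missing in the source file.
#' Values under a `TRUE` mask cell are `NA`; everywhere else they must be
#' finite.
#'
#' @param values numeric matrix, instances in rows, features in columns.
#' @param feature_ids character vector of unique feature identifiers; by
#'   default `"V1"`, `"V2"`, ... following the UCI attribute convention.
#' @param missing_mask logical matrix of the same shape as `values`;
#'   defaults to `is.na(values)`.
#' @return An object of class `feature_table` with elements `values`,
#'   `feature_ids`, `missing_mask`.
#' @seealso [read_delimited()], [drop_missing()], [encode_features()]
#' @export
feature_table <- function(values,
                          feature_ids = paste0("V", seq_len(ncol(values))),
                          missing_mask = is.na(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing_mask <- as.matrix(missing_mask)
  if (!is.logical(missing_mask)) stopf("`missing_mask` must be logical")
  if (!identical(dim(values), dim(missing_mask))) {
    stopf("`missing_mask` shape (%d x %d) differs from `values` (%d x %d)",
          nrow(missing_mask), ncol(missing_mask), nrow(values), ncol(values))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values)) {
    stopf("%d feature_ids for %d columns", length(feature_ids), ncol(values))
  }
  if (anyDuplicated(feature_ids)) {
    stopf("duplicate feature_ids: %s",
          paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values[!missing_mask]))) {
    stopf("non-finite values present outside the missing mask")
  }
  colnames(values) <- feature_ids
  colnames(missing_mask) <- feature_ids
  structure(
    list(values = values, feature_ids = feature_ids,
         missing_mask = missing_mask),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d instances x %d features (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  cat("features:", paste(utils::head(x$feature_ids, 8), collapse = ", "),
      if (length(x$feature_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Construct a label vector
#'
#' Class labels are integer codes `1..K` (1-based, matching the usual
#' "Class 1..Class K" naming of the UCI benchmarks); an optional map from
#' code to a human-readable name may be attached.
#'
#' @param labels integer vector of class codes in `1..K`.
#' @param class_names optional named character vector mapping codes (as
#'   names) to class names.
#' @return An object of class `label_vector` with elements `labels`,
#'   `class_names`.
#' @export
label_vector <- function(labels, class_names = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stopf("labels contain NA")
  if (any(labels < 1L)) stopf("class codes must be >= 1")
  k <- max(labels)
  if (length(unique(labels)) < 2L) {
    stopf("need at least 2 classes, got %d", length(unique(labels)))
  }
  if (!is.null(class_names)) class_names <- as.character(class_names)
  structure(list(labels = labels, class_names = class_names, k = k),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_vector> %d instances, %d classes\n",
              length(x$labels), length(tab)))
  print(tab)
  invisible(x)
}

check_paired <- function(table, labels) {
  if (nrow(table$values) != length(labels$labels)) {
    stopf("table has %d rows but labels have %d entries",
          nrow(table$values), length(labels$labels))
  }
}

#' Read a delimited UCI-style dataset
#'
#' Parses delimited text following the UCI `.data` convention: one
#' instance per line, a configurable field separator (comma by default),
#' a designated missing-value token (`"?"` by default), and the class
#' label in one column (the last, by default). Ragged rows and
#' non-numeric non-missing fields are hard errors that name the
#' offending line.
#'
#' Label fields that parse as integers are used directly as class codes;
#' otherwise the sorted unique label strings are coded `1..K` and the
#' mapping is recorded in the returned `label_vector`.
#'
#' @param path path to the delimited text file.
#' @param sep field separator, default `","`.
#' @param missing_token string marking a missing field, default `"?"`.
#' @param label_column column index holding the class label; `NULL`
#'   (default) means the last column.
#' @param exclude_columns optional integer indices (into the feature
#'   columns, after removing the label column) to drop, e.g. to exclude
#'   a non-ordinal attribute from SVM training.
#' @return A list with elements `table` ([feature_table]) and `labels`
#'   ([label_vector]).
#' @examples
#' tf <- tempfile(fileext = ".data")
#' writeLines(c("1,2,1", "3,?,2"), tf)
#' d <- read_delimited(tf)
#' d$table$missing_mask
#' @export
read_delimited <- function(path, sep = ",", missing_token = "?",
                           label_column = NULL, exclude_columns = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty file: %s", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stopf("ragged row: line %d has %d fields, expected %d",
          bad, nf[bad], nf[1L])
  }
  p <- nf[1L]
  if (is.null(label_column)) label_column <- p
  if (!is_count(label_column) || label_column > p) {
    stopf("label_column %s out of range 1..%d", label_column, p)
  }
  raw <- matrix(trimws(unlist(fields)), nrow = length(lines), ncol = p,
                byrow = TRUE)

  lab_raw <- raw[, label_column]
  if (any(lab_raw == missing_token)) {
    stopf("missing label on line %d", which(lab_raw == missing_token)[1L])
  }
  lab_int <- suppressWarnings(as.integer(lab_raw))
  if (anyNA(lab_int) || any(lab_int != as.numeric(lab_raw))) {
    lev <- sort(unique(lab_raw))
    lab_int <- match(lab_raw, lev)
    class_names <- stats::setNames(lev, seq_along(lev))
  } else {
    class_names <- NULL
  }

  feat <- raw[, -label_column, drop = FALSE]
  mask <- feat == missing_token
  vals <- suppressWarnings(array(as.numeric(feat), dim = dim(feat)))
  bad <- which(is.na(vals) & !mask, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric field \"%s\" at line %d, feature column %d",
          feat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L])
  }
  vals[mask] <- NA_real_
  tab <- feature_table(vals, paste0("V", seq_len(ncol(vals))), mask)
  if (!is.null(exclude_columns)) {
    keep <- setdiff(seq_len(ncol(vals)), exclude_columns)
    tab <- feature_table(tab$values[, keep, drop = FALSE],
                         tab$feature_ids[keep],
                         tab$missing_mask[, keep, drop = FALSE])
  }
  list(table = tab, labels = label_vector(lab_int, class_names))
}

#' Write a feature table back to the UCI delimited dialect
#'
#' Inverse of [read_delimited()]: masked cells are written as the missing
#' token and the label goes in the last column.
#'
#' @inheritParams read_delimited
#' @param table a [feature_table].
#' @param labels a [label_vector] paired with `table`.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(table, labels, path, sep = ",",
                            missing_token = "?") {
  check_paired(table, labels)
  chr <- matrix(as.character(table$values), nrow = nrow(table$values))
  chr[table$missing_mask] <- missing_token
  out <- cbind(chr, as.character(labels$labels))
  writeLines(apply(out, 1L, paste, collapse = sep), path)
  invisible(path)
}

#' Drop instances with missing values
#'
#' Listwise deletion: every instance with at least one masked cell is
#' removed, preserving the relative order of the rest. This mirrors the
#' usual UCI preprocessing (e.g. dropping the 8 incomplete Dermatology
#' rows to retain 358 of 366). No imputation is offered.
#'
#' @param table a [feature_table].
#' @param labels a [label_vector] paired with `table`.
#' @return A list with elements `table`, `labels` (filtered) and
#'   `report`, a `preprocess_report` with counts `n_input`,
#'   `n_dropped_missing`, `n_retained` and `dropped_row_indices`.
#' @export
drop_missing <- function(table, labels) {
  check_paired(table, labels)
  drop <- rowSums(table$missing_mask) > 0L
  if (all(drop)) stopf("empty dataset after filtering")
  keep <- which(!drop)
  report <- structure(
    list(n_input = nrow(table$values),
         n_dropped_missing = sum(drop),
         n_retained = length(keep),
         dropped_row_indices = which(drop)),
    class = "preprocess_report"
  )
  tab <- feature_table(table$values[keep, , drop = FALSE],
                       table$feature_ids,
                       table$missing_mask[keep, , drop = FALSE])
  list(table = tab,
       labels = label_vector(labels$labels[keep], labels$class_names),
       report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess: %d in, %d dropped (missing), %d retained\n",
              x$n_input, x$n_dropped_missing, x$n_retained))
  invisible(x)
}

#' Recode feature values
#'
#' Applies per-feature value maps (e.g. `FALSE/TRUE` to `0/1`, or an
#' ordinal severity recoding). Features without an entry in `coding`
#' pass through unchanged; an observed value absent from its feature's
#' map is an error. Both UCI benchmarks used here are already numerically
#' coded, so the default (empty coding) is the identity.
#'
#' @param table a [feature_table].
#' @param coding named list; names are feature ids, each element a named
#'   numeric vector mapping observed values (as names) to new values.
#' @return The recoded [feature_table].
#' @export
encode_features <- function(table, coding = list()) {
  if (!length(coding)) return(table)
  unknown <- setdiff(names(coding), table$feature_ids)
  if (length(unknown)) stopf("coding for unknown feature: %s", unknown[1L])
  vals <- table$values
  for (fid in names(coding)) {
    map <- coding[[fid]]
    j <- match(fid, table$feature_ids)
    obs <- vals[, j]
    seen <- !table$missing_mask[, j]
    idx <- match(as.character(obs[seen]), names(map))
    if (anyNA(idx)) {
      bad <- as.character(obs[seen])[which(is.na(idx))[1L]]
      stopf("feature %s: observed value %s not in coding map", fid, bad)
    }
    vals[seen, j] <- as.numeric(map)[idx]
  }
  feature_table(vals, table$feature_ids, table$missing_mask)
}

#' Min-max rescale features to [0, 1]
#'
#' Optional preprocessing for RBF kernels, whose distances otherwise
#' depend on raw attribute units. Off by default throughout the package.
#' Constant features are mapped to 0.
#'
#' @param table a [feature_table] with no missing cells.
#' @return The rescaled [feature_table].
#' @export
rescale_unit <- function(table) {
  if (any(table$missing_mask)) stopf("rescale requires complete data")
  vals <- apply(table$values, 2L, function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) rep(0, length(v)) else (v - r[1L]) / (r[2L] - r[1L])
  })
  feature_table(vals, table$feature_ids)
}
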