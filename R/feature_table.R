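#' Construct a feature table
#'
#' A feature table is the central data container of the package: a numeric
#' matrix of molecular descriptors (samples in rows, named descriptors in
#' columns) with unique sample identifiers and an optional activity column
#' (pIC50, the negative decadic logarithm of the molar IC50).
#'
#' @param values numeric matrix, `n_samples x n_features`. Column names are
#'   the feature names; they must be unique and non-empty (a 0-column matrix
#'   is allowed).
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `values`.
#' @param activity optional numeric vector of activities (pIC50), aligned
#'   with `sample_ids`.
#' @return An object of class `feature_table` with fields `values`,
#'   `sample_ids` and `activity`.
#' @examples
#' ft <- feature_table(matrix(1:4, 2, dimnames = list(NULL, c("a", "b"))),
#'                     sample_ids = c("m1", "m2"), activity = c(6.5, 7.2))
#' n_samples(ft)
#' @export
feature_table <- function(values, sample_ids, activity = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(sample_ids)) {
    stop("number of rows of `values` (", nrow(values),
         ") does not match the number of sample ids (", length(sample_ids), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (ncol(values) > 0) {
    fn <- colnames(values)
    if (is.null(fn) || any(!nzchar(fn))) {
      stop("`values` must have non-empty column (feature) names")
    }
    if (anyDuplicated(fn)) {
      stop("duplicate feature names: ",
           paste(unique(fn[duplicated(fn)]), collapse = ", "))
    }
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("feature values must be finite and non-missing")
  }
  if (!is.null(activity)) {
    activity <- as.numeric(activity)
    if (length(activity) != length(sample_ids)) {
      stop("`activity` length (", length(activity),
           ") does not match the number of samples (", length(sample_ids), ")")
    }
    if (anyNA(activity)) stop("`activity` must not contain missing values")
  }
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids, activity = activity),
            class = "feature_table")
}

#' @rdname feature_table
#' @param x a `feature_table`
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  nrow(x$values)
}

#' @rdname feature_table
#' @export
feature_names <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (ncol(x$values) == 0) character(0) else colnames(x$values)
}

#' Subset a feature table
#'
#' @param x a `feature_table`
#' @param i row (sample) index: integer, logical, or sample-id character
#' @param j column (feature) index: integer, logical, or feature-name
#'   character
#' @param ... unused
#' @param drop ignored; subsetting always returns a `feature_table`
#' @return a `feature_table` restricted to the selected samples/features
#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(j)) {
    missing_j <- setdiff(j, feature_names(x))
    if (length(missing_j)) {
      stop("unknown feature(s): ", paste(missing_j, collapse = ", "))
    }
  }
  if (is.character(i)) {
    missing_i <- setdiff(i, x$sample_ids)
    if (length(missing_i)) {
      stop("unknown sample id(s): ", paste(missing_i, collapse = ", "))
    }
    i <- match(i, x$sample_ids)
  }
  vals <- x$values[i, j, drop = FALSE]
  act <- if (is.null(x$activity)) NULL else x$activity[i]
  feature_table(vals, x$sample_ids[i], act)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", n_samples(x), " samples x ",
      ncol(x$values), " features",
      if (!is.null(x$activity)) " (+ activity)", "\n", sep = "")
  if (ncol(x$values) > 0) {
    cat("features: ",
        paste(utils::head(feature_names(x), 8), collapse = ", "),
        if (ncol(x$values) > 8) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' Read a feature table from CSV
#'
#' The expected layout is `sample_id,<descriptor1>,...,<descriptorK>[,pIC50]`:
#' first column sample id, then one numeric column per descriptor, with an
#' optional activity column named by `activity_column`. The file must have a
#' header row; decimal separator is the dot regardless of locale. Missing or
#' non-numeric cells are an error (descriptor matrices must be complete).
#'
#' @param path path to a CSV file
#' @param activity_column name of the activity column to split off as the
#'   table's activity (default `"pIC50"`); `NULL` to treat every non-id
#'   column as a feature
#' @return a [feature_table]
#' @seealso [write_feature_csv()]
#' @export
read_feature_csv <- function(path, activity_column = "pIC50") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (ncol(df) < 1) stop("CSV has no columns: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  other <- names(df)[-1]
  has_activity <- !is.null(activity_column) && activity_column %in% other
  feat_cols <- setdiff(other, if (has_activity) activity_column else character(0))
  parse_num <- function(col, name) {
    raw <- trimws(col)
    bad <- !nzchar(raw)
    num <- suppressWarnings(as.numeric(raw))
    bad <- bad | is.na(num)
    if (any(bad)) {
      r <- which(bad)[1]
      stop("non-numeric or missing value at row ", r, " (sample '", ids[r],
           "'), column '", name, "'")
    }
    num
  }
  vals <- matrix(0, nrow(df), length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (fc in feat_cols) vals[, fc] <- parse_num(df[[fc]], fc)
  act <- if (has_activity) parse_num(df[[activity_column]], activity_column) else NULL
  feature_table(vals, ids, act)
}

#' Write a feature table to CSV
#'
#' Values are written with enough significant digits (15) that
#' [read_feature_csv()] reproduces the table exactly for all practically
#' occurring magnitudes; the round trip is the identity at that precision.
#'
#' @param table a [feature_table]
#' @param path output file path
#' @param activity_column name under which to write the activity column
#'   (only written when the table has one)
#' @return `path`, invisibly
#' @export
write_feature_csv <- function(table, path, activity_column = "pIC50") {
  stopifnot(inherits(table, "feature_table"))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (fn in feature_names(table)) df[[fn]] <- fmt(table$values[, fn])
  if (!is.null(table$activity)) df[[activity_column]] <- fmt(table$activity)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write feature CSV to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}
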