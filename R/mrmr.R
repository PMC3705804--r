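#' Discretization scheme for mutual-information estimation
#'
#' Mutual information between continuous descriptors is estimated after
#' discretization. Two schemes are offered:
#' \describe{
#'   \item{`mean_sigma`}{three states split at
#'     `mean - sigma_factor * sd` and `mean + sigma_factor * sd` — the
#'     classic mRMR practice for continuous variables;}
#'   \item{`equal_frequency`}{`n_bins` quantile bins with counts differing
#'     by at most one.}
#' }
#'
#' @param method `"mean_sigma"` or `"equal_frequency"`
#' @param n_bins number of bins (`equal_frequency` only, >= 2)
#' @param sigma_factor multiple of the standard deviation used for the
#'   `mean_sigma` split (default 1)
#' @return a `discretization_scheme` list
#' @export
discretization_scheme <- function(method = c("mean_sigma", "equal_frequency"),
                                  n_bins = 3L, sigma_factor = 1.0) {
  method <- match.arg(method)
  if (method == "equal_frequency" && n_bins < 2) {
    stop("`n_bins` must be >= 2 for equal-frequency binning")
  }
  if (method == "mean_sigma" && sigma_factor <= 0) {
    stop("`sigma_factor` must be positive")
  }
  structure(list(method = method, n_bins = as.integer(n_bins),
                 sigma_factor = sigma_factor),
            class = "discretization_scheme")
}

#' Discretize a numeric vector
#'
#' Returns integer state labels `0 .. k-1` according to the scheme. A
#' constant vector yields a single label (with a warning under
#' equal-frequency binning, where the requested bin count cannot be
#' realized).
#'
#' @param values numeric vector, length >= 2
#' @param scheme a [discretization_scheme]
#' @return integer vector of labels starting at 0
#' @export
discretize <- function(values, scheme = discretization_scheme()) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  if (length(values) < 2) stop("need at least 2 values to discretize")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (max(values) == min(values)) {
    if (scheme$method == "equal_frequency") {
      warning("constant vector: returning a single label")
    }
    return(integer(length(values)))
  }
  if (scheme$method == "mean_sigma") {
    m <- mean(values); s <- stats::sd(values)
    lo <- m - scheme$sigma_factor * s
    hi <- m + scheme$sigma_factor * s
    labels <- integer(length(values))
    labels[values >= lo & values <= hi] <- 1L
    labels[values > hi] <- 2L
    # collapse unused states so labels cover 0..(k-1)
    match(labels, sort(unique(labels))) - 1L
  } else {
    # rank-based equal-frequency split: bin counts differ by at most one
    n <- length(values)
    r <- rank(values, ties.method = "first")
    labels <- floor((r - 1) * scheme$n_bins / n)
    match(labels, sort(unique(labels))) - 1L
  }
}

#' Mutual information of two label vectors
#'
#' Empirical mutual information (natural log, nats) of two discrete label
#' vectors, computed from the joint frequency table with the convention
#' `0 * log 0 = 0`. Symmetric and nonnegative.
#'
#' @param x,y equal-length label vectors (any discrete values)
#' @return mutual information in nats, >= 0
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1))  # independent: 0
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1))  # identical fair coin: log(2)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (", length(x), " vs ",
         length(y), ")")
  }
  if (length(x) < 2) stop("need at least 2 observations")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  mi <- sum(terms[joint > 0])
  max(mi, 0)
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Implements the difference (MID) form of the mRMR criterion: the first
#' feature maximizes the mutual information with the (discretized) activity;
#' each subsequent feature `f_j` maximizes
#' `score_j = I(f_j, c) - (1/m) * sum_{f_i in selected} I(f_i, f_j)`.
#' At the first step the redundancy average is vacuous and defined as 0.
#' Ties in score are broken by larger relevance, then by earlier column
#' order, so the ranking is deterministic.
#'
#' @param table a [feature_table] with activity column
#' @param scheme [discretization_scheme] applied to features and activity
#' @param top_k number of features to select (default 50)
#' @return an object of class `mrmr_ranking`: data frame with columns
#'   `rank`, `feature`, `relevance`, `redundancy`, `score`, plus attributes
#'   `selected` (the ranked names, S_n) and `rest` (unselected names, S_m)
#' @export
mrmr_rank <- function(table, scheme = discretization_scheme(), top_k = 50L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$activity)) {
    stop("mRMR ranking needs an activity column")
  }
  fn <- feature_names(table)
  if (length(fn) == 0) stop("feature table has no features")
  top_k <- min(as.integer(top_k), length(fn))
  if (top_k < 1) stop("`top_k` must be >= 1")
  labels <- apply(table$values, 2, discretize, scheme = scheme)
  target <- discretize(table$activity, scheme)
  relevance <- apply(labels, 2, mutual_information, y = target)

  selected <- integer(0)
  mi_cache <- matrix(NA_real_, length(fn), length(fn))
  rows <- vector("list", top_k)
  remaining <- seq_along(fn)
  for (step in seq_len(top_k)) {
    if (length(selected) == 0) {
      red <- rep(0, length(remaining))
    } else {
      red <- vapply(remaining, function(j) {
        for (i in selected) {
          if (is.na(mi_cache[i, j])) {
            mi_cache[i, j] <<- mi_cache[j, i] <<-
              mutual_information(labels[, i], labels[, j])
          }
        }
        mean(mi_cache[selected, j])
      }, numeric(1))
    }
    score <- relevance[remaining] - red
    best <- order(-score, -relevance[remaining], remaining)[1]
    pick <- remaining[best]
    rows[[step]] <- data.frame(rank = step, feature = fn[pick],
                               relevance = unname(relevance[pick]),
                               redundancy = red[best],
                               score = unname(score[best]),
                               stringsAsFactors = FALSE)
    selected <- c(selected, pick)
    remaining <- remaining[-best]
  }
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$feature
  attr(out, "rest") <- fn[remaining]
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' Write an mRMR ranking to CSV
#'
#' @param ranking an `mrmr_ranking` from [mrmr_rank()]
#' @param path output path; columns `rank,feature,relevance,redundancy,score`
#' @return `path`, invisibly
#' @export
write_mrmr_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  utils::write.csv(as.data.frame(ranking)[, c("rank", "feature", "relevance",
                                              "redundancy", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
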