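#' Prediction set
#'
#' Pairs experimental activities with model predictions for a set of
#' samples; the input to [evaluate()].
#'
#' @param sample_ids character ids
#' @param y experimental activities (pIC50)
#' @param y_hat predicted activities
#' @return a `prediction_set`
#' @export
prediction_set <- function(sample_ids, y, y_hat) {
  sample_ids <- as.character(sample_ids)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(sample_ids) || length(y_hat) != length(sample_ids)) {
    stop("sample_ids, y and y_hat must have equal length")
  }
  if (length(y) < 1) stop("a prediction set needs at least one sample")
  structure(list(sample_ids = sample_ids, y = y, y_hat = y_hat,
                 n = length(y)), class = "prediction_set")
}

#' Evaluate predictions: q-squared and RMSE
#'
#' The squared correlation coefficient
#' `q2 = 1 - sum((y - y_hat)^2) / sum((y - y_mean)^2)` and the root mean
#' square error `RMSE = sqrt(sum((y - y_hat)^2) / N)`, with `y_mean` the
#' mean experimental activity of the evaluated set itself (per-set
#' convention, recorded in the report).
#'
#' @param preds a [prediction_set]
#' @return an `evaluation_report` with `q_squared`, `rmse`, `y_mean`, `n`
#'   and `y_mean_convention = "per_set"`
#' @export
evaluate <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  y <- preds$y; yh <- preds$y_hat
  rmse <- sqrt(mean((y - yh)^2))
  if (preds$n < 2) stop("q-squared needs at least 2 samples")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("q-squared undefined: zero variance in experimental values")
  structure(list(q_squared = 1 - sum((y - yh)^2) / sst,
                 rmse = rmse, y_mean = mean(y), n = preds$n,
                 y_mean_convention = "per_set"),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d  q2 = %.4f  RMSE = %.4f\n",
              x$n, x$q_squared, x$rmse))
  invisible(x)
}

#' Activity-ranked every-kth train/test split
#'
#' Samples are sorted by activity in descending order (stable: ties keep
#' their original input order) and every `every_k`-th sample of the ranking
#' (ranks `every_k`, `2 * every_k`, ...) forms the test set; the rest is the
#' training set. With the default `every_k = 4` a 48-compound set splits
#' 36/12. Original input order is preserved within each output table.
#'
#' @param table a [feature_table] with activity
#' @param every_k stride of the test extraction (>= 2)
#' @return list with `train` and `test` feature tables
#' @export
split_every_kth <- function(table, every_k = 4L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$activity)) stop("split needs an activity column")
  every_k <- as.integer(every_k)
  if (every_k < 2) stop("`every_k` must be >= 2")
  n <- n_samples(table)
  if (n < every_k) stop("fewer samples (", n, ") than `every_k` (", every_k,
                        "): the test set would be empty")
  ord <- order(-table$activity)  # stable: ties keep input order
  test_rows <- sort(ord[seq(every_k, n, by = every_k)])
  train_rows <- setdiff(seq_len(n), test_rows)
  list(train = table[train_rows, ], test = table[test_rows, ])
}

#' Leave-one-out cross-validation of an SVR model
#'
#' For each sample the model is trained on all other samples (the min-max
#' scaler is refit inside each fold) with a fixed feature subset and fixed
#' hyperparameters, and the held-out sample is predicted once. Output is
#' aligned to the input row order.
#'
#' @param table a [feature_table] with activity
#' @param features feature names to use
#' @param hyper an [svr_hyperparams]
#' @return a [prediction_set] of LOOCV predictions
#' @export
loocv <- function(table, features = feature_names(table),
                  hyper = svr_hyperparams()) {
  stopifnot(inherits(table, "feature_table"))
  n <- n_samples(table)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 samples")
  if (is.null(table$activity)) stop("LOOCV needs an activity column")
  missing_f <- setdiff(features, feature_names(table))
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  }
  X <- table$values[, features, drop = FALSE]
  if (any(!is.finite(X))) stop("non-finite feature values")
  yh <- svr_loocv_cpp(X, table$activity, hyper$C, hyper$epsilon, hyper$gamma,
                      grad_tol = 1e-8, max_iter = 200000L,
                      kkt_tol = hyper$kkt_tolerance)
  prediction_set(table$sample_ids, table$activity, yh)
}

loocv_rmse <- function(table, features, hyper) {
  ps <- loocv(table, features, hyper)
  sqrt(mean((ps$y - ps$y_hat)^2))
}

#' Backward feature elimination driven by LOOCV RMSE
#'
#' Starting from an (mRMR-)ranked feature list, every single-feature
#' removal is scored by the leave-one-out cross-validated RMSE of an SVR
#' trained on the remaining features; the removal giving the lowest RMSE is
#' applied, the step recorded, and the process repeats until one feature
#' remains. The best subset is the recorded set (including the full
#' starting set) with the globally minimal LOOCV RMSE, ties broken toward
#' the smaller subset. Candidate ties within a step are broken by removing
#' the lowest-ranked (least important) feature first.
#'
#' @param table a [feature_table] with activity
#' @param ranked_features feature names in decreasing importance order
#'   (e.g. from [mrmr_rank()])
#' @param hyper an [svr_hyperparams]
#' @param verbose print one line per elimination step
#' @return a `selection_trace`: data frame with columns `step`,
#'   `removed_feature`, `n_remaining`, `loocv_rmse` (step 0 is the untouched
#'   starting set), plus attributes `best_subset` and `best_rmse`
#' @export
backward_select <- function(table, ranked_features, hyper = svr_hyperparams(),
                            verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  missing_f <- setdiff(ranked_features, feature_names(table))
  if (length(missing_f)) {
    stop("ranked feature(s) not in table: ", paste(missing_f, collapse = ", "))
  }
  if (length(ranked_features) < 2) stop("need at least 2 features to eliminate")
  current <- ranked_features
  steps <- list()
  rmse0 <- loocv_rmse(table, current, hyper)
  steps[[1]] <- data.frame(step = 0L, removed_feature = "",
                           n_remaining = length(current), loocv_rmse = rmse0,
                           stringsAsFactors = FALSE)
  sets <- list(current)
  step <- 0L
  while (length(current) > 1) {
    step <- step + 1L
    cand_rmse <- vapply(seq_along(current), function(k) {
      loocv_rmse(table, current[-k], hyper)
    }, numeric(1))
    # tie-break: lowest mRMR rank (= latest position in the ranked list) first
    pos_in_ranking <- match(current, ranked_features)
    drop_k <- order(cand_rmse, -pos_in_ranking)[1]
    removed <- current[drop_k]
    current <- current[-drop_k]
    steps[[step + 1L]] <- data.frame(step = step, removed_feature = removed,
                                     n_remaining = length(current),
                                     loocv_rmse = cand_rmse[drop_k],
                                     stringsAsFactors = FALSE)
    sets[[step + 1L]] <- current
    if (verbose) {
      message(sprintf("step %d: removed %-24s %d left, LOOCV RMSE %.4f",
                      step, removed, length(current), cand_rmse[drop_k]))
    }
  }
  trace <- do.call(rbind, steps)
  # global minimum; ties toward the smaller subset (later step)
  best <- order(trace$loocv_rmse, trace$n_remaining)[1]
  attr(trace, "best_subset") <- sets[[best]]
  attr(trace, "best_rmse") <- trace$loocv_rmse[best]
  class(trace) <- c("selection_trace", "data.frame")
  trace
}

#' Write a backward-selection trace to CSV
#'
#' @param trace a `selection_trace` from [backward_select()]
#' @param path output path; columns `step,removed_feature,n_remaining,loocv_rmse`
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multiple-linear-regression baseline
#'
#' Ordinary least squares on the selected features with leave-one-out
#' cross-validation by per-fold refitting; the reference point against
#' which the SVR's generalization is compared.
#'
#' @param table a [feature_table] with activity
#' @param features feature names to regress on
#' @return list with `coefficients` (intercept first) and `loocv`
#'   (a [prediction_set] of per-fold held-out predictions)
#' @export
mlr_baseline <- function(table, features = feature_names(table)) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$activity)) stop("mlr_baseline needs an activity column")
  n <- n_samples(table)
  if (n <= length(features) + 1) {
    stop("need n > p + 1 samples (n = ", n, ", p = ", length(features), ")")
  }
  df <- as.data.frame(table$values[, features, drop = FALSE])
  df$.y <- table$activity
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design matrix: drop collinear features")
  }
  yh <- vapply(seq_len(n), function(i) {
    f <- stats::lm(.y ~ ., data = df[-i, , drop = FALSE])
    unname(stats::predict(f, newdata = df[i, , drop = FALSE]))
  }, numeric(1))
  list(coefficients = stats::coef(fit),
       loocv = prediction_set(table$sample_ids, table$activity, yh))
}
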