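#' Specification for a synthetic descriptor table
#'
#' Describes a feature table with known planted structure used to exercise
#' the whole selection/validation pipeline: `n_informative` features drive
#' the target through the chosen link, `n_redundant` features are noisy
#' copies of informative ones (correlation `rho`), and `n_noise` features
#' are independent of everything. The defaults mirror the shape of a
#' typical descriptor-pool screening problem: 48 samples and 75 features of
#' which 6 matter.
#'
#' @param n_samples number of samples (>= 10)
#' @param n_informative features that enter the target
#' @param n_redundant correlated copies of informative features
#' @param n_noise irrelevant features
#' @param rho parent/copy correlation of redundant features, in `[0, 1]`
#' @param noise_sigma standard deviation of additive target noise
#' @param link functional form of the target: `"linear"`, `"sin"` or
#'   `"mixed"` (half linear, half sinusoidal terms)
#' @param seed integer RNG seed; generation is deterministic per seed
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_samples = 48L, n_informative = 6L,
                           n_redundant = 9L, n_noise = 60L, rho = 0.9,
                           noise_sigma = 0.3, link = c("linear", "sin", "mixed"),
                           seed = 7L) {
  link <- match.arg(link)
  if (n_samples < 10) stop("`n_samples` must be >= 10")
  if (any(c(n_informative, n_redundant, n_noise) < 0)) {
    stop("feature counts must be nonnegative")
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant features need at least one informative parent")
  }
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]")
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative")
  structure(list(n_samples = as.integer(n_samples),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 rho = rho, noise_sigma = noise_sigma, link = link,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature table with planted signal
#'
#' Informative features are standard normal draws; the activity is
#' `link(informative) + N(0, noise_sigma)`. Redundant feature `r` copies
#' its parent as `rho * parent + sqrt(1 - rho^2) * N(0, 1)` (parents cycle
#' through the informative features); noise features are independent
#' standard normal. Feature names encode their role (`inf_1`, `red_1_of_2`,
#' `noise_1`, ...), so tests can check where planted features land in a
#' ranking.
#'
#' @param spec a [synthetic_spec]
#' @return a [feature_table] with activity; attribute `truth` lists the
#'   informative, redundant and noise feature names
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  set.seed(spec$seed)
  inf <- matrix(stats::rnorm(n * spec$n_informative), n)
  inf_names <- if (spec$n_informative)
    paste0("inf_", seq_len(spec$n_informative)) else character(0)
  red <- matrix(0, n, spec$n_redundant)
  red_names <- character(spec$n_redundant)
  if (spec$n_redundant > 0) {
    parents <- rep(seq_len(spec$n_informative), length.out = spec$n_redundant)
    for (r in seq_len(spec$n_redundant)) {
      red[, r] <- spec$rho * inf[, parents[r]] +
        sqrt(1 - spec$rho^2) * stats::rnorm(n)
      red_names[r] <- paste0("red_", r, "_of_", parents[r])
    }
  }
  noise <- matrix(stats::rnorm(n * spec$n_noise), n)
  noise_names <- if (spec$n_noise)
    paste0("noise_", seq_len(spec$n_noise)) else character(0)
  signal <- if (spec$n_informative == 0) {
    rep(0, n)
  } else {
    switch(spec$link,
      linear = rowSums(inf),
      # half an oscillation per 2 standard deviations: curved enough that a
      # straight line fits poorly, smooth enough that an RBF kernel of width
      # comparable to the scaled feature range can resolve it
      sin = rowSums(sin(pi / 2 * inf)),
      mixed = {
        half <- ceiling(spec$n_informative / 2)
        lin <- rowSums(inf[, seq_len(half), drop = FALSE])
        nl <- if (half < spec$n_informative) {
          rowSums(sin(pi / 2 * inf[, (half + 1):spec$n_informative, drop = FALSE]))
        } else 0
        lin + nl
      })
  }
  y <- signal + stats::rnorm(n, sd = spec$noise_sigma)
  vals <- cbind(inf, red, noise)
  colnames(vals) <- c(inf_names, red_names, noise_names)
  out <- feature_table(vals, paste0("s", seq_len(n)), y)
  attr(out, "truth") <- list(informative = inf_names, redundant = red_names,
                             noise = noise_names)
  out
}

table2_md5 <- "1c5643ab456b2c0b5abbf12d941293e7"

#' Load the packaged 48-compound pyrrolidine-amide benchmark
#'
#' A transcription (two decimal places) of the reference dataset of 48
#' cyanopyrrolidine-amide DPP-IV inhibitors: experimental pIC50, fitted
#' pIC50, leave-one-out cross-validated pIC50 (training compounds only) and
#' the test-set flag. 36 compounds are training, 12 are test. The file's
#' checksum is verified on load so a corrupted installation fails loudly.
#'
#' @return a data frame with columns `compound`, `pIC50_exp`, `pIC50_pred`,
#'   `pIC50_loocv` (NA on test rows) and `is_test` (logical)
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "qsardpp",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != table2_md5) {
    stop("integrity error: packaged benchmark table has been modified ",
         "(checksum mismatch)")
  }
  df <- utils::read.csv(path)
  df$is_test <- df$is_test == 1
  stopifnot(nrow(df) == 48, sum(df$is_test) == 12,
            sum(!is.na(df$pIC50_loocv)) == 36,
            all(is.na(df$pIC50_loocv) == df$is_test))
  df
}

#' Recompute the benchmark's headline statistics
#'
#' From the packaged benchmark table alone, recomputes the six fitting and
#' validation statistics of the reference SVR model: q2 and RMSE for the
#' training fit (36 compounds, experimental vs fitted), the training
#' leave-one-out cross-validation (experimental vs LOOCV) and the external
#' test set (12 compounds, experimental vs predicted), each with the
#' per-set mean convention of [evaluate()].
#'
#' @return data frame with columns `statistic`, `value`, `n`
#' @examples
#' reproduce_table2()
#' @export
reproduce_table2 <- function() {
  df <- load_table2()
  tr <- df[!df$is_test, ]
  te <- df[df$is_test, ]
  ev <- function(y, yh) evaluate(prediction_set(seq_along(y), y, yh))
  fit <- ev(tr$pIC50_exp, tr$pIC50_pred)
  cv <- ev(tr$pIC50_exp, tr$pIC50_loocv)
  test <- ev(te$pIC50_exp, te$pIC50_pred)
  data.frame(
    statistic = c("q2_train", "rmse_train", "q2_train_cv", "rmse_train_cv",
                  "q2_test", "rmse_test"),
    value = c(fit$q_squared, fit$rmse, cv$q_squared, cv$rmse,
              test$q_squared, test$rmse),
    n = c(fit$n, fit$n, cv$n, cv$n, test$n, test$n)
  )
}
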