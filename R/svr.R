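#' SVR hyperparameters
#'
#' The hyperparameters of epsilon support vector regression with the radial
#' basis function kernel `K(x, x') = exp(-gamma * ||x - x'||^2)`. The
#' defaults (C = 2, epsilon = 0.05, gamma = 1) are the settings under which
#' the packaged DPP-IV benchmark model was built; epsilon is interpreted in
#' scaled-target units (the target is min-max scaled to `[0, 1]` before
#' training, see [fit_scaler()]).
#'
#' @param C box constraint on the dual coefficients (> 0)
#' @param epsilon insensitive-tube half width in scaled-target units (>= 0)
#' @param gamma RBF kernel width (> 0)
#' @param kkt_tolerance tolerance on the dual optimality conditions (> 0)
#' @return an `svr_hyperparams` list
#' @export
svr_hyperparams <- function(C = 2.0, epsilon = 0.05, gamma = 1.0,
                            kkt_tolerance = 1e-3) {
  stopifnot(C > 0, epsilon >= 0, gamma > 0, kkt_tolerance > 0)
  structure(list(C = C, epsilon = epsilon, gamma = gamma,
                 kkt_tolerance = kkt_tolerance), class = "svr_hyperparams")
}

#' Fit the min-max scaler from training data
#'
#' Records per-feature minima and maxima and the activity minimum
#' (`target_offset`) and range (`target_scale`) of the training set.
#' Features and target are scaled to `[0, 1]` on the training data; query
#' rows are transformed with the training constants unchanged (values may
#' fall outside `[0, 1]`). A trained model's prediction in original units is
#' `target_scale * (sum_i beta_i K(x, x_i) + b) + target_offset`, which is
#' how the kernel-expansion form of a fitted pIC50 model with printed
#' constants (e.g. scale 2.10, offset 6.60 for a training set spanning
#' 6.60 to 8.70) arises.
#'
#' @param table a [feature_table] with activity column
#' @param features feature names to include (default: all)
#' @return a `scaler_spec` list with `feature_min`, `feature_max`,
#'   `target_offset`, `target_scale`
#' @export
fit_scaler <- function(table, features = feature_names(table)) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$activity)) stop("fit_scaler needs an activity column")
  y <- table$activity
  if (max(y) == min(y)) {
    stop("constant activity: target scale would be zero")
  }
  missing_f <- setdiff(features, feature_names(table))
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  }
  vals <- table$values[, features, drop = FALSE]
  structure(list(
    feature_min = apply(vals, 2, min),
    feature_max = apply(vals, 2, max),
    target_offset = min(y),
    target_scale = max(y) - min(y)
  ), class = "scaler_spec")
}

# scale a raw feature matrix with training constants; constant training
# columns (min == max) map to 0
scale_features <- function(scaler, raw) {
  fmin <- scaler$feature_min
  rng <- scaler$feature_max - fmin
  rng[rng == 0] <- 1
  sweep(sweep(raw, 2, fmin, "-"), 2, rng, "/")
}

# KKT bias recovery: free support vectors (strictly inside the box) sit
# exactly on the tube boundary and pin the bias; if none is free, every
# sample only bounds the bias and the midpoint of the admissible interval
# is taken
svr_bias <- function(beta, y, f, hyper) {
  C <- hyper$C; eps <- hyper$epsilon; tol <- hyper$kkt_tolerance
  free_pos <- beta > tol & beta < C - tol
  free_neg <- beta < -tol & beta > -C + tol
  est <- c((y - eps - f)[free_pos], (y + eps - f)[free_neg])
  if (length(est) > 0) return(mean(est))
  r <- y - f
  at_upper <- beta >= C - tol
  at_lower <- beta <= -C + tol
  inactive <- !at_upper & !at_lower
  hi <- min(c(Inf, (r - eps)[at_upper], (r + eps)[inactive]))
  lo <- max(c(-Inf, (r + eps)[at_lower], (r - eps)[inactive]))
  if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else 0
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train an epsilon-SVR model
#'
#' Min-max scales the selected features and the activity with training-set
#' constants, then solves the epsilon-SVR dual on the RBF kernel by
#' deterministic pairwise coordinate ascent (SMO-style). Support vectors are
#' the training rows with nonzero dual coefficient; the bias is recovered
#' from the Karush-Kuhn-Tucker conditions of the free support vectors.
#'
#' @param table training [feature_table] with activity
#' @param features feature names to train on (default: all)
#' @param hyper an [svr_hyperparams] object
#' @return an `svr_model` with fields `feature_names`, `support_vectors`
#'   (scaled rows), `dual_coefficients`, `bias`, `hyperparams`, `scaler`
#' @seealso [predict.svr_model()], [svr_to_json()]
#' @export
train_svr <- function(table, features = feature_names(table),
                      hyper = svr_hyperparams()) {
  stopifnot(inherits(table, "feature_table"), inherits(hyper, "svr_hyperparams"))
  if (n_samples(table) < 2) stop("need at least 2 training samples")
  scaler <- fit_scaler(table, features)
  X <- scale_features(scaler, table$values[, features, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values after scaling")
  y <- (table$activity - scaler$target_offset) / scaler$target_scale
  K <- rbf_kernel(X, X, hyper$gamma)
  sol <- svr_smo_cpp(K, y, hyper$C, hyper$epsilon,
                     grad_tol = 1e-8, max_iter = 200000L)
  beta <- sol$beta
  f <- sol$f
  bias <- svr_bias(beta, y, f, hyper)
  sv <- which(abs(beta) > 1e-12)
  structure(list(
    feature_names = features,
    support_vectors = X[sv, , drop = FALSE],
    dual_coefficients = beta[sv],
    bias = bias,
    hyperparams = hyper,
    scaler = scaler,
    dual_objective = sol$objective
  ), class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> ", length(x$dual_coefficients), " support vectors over ",
      length(x$feature_names), " features (C = ", x$hyperparams$C,
      ", epsilon = ", x$hyperparams$epsilon, ", gamma = ", x$hyperparams$gamma,
      ")\n", sep = "")
  invisible(x)
}

#' Predict activities with a trained SVR model
#'
#' Applies the kernel expansion
#' `target_scale * (sum_i beta_i * K(x, x_i) + b) + target_offset`
#' to each query row after scaling it with the training constants.
#'
#' @param object an `svr_model`
#' @param rows a [feature_table] containing the model's features (extra
#'   columns and arbitrary column order are fine)
#' @param ... unused
#' @return numeric vector of predictions (pIC50 units), named by sample id
#' @export
predict.svr_model <- function(object, rows, ...) {
  stopifnot(inherits(rows, "feature_table"))
  missing_f <- setdiff(object$feature_names, feature_names(rows))
  if (length(missing_f)) {
    stop("query table lacks model feature(s): ",
         paste(missing_f, collapse = ", "))
  }
  X <- scale_features(object$scaler,
                      rows$values[, object$feature_names, drop = FALSE])
  raw <- if (length(object$dual_coefficients) == 0) {
    rep(0, nrow(X))
  } else {
    as.numeric(rbf_kernel(X, object$support_vectors,
                          object$hyperparams$gamma) %*% object$dual_coefficients)
  }
  scaled <- raw + object$bias
  stats::setNames(object$scaler$target_scale * scaled + object$scaler$target_offset,
                  rows$sample_ids)
}

svr_schema_version <- 1L

#' Serialize / deserialize an SVR model as JSON
#'
#' The JSON schema carries everything needed to reproduce predictions
#' bit-identically: feature names, hyperparameters, scaler constants,
#' support vectors and dual coefficients (all numbers written at full
#' precision).
#'
#' @param model an `svr_model`
#' @param path optional file path; when given the JSON is written there
#' @return `svr_to_json`: JSON text (invisibly, when `path` is given);
#'   `svr_from_json`: an `svr_model`
#' @export
svr_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "svr_model"))
  obj <- list(
    schema_version = svr_schema_version,
    feature_names = as.list(model$feature_names),
    hyperparams = list(C = model$hyperparams$C,
                       epsilon = model$hyperparams$epsilon,
                       gamma = model$hyperparams$gamma,
                       kkt_tolerance = model$hyperparams$kkt_tolerance),
    scaler = list(feature_min = unname(model$scaler$feature_min),
                  feature_max = unname(model$scaler$feature_max),
                  target_offset = model$scaler$target_offset,
                  target_scale = model$scaler$target_scale),
    support_vectors = unname(lapply(seq_len(nrow(model$support_vectors)),
                                    function(i) unname(model$support_vectors[i, ]))),
    dual_coefficients = model$dual_coefficients,
    bias = model$bias
  )
  # 17 significant digits: lossless round trip for IEEE doubles
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname svr_to_json
#' @param text JSON text (or a file path to read, for `svr_from_json`)
#' @export
svr_from_json <- function(text) {
  if (length(text) == 1 && file.exists(text)) text <- readLines(text, warn = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(paste(text, collapse = "\n"),
                                     simplifyVector = TRUE),
                  error = function(e) stop("malformed model JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) || obj$schema_version != svr_schema_version) {
    stop("unsupported model schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version)
  }
  needed <- c("feature_names", "hyperparams", "scaler", "support_vectors",
              "dual_coefficients", "bias")
  absent <- setdiff(needed, names(obj))
  if (length(absent)) {
    stop("model JSON lacks field(s): ", paste(absent, collapse = ", "))
  }
  fn <- unlist(obj$feature_names)
  sv <- obj$support_vectors   # serialized row-major: one array per vector
  if (is.list(sv)) {
    sv <- matrix(unlist(lapply(sv, as.numeric)), ncol = length(fn), byrow = TRUE)
  } else if (is.null(sv) || length(sv) == 0) {
    sv <- matrix(0, 0, length(fn))
  } else {
    sv <- matrix(as.numeric(sv), ncol = length(fn))
  }
  colnames(sv) <- fn
  structure(list(
    feature_names = fn,
    support_vectors = sv,
    dual_coefficients = as.numeric(obj$dual_coefficients),
    bias = obj$bias,
    hyperparams = svr_hyperparams(obj$hyperparams$C, obj$hyperparams$epsilon,
                                  obj$hyperparams$gamma,
                                  obj$hyperparams$kkt_tolerance),
    scaler = structure(list(
      feature_min = stats::setNames(as.numeric(obj$scaler$feature_min), fn),
      feature_max = stats::setNames(as.numeric(obj$scaler$feature_max), fn),
      target_offset = obj$scaler$target_offset,
      target_scale = obj$scaler$target_scale
    ), class = "scaler_spec")
  ), class = "svr_model")
}
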