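test_that("the scaler records training min-max constants", {
  tab <- quick_table(cbind(x = c(0.2, 0.8)), activity = c(0, 1))
  sc <- fit_scaler(tab)
  expect_equal(sc$target_offset, 0)
  expect_equal(sc$target_scale, 1)
  expect_equal(unname(sc$feature_min), 0.2)
  expect_equal(unname(sc$feature_max), 0.8)

  expect_error(fit_scaler(quick_table(cbind(x = 1:3), activity = rep(2, 3))),
               "constant activity")

  # constant feature column scales to 0, not NaN
  tabc <- quick_table(cbind(k = rep(5, 3), x = 1:3), activity = c(1, 2, 3))
  sc2 <- fit_scaler(tabc)
  scaled <- qsardpp:::scale_features(sc2, tabc$values)
  expect_equal(unname(scaled[, "k"]), rep(0, 3))
})

test_that("the benchmark training activities give the published scaling constants", {
  df <- load_table2()
  train <- df[!df$is_test, ]
  tab <- feature_table(matrix(0, nrow(train), 0), train$compound,
                       train$pIC50_exp)
  sc <- fit_scaler(tab)
  expect_equal(sc$target_offset, 6.60)
  expect_equal(sc$target_scale, 2.10)
})

test_that("a near-interpolating fit stays within the insensitive tube", {
  x <- seq(0, 1, length.out = 5)
  tab <- quick_table(cbind(x = x), activity = x)
  m <- train_svr(tab, hyper = svr_hyperparams(C = 100, epsilon = 0.01, gamma = 1))
  pred <- predict(m, tab)
  # predictions in original units; tube is eps * target_scale wide
  expect_true(all(abs(pred - x) <= 0.01 + 0.01))
  expect_equal(sum(m$dual_coefficients), 0, tolerance = 1e-8)
})

test_that("targets inside the tube produce an essentially flat model", {
  # all scaled targets within 2*eps of their mean: flat function suffices
  y <- 7 + c(-0.02, 0.02, 0.01, -0.01, 0) * 2  # range 0.08
  tab <- quick_table(cbind(x = seq(0, 1, length.out = 5)), activity = y)
  m <- train_svr(tab, hyper = svr_hyperparams(C = 2, epsilon = 0.5, gamma = 1))
  pred <- predict(m, tab)
  eps_raw <- 0.5 * m$scaler$target_scale
  expect_true(all(abs(pred - y) <= eps_raw + 1e-6))
  expect_true(all(abs(m$dual_coefficients) < 1e-8) ||
                length(m$dual_coefficients) == 0)
})

test_that("the dual solution matches an interior-point QP oracle on small problems", {
  set.seed(17)
  for (case in 1:8) {
    n <- sample(3:6, 1)
    p <- sample(1:3, 1)
    X <- matrix(runif(n * p), n)
    y <- runif(n)
    C <- sample(c(0.5, 2, 10), 1)
    eps <- sample(c(0, 0.05, 0.2), 1)
    gamma <- sample(c(0.5, 1, 4), 1)
    K <- qsardpp:::rbf_kernel(X, X, gamma)
    sol <- qsardpp:::svr_smo_cpp(K, y, C, eps, grad_tol = 1e-10,
                                 max_iter = 200000L)
    expect_true(all(abs(sol$beta) <= C + 1e-9))
    expect_equal(sum(sol$beta), 0, tolerance = 1e-9)
    oracle <- qp_oracle(K, y, C, eps)
    expect_equal(sol$objective,
                 svr_dual_objective(K, y, eps, sol$beta), tolerance = 1e-10)
    expect_lte(abs(sol$objective - oracle$objective), 1e-6)
  }
})

test_that("libsvm agrees with the packaged solver on a toy regression", {
  x <- seq(0, 1, length.out = 7)
  y <- x^2
  tab <- quick_table(cbind(x = x), activity = y)
  m <- train_svr(tab, hyper = svr_hyperparams(C = 2, epsilon = 0.05, gamma = 1))
  ours <- predict(m, tab)
  X <- qsardpp:::scale_features(m$scaler, tab$values)
  ys <- (y - m$scaler$target_offset) / m$scaler$target_scale
  ref <- e1071::svm(x = X, y = ys, type = "eps-regression", kernel = "radial",
                    gamma = 1, cost = 2, epsilon = 0.05, scale = FALSE,
                    tolerance = 1e-6)
  ref_pred <- m$scaler$target_scale * predict(ref, X) + m$scaler$target_offset
  expect_equal(unname(ours), unname(ref_pred), tolerance = 1e-3)
})

test_that("prediction follows the kernel expansion exactly", {
  # hand-built model: one support vector at the origin, beta = 1, identity scaling
  m <- structure(list(
    feature_names = "x",
    support_vectors = matrix(0, 1, 1, dimnames = list(NULL, "x")),
    dual_coefficients = 1,
    bias = 0,
    hyperparams = svr_hyperparams(C = 1, epsilon = 0, gamma = 1),
    scaler = structure(list(feature_min = c(x = 0), feature_max = c(x = 1),
                            target_offset = 0, target_scale = 1),
                       class = "scaler_spec")
  ), class = "svr_model")
  expect_equal(unname(predict(m, quick_table(cbind(x = 0)))), 1)
  expect_lt(unname(predict(m, quick_table(cbind(x = 50)))), 1e-10)

  # zero support vectors: constant prediction scale * bias + offset
  m$support_vectors <- m$support_vectors[0, , drop = FALSE]
  m$dual_coefficients <- numeric(0)
  m$bias <- 0.25
  m$scaler$target_scale <- 2
  m$scaler$target_offset <- 6
  p <- predict(m, quick_table(cbind(x = c(-3, 0, 11))))
  expect_equal(unname(p), rep(2 * 0.25 + 6, 3))
})

test_that("predictions ignore query column order and name missing features", {
  set.seed(5)
  tab <- quick_table(cbind(a = rnorm(8), b = rnorm(8)), activity = rnorm(8))
  m <- train_svr(tab)
  q <- quick_table(cbind(b = tab$values[, "b"], a = tab$values[, "a"]))
  expect_equal(predict(m, q), predict(m, tab[, c("a", "b")]))
  expect_error(predict(m, quick_table(cbind(a = 1))), "b")
})

test_that("gamma -> 0 flattens predictions across queries", {
  set.seed(6)
  tab <- quick_table(cbind(x = rnorm(10)), activity = rnorm(10))
  m <- train_svr(tab, hyper = svr_hyperparams(gamma = 1e-10))
  p <- predict(m, quick_table(cbind(x = c(-5, 0, 5))))
  expect_lt(diff(range(p)), 1e-6)
})

test_that("JSON serialization round-trips predictions bit-identically", {
  set.seed(7)
  tab <- quick_table(cbind(a = rnorm(9), b = rnorm(9)), activity = rnorm(9))
  m <- train_svr(tab)
  txt <- svr_to_json(m)
  m2 <- svr_from_json(txt)
  q <- quick_table(cbind(a = rnorm(100), b = rnorm(100)))
  expect_identical(predict(m, q), predict(m2, q))

  parsed <- jsonlite::fromJSON(txt)
  expect_equal(parsed$hyperparams$gamma, 1)
  expect_equal(parsed$hyperparams$C, 2)
  expect_equal(parsed$hyperparams$epsilon, 0.05)
  expect_named(parsed$scaler, c("feature_min", "feature_max", "target_offset",
                                "target_scale"))

  expect_error(svr_from_json(substr(txt, 1, 50)), "malformed")
  bad <- jsonlite::toJSON(list(schema_version = 99), auto_unbox = TRUE)
  expect_error(svr_from_json(bad), "schema version")
})
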