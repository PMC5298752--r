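# MLP -----------------------------------------------------------------------

test_that("tan-sigmoid activation is odd, matches its definition, saturates", {
  expect_equal(tanh_activation(0), 0)
  expect_equal(tanh_activation(1), (exp(1) - exp(-1)) / (exp(1) + exp(-1)))
  expect_equal(tanh_activation(1000), 1)
  expect_equal(tanh_activation(-1000), -1)
})

test_that("MLP predictions match the term-by-term network equation", {
  # degenerate parameter cases
  m0 <- structure(list(W = matrix(0, 1, 2), b_hidden = 0, a = 0, beta = 0.5,
                       k = 1L, d = 2L), class = "mlp_model")
  expect_equal(mlp_predict(m0, matrix(rnorm(10), 5, 2)), rep(0.5, 5))

  set.seed(21)
  m <- structure(list(W = matrix(rnorm(12), 3, 4), b_hidden = rnorm(3),
                      a = rnorm(3), beta = rnorm(1), k = 3L, d = 4L),
                 class = "mlp_model")
  X <- matrix(rnorm(40), 10, 4)
  oracle <- apply(X, 1, function(x) mlp_oracle_one(m, x))
  expect_equal(mlp_predict(m, X), unname(oracle), tolerance = 1e-12)
  expect_error(mlp_predict(m, matrix(1, 2, 5)),
               class = "bisguard_dimension_error")
})

test_that("Levenberg-Marquardt drives a one-unit net onto a linear target", {
  set.seed(4)
  X <- matrix(runif(50, -1, 1), 50, 1)
  y <- 2 * X[, 1] + 1
  m <- mlp_train(X, y, k_hidden = 1, seed = 3, max_iter = 200)
  expect_lt(tail(m$mse_trace, 1), 1e-4)
})

test_that("accepted-step MSE is non-increasing on every training run", {
  set.seed(14)
  for (i in 1:5) {
    X <- matrix(rnorm(60 * 2), 60, 2)
    y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + rnorm(60, 0, 0.1)
    m <- mlp_train(X, y, k_hidden = sample(1:5, 1), seed = i, max_iter = 30)
    expect_true(all(diff(m$mse_trace) <= 0))
    # never worse than the initial model
    expect_lte(tail(m$mse_trace, 1), m$mse_trace[1])
  }
})

test_that("a five-unit net fits sin(3x), on par with an independent trainer", {
  set.seed(8)
  X <- matrix(runif(200, -1, 1), 200, 1)
  y <- sin(3 * X[, 1])
  m <- mlp_train(X, y, k_hidden = 5, seed = 2, max_iter = 200)
  expect_lt(tail(m$mse_trace, 1), 1e-3)
  if (requireNamespace("nnet", quietly = TRUE)) {
    ref <- nnet::nnet(X, y, size = 5, linout = TRUE, maxit = 500, trace = FALSE)
    ref_mse <- mean((y - predict(ref, X))^2)
    # both trainers reach the same regime on this easy target
    expect_lt(tail(m$mse_trace, 1), max(10 * ref_mse, 1e-3))
  }
})

# LS-SVR --------------------------------------------------------------------

test_that("LS-SVR satisfies the KKT system and its algebraic identities", {
  set.seed(33)
  X <- matrix(rnorm(30), 15, 2)
  y <- X[, 1]^2 + rnorm(15, 0, 0.1)
  gamma <- 5; sigma <- 1.5
  m <- lssvr_train(X, y, gamma, sigma)

  # KKT residual: sum(b) = 0 and b0*1 + (K + I/gamma) b = y
  K <- exp(-as.matrix(dist(X))^2 / sigma^2)
  expect_lt(abs(sum(m$b_dual)), 1e-8)
  expect_lt(max(abs(m$b0 + (K + diag(15) / gamma) %*% m$b_dual - y)), 1e-8)

  # training-point identity: yhat_i = y_i - b_i / gamma
  expect_equal(lssvr_predict(m, X), y - m$b_dual / gamma, tolerance = 1e-8)

  # constant target: b = 0, b0 = c
  mc <- lssvr_train(X, rep(3.5, 15), gamma, sigma)
  expect_equal(mc$b_dual, rep(0, 15), tolerance = 1e-10)
  expect_equal(mc$b0, 3.5, tolerance = 1e-10)

  # far from every support point the kernel dies and prediction tends to b0
  far <- matrix(1e4, 1, 2)
  expect_equal(lssvr_predict(m, far), m$b0)
})

test_that("a two-point LS-SVR matches the hand-solved 3x3 system", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(0, 2)
  gamma <- 2; sigma <- 1
  m <- lssvr_train(X, y, gamma, sigma)
  k12 <- exp(-4 / 1)   # ||x1 - x2||^2 = 4
  A <- rbind(c(0, 1, 1),
             c(1, 1 + 1 / gamma, k12),
             c(1, k12, 1 + 1 / gamma))
  sol <- solve(A, c(0, y))
  expect_equal(c(m$b0, m$b_dual), sol, tolerance = 1e-10)
})

test_that("training error is non-increasing in gamma", {
  set.seed(44)
  X <- matrix(rnorm(40), 20, 2)
  y <- sin(X[, 1]) + rnorm(20, 0, 0.2)
  mses <- vapply(10^seq(0, 6), function(g) {
    m <- lssvr_train(X, y, g, 1)
    mean((lssvr_predict(m, X) - y)^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-12))
})

test_that("closed-form LOO residuals equal explicit re-solves", {
  set.seed(55)
  for (i in 1:3) {
    n <- sample(8:15, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- X[, 1] + rnorm(n, 0, 0.3)
    gamma <- 10^runif(1, -1, 2); sigma <- 10^runif(1, -0.5, 0.5)
    closed <- bisguard:::lssvr_loo_residuals(X, y, gamma, sigma)
    resolve <- vapply(seq_len(n), function(j) {
      m <- lssvr_train(X[-j, , drop = FALSE], y[-j], gamma, sigma)
      y[j] - lssvr_predict(m, X[j, , drop = FALSE])
    }, numeric(1))
    expect_equal(closed, resolve, tolerance = 1e-8)
  }
})

test_that("simplex tuning is competitive with a log-grid search", {
  set.seed(66)
  X <- matrix(runif(40, -2, 2), 40, 1)
  y <- sin(X[, 1]) + rnorm(40, 0, 0.05)
  tuned <- lssvr_tune(X, y, seed = 1)
  grid <- expand.grid(lg = seq(-2, 4, length.out = 5),
                      ls2 = seq(-2, 2, length.out = 5))
  grid_best <- min(apply(grid, 1, function(g) {
    mean(bisguard:::lssvr_loo_residuals(X, y, 10^g[1], sqrt(10^g[2]))^2)
  }))
  expect_lte(tuned$loo_mse, 1.05 * grid_best)

  # never worse than its own start (gamma = 1, sigma = 1)
  noise <- rnorm(40)
  t2 <- lssvr_tune(X, noise, seed = 2)
  start_mse <- mean(bisguard:::lssvr_loo_residuals(X, noise, 1, 1)^2)
  expect_lte(t2$loo_mse, start_mse + 1e-12)
})

# polynomial ----------------------------------------------------------------

test_that("polynomial bases have the documented coefficient counts", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_length(poly_train(X, y, 1)$coefficients, 3)
  m2 <- poly_train(X, y, 2)
  expect_length(m2$coefficients, 6)
  expect_setequal(names(m2$coefficients),
                  c("1", "x1", "x2", "x1*x1", "x1*x2", "x2*x2"))
  expect_error(poly_train(X[1:4, ], y[1:4], 2), class = "bisguard_data_error")
})

test_that("a planted degree-2 polynomial in 8 inputs is recovered exactly", {
  set.seed(77)
  d <- 8; n <- 200
  X <- matrix(rnorm(n * d), n, d)
  true_coef <- rnorm(bisguard:::poly_n_coef(d, 2))
  y <- as.numeric(bisguard:::poly_basis(X, 2) %*% true_coef)
  m <- poly_train(X, y, 2)
  expect_length(m$coefficients, 45)
  expect_equal(unname(m$coefficients), true_coef, tolerance = 1e-6)
  expect_lt(mean((poly_predict(m, X) - y)^2), 1e-12)
})

test_that("degree-1 fits of affine data are exact and predict via the basis", {
  set.seed(88)
  X <- matrix(rnorm(60), 20, 3)
  beta <- c(2, -1, 0.5, 3)
  y <- beta[1] + X %*% beta[-1]
  m <- poly_train(X, as.numeric(y), 1)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-10)
  expect_equal(poly_predict(m, X), as.numeric(y), tolerance = 1e-10)

  # constant-only model
  mc <- structure(list(degree = 1L, d = 3L,
                       coefficients = c(7, 0, 0, 0)), class = "poly_model")
  expect_equal(poly_predict(mc, X), rep(7, 20))

  # random model matches the explicit monomial-sum oracle
  m2 <- poly_train(X, rnorm(20), 2)
  oracle <- apply(X, 1, function(x) poly_oracle_one(m2, x))
  expect_equal(poly_predict(m2, X), unname(oracle), tolerance = 1e-12)
})

test_that("each family predicts identically after serialization round-trip", {
  set.seed(99)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] - X[, 2]^2
  models <- list(
    mlp_train(X, y, 2, seed = 1, max_iter = 20),
    lssvr_train(X, y, 10, 1),
    poly_train(X, y, 2)
  )
  for (m in models) {
    l <- bisguard:::local_model_to_list(m)
    json <- jsonlite::fromJSON(
      jsonlite::toJSON(l, auto_unbox = TRUE, digits = I(17)),
      simplifyVector = FALSE)
    back <- bisguard:::local_model_from_list(json)
    expect_equal(bisguard:::predict_local(back, X),
                 bisguard:::predict_local(m, X), tolerance = 1e-15)
  }
})
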