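test_that("cross-validated MSE pools held-out errors and is deterministic", {
  set.seed(1)
  X <- matrix(rnorm(100 * 2), 100, 2)
  y <- rep(4.2, 100)
  cand <- list(family = "POLY", hyper = 1L)
  expect_lt(kfold_mse(cand, X, y, n_folds = 5, seed = 9), 1e-20)

  y2 <- X[, 1] + rnorm(100, 0, 0.5)
  a <- kfold_mse(cand, X, y2, n_folds = 5, seed = 9)
  b <- kfold_mse(cand, X, y2, n_folds = 5, seed = 9)
  expect_identical(a, b)
  expect_error(kfold_mse(cand, X[1:3, ], y2[1:3], n_folds = 5),
               class = "bisguard_data_error")
})

test_that("the weighted MSE is the size-weighted mean of cluster MSEs", {
  expect_equal(combined_mse(c(2, 2, 2), c(10, 5, 100)), 2)
  expect_equal(combined_mse(0.7, 42), 0.7)
  expect_equal(combined_mse(c(1, 3), c(1, 3)), 2.5)
  expect_error(combined_mse(c(1, 2), 3), class = "bisguard_parameter_error")
})

test_that("weighted cluster MSE equals the pooled MSE over all samples", {
  # the identity the aggregation relies on: pooling held-out squared errors
  # directly gives the same number as weighting per-cluster means by size
  set.seed(12)
  sq1 <- rnorm(30)^2; sq2 <- rnorm(70)^2
  pooled <- mean(c(sq1, sq2))
  weighted <- combined_mse(c(mean(sq1), mean(sq2)), c(30, 70))
  expect_equal(weighted, pooled, tolerance = 1e-12)
})

test_that("partition evaluation applies the validity rule and prefers simplicity", {
  set.seed(2)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- 3 + X %*% rnorm(8)
  cfg <- small_config()

  # a 10-sample cluster kills the whole partition
  partition <- rep(c(1L, 2L), c(10, 50))
  expect_null(evaluate_partition_candidates(X, as.numeric(y), partition,
                                            config = cfg))

  # exactly affine cluster: degree-1 polynomial wins with ~zero MSE
  partition <- rep(c(1L, 2L), c(30, 30))
  ev <- evaluate_partition_candidates(X, as.numeric(y), partition, config = cfg)
  expect_equal(ev[[1]]$label, "POLY-01")
  expect_lt(ev[[1]]$mse, 1e-12)

  # equal MSEs: the earlier candidate wins
  dup <- list(list(family = "POLY", hyper = 1L), list(family = "POLY", hyper = 1L))
  ev2 <- evaluate_partition_candidates(X, as.numeric(y), partition,
                                       candidates = dup, config = cfg)
  expect_equal(unname(ev2[[1]]$all_mse[1]), unname(ev2[[1]]$all_mse[2]))
  expect_identical(ev2[[1]]$spec, dup[[1]])
})

test_that("too-few samples invalidate every clustered topology", {
  # n = 20: any K >= 2 split leaves a cluster below 15 samples
  set.seed(3)
  X <- matrix(rnorm(20 * 8), 20, 8)
  colnames(X) <- bisguard:::FEATURE_NAMES
  ds <- structure(list(X = X, y = as.numeric(1 + X %*% rnorm(8)),
                       source_ids = rep("s", 20),
                       source_index = 3:22),
                  class = "regression_dataset")
  cfg <- small_config(k_max = 4L)
  model <- fit_hybrid(ds, cfg)
  pk <- model$report$per_k
  expect_true(pk$valid[pk$k == 1])
  expect_false(any(pk$valid[pk$k >= 2]))
  expect_true(all(is.na(pk$weighted_mse[pk$k >= 2])))
  expect_equal(model$report$chosen_k, 1L)
})

test_that("a single global affine law is recovered by the chosen model", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- bisguard:::FEATURE_NAMES
  beta <- c(50, rnorm(8))
  y <- beta[1] + X %*% beta[-1]
  ds <- structure(list(X = X, y = as.numeric(y), source_ids = rep("s", n),
                       source_index = seq_len(n) + 2L),
                  class = "regression_dataset")
  cfg <- small_config(k_max = 2L, seed = 5L)
  model <- fit_hybrid(ds, cfg)
  pred <- hybrid_predict(model, X)
  target <- pmin(pmax(as.numeric(y), 0), 100)
  expect_lt(mean((pred - target)^2), 1e-10)
  # the chosen topology's weighted MSE is minimal among valid ones
  pk <- model$report$per_k
  chosen <- pk$weighted_mse[pk$k == model$report$chosen_k]
  expect_true(all(chosen <= pk$weighted_mse[pk$valid] + 1e-15))
})

test_that("training is deterministic given the seed", {
  two <- make_two_regime_dataset(40, 40, c(10, rnorm(8)), c(60, rnorm(8)),
                                 separation = 15, seed = 6)
  cfg <- small_config(k_max = 3L, seed = 17L)
  m1 <- fit_hybrid(two$dataset, cfg)
  m2 <- fit_hybrid(two$dataset, cfg)
  expect_identical(m1$report, m2$report)
  xs <- matrix(rnorm(80), 10, 8)
  expect_identical(hybrid_predict(m1, xs), hybrid_predict(m2, xs))
})

test_that("prediction routes through the assigned cluster and clamps to BIS", {
  set.seed(7)
  two <- make_two_regime_dataset(50, 50, c(20, rep(0.5, 8)), c(80, rep(-0.5, 8)),
                                 separation = 15, seed = 8)
  cfg <- small_config(k_max = 2L, seed = 9L)
  model <- fit_hybrid(two$dataset, cfg)
  X <- two$dataset$X
  batch <- hybrid_predict(model, X)
  # per-sample route-then-evaluate oracle
  Z <- standardize(X, model$stats)$X
  oracle <- vapply(seq_len(nrow(X)), function(i) {
    k <- if (is.null(model$kmeans)) 1L else assign_cluster(model$kmeans, Z[i, ])
    p <- bisguard:::predict_local(model$local_models[[k]], Z[i, , drop = FALSE])
    min(max(p, 0), 100)
  }, numeric(1))
  expect_equal(batch, oracle, tolerance = 1e-12)
  expect_true(all(batch >= 0 & batch <= 100))
  expect_error(hybrid_predict(model, matrix(1, 1, 5)),
               class = "bisguard_dimension_error")
})

test_that("models survive a save/load round trip and reject bad files", {
  two <- make_two_regime_dataset(40, 40, c(30, rnorm(8)), c(70, rnorm(8)),
                                 separation = 15, seed = 10)
  cfg <- train_config(k_max = 2L, mlp_hidden_range = 1L, mlp_max_iter = 15L,
                      seed = 11L)  # includes LS-SVR so all families serialize
  model <- fit_hybrid(two$dataset, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  set.seed(12)
  Xnew <- matrix(rnorm(100 * 8), 100, 8)
  expect_equal(hybrid_predict(back, Xnew), hybrid_predict(model, Xnew),
               tolerance = 1e-15)
  expect_equal(back$report$chosen_k, model$report$chosen_k)

  # truncated file: parse error, no partial model
  txt <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 100), trunc)
  expect_error(load_model(trunc), class = "bisguard_parse_error")

  # version mismatch
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version": "bisguard-model-99"}', bad)
  expect_error(load_model(bad), class = "bisguard_version_error")
})
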