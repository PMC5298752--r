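# Independent oracles and small fixture builders used across the suite.

# Exhaustive 2-cluster K-means optimum: enumerate every split of n points into
# two non-empty parts, place each centroid at its part mean, return the
# minimal summed squared distance. Independent of the Lloyd implementation.
brute_force_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {          # point 1 fixed in part A
    members <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- X[!members, , drop = FALSE]
    b <- X[members, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    obj <- sum(sweep(a, 2, colMeans(a))^2) + sum(sweep(b, 2, colMeans(b))^2)
    if (obj < best) best <- obj
  }
  best
}

# Term-by-term evaluation of the MLP output for one input vector.
mlp_oracle_one <- function(model, x) {
  out <- model$beta
  for (i in seq_len(model$k)) {
    out <- out + model$a[i] * tanh(sum(model$W[i, ] * x) + model$b_hidden[i])
  }
  out
}

# Explicit monomial-sum evaluation of a polynomial model for one input vector.
poly_oracle_one <- function(model, x) {
  d <- model$d
  co <- model$coefficients
  out <- co[1] + sum(co[1 + seq_len(d)] * x)
  if (model$degree == 2) {
    idx <- 1 + d
    for (i in seq_len(d)) {
      for (j in i:d) {
        idx <- idx + 1
        out <- out + co[idx] * x[i] * x[j]
      }
    }
  }
  unname(out)
}

# Rand index between two labelings (pair-counting agreement).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree) - n) / (n * (n - 1))
}

# A small valid surgery record with gently varying channels.
make_test_record <- function(n = 20, dt = 5, id = "test") {
  t <- seq(0, by = dt, length.out = n)
  surgery_record(id, t,
                 bis = 50 + 5 * sin(t / 100),
                 emg = 2 + 0.5 * cos(t / 80),
                 propofol_rate = rep(8, n))
}

# A constant steady-state record whose fault-free BIS is exactly `level`:
# serves the "oracle predictor" detector tests together with
# make_constant_oracle_model().
make_constant_record <- function(n = 60, level = 50, dt = 5, id = "flat") {
  t <- seq(0, by = dt, length.out = n)
  surgery_record(id, t,
                 bis = rep(level, n),
                 emg = rep(2, n),
                 propofol_rate = rep(8, n),
                 fault_mask = rep(FALSE, n),
                 bis_true = rep(level, n))
}

# Hand-built hybrid model that predicts exactly `level` for any input --
# an oracle for records whose true BIS is constant. Its config disables the
# low-pass preconditioning so detection sees the record exactly as written.
make_constant_oracle_model <- function(level = 50) {
  coef <- c(level, rep(0, 8))
  names(coef) <- c("1", paste0("x", 1:8))
  pm <- structure(list(degree = 1L, d = 8L, coefficients = coef),
                  class = "poly_model")
  structure(list(
    stats = list(mean = rep(0, 8), sd = rep(1, 8)),
    kmeans = NULL,
    local_models = list(pm),
    report = structure(list(per_k = data.frame(k = 1L, valid = TRUE,
                                               weighted_mse = 0),
                            details = NULL, chosen_k = 1L,
                            winners = list(list(label = "POLY-01",
                                                cv_mse = 0, size = 0L))),
                       class = "selection_report"),
    config = unclass(train_config(lowpass_cutoff_hz = 0)),
    version = "bisguard-model-1"
  ), class = "hybrid_model")
}

# Fast trainer configuration for end-to-end tests (small candidate grid).
small_config <- function(...) {
  train_config(k_max = 3L, mlp_hidden_range = c(1L, 2L), mlp_max_iter = 20L,
               include_lssvr = FALSE, ...)
}
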