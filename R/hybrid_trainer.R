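# The hybrid modeling process:
#   standardize -> for each topology (global model, then K = k_min..k_max
#   clusters): K-means with restart search, the minimum-cluster-size validity
#   rule, per-cluster 5-fold cross-validated selection among the candidate
#   regressors, sample-weighted MSE aggregation -> choose the valid topology
#   with minimal weighted MSE -> retrain each winning candidate on its full
#   cluster.

MODEL_FORMAT_VERSION <- "bisguard-model-1"

# Candidate grid in tie-break order: POLY (by degree), MLP (by hidden count),
# LS-SVR. Earlier/simpler candidates win ties.
candidate_specs <- function(config) {
  specs <- list()
  for (dg in config$poly_degrees) {
    specs[[length(specs) + 1]] <- list(family = "POLY", hyper = dg)
  }
  for (h in config$mlp_hidden_range) {
    specs[[length(specs) + 1]] <- list(family = "MLP", hyper = h)
  }
  if (isTRUE(config$include_lssvr)) {
    specs[[length(specs) + 1]] <- list(family = "LSSVR", hyper = "tuned")
  }
  specs
}

candidate_label <- function(spec) {
  if (spec$family == "LSSVR") "LSSVR" else sprintf("%s-%02d", spec$family, spec$hyper)
}

# Train one candidate; returns NULL when the candidate is infeasible on this
# sample size (e.g. degree-2 polynomial with fewer rows than coefficients).
train_candidate <- function(spec, X, y, seed, config) {
  switch(spec$family,
    POLY = {
      if (nrow(X) < poly_n_coef(ncol(X), spec$hyper)) return(NULL)
      poly_train(X, y, spec$hyper)
    },
    MLP = mlp_train(X, y, spec$hyper, seed = seed,
                    max_iter = config$mlp_max_iter %||% 40L),
    LSSVR = {
      if (nrow(X) < 3) return(NULL)
      tuned <- lssvr_tune(X, y, seed = seed)
      lssvr_train(X, y, tuned$gamma, tuned$sigma)
    },
    stop_bisguard(sprintf("unknown candidate family %s", spec$family),
                  "bisguard_config_error")
  )
}

predict_local <- function(model, X) {
  switch(class(model)[1],
    mlp_model = mlp_predict(model, X),
    lssvr_model = lssvr_predict(model, X),
    poly_model = poly_predict(model, X),
    stop_bisguard("unknown local model class", "bisguard_model_error")
  )
}

#' Cross-validated MSE of one candidate
#'
#' Seeded shuffle into `n_folds` near-equal folds; for each fold the candidate
#' is trained on the remaining folds (stochastic trainers receive fold-derived
#' seeds) and squared errors are recorded on the held-out fold. Returns the
#' pooled mean over all n held-out squared errors — identical to the
#' size-weighted mean of per-fold MSEs. `NA` when the candidate is infeasible
#' on some fold-train set.
#'
#' @param candidate list with `family` ("POLY", "MLP" or "LSSVR") and `hyper`.
#' @param X n x d matrix.
#' @param y length-n targets.
#' @param n_folds fold count; requires `n >= n_folds`.
#' @param seed integer seed.
#' @param config a [train_config()] (controls trainer internals).
#' @return Pooled held-out MSE (scalar), or `NA_real_`.
#' @export
kfold_mse <- function(candidate, X, y, n_folds = 5L, seed = 1L,
                      config = train_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < n_folds) {
    stop_bisguard("fewer samples than folds", "bisguard_data_error")
  }
  perm <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(n_folds), length.out = n)
  sq <- numeric(n)
  for (f in seq_len(n_folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    model <- train_candidate(candidate, X[train, , drop = FALSE], y[train],
                             seed = derive_seed(seed, f), config = config)
    if (is.null(model)) return(NA_real_)
    pred <- predict_local(model, X[test, , drop = FALSE])
    sq[test] <- (y[test] - pred)^2
  }
  mean(sq)
}

#' Sample-weighted MSE across clusters
#'
#' `sum_k n_k * MSE_k / sum_k n_k` — the per-cluster errors weighted by
#' cluster size, so the aggregate is comparable across cluster counts.
#'
#' @param cluster_mses per-cluster MSE values.
#' @param cluster_sizes per-cluster sample counts (> 0).
#' @return The weighted MSE.
#' @examples
#' combined_mse(c(8.15e-4, 0.4129), c(0.008, 0.992))
#' @export
combined_mse <- function(cluster_mses, cluster_sizes) {
  if (length(cluster_mses) != length(cluster_sizes)) {
    stop_bisguard("cluster_mses and cluster_sizes must have equal length",
                  "bisguard_parameter_error")
  }
  if (any(cluster_sizes <= 0)) {
    stop_bisguard("cluster sizes must be positive", "bisguard_parameter_error")
  }
  sum(cluster_sizes * cluster_mses) / sum(cluster_sizes)
}

#' Select the best candidate per cluster of a partition
#'
#' Applies the validity rule first: if any cluster holds fewer than
#' `config$min_cluster_size` samples the whole partition is not applicable
#' and `NULL` is returned. Otherwise each cluster gets the candidate with
#' minimal [kfold_mse()]; ties go to the earlier candidate in the order
#' POLY < MLP < LSSVR, smaller hyperparameter first.
#'
#' @param X n x d matrix; @param y targets.
#' @param partition integer cluster index per row (1..C).
#' @param candidates list of candidate specs (default: the config's grid).
#' @param config a [train_config()].
#' @param seed integer seed for the fold draws.
#' @param enforce_min_size apply the minimum-cluster-size rule (the global
#'   single-cluster topology is exempt).
#' @return `NULL` (not applicable), or a list per cluster with `spec`, `mse`,
#'   `size`, and `all_mse` (the full candidate grid for inspection).
#' @export
evaluate_partition_candidates <- function(X, y, partition,
                                          candidates = NULL,
                                          config = train_config(),
                                          seed = 1L,
                                          enforce_min_size = TRUE) {
  if (length(partition) != nrow(X)) {
    stop_bisguard("partition must cover all rows", "bisguard_parameter_error")
  }
  if (is.null(candidates)) candidates <- candidate_specs(config)
  C <- max(partition)
  sizes <- tabulate(partition, nbins = C)
  if (enforce_min_size && !validate_partition(sizes, config$min_cluster_size)) {
    return(NULL)
  }
  if (any(sizes < config$n_folds)) return(NULL)
  lapply(seq_len(C), function(k) {
    rows <- which(partition == k)
    Xk <- X[rows, , drop = FALSE]; yk <- y[rows]
    mses <- vapply(seq_along(candidates), function(ci) {
      kfold_mse(candidates[[ci]], Xk, yk, n_folds = config$n_folds,
                seed = derive_seed(seed, k, ci), config = config)
    }, numeric(1))
    names(mses) <- vapply(candidates, candidate_label, character(1))
    feasible <- which(!is.na(mses))
    if (length(feasible) == 0) {
      stop_bisguard("no feasible candidate for a cluster", "bisguard_data_error")
    }
    best <- feasible[which.min(mses[feasible])]  # which.min keeps first on ties
    list(spec = candidates[[best]], label = candidate_label(candidates[[best]]),
         mse = mses[[best]], size = length(rows), all_mse = mses)
  })
}

#' Fit the hybrid local-model predictor
#'
#' Runs the full modeling process on lag-embedded surgery data: feature
#' standardization; the global (single-model) topology plus K-means partitions
#' for `K = k_min..k_max` (each with `n_restarts` restarts); the
#' minimum-cluster-size validity rule; per-cluster candidate selection by
#' cross-validated MSE; sample-weighted aggregation; selection of the valid
#' topology with minimal weighted MSE; and a final retraining of each winning
#' candidate on all of its cluster's data.
#'
#' @param data a `regression_dataset` (from [build_regression_dataset()]), a
#'   `surgery_record`, or a list of records (records are trimmed/filtered per
#'   the config before embedding).
#' @param config a [train_config()].
#' @return A `hybrid_model`: `stats` (standardization), `kmeans` (`NULL` for
#'   the global topology), `local_models`, `report` (the selection report),
#'   `config`, `version`.
#' @export
fit_hybrid <- function(data, config = train_config()) {
  if (inherits(data, "surgery_record")) data <- list(data)
  if (is.list(data) && !inherits(data, "regression_dataset") &&
      all(vapply(data, inherits, logical(1), "surgery_record"))) {
    data <- build_regression_dataset(lapply(data, preprocess_record, config = config))
  }
  stopifnot(inherits(data, "regression_dataset"))
  X_raw <- data$X
  y <- data$y
  n <- nrow(X_raw)
  if (n < config$n_folds) {
    stop_bisguard("not enough samples to cross-validate", "bisguard_data_error")
  }
  if (isTRUE(config$standardize)) {
    std <- standardize(X_raw)
  } else {
    std <- list(X = X_raw,
                stats = list(mean = rep(0, ncol(X_raw)), sd = rep(1, ncol(X_raw))))
  }
  Z <- std$X
  candidates <- candidate_specs(config)
  seed <- config$seed

  topologies <- list()
  # global model: one cluster holding everything, exempt from the size rule
  topologies[["1"]] <- list(k = 1L, kmeans = NULL, partition = rep(1L, n))
  ks <- seq(config$k_min, config$k_max)
  ks <- ks[ks >= 2 & ks <= n]
  for (K in ks) {
    km <- kmeans_fit(Z, K, n_restarts = config$n_restarts,
                     seed = derive_seed(seed, 1000L, K))
    topologies[[as.character(K)]] <- list(k = K, kmeans = km, partition = km$assign)
  }

  per_k <- data.frame(k = integer(0), valid = logical(0), weighted_mse = numeric(0))
  details <- list()
  for (tp in topologies) {
    ev <- evaluate_partition_candidates(
      Z, y, tp$partition, candidates = candidates, config = config,
      seed = derive_seed(seed, 2000L, tp$k),
      enforce_min_size = tp$k > 1L
    )
    valid <- !is.null(ev)
    wmse <- if (valid) {
      combined_mse(vapply(ev, `[[`, numeric(1), "mse"),
                   vapply(ev, `[[`, numeric(1), "size"))
    } else NA_real_
    per_k <- rbind(per_k, data.frame(k = tp$k, valid = valid, weighted_mse = wmse))
    details[[as.character(tp$k)]] <- ev
  }
  if (!any(per_k$valid)) {
    stop_bisguard("no valid topology (data error)", "bisguard_data_error")
  }
  valid_rows <- per_k[per_k$valid, ]
  # minimal weighted MSE wins; differences below 1e-12 (numerical dust on the
  # BIS^2 scale) are ties, resolved toward fewer clusters
  best_mse <- min(valid_rows$weighted_mse)
  chosen_k <- min(valid_rows$k[valid_rows$weighted_mse <= best_mse + 1e-12])
  chosen <- topologies[[as.character(chosen_k)]]
  chosen_ev <- details[[as.character(chosen_k)]]

  # final retraining on all data in each cluster
  local_models <- lapply(seq_along(chosen_ev), function(k) {
    rows <- which(chosen$partition == k)
    train_candidate(chosen_ev[[k]]$spec, Z[rows, , drop = FALSE], y[rows],
                    seed = derive_seed(seed, 3000L, chosen_k, k), config = config)
  })

  report <- structure(list(
    per_k = per_k,
    details = details,
    chosen_k = chosen_k,
    winners = lapply(chosen_ev, function(e)
      list(label = e$label, cv_mse = e$mse, size = e$size))
  ), class = "selection_report")

  structure(list(
    stats = std$stats,
    kmeans = if (chosen_k > 1L) chosen$kmeans else NULL,
    local_models = local_models,
    report = report,
    config = unclass(config),
    version = MODEL_FORMAT_VERSION
  ), class = "hybrid_model")
}

preprocess_record <- function(record, config) {
  rec <- record
  if ((config$trim_head_s %||% 0) > 0 || (config$trim_tail_s %||% 0) > 0) {
    rec <- trim_phases(rec, config$trim_head_s, config$trim_tail_s)
  }
  cutoff <- config$lowpass_cutoff_hz %||% 0
  if (cutoff > 0 && cutoff < 1 / (2 * rec$dt_s)) {
    order <- config$lowpass_order %||% 2L
    bis_f <- pmin(pmax(lowpass_filter(rec$bis, rec$dt_s, cutoff, order), 0), 100)
    emg_f <- pmax(lowpass_filter(rec$emg, rec$dt_s, cutoff, order), 0)
    rec <- surgery_record(rec$record_id, rec$time_s, bis_f, emg_f,
                          rec$propofol_rate, rec$fault_mask, rec$bis_true)
  }
  rec
}

#' @export
print.hybrid_model <- function(x, ...) {
  k <- x$report$chosen_k
  cat(sprintf("Hybrid BIS model (format %s)\n", x$version))
  cat(sprintf("  chosen topology: %s (weighted CV MSE %.6g)\n",
              if (k == 1) "global model" else sprintf("%d clusters", k),
              x$report$per_k$weighted_mse[x$report$per_k$k == k]))
  for (i in seq_along(x$report$winners)) {
    w <- x$report$winners[[i]]
    cat(sprintf("  cluster %d: %s, %d samples, CV MSE %.6g\n",
                i, w$label, w$size, w$cv_mse))
  }
  invisible(x)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Topology comparison (weighted CV MSE; N/A = undersized cluster):\n")
  for (i in seq_len(nrow(x$per_k))) {
    row <- x$per_k[i, ]
    lab <- if (row$k == 1) "global" else sprintf("K = %2d", row$k)
    cat(sprintf("  %-8s %s\n", lab,
                if (row$valid) sprintf("%.6g", row$weighted_mse) else "N/A"))
  }
  cat(sprintf("chosen: %s\n",
              if (x$chosen_k == 1) "global model" else sprintf("K = %d", x$chosen_k)))
  invisible(x)
}

#' Predict BIS with a hybrid model
#'
#' Takes raw (unstandardized) 8-input feature vectors, standardizes them with
#' the model's stored training stats, routes each to its cluster by nearest
#' centroid, evaluates that cluster's local model, and clamps the result to
#' the BIS scale `[0, 100]`.
#'
#' @param model a `hybrid_model`.
#' @param x an 8-vector or m x 8 matrix in raw units.
#' @return Predicted BIS (length-m vector).
#' @export
hybrid_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$stats$mean)) {
    stop_bisguard("feature dimension does not match the model",
                  "bisguard_dimension_error")
  }
  Z <- standardize(x, model$stats)$X
  if (is.null(model$kmeans)) {
    pred <- predict_local(model$local_models[[1]], Z)
  } else {
    idx <- assign_cluster(model$kmeans, Z)
    pred <- numeric(nrow(Z))
    for (k in unique(idx)) {
      rows <- which(idx == k)
      pred[rows] <- predict_local(model$local_models[[k]], Z[rows, , drop = FALSE])
    }
  }
  pmin(pmax(pred, 0), 100)
}

# ---- serialization --------------------------------------------------------

local_model_to_list <- function(m) {
  switch(class(m)[1],
    mlp_model = list(family = "MLP", W = m$W, b_hidden = m$b_hidden, a = m$a,
                     beta = m$beta, k = m$k, d = m$d),
    lssvr_model = list(family = "LSSVR", X_train = m$X_train, b_dual = m$b_dual,
                       b0 = m$b0, gamma = m$gamma, sigma = m$sigma),
    poly_model = list(family = "POLY", degree = m$degree, d = m$d,
                      coefficients = unname(m$coefficients),
                      terms = names(m$coefficients))
  )
}

local_model_from_list <- function(l) {
  switch(l$family,
    MLP = structure(list(W = do.call(rbind, lapply(l$W, unlist)),
                         b_hidden = as.numeric(l$b_hidden),
                         a = as.numeric(l$a), beta = as.numeric(l$beta),
                         k = as.integer(l$k), d = as.integer(l$d),
                         mse_trace = NULL),
                    class = "mlp_model"),
    LSSVR = structure(list(X_train = do.call(rbind, lapply(l$X_train, unlist)),
                           b_dual = as.numeric(l$b_dual),
                           b0 = as.numeric(l$b0),
                           gamma = as.numeric(l$gamma),
                           sigma = as.numeric(l$sigma)),
                      class = "lssvr_model"),
    POLY = {
      coef <- as.numeric(l$coefficients)
      names(coef) <- unlist(l$terms)
      structure(list(degree = as.integer(l$degree), d = as.integer(l$d),
                     coefficients = coef),
                class = "poly_model")
    },
    stop_bisguard("unknown local model family in file", "bisguard_model_error")
  )
}

#' Save a hybrid model to a versioned JSON file
#'
#' @param model a `hybrid_model`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_model"))
  payload <- list(
    version = model$version,
    stats = model$stats,
    kmeans = if (!is.null(model$kmeans)) {
      list(C = model$kmeans$C, centroids = model$kmeans$centroids,
           objective_e = model$kmeans$objective_e, sizes = model$kmeans$sizes,
           seed = model$kmeans$seed, restart = model$kmeans$restart)
    },
    local_models = lapply(model$local_models, local_model_to_list),
    report = list(
      per_k = model$report$per_k,
      chosen_k = model$report$chosen_k,
      winners = model$report$winners
    ),
    config = model$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Load a hybrid model from JSON
#'
#' Fails with an explicit error on an unknown format version or a truncated
#' file; never returns a partial model.
#'
#' @param path path to a file written by [save_model()].
#' @return A `hybrid_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop_bisguard(sprintf("model file not found: %s", path), "bisguard_io_error")
  }
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
    stop_bisguard(sprintf("cannot parse model file: %s", conditionMessage(e)),
                  "bisguard_parse_error")
  })
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop_bisguard(sprintf("unsupported model format version '%s' (expected '%s')",
                          payload$version %||% "<missing>", MODEL_FORMAT_VERSION),
                  "bisguard_version_error")
  }
  stats <- list(mean = as.numeric(unlist(payload$stats$mean)),
                sd = as.numeric(unlist(payload$stats$sd)))
  kmeans <- NULL
  if (!is.null(payload$kmeans)) {
    C <- as.integer(payload$kmeans$C)
    kmeans <- structure(list(
      C = C,
      centroids = do.call(rbind, lapply(payload$kmeans$centroids, unlist)),
      objective_e = as.numeric(payload$kmeans$objective_e),
      sizes = as.integer(unlist(payload$kmeans$sizes)),
      assign = NULL,
      seed = as.integer(payload$kmeans$seed),
      restart = as.integer(payload$kmeans$restart)
    ), class = "kmeans_model")
  }
  per_k <- do.call(rbind, lapply(payload$report$per_k, function(r)
    data.frame(k = as.integer(r$k), valid = as.logical(r$valid),
               weighted_mse = if (is.null(r$weighted_mse)) NA_real_
                              else as.numeric(r$weighted_mse))))
  report <- structure(list(
    per_k = per_k,
    details = NULL,
    chosen_k = as.integer(payload$report$chosen_k),
    winners = lapply(payload$report$winners, function(w)
      list(label = w$label, cv_mse = as.numeric(w$cv_mse),
           size = as.integer(w$size)))
  ), class = "selection_report")
  structure(list(
    stats = stats,
    kmeans = kmeans,
    local_models = lapply(payload$local_models, local_model_from_list),
    report = report,
    config = payload$config,
    version = payload$version
  ), class = "hybrid_model")
}
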