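# K-means partitioning of the 8-dimensional regression inputs.
#
# Lloyd's algorithm with Forgy initialization (random distinct points),
# restart search keeping the run with the smallest squared-error objective
#   e = sum_k sum_{x in Q_k} ||x - c_k||^2,
# deterministic tie-breaking (nearest centroid, lowest index on ties), and
# farthest-point re-seeding when a cluster empties during iteration. These
# details are fixed here, rather than delegated, because inference-time
# routing of a sample to its local model reuses exactly this assignment rule.

#' K-means squared-error objective
#'
#' Assigns each row of `X` to its nearest centroid (squared Euclidean) and
#' returns the summed squared distances.
#'
#' @param X n x d matrix.
#' @param centroids C x d matrix.
#' @return The objective value (a scalar).
#' @export
kmeans_objective <- function(X, centroids) {
  X <- as.matrix(X)
  centroids <- matrix(as.numeric(centroids), ncol = ncol(X))
  d2 <- point_centroid_dist2(X, centroids)
  sum(apply(d2, 1, min))
}

# squared Euclidean distances, n x C
point_centroid_dist2 <- function(X, centroids) {
  xx <- rowSums(X^2)
  cc <- rowSums(centroids^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(centroids)
  pmax(d2, 0)
}

# nearest-centroid assignment; ties go to the lowest index (max.col with
# ties.method = "first" on the negated distances)
nearest_centroid <- function(X, centroids) {
  d2 <- point_centroid_dist2(as.matrix(X), centroids)
  max.col(-d2, ties.method = "first")
}

lloyd_once <- function(X, C, max_iter = 300L) {
  n <- nrow(X)
  init <- sample.int(n, C)
  centroids <- X[init, , drop = FALSE]
  assign_prev <- rep(0L, n)
  obj_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    assign <- nearest_centroid(X, centroids)
    # re-seed empty clusters at the point farthest from its centroid
    repeat {
      sizes <- tabulate(assign, nbins = C)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      d2 <- point_centroid_dist2(X, centroids)
      cur <- d2[cbind(seq_len(n), assign)]
      far <- which.max(cur)
      centroids[empty[1], ] <- X[far, ]
      assign <- nearest_centroid(X, centroids)
    }
    obj_trace <- c(obj_trace, kmeans_objective(X, centroids))
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (k in seq_len(C)) {
      centroids[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    }
  }
  ref <- hartigan_refine(X, centroids, assign)
  list(centroids = ref$centroids, assign = ref$assign,
       objective = kmeans_objective(X, ref$centroids),
       trace = c(obj_trace, ref$objective))
}

# Single-point improvement pass (Hartigan-style): Lloyd fixed points are not
# always local optima of the objective; moving one point x from cluster i
# (size ni) to j (size nj) changes e by
#   delta = nj/(nj+1) * ||x - c_j||^2 - ni/(ni-1) * ||x - c_i||^2.
# Apply strictly improving moves until none remains.
hartigan_refine <- function(X, centroids, assign, max_pass = 50L) {
  n <- nrow(X); C <- nrow(centroids)
  sizes <- tabulate(assign, nbins = C)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (p in seq_len(n)) {
      i <- assign[p]
      if (sizes[i] <= 1L) next
      d2 <- colSums((t(centroids) - X[p, ])^2)
      gain_out <- sizes[i] / (sizes[i] - 1) * d2[i]
      cost_in <- sizes / (sizes + 1) * d2
      cost_in[i] <- Inf
      j <- which.min(cost_in)
      if (cost_in[j] < gain_out - 1e-12) {
        centroids[i, ] <- (sizes[i] * centroids[i, ] - X[p, ]) / (sizes[i] - 1)
        centroids[j, ] <- (sizes[j] * centroids[j, ] + X[p, ]) / (sizes[j] + 1)
        sizes[i] <- sizes[i] - 1L
        sizes[j] <- sizes[j] + 1L
        assign[p] <- j
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # settle back to a Lloyd fixed point (centroids = means, assignments stable)
  repeat {
    for (k in seq_len(C)) {
      if (any(assign == k)) centroids[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    }
    new_assign <- nearest_centroid(X, centroids)
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  list(centroids = centroids, assign = assign,
       objective = kmeans_objective(X, centroids))
}

#' Fit K-means with restart search
#'
#' Runs Lloyd iterations from `n_restarts` random (Forgy) initializations and
#' keeps the run minimizing the squared-error objective. Deterministic given
#' `seed`. Convergence is assignment stability (or 300 iterations).
#'
#' @param X n x d matrix (standardized features in the hybrid pipeline).
#' @param C number of clusters; must satisfy `C <= n`.
#' @param n_restarts number of random initializations (default 20).
#' @param seed integer seed.
#' @return A `kmeans_model`: list with `C`, `centroids` (C x d), `objective_e`,
#'   `sizes`, `assign` (training assignments), `seed`, and `restart` (index of
#'   the winning restart).
#' @export
kmeans_fit <- function(X, C, n_restarts = 20L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (C > n) {
    stop_bisguard("more clusters than samples", "bisguard_data_error")
  }
  if (n_restarts < 1L) {
    stop_bisguard("n_restarts must be >= 1", "bisguard_parameter_error")
  }
  best <- NULL
  best_r <- NA_integer_
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- lloyd_once(X, C)
      if (is.null(best) || run$objective < best$objective) {
        best <- run
        best_r <- r
      }
    }
  })
  structure(list(
    C = as.integer(C),
    centroids = best$centroids,
    objective_e = best$objective,
    sizes = tabulate(best$assign, nbins = C),
    assign = best$assign,
    seed = as.integer(seed),
    restart = best_r
  ), class = "kmeans_model")
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("K-means model: C = %d, objective e = %.6g, sizes = [%s]\n",
              x$C, x$objective_e, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Route samples to their cluster
#'
#' Nearest-centroid assignment with the same squared-Euclidean metric and
#' lowest-index tie rule as training; this is the inference-time routing from
#' a feature vector to its local model.
#'
#' @param model a `kmeans_model`.
#' @param x a d-vector or m x d matrix.
#' @return Integer cluster index (or vector of them), 1-based.
#' @export
assign_cluster <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$centroids)) {
    stop_bisguard("feature dimension does not match the fitted centroids",
                  "bisguard_dimension_error")
  }
  nearest_centroid(x, model$centroids)
}

#' Cluster-size validity rule
#'
#' A partition is usable for per-cluster cross-validated model selection only
#' if every cluster holds at least `min_cluster_size` samples; otherwise the
#' whole cluster count is marked not applicable.
#'
#' @param sizes per-cluster sample counts.
#' @param min_cluster_size minimum samples per cluster (default 15).
#' @return `TRUE` iff every cluster has at least `min_cluster_size` samples.
#' @export
validate_partition <- function(sizes, min_cluster_size = 15L) {
  if (any(sizes < 0)) {
    stop_bisguard("cluster sizes must be non-negative", "bisguard_parameter_error")
  }
  all(sizes >= min_cluster_size)
}
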