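# The three local regression families fitted per cluster:
#   * MLP: one tan-sigmoid hidden layer, linear output, trained by
#     Levenberg-Marquardt on squared error,
#   * LS-SVR: least-squares support vector regression with an RBF kernel,
#     solved as a single linear KKT system,
#   * polynomial regression of degree 1 or 2 over the full monomial basis.
# Each model is a plain parameter container; predict is an exact function of
# the stored parameters.

#' Tan-sigmoid activation
#'
#' The hidden-layer activation `(e^t - e^{-t}) / (e^t + e^{-t})`, evaluated
#' through `tanh()` so it saturates cleanly (no overflow) for large `|t|`.
#'
#' @param t numeric vector.
#' @return `tanh(t)`.
#' @export
tanh_activation <- function(t) tanh(t)

# ---- MLP ------------------------------------------------------------------

mlp_forward <- function(W, b_hidden, a, beta, X) {
  H <- tanh(X %*% t(W) + matrix(b_hidden, nrow(X), length(b_hidden), byrow = TRUE))
  as.numeric(H %*% a + beta)
}

# Jacobian of the network output w.r.t. the flat parameter vector
# [vec(W) row-wise, b_hidden, a, beta]; n x (k*(d+2)+1)
mlp_jacobian <- function(W, b_hidden, a, X) {
  n <- nrow(X); k <- length(a); d <- ncol(X)
  Z <- X %*% t(W) + matrix(b_hidden, n, k, byrow = TRUE)
  H <- tanh(Z)
  S <- (1 - H^2) * matrix(a, n, k, byrow = TRUE)  # d f / d z_i
  J <- matrix(0, n, k * (d + 2) + 1)
  for (i in seq_len(k)) {
    J[, (i - 1) * d + seq_len(d)] <- S[, i] * X   # d f / d w_ij
  }
  J[, k * d + seq_len(k)] <- S                    # d f / d b_i
  J[, k * (d + 1) + seq_len(k)] <- H              # d f / d a_i
  J[, k * (d + 2) + 1] <- 1                       # d f / d beta
  J
}

mlp_unpack <- function(theta, k, d) {
  list(W = matrix(theta[seq_len(k * d)], k, d, byrow = TRUE),
       b_hidden = theta[k * d + seq_len(k)],
       a = theta[k * (d + 1) + seq_len(k)],
       beta = theta[k * (d + 2) + 1])
}

#' Train a single-hidden-layer MLP by Levenberg-Marquardt
#'
#' Fits `f(x) = beta + sum_i a_i * tanh(w_i' x + b_i)` to squared error.
#' Each LM step solves `(J'J + mu I) delta = J' r`; `mu` is divided by 10 on
#' an accepted step (error decreased) and multiplied by 10 on a rejected one,
#' so the recorded MSE sequence over accepted steps is non-increasing. Weight
#' initialization is uniform in `[-0.5, 0.5]` scaled by fan-in, seeded, with
#' the output offset started at `mean(y)`.
#'
#' @param X n x d input matrix.
#' @param y length-n target vector.
#' @param k_hidden hidden-unit count (>= 1).
#' @param seed integer seed for the weight initialization.
#' @param max_iter maximum accepted LM iterations (default 100).
#' @return An `mlp_model`: `W` (k x d), `b_hidden`, `a`, `beta`, `k`, `d`,
#'   plus `mse_trace` (training MSE at initialization and after each accepted
#'   step).
#' @export
mlp_train <- function(X, y, k_hidden, seed = 1L, max_iter = 100L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (k_hidden < 1) {
    stop_bisguard("k_hidden must be >= 1", "bisguard_parameter_error")
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_bisguard("non-finite values in training data", "bisguard_data_error")
  }
  if (nrow(X) < 2) {
    stop_bisguard("need at least 2 training samples", "bisguard_data_error")
  }
  n <- nrow(X); d <- ncol(X); k <- as.integer(k_hidden)
  npar <- k * (d + 2) + 1
  theta <- with_seed(seed, {
    th <- stats::runif(npar, -0.5, 0.5)
    th[seq_len(k * d)] <- th[seq_len(k * d)] / sqrt(d)  # fan-in scaling
    th[npar] <- mean(y)
    th
  })
  p <- mlp_unpack(theta, k, d)
  r <- y - mlp_forward(p$W, p$b_hidden, p$a, p$beta, X)
  mse <- mean(r^2)
  mse_trace <- mse
  mu <- 1e-2
  for (iter in seq_len(max_iter)) {
    J <- mlp_jacobian(p$W, p$b_hidden, p$a, X)
    g <- crossprod(J, r)
    if (sqrt(sum(g^2)) < 1e-12 * n) break
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (mu <= 1e12) {
      delta <- tryCatch(solve(JtJ + mu * diag(npar), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + as.numeric(delta)
        pn <- mlp_unpack(theta_new, k, d)
        r_new <- y - mlp_forward(pn$W, pn$b_hidden, pn$a, pn$beta, X)
        mse_new <- mean(r_new^2)
        if (is.finite(mse_new) && mse_new < mse) {
          theta <- theta_new; p <- pn; r <- r_new; mse <- mse_new
          mse_trace <- c(mse_trace, mse)
          mu <- mu / 10
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!accepted) break            # damping exhausted: local minimum
    if (mse < 1e-24) break
  }
  structure(list(W = p$W, b_hidden = as.numeric(p$b_hidden),
                 a = as.numeric(p$a), beta = as.numeric(p$beta),
                 k = k, d = d, mse_trace = mse_trace),
            class = "mlp_model")
}

#' Evaluate an MLP
#'
#' @param model an `mlp_model`.
#' @param X m x d matrix (or a d-vector).
#' @return Length-m prediction vector.
#' @export
mlp_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop_bisguard("input dimension does not match the model",
                  "bisguard_dimension_error")
  }
  mlp_forward(model$W, model$b_hidden, model$a, model$beta, X)
}

# ---- LS-SVR ---------------------------------------------------------------

rbf_kernel <- function(A, B, sigma2) {
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  d2 <- pmax(outer(aa, bb, "+") - 2 * A %*% t(B), 0)
  exp(-d2 / sigma2)
}

#' Train an LS-SVR model
#'
#' Least-squares support vector regression with the RBF kernel
#' `K(x, x') = exp(-||x - x'||^2 / sigma^2)`. The dual solution comes from
#' one linear KKT system
#' \deqn{\begin{pmatrix} 0 & 1^T \\ 1 & K + \gamma^{-1} I \end{pmatrix}
#'       \begin{pmatrix} b_0 \\ b \end{pmatrix} =
#'       \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' so `sum(b) = 0` and the fitted value at training point i is
#' `y_i - b_i / gamma`.
#'
#' @param X n x d training inputs (stored in the model as support inputs).
#' @param y length-n targets.
#' @param gamma regularization weight (> 0); larger means less smoothing.
#' @param sigma RBF kernel width (> 0); the kernel uses `sigma^2`.
#' @return An `lssvr_model`: `X_train`, `b_dual`, `b0`, `gamma`, `sigma`.
#' @export
lssvr_train <- function(X, y, gamma, sigma) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2) stop_bisguard("need at least 2 samples", "bisguard_data_error")
  if (gamma <= 0 || sigma <= 0) {
    stop_bisguard("gamma and sigma must be positive", "bisguard_parameter_error")
  }
  K <- rbf_kernel(X, X, sigma^2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop_bisguard(sprintf(
      "singular KKT system (reciprocal condition ~ %.3g); adjust gamma/sigma",
      rcond(A)), "bisguard_numeric_error")
  })
  structure(list(X_train = X, b_dual = sol[-1], b0 = sol[1],
                 gamma = gamma, sigma = sigma),
            class = "lssvr_model")
}

#' Evaluate an LS-SVR model
#'
#' Dual-form expansion `yhat(x) = sum_i b_i K(x, x_i) + b0` over the stored
#' support inputs.
#'
#' @param model an `lssvr_model`.
#' @param X m x d matrix (or a d-vector).
#' @return Length-m prediction vector.
#' @export
lssvr_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$X_train)) {
    stop_bisguard("input dimension does not match the model",
                  "bisguard_dimension_error")
  }
  Kx <- rbf_kernel(X, model$X_train, model$sigma^2)
  as.numeric(Kx %*% model$b_dual + model$b0)
}

# Exact leave-one-out residuals from one factorization of the KKT matrix:
# e_i = b_i / (A^-1)_{i+1, i+1}  (dual coefficient over the matching diagonal
# entry of the inverse KKT matrix).
lssvr_loo_residuals <- function(X, y, gamma, sigma) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, sigma^2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  sol <- Ainv %*% c(0, y)
  b <- sol[-1]
  b / diag(Ainv)[-1]
}

#' Tune LS-SVR hyperparameters by simplex search on leave-one-out MSE
#'
#' Nelder-Mead over `(log10 gamma, log10 sigma^2)`, bounded to
#' `[-6, 6] x [-4, 4]`, minimizing the exact leave-one-out MSE computed in
#' closed form from one KKT factorization per candidate point. The search
#' starts at `gamma = 1, sigma = 1`, so the tuned objective never exceeds the
#' objective there. For fold-train sets larger than `n_max` the search runs on
#' a seeded subsample (the final model is still solved on the full set by the
#' caller).
#'
#' @param X n x d training inputs.
#' @param y length-n targets.
#' @param seed integer seed (used only for the subsample draw).
#' @param n_max tuning-subsample cap (default 150).
#' @param maxit Nelder-Mead evaluation budget (default 60).
#' @return List with `gamma`, `sigma`, and `loo_mse` at the optimum.
#' @export
lssvr_tune <- function(X, y, seed = 1L, n_max = 150L, maxit = 60L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop_bisguard("need at least 3 samples to tune", "bisguard_data_error")
  if (n > n_max) {
    idx <- with_seed(seed, sort(sample.int(n, n_max)))
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  objective <- function(par) {
    lg <- par[1]; ls2 <- par[2]
    if (lg < -6 || lg > 6 || ls2 < -4 || ls2 > 4) {
      return(1e10 * (1 + sum(pmax(abs(par) - c(6, 4), 0))))
    }
    e <- lssvr_loo_residuals(X, y, 10^lg, sqrt(10^ls2))
    if (is.null(e) || !all(is.finite(e))) return(1e10)
    mean(e^2)
  }
  fit <- stats::optim(c(0, 0), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, warn.1d.NelderMead = FALSE))
  best <- fit$par
  # keep the start if the polytope somehow ended worse (degenerate data)
  if (fit$value > objective(c(0, 0))) best <- c(0, 0)
  list(gamma = 10^best[1], sigma = sqrt(10^best[2]),
       loo_mse = min(fit$value, objective(c(0, 0))))
}

# ---- polynomial -----------------------------------------------------------

# Monomial basis, fixed term order:
# degree 1: 1, x_1, ..., x_d
# degree 2: adds x_i * x_j for i = 1..d, j = i..d (squares and cross terms)
poly_basis <- function(X, degree) {
  X <- as.matrix(X)
  d <- ncol(X)
  B <- cbind(1, X)
  names_b <- c("1", paste0("x", seq_len(d)))
  if (degree == 2) {
    for (i in seq_len(d)) {
      for (j in i:d) {
        B <- cbind(B, X[, i] * X[, j])
        names_b <- c(names_b, paste0("x", i, "*x", j))
      }
    }
  }
  colnames(B) <- names_b
  B
}

poly_n_coef <- function(d, degree) {
  if (degree == 1) 1 + d else 1 + d + d * (d + 1) / 2
}

#' Fit a polynomial regression of degree 1 or 2
#'
#' Ordinary least squares over the full monomial basis: the constant and all
#' linear terms at degree 1; plus every square and pairwise cross term at
#' degree 2 (for d inputs, `1 + d + d(d+1)/2` coefficients). Solved through
#' the SVD, giving the minimal-norm solution on rank deficiency.
#'
#' @param X n x d input matrix.
#' @param y length-n targets; `n` must be at least the coefficient count.
#' @param degree 1 or 2.
#' @return A `poly_model`: `degree`, `d`, `coefficients` (named by term).
#' @export
poly_train <- function(X, y, degree) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!degree %in% 1:2) {
    stop_bisguard("degree must be 1 or 2", "bisguard_parameter_error")
  }
  p <- poly_n_coef(ncol(X), degree)
  if (nrow(X) < p) {
    stop_bisguard(sprintf("need n >= %d samples for degree %d in %d inputs",
                          p, degree, ncol(X)), "bisguard_data_error")
  }
  B <- poly_basis(X, degree)
  sv <- svd(B)
  tol <- max(dim(B)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  coef <- as.numeric(coef)
  names(coef) <- colnames(B)
  structure(list(degree = as.integer(degree), d = ncol(X), coefficients = coef),
            class = "poly_model")
}

#' Evaluate a polynomial model
#'
#' @param model a `poly_model`.
#' @param X m x d matrix (or a d-vector).
#' @return Length-m prediction vector.
#' @export
poly_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop_bisguard("input dimension does not match the model",
                  "bisguard_dimension_error")
  }
  as.numeric(poly_basis(X, model$degree) %*% model$coefficients)
}
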