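# Preprocessing: low-pass filtering, maintenance-phase trimming, lag embedding
# into the 8-input regression form, and feature standardization.
#
# The regression form is one-step-ahead: the current BIS is predicted from the
# current and two previous EMG values, the current and two previous propofol
# rates, and the two previous BIS values. Fixed column order:
#   [EMG(t), EMG(t-1), EMG(t-2), U(t), U(t-1), U(t-2), BIS(t-1), BIS(t-2)]
# where U is the propofol infusion rate.

FEATURE_NAMES <- c("emg_t", "emg_t1", "emg_t2",
                   "u_t", "u_t1", "u_t2",
                   "bis_t1", "bis_t2")

#' Zero-phase low-pass filter
#'
#' Removes measurement noise superposed on the slowly varying anesthesia
#' signals. A Butterworth low-pass of the given order is applied forward and
#' backward (`signal::filtfilt`), so the output has zero phase shift and unit
#' DC gain.
#'
#' @param values numeric series, uniformly sampled.
#' @param dt_s sampling interval in seconds.
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `1/(2*dt_s)`.
#' @param order filter order (default 2).
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(values, dt_s, cutoff_hz, order = 2L) {
  nyquist <- 1 / (2 * dt_s)
  if (cutoff_hz >= nyquist) {
    stop_bisguard(sprintf("cutoff %g Hz is not below Nyquist %g Hz",
                          cutoff_hz, nyquist),
                  "bisguard_parameter_error")
  }
  if (cutoff_hz <= 0) {
    stop_bisguard("cutoff must be positive", "bisguard_parameter_error")
  }
  # filtfilt needs enough samples for its edge padding (3 * filter length)
  if (length(values) < 3 * (order + 1)) {
    stop_bisguard("series too short for filter warm-up", "bisguard_parameter_error")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  # centre and pad with odd reflection so start-up transients of the
  # zero-state filter stay out of the returned window
  n <- length(values)
  mu <- mean(values)
  x <- values - mu
  L <- min(n - 1, max(3 * (order + 1), ceiling(6 * nyquist / cutoff_hz)))
  front <- 2 * x[1] - x[(L + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - L)]
  padded <- c(front, x, back)
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[(L + 1):(L + n)] + mu
}

#' Trim a record to the maintenance phase
#'
#' The hybrid model is valid only during maintenance anesthesia, so the
#' induction head and recovery tail of a surgery log are removed before
#' training. Timestamps are preserved, not re-zeroed.
#'
#' @param record a [surgery_record()].
#' @param head_s seconds to drop from the start.
#' @param tail_s seconds to drop from the end.
#' @return The trimmed `surgery_record`.
#' @export
trim_phases <- function(record, head_s, tail_s) {
  stopifnot(inherits(record, "surgery_record"))
  if (head_s < 0 || tail_s < 0) {
    stop_bisguard("trim durations must be non-negative", "bisguard_parameter_error")
  }
  t0 <- record$time_s[1]
  t1 <- record$time_s[length(record$time_s)]
  duration <- t1 - t0
  if (head_s + tail_s >= duration) {
    stop_bisguard("head_s + tail_s must be less than the record duration",
                  "bisguard_parameter_error")
  }
  keep <- record$time_s >= t0 + head_s & record$time_s <= t1 - tail_s
  surgery_record(
    record_id = record$record_id,
    time_s = record$time_s[keep],
    bis = record$bis[keep],
    emg = record$emg[keep],
    propofol_rate = record$propofol_rate[keep],
    fault_mask = if (!is.null(record$fault_mask)) record$fault_mask[keep] else NULL,
    bis_true = if (!is.null(record$bis_true)) record$bis_true[keep] else NULL
  )
}

#' Lag-embed surgery records into the regression form
#'
#' Builds the 8-input / 1-output sample matrix used by clustering and the
#' local regressors. Each row t (t = 3..len of its source record) carries
#' `[EMG(t), EMG(t-1), EMG(t-2), U(t), U(t-1), U(t-2), BIS(t-1), BIS(t-2)]`
#' and the target `y = BIS(t)`. No row mixes samples from two records.
#'
#' @param records a `surgery_record` or list of them.
#' @return A `regression_dataset`: list with `X` (n x 8 matrix), `y`,
#'   `source_ids` (record id per row) and `source_index` (1-based time index
#'   of the target sample in its source record).
#' @export
build_regression_dataset <- function(records) {
  if (inherits(records, "surgery_record")) records <- list(records)
  stopifnot(length(records) > 0)
  parts <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "surgery_record"))
    len <- length(rec$time_s)
    if (len < 3) {
      stop_bisguard("records must have at least 3 samples for lag embedding",
                    "bisguard_data_error")
    }
    t <- 3:len
    X <- cbind(
      rec$emg[t], rec$emg[t - 1], rec$emg[t - 2],
      rec$propofol_rate[t], rec$propofol_rate[t - 1], rec$propofol_rate[t - 2],
      rec$bis[t - 1], rec$bis[t - 2]
    )
    list(X = X, y = rec$bis[t], ids = rep(rec$record_id, length(t)), idx = t)
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  colnames(X) <- FEATURE_NAMES
  structure(list(
    X = X,
    y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
    source_ids = unlist(lapply(parts, `[[`, "ids"), use.names = FALSE),
    source_index = unlist(lapply(parts, `[[`, "idx"), use.names = FALSE)
  ), class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("Regression dataset: %d samples x %d inputs from %d record(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$source_ids))))
  invisible(x)
}

#' Standardize feature columns
#'
#' Column-wise z-scoring. When `stats` is absent the column means and standard
#' deviations are estimated from `X` and returned; when supplied they are
#' applied unchanged (the trained model stores the training-set stats so that
#' inference uses the same transform). Constant columns receive sd = 1 so the
#' transform stays invertible.
#'
#' @param X numeric matrix.
#' @param stats optional list with `mean` and `sd` vectors.
#' @return List with `X` (transformed matrix) and `stats`.
#' @export
standardize <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    if (nrow(X) < 2) {
      stop_bisguard("need at least 2 rows to estimate standardization stats",
                    "bisguard_data_error")
    }
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[!is.finite(sd) | sd <= 0] <- 1
    stats <- list(mean = unname(mu), sd = unname(sd))
  }
  Z <- sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
  list(X = Z, stats = stats)
}

#' Invert a standardization
#'
#' @param Z standardized matrix.
#' @param stats list with `mean` and `sd` as returned by [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(Z, stats) {
  sweep(sweep(as.matrix(Z), 2, stats$sd, "*"), 2, stats$mean, "+")
}
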