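# Residual-threshold fault detection.
#
# The detector runs the hybrid model one step ahead over a surgery, compares
# the measured BIS against the prediction, and flags samples whose absolute
# residual exceeds a range limit in BIS units (the scale is dimensionless so
# the band is absolute, typically 10 or 15). Optionally a fault is raised
# only after `consecutive_m` out-of-range samples in a row; all samples of a
# qualifying run are flagged so episode extents match the excursion.
#
# Because past measured BIS values are model inputs, a faulty reading would
# contaminate the predictor during the very episode to be detected. Two lag
# policies are provided: MEASURED always feeds the measured lags (the literal
# one-step-ahead form), FREEZE substitutes the model's own predictions into
# the lag buffer while the detector is in a fault state and reverts once the
# residual returns within range. FREEZE is the default.

#' Detector configuration
#'
#' @param range_limit absolute residual threshold in BIS units (default 10;
#'   15 gives a more permissive band).
#' @param consecutive_m out-of-range samples in a row required to raise a
#'   fault (default 1; 2-3 suppress single-sample excursions).
#' @param lag_policy `"FREEZE"` (default) or `"MEASURED"`; see the module
#'   comments.
#' @return A `detector_config` list.
#' @export
detector_config <- function(range_limit = 10, consecutive_m = 1L,
                            lag_policy = c("FREEZE", "MEASURED")) {
  lag_policy <- match.arg(lag_policy)
  if (range_limit <= 0) {
    stop_bisguard("range_limit must be > 0", "bisguard_config_error")
  }
  if (consecutive_m < 1) {
    stop_bisguard("consecutive_m must be >= 1", "bisguard_config_error")
  }
  structure(list(range_limit = range_limit,
                 consecutive_m = as.integer(consecutive_m),
                 lag_policy = lag_policy),
            class = "detector_config")
}

#' Residuals between measured and predicted BIS
#'
#' @param measured measured BIS series.
#' @param predicted predicted BIS series of equal length.
#' @return `measured - predicted`, elementwise.
#' @export
residual_series <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop_bisguard("measured and predicted series differ in length",
                  "bisguard_dimension_error")
  }
  measured - predicted
}

# flag all samples belonging to an out-of-range run of length >= m
runs_to_faults <- function(oor, m) {
  fault <- rep(FALSE, length(oor))
  r <- rle(oor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qualify <- r$values & r$lengths >= m
  for (i in which(qualify)) fault[starts[i]:ends[i]] <- TRUE
  fault
}

flags_to_episodes <- function(fault, scored_offset = 0L) {
  r <- rle(fault)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = starts[keep] + scored_offset, end = ends[keep] + scored_offset)
}

#' Run the fault detector over a surgery record
#'
#' For each sample t >= 3, builds the 8-input lag vector according to the lag
#' policy, predicts BIS with the hybrid model, and compares. `out_of_range` is
#' `|measured - predicted| > range_limit`; `fault` marks every sample of an
#' out-of-range run of length at least `consecutive_m`. The first two samples
#' are the lag warm-up and are reported as unscored (`NA`).
#'
#' @param record a [surgery_record()].
#' @param model a `hybrid_model` (from [fit_hybrid()] or [load_model()]).
#' @param config a [detector_config()].
#' The record's BIS and EMG channels are first passed through the same
#' low-pass preconditioning the model was trained with (stored in the model's
#' configuration echo), so residuals compare like with like; `measured` in the
#' report is this preconditioned series.
#'
#' @return A `fault_report`: list with `samples` (data frame: `time_s`,
#'   `measured`, `predicted`, `residual`, `out_of_range`, `fault`),
#'   `episodes` (data frame of 1-based start/end sample indices of maximal
#'   fault runs), and `config`.
#' @export
detect_faults <- function(record, model, config = detector_config()) {
  stopifnot(inherits(record, "surgery_record"))
  cutoff <- model$config$lowpass_cutoff_hz %||% 0
  if (cutoff > 0 && cutoff < 1 / (2 * record$dt_s)) {
    order <- model$config$lowpass_order %||% 2L
    record <- surgery_record(
      record$record_id, record$time_s,
      pmin(pmax(lowpass_filter(record$bis, record$dt_s, cutoff, order), 0), 100),
      pmax(lowpass_filter(record$emg, record$dt_s, cutoff, order), 0),
      record$propofol_rate, record$fault_mask, record$bis_true)
  }
  n <- length(record$time_s)
  if (n < 3) {
    stop_bisguard("record shorter than the lag warm-up", "bisguard_data_error")
  }
  predicted <- rep(NA_real_, n)
  residual <- rep(NA_real_, n)
  oor <- rep(NA, n)
  # lag buffer of the two previous BIS values fed to the model
  lag1 <- record$bis[2]
  lag2 <- record$bis[1]
  for (t in 3:n) {
    x <- c(record$emg[t], record$emg[t - 1], record$emg[t - 2],
           record$propofol_rate[t], record$propofol_rate[t - 1],
           record$propofol_rate[t - 2],
           lag1, lag2)
    p <- hybrid_predict(model, x)
    predicted[t] <- p
    residual[t] <- record$bis[t] - p
    out <- abs(residual[t]) > config$range_limit
    oor[t] <- out
    # advance the lag buffer: FREEZE feeds the prediction back while the
    # residual is out of range, reverting as soon as it returns within range
    next_val <- if (config$lag_policy == "FREEZE" && out) p else record$bis[t]
    lag2 <- lag1
    lag1 <- next_val
  }
  scored <- 3:n
  fault <- rep(NA, n)
  fault[scored] <- runs_to_faults(oor[scored], config$consecutive_m)
  samples <- data.frame(
    time_s = record$time_s,
    measured = record$bis,
    predicted = predicted,
    residual = residual,
    out_of_range = oor,
    fault = fault
  )
  episodes <- flags_to_episodes(fault[scored], scored_offset = 2L)
  structure(list(samples = samples, episodes = episodes, config = config),
            class = "fault_report")
}

#' @export
print.fault_report <- function(x, ...) {
  scored <- !is.na(x$samples$fault)
  cat(sprintf("Fault report: %d scored samples, %d flagged, %d episode(s)\n",
              sum(scored), sum(x$samples$fault[scored]), nrow(x$episodes)))
  if (nrow(x$episodes) > 0) {
    for (i in seq_len(nrow(x$episodes))) {
      ep <- x$episodes[i, ]
      cat(sprintf("  episode %d: samples %d..%d (t = %gs..%gs)\n", i,
                  ep$start, ep$end, x$samples$time_s[ep$start],
                  x$samples$time_s[ep$end]))
    }
  }
  invisible(x)
}

#' Score a fault report against ground truth
#'
#' Per-sample sensitivity (flagged true-fault samples over true-fault samples)
#' and specificity (unflagged clean samples over clean samples), computed over
#' the scored samples only, plus episode-level counts (a true episode is
#' detected when any of its samples is flagged).
#'
#' @param report a `fault_report`.
#' @param truth_mask logical ground-truth fault indicator per sample (same
#'   length as the record).
#' @return List with `sensitivity` (`NA` when there are no true fault
#'   samples), `specificity`, `n_true_episodes`, `n_detected_episodes`,
#'   `n_flagged_episodes`.
#' @export
score_detection <- function(report, truth_mask) {
  stopifnot(inherits(report, "fault_report"))
  flags <- report$samples$fault
  if (length(truth_mask) != length(flags)) {
    stop_bisguard("truth mask length does not match the report",
                  "bisguard_dimension_error")
  }
  scored <- !is.na(flags)
  f <- flags[scored]; tr <- as.logical(truth_mask)[scored]
  sens <- if (sum(tr) == 0) NA_real_ else sum(f & tr) / sum(tr)
  spec <- if (sum(!tr) == 0) NA_real_ else sum(!f & !tr) / sum(!tr)
  true_eps <- flags_to_episodes(tr)
  detected <- 0L
  if (nrow(true_eps) > 0) {
    for (i in seq_len(nrow(true_eps))) {
      if (any(f[true_eps$start[i]:true_eps$end[i]])) detected <- detected + 1L
    }
  }
  list(sensitivity = sens, specificity = spec,
       n_true_episodes = nrow(true_eps),
       n_detected_episodes = detected,
       n_flagged_episodes = nrow(report$episodes))
}
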