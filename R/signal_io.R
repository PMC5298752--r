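# Surgery record and configuration I/O.
#
# A surgery record is one patient's uniformly sampled maintenance-phase log:
# the measured BIS (dimensionless, 0-100), the EMG activity level, and the
# propofol infusion rate. Simulated records additionally carry the fault-free
# BIS (`bis_true`) and a ground-truth fault mask. Records travel as one CSV per
# surgery with columns `time_s,bis,emg,propofol_rate[,fault_mask,bis_true]`.

#' Construct a surgery record
#'
#' Bundles the three monitored channels of one surgery into a validated
#' `surgery_record` object. Channels must share a common length (at least 3,
#' the lag-embedding warm-up) and be sampled on a strict uniform time grid.
#'
#' @param record_id character identifier for the surgery.
#' @param time_s numeric vector of timestamps in seconds, strictly increasing
#'   with a constant step.
#' @param bis measured Bispectral Index per sample, in `[0, 100]`.
#' @param emg EMG activity per sample, non-negative (dimensionless; only
#'   within-dataset consistency is assumed).
#' @param propofol_rate propofol infusion rate per sample, non-negative
#'   (the simulator uses mg/kg/h; the pipeline does not interpret the unit).
#' @param fault_mask optional logical vector: ground-truth fault indicator
#'   (simulator output only).
#' @param bis_true optional fault-free BIS (simulator output only).
#' @return A `surgery_record`: a list with the channels above plus `dt_s`, the
#'   inferred sampling interval in seconds.
#' @examples
#' rec <- surgery_record("demo", time_s = seq(0, 45, by = 5),
#'                       bis = rep(50, 10), emg = rep(2, 10),
#'                       propofol_rate = rep(8, 10))
#' rec$dt_s
#' @export
surgery_record <- function(record_id, time_s, bis, emg, propofol_rate,
                           fault_mask = NULL, bis_true = NULL) {
  n <- length(time_s)
  if (n < 3) {
    stop_bisguard("surgery record needs at least 3 samples", "bisguard_data_error")
  }
  lens <- c(length(bis), length(emg), length(propofol_rate))
  if (!is.null(fault_mask)) lens <- c(lens, length(fault_mask))
  if (!is.null(bis_true)) lens <- c(lens, length(bis_true))
  if (any(lens != n)) {
    stop_bisguard("all channels must have the same length as time_s",
                  "bisguard_data_error")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    stop_bisguard("time_s must be strictly increasing", "bisguard_sampling_error")
  }
  dt_s <- stats::median(dt)
  if (any(abs(dt - dt_s) > 1e-6 * dt_s)) {
    stop_bisguard("time_s is not uniformly sampled within tolerance",
                  "bisguard_sampling_error")
  }
  if (any(bis < 0 | bis > 100)) {
    stop_bisguard("bis values must lie in [0, 100]", "bisguard_range_error")
  }
  if (any(emg < 0)) {
    stop_bisguard("emg must be non-negative", "bisguard_range_error")
  }
  if (any(propofol_rate < 0)) {
    stop_bisguard("propofol_rate must be non-negative", "bisguard_range_error")
  }
  rec <- list(
    record_id = as.character(record_id),
    dt_s = dt_s,
    time_s = as.numeric(time_s),
    bis = as.numeric(bis),
    emg = as.numeric(emg),
    propofol_rate = as.numeric(propofol_rate)
  )
  if (!is.null(fault_mask)) rec$fault_mask <- as.logical(fault_mask)
  if (!is.null(bis_true)) rec$bis_true <- as.numeric(bis_true)
  structure(rec, class = "surgery_record")
}

#' @export
print.surgery_record <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf("Surgery record '%s': %d samples at dt = %g s (%.1f min)\n",
              x$record_id, n, x$dt_s, n * x$dt_s / 60))
  cat(sprintf("  BIS  %6.1f .. %6.1f   EMG %6.2f .. %6.2f   rate %5.2f .. %5.2f\n",
              min(x$bis), max(x$bis), min(x$emg), max(x$emg),
              min(x$propofol_rate), max(x$propofol_rate)))
  if (!is.null(x$fault_mask)) {
    cat(sprintf("  ground truth: %d fault samples\n", sum(x$fault_mask)))
  }
  invisible(x)
}

#' @export
length.surgery_record <- function(x) length(x$time_s)

#' Read a surgery record from CSV
#'
#' Reads one surgery's log in the package dialect: header
#' `time_s,bis,emg,propofol_rate` with optional `fault_mask` (0/1) and
#' `bis_true` columns, comma delimited, `.` decimal separator. The sampling
#' interval is inferred from the timestamps and uniformity is enforced, so
#' malformed files fail on read rather than downstream.
#'
#' @param path path to the CSV file.
#' @return A validated [surgery_record()].
#' @export
read_surgery_csv <- function(path) {
  if (!file.exists(path)) {
    stop_bisguard(sprintf("file not found: %s", path), "bisguard_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "bis", "emg", "propofol_rate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_bisguard(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")),
                  "bisguard_format_error")
  }
  surgery_record(
    record_id = sub("\\.csv$", "", basename(path)),
    time_s = df$time_s,
    bis = df$bis,
    emg = df$emg,
    propofol_rate = df$propofol_rate,
    fault_mask = if ("fault_mask" %in% names(df)) df$fault_mask != 0 else NULL,
    bis_true = df[["bis_true"]]
  )
}

#' Write a surgery record to CSV
#'
#' Inverse of [read_surgery_csv()]: full double precision, optional columns
#' written only when present (`fault_mask` as 0/1).
#'
#' @param record a [surgery_record()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_surgery_csv <- function(record, path) {
  stopifnot(inherits(record, "surgery_record"))
  df <- data.frame(
    time_s = record$time_s,
    bis = record$bis,
    emg = record$emg,
    propofol_rate = record$propofol_rate
  )
  if (!is.null(record$fault_mask)) df$fault_mask <- as.integer(record$fault_mask)
  if (!is.null(record$bis_true)) df$bis_true <- record$bis_true
  # format() at 17 significant digits keeps the round trip below 1e-9
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop_bisguard(sprintf("cannot write to %s", path), "bisguard_io_error")
  }
  invisible(path)
}

# ---- training configuration ---------------------------------------------

train_config_defaults <- function() {
  list(
    k_min = 2L,
    k_max = 10L,
    n_restarts = 20L,
    min_cluster_size = 15L,
    n_folds = 5L,
    mlp_hidden_range = 1:10,
    mlp_max_iter = 40L,
    poly_degrees = c(1L, 2L),
    include_lssvr = TRUE,
    standardize = TRUE,
    fault_range_default = 10,
    consecutive_m = 1L,
    lowpass_cutoff_hz = 0.02,
    lowpass_order = 2L,
    trim_head_s = 0,
    trim_tail_s = 0,
    seed = 1L
  )
}

#' Build a training configuration
#'
#' Assembles and validates the hybrid trainer's settings. Defaults follow the
#' reference protocol: cluster counts 2..10 searched alongside the global
#' model, 20 K-means restarts, a 15-sample minimum cluster size, 5-fold
#' cross-validation, MLP hidden sizes 1..10, polynomial degrees 1..2, and the
#' tuned LS-SVR candidate enabled.
#'
#' @param ... named overrides of the defaults (see Details in
#'   [load_config()] for the key list). Unknown names are rejected.
#' @return A `train_config` list.
#' @export
train_config <- function(...) {
  cfg <- train_config_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop_bisguard("all config arguments must be named", "bisguard_config_error")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop_bisguard(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "bisguard_config_error")
  }
  cfg[names(over)] <- over
  validate_train_config(cfg)
}

validate_train_config <- function(cfg) {
  int_keys <- c("k_min", "k_max", "n_restarts", "min_cluster_size", "n_folds",
                "mlp_max_iter", "consecutive_m", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  cfg$mlp_hidden_range <- as.integer(cfg$mlp_hidden_range)
  cfg$poly_degrees <- as.integer(cfg$poly_degrees)
  if (cfg$k_min < 1L) {
    stop_bisguard("k_min must be >= 1", "bisguard_config_error")
  }
  if (cfg$k_max < cfg$k_min) {
    stop_bisguard("k_max must be >= k_min", "bisguard_config_error")
  }
  if (cfg$min_cluster_size < cfg$n_folds) {
    stop_bisguard("min_cluster_size must be >= n_folds", "bisguard_config_error")
  }
  if (cfg$n_restarts < 1L) {
    stop_bisguard("n_restarts must be >= 1", "bisguard_config_error")
  }
  has_poly <- length(cfg$poly_degrees) > 0
  has_mlp <- length(cfg$mlp_hidden_range) > 0
  if (!has_poly && !has_mlp && !isTRUE(cfg$include_lssvr)) {
    stop_bisguard("candidate set is empty", "bisguard_config_error")
  }
  if (has_poly && !all(cfg$poly_degrees %in% 1:2)) {
    stop_bisguard("poly_degrees must be a subset of {1, 2}", "bisguard_config_error")
  }
  if (has_mlp && any(cfg$mlp_hidden_range < 1L)) {
    stop_bisguard("mlp_hidden_range entries must be >= 1", "bisguard_config_error")
  }
  if (cfg$fault_range_default <= 0) {
    stop_bisguard("fault_range_default must be > 0", "bisguard_config_error")
  }
  if (cfg$consecutive_m < 1L) {
    stop_bisguard("consecutive_m must be >= 1", "bisguard_config_error")
  }
  structure(cfg, class = "train_config")
}

#' Load a training configuration from YAML
#'
#' Reads a YAML file whose keys mirror [train_config()]'s arguments; absent
#' keys take the defaults, unknown keys are rejected, and the resulting
#' configuration is validated (for example `min_cluster_size >= n_folds`,
#' because each cluster is cross-validated independently). An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML config file.
#' @return A validated `train_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_bisguard(sprintf("config file not found: %s", path), "bisguard_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop_bisguard("config file must contain a YAML mapping", "bisguard_config_error")
  }
  # accept the short alias used in detector examples
  if ("fault_range" %in% names(vals)) {
    vals$fault_range_default <- vals$fault_range
    vals$fault_range <- NULL
  }
  do.call(train_config, vals)
}
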