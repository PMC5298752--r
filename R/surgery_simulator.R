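# Synthetic maintenance-phase surgery generator.
#
# Propofol infusion drives a one-compartment plasma model with a first-order
# effect site; the effect-site concentration maps to BIS through a sigmoid
# Emax (Hill) model. EMG disturbances arrive as seeded Poisson bursts with a
# smooth rise/decay envelope, and EMG activity above baseline couples
# additively into the BIS (a rise in EMG raises the displayed BIS without
# reflecting hypnotic state). Measurement noise is Gaussian. Sensor faults
# (constant offsets, isolated spikes, frozen dropouts) are injected on top of
# the measured signal with a ground-truth mask.
#
# Dynamics (rates per minute, integrated by fixed-step RK4 at dt_s):
#   Cp' = -k10 * Cp + u(t) / (60 * Vd)        u in mg/kg/h, Cp in ug/mL
#   Ce' = ke0 * (Cp - Ce)
#   bis_true = clamp(E0 - Emax * Ce^g / (Ce50^g + Ce^g)
#                    + k_emg * max(0, EMG - baseline), 0, 100)

#' Simulation parameters
#'
#' Defaults place the fault-free BIS in the general-anesthesia band (40-60)
#' at a typical maintenance infusion of 8 mg/kg/h, with a dominant quiet-EMG
#' regime and occasional short EMG bursts (a few percent of samples), echoing
#' the strongly imbalanced regime structure of maintenance-phase data.
#'
#' @param duration_s record length in seconds (default 7200, a 2 h surgery).
#' @param dt_s sampling interval in seconds (default 5).
#' @param k10 plasma elimination rate, 1/min (default 0.12).
#' @param ke0 plasma-to-effect-site rate, 1/min (default 0.456).
#' @param vd apparent distribution volume, L/kg (default 0.25; folds the
#'   dose-to-concentration scaling).
#' @param e0 baseline BIS with no drug (default 93).
#' @param emax maximal BIS depression (default 87).
#' @param ce50 effect-site concentration at half effect, ug/mL (default 4.5).
#' @param hill_gamma Hill slope (default 2.5).
#' @param dose_schedule data frame with `start_s` and `rate` (mg/kg/h);
#'   piecewise-constant infusion (default: constant 8 mg/kg/h).
#' @param emg_baseline quiet-regime EMG level (default 2).
#' @param burst_rate_per_h EMG burst arrivals per hour (default 1.5).
#' @param burst_amp_mean,burst_amp_sd lognormal-ish burst amplitude (default
#'   mean 15, sd 4, truncated at 1).
#' @param burst_dur_s_mean burst time constant in seconds (default 30; the
#'   envelope `(t/tau) exp(1 - t/tau)` rises and decays smoothly and is
#'   truncated below 1% of peak).
#' @param k_emg BIS units added per EMG unit above baseline (default 0.8).
#' @param noise_sd BIS measurement noise sd (default 1).
#' @param seed integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(duration_s = 7200, dt_s = 5,
                       k10 = 0.12, ke0 = 0.456, vd = 0.25,
                       e0 = 93, emax = 87, ce50 = 4.5, hill_gamma = 2.5,
                       dose_schedule = data.frame(start_s = 0, rate = 8),
                       emg_baseline = 2, burst_rate_per_h = 1.5,
                       burst_amp_mean = 15, burst_amp_sd = 4,
                       burst_dur_s_mean = 30,
                       k_emg = 0.8, noise_sd = 1, seed = 1L) {
  p <- list(duration_s = duration_s, dt_s = dt_s, k10 = k10, ke0 = ke0,
            vd = vd, e0 = e0, emax = emax, ce50 = ce50,
            hill_gamma = hill_gamma, dose_schedule = dose_schedule,
            emg_baseline = emg_baseline, burst_rate_per_h = burst_rate_per_h,
            burst_amp_mean = burst_amp_mean, burst_amp_sd = burst_amp_sd,
            burst_dur_s_mean = burst_dur_s_mean, k_emg = k_emg,
            noise_sd = noise_sd, seed = as.integer(seed))
  nonneg <- c("duration_s", "k10", "ke0", "emg_baseline", "burst_rate_per_h",
              "burst_amp_mean", "burst_amp_sd", "burst_dur_s_mean", "k_emg",
              "noise_sd")
  if (any(unlist(p[nonneg]) < 0)) {
    stop_bisguard("rates, durations and sds must be non-negative",
                  "bisguard_parameter_error")
  }
  if (p$dt_s <= 0 || p$vd <= 0 || p$ce50 <= 0 || p$hill_gamma <= 0) {
    stop_bisguard("dt_s, vd, ce50 and hill_gamma must be positive",
                  "bisguard_parameter_error")
  }
  if (p$e0 - p$emax < 0) {
    stop_bisguard("e0 must be at least emax (BIS cannot go below 0)",
                  "bisguard_parameter_error")
  }
  if (any(p$dose_schedule$rate < 0)) {
    stop_bisguard("infusion rates must be non-negative", "bisguard_parameter_error")
  }
  structure(p, class = "sim_params")
}

dose_at <- function(schedule, t_s) {
  rates <- numeric(length(t_s))
  ord <- order(schedule$start_s)
  for (i in ord) {
    rates[t_s >= schedule$start_s[i]] <- schedule$rate[i]
  }
  rates
}

#' Simulate a maintenance-phase surgery
#'
#' Integrates the PK/PD dynamics by fixed-step RK4, adds seeded Poisson EMG
#' bursts and Gaussian measurement noise. Deterministic given the seed.
#'
#' @param params a [sim_params()].
#' @param record_id identifier for the record (default `"sim"`).
#' @return A [surgery_record()] with `bis_true` set and `fault_mask` all
#'   `FALSE` (inject faults separately with [inject_faults()]).
#' @export
simulate_surgery <- function(params = sim_params(), record_id = "sim") {
  stopifnot(inherits(params, "sim_params"))
  dt <- params$dt_s
  time_s <- seq(0, params$duration_s, by = dt)
  n <- length(time_s)
  if (n < 3) stop_bisguard("duration too short", "bisguard_parameter_error")
  u <- dose_at(params$dose_schedule, time_s)       # mg/kg/h
  infl <- u / (60 * params$vd)                     # ug/mL per min
  dt_min <- dt / 60

  # RK4 on the linear two-state system with piecewise-constant input
  cp <- numeric(n); ce <- numeric(n)
  deriv <- function(state, inf_rate) {
    c(-params$k10 * state[1] + inf_rate,
      params$ke0 * (state[1] - state[2]))
  }
  # start at the steady state of the initial rate: the record is a
  # maintenance-phase log, not an induction transient
  cp_ss <- infl[1] / params$k10
  state <- c(cp_ss, cp_ss)
  cp[1] <- state[1]; ce[1] <- state[2]
  for (i in seq_len(n - 1)) {
    k1 <- deriv(state, infl[i])
    k2 <- deriv(state + dt_min / 2 * k1, infl[i])
    k3 <- deriv(state + dt_min / 2 * k2, infl[i])
    k4 <- deriv(state + dt_min * k3, infl[i])
    state <- state + dt_min / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cp[i + 1] <- state[1]; ce[i + 1] <- state[2]
  }

  # EMG: baseline plus Poisson bursts with a smooth gamma-shaped envelope
  emg <- rep(params$emg_baseline, n)
  noise <- numeric(n)
  with_seed(params$seed, {
    expected <- params$burst_rate_per_h * params$duration_s / 3600
    n_bursts <- stats::rpois(1, expected)
    if (n_bursts > 0) {
      starts <- stats::runif(n_bursts, 0, params$duration_s)
      amps <- pmax(stats::rnorm(n_bursts, params$burst_amp_mean,
                                params$burst_amp_sd), 1)
      for (b in seq_len(n_bursts)) {
        tau <- params$burst_dur_s_mean
        rel <- (time_s - starts[b]) / tau
        env <- ifelse(rel > 0, rel * exp(1 - rel), 0)
        env[env < 0.01] <- 0   # truncate the tail: quiet regime stays quiet
        emg <- emg + amps[b] * env
      }
    }
    if (params$noise_sd > 0) noise <- stats::rnorm(n, 0, params$noise_sd)
  })

  g <- params$hill_gamma
  hill <- ce^g / (params$ce50^g + ce^g)
  bis_true <- params$e0 - params$emax * hill +
    params$k_emg * pmax(0, emg - params$emg_baseline)
  bis_true <- pmin(pmax(bis_true, 0), 100)
  bis_meas <- pmin(pmax(bis_true + noise, 0), 100)

  surgery_record(record_id, time_s, bis_meas, emg, u,
                 fault_mask = rep(FALSE, n), bis_true = bis_true)
}

#' Fault episode specification
#'
#' @param start_s episode start, seconds.
#' @param duration_s episode length, seconds.
#' @param kind `"OFFSET"` (constant additive bias), `"SPIKE"` (isolated
#'   spiked samples within the episode), or `"DROPOUT"` (sensor frozen at the
#'   last pre-episode value).
#' @param magnitude BIS units (sign respected for OFFSET/SPIKE).
#' @return A one-row data frame; rbind several to build a multi-episode spec.
#' @export
fault_episode <- function(start_s, duration_s, kind, magnitude = 20) {
  kind <- match.arg(kind, c("OFFSET", "SPIKE", "DROPOUT"))
  if (!is.finite(magnitude)) {
    stop_bisguard("magnitude must be finite", "bisguard_parameter_error")
  }
  data.frame(start_s = start_s, duration_s = duration_s, kind = kind,
             magnitude = magnitude, stringsAsFactors = FALSE)
}

#' Inject sensor faults into a simulated record
#'
#' Alters the measured BIS over each episode and marks exactly the altered
#' samples in `fault_mask`; `bis_true` is untouched. OFFSET adds the
#' magnitude; SPIKE adds it at isolated samples (roughly every third sample,
#' seeded); DROPOUT holds the last pre-episode measured value. The measured
#' signal is clamped to `[0, 100]` after alteration.
#'
#' @param record a [surgery_record()] carrying `bis_true`.
#' @param spec data frame of episodes (rbind of [fault_episode()] rows).
#' @param seed integer seed (SPIKE sample draw).
#' @return The faulted `surgery_record`.
#' @export
inject_faults <- function(record, spec, seed = 1L) {
  stopifnot(inherits(record, "surgery_record"))
  if (is.null(record$bis_true)) {
    stop_bisguard("record must carry bis_true to inject faults",
                  "bisguard_data_error")
  }
  bis <- record$bis
  mask <- record$fault_mask %||% rep(FALSE, length(bis))
  if (is.null(spec) || nrow(spec) == 0) {
    return(record)
  }
  t0 <- record$time_s[1]
  t_end <- record$time_s[length(record$time_s)]
  for (i in seq_len(nrow(spec))) {
    ep <- spec[i, ]
    if (ep$start_s < 0 || t0 + ep$start_s + ep$duration_s > t_end) {
      stop_bisguard("fault episode extends outside the record",
                    "bisguard_parameter_error")
    }
    idx <- which(record$time_s >= t0 + ep$start_s &
                 record$time_s < t0 + ep$start_s + ep$duration_s)
    if (length(idx) == 0) next
    if (ep$kind == "OFFSET") {
      bis[idx] <- bis[idx] + ep$magnitude
      mask[idx] <- TRUE
    } else if (ep$kind == "SPIKE") {
      hit <- with_seed(derive_seed(seed, i), {
        sort(sample(idx, max(1, floor(length(idx) / 3))))
      })
      bis[hit] <- bis[hit] + ep$magnitude
      mask[hit] <- TRUE
    } else { # DROPOUT
      hold <- bis[max(1, idx[1] - 1)]
      bis[idx] <- hold
      mask[idx] <- TRUE
    }
  }
  surgery_record(record$record_id, record$time_s,
                 pmin(pmax(bis, 0), 100), record$emg, record$propofol_rate,
                 fault_mask = mask, bis_true = record$bis_true)
}

#' Planted two-regime regression fixture
#'
#' Draws inputs from two well-separated Gaussian blobs in the 8-input space
#' (unit within-blob sd, centers `separation` apart along the fixed diagonal
#' direction) and targets from a different affine law per blob (plus optional
#' noise).
#' Used to exercise structure recovery: a well-working hybrid trainer should
#' split the data at K = 2 and fit each law near-exactly.
#'
#' @param n1,n2 samples per regime.
#' @param coeffs1,coeffs2 length-9 vectors (intercept then 8 slopes).
#' @param separation distance between the blob centers (blob sd is 1).
#' @param noise_sd target noise sd (default 0).
#' @param seed integer seed.
#' @return List with `dataset` (a `regression_dataset`) and `labels`
#'   (regime index per row).
#' @export
make_two_regime_dataset <- function(n1, n2, coeffs1, coeffs2,
                                    separation = 20, noise_sd = 0, seed = 1L) {
  stopifnot(n1 >= 1, n2 >= 1, length(coeffs1) == 9, length(coeffs2) == 9)
  d <- 8
  with_seed(seed, {
    # fixed separation axis: independent draws (training vs held-out) from the
    # same regime laws then share the same geometry
    dir <- rep(1, d) / sqrt(d)
    c1 <- -dir * separation / 2
    c2 <- dir * separation / 2
    X1 <- matrix(stats::rnorm(n1 * d), n1, d) +
      matrix(c1, n1, d, byrow = TRUE)
    X2 <- matrix(stats::rnorm(n2 * d), n2, d) +
      matrix(c2, n2, d, byrow = TRUE)
    y1 <- coeffs1[1] + X1 %*% coeffs1[-1] + stats::rnorm(n1, 0, noise_sd)
    y2 <- coeffs2[1] + X2 %*% coeffs2[-1] + stats::rnorm(n2, 0, noise_sd)
    X <- rbind(X1, X2)
    colnames(X) <- FEATURE_NAMES
    ds <- structure(list(
      X = X,
      y = as.numeric(c(y1, y2)),
      source_ids = rep("synthetic", n1 + n2),
      source_index = seq_len(n1 + n2) + 2L
    ), class = "regression_dataset")
    list(dataset = ds, labels = rep(1:2, c(n1, n2)))
  })
}
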