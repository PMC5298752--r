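test_that("no drug, no noise, no bursts leaves BIS at its baseline", {
  p <- sim_params(duration_s = 600, noise_sd = 0, burst_rate_per_h = 0,
                  dose_schedule = data.frame(start_s = 0, rate = 0), seed = 1)
  rec <- simulate_surgery(p)
  expect_equal(rec$bis_true, rep(p$e0, length(rec$time_s)))
  expect_equal(rec$bis, rec$bis_true)   # noiseless: measured equals true
  expect_false(any(rec$fault_mask))
})

test_that("steady-state BIS decreases with the infusion rate", {
  bis_at <- function(rate) {
    p <- sim_params(duration_s = 7200, noise_sd = 0, burst_rate_per_h = 0,
                    dose_schedule = data.frame(start_s = 0, rate = rate),
                    seed = 1)
    rec <- simulate_surgery(p)
    tail(rec$bis_true, 1)
  }
  b4 <- bis_at(4); b8 <- bis_at(8); b12 <- bis_at(12)
  expect_gt(b4, b8)
  expect_gt(b8, b12)
  # default maintenance rate sits in the general-anesthesia band
  expect_gt(b8, 40)
  expect_lt(b8, 60)
})

test_that("the default scenario is dominated by the quiet-EMG regime", {
  fracs <- vapply(1:8, function(s) {
    p <- sim_params(seed = s)
    rec <- simulate_surgery(p)
    mean(rec$emg > p$emg_baseline + 1)
  }, numeric(1))
  expect_lt(mean(fracs), 0.10)
  expect_gt(mean(fracs), 0)   # bursts do occur
})

test_that("simulated records always satisfy the record invariants", {
  set.seed(5)
  for (i in 1:8) {
    p <- sim_params(duration_s = sample(300:1200, 1),
                    dt_s = sample(c(1, 5, 10), 1),
                    noise_sd = runif(1, 0, 3),
                    burst_rate_per_h = runif(1, 0, 10),
                    dose_schedule = data.frame(start_s = 0, rate = runif(1, 0, 12)),
                    seed = i)
    rec <- simulate_surgery(p)
    expect_s3_class(rec, "surgery_record")   # constructor enforces invariants
    expect_true(all(rec$bis >= 0 & rec$bis <= 100))
    expect_true(all(rec$emg >= 0))
    expect_equal(rec$dt_s, p$dt_s)
  }
})

test_that("burst amplitude couples into the true BIS", {
  base <- sim_params(duration_s = 3600, noise_sd = 0, seed = 7)
  quiet <- simulate_surgery(sim_params(duration_s = 3600, noise_sd = 0,
                                       burst_rate_per_h = 0, seed = 7))
  small <- simulate_surgery(base)
  big_p <- base; big_p$burst_amp_mean <- 2 * base$burst_amp_mean
  big <- simulate_surgery(big_p)
  dev_small <- sum(abs(small$bis_true - quiet$bis_true) > 0.5)
  dev_big <- sum(abs(big$bis_true - quiet$bis_true) > 0.5)
  expect_gte(dev_big, dev_small)
  expect_gt(dev_big, 0)
})

test_that("fault injection alters exactly the specified samples", {
  p <- sim_params(duration_s = 1500, noise_sd = 0, burst_rate_per_h = 0, seed = 9)
  rec <- simulate_surgery(p)

  f <- inject_faults(rec, fault_episode(100, 150, "OFFSET", 20), seed = 1)
  idx <- which(f$fault_mask)
  expect_length(idx, 30)   # 150 s at dt = 5
  expect_equal(f$bis[idx] - f$bis_true[idx], rep(20, 30), tolerance = 1e-12)
  expect_equal(f$bis_true, rec$bis_true)
  expect_equal(f$bis[-idx], rec$bis[-idx])

  # empty spec: unchanged
  f0 <- inject_faults(rec, NULL, seed = 1)
  expect_equal(f0$bis, rec$bis)
  expect_false(any(f0$fault_mask))

  # determinism
  s1 <- inject_faults(rec, fault_episode(200, 100, "SPIKE", 30), seed = 4)
  s2 <- inject_faults(rec, fault_episode(200, 100, "SPIKE", 30), seed = 4)
  expect_identical(s1$bis, s2$bis)
  expect_identical(s1$fault_mask, s2$fault_mask)

  # dropout holds the last pre-episode value
  d <- inject_faults(rec, fault_episode(500, 50, "DROPOUT"), seed = 1)
  didx <- which(d$fault_mask)
  expect_equal(d$bis[didx], rep(rec$bis[didx[1] - 1], length(didx)))

  expect_error(inject_faults(rec, fault_episode(1400, 500, "OFFSET", 20)),
               class = "bisguard_parameter_error")
})

test_that("the two-regime fixture reproduces the validity (N/A) mechanics", {
  two <- make_two_regime_dataset(60, 10, c(20, rnorm(8)), c(70, rnorm(8)),
                                 separation = 20, seed = 11)
  expect_equal(table(two$labels), table(rep(1:2, c(60, 10))), ignore_attr = TRUE)
  cfg <- small_config(k_max = 2L, seed = 12L)
  model <- fit_hybrid(two$dataset, cfg)
  pk <- model$report$per_k
  # the 10-sample regime leaves K = 2 with an undersized cluster
  expect_false(pk$valid[pk$k == 2])
  expect_equal(model$report$chosen_k, 1L)
})
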