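test_that("flic simulator produces the configured trace geometry", {
  cfg <- flic_sim_config(seed = 1)
  sim <- gen_flic_trace(cfg)
  # default window is the 15-minute recording at 5 Hz
  expect_equal(nrow(sim$trace), 900 * 5)
  expect_equal(sim$trace$time_s[1], 0)
  expect_equal(diff(sim$trace$time_s)[1], 0.2)
  expect_true(all(sim$truth$start_s >= 0 & sim$truth$end_s <= 900))
})

test_that("a zero event rate yields an empty ground truth and pure background", {
  sim <- gen_flic_trace(flic_sim_config(event_rate_per_min = 0,
                                        noise_sd = 0, drift_amplitude = 0,
                                        baseline_level = 3, seed = 4))
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$trace$signal == 3))
})

test_that("noiseless driftless trace is exactly amplitude inside events, 0 outside", {
  sim <- gen_flic_trace(flic_sim_config(noise_sd = 0, drift_amplitude = 0,
                                        baseline_level = 0, seed = 11))
  t <- sim$trace$time_s
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sim$truth))) {
    inside <- inside | (t >= sim$truth$start_s[i] & t < sim$truth$end_s[i])
  }
  expect_true(all(sim$trace$signal[inside] == 100))
  expect_true(all(sim$trace$signal[!inside] == 0))
})

test_that("event counts follow the Poisson expectation across seeds", {
  counts <- vapply(1:200, function(s) {
    # count simulated events before ground-truth merging is not observable;
    # merged intervals undercount slightly, so compare with a merge-aware
    # margin below the exact Poisson mean of 30
    nrow(gen_flic_trace(flic_sim_config(seed = s))$truth)
  }, numeric(1))
  # mean merged-interval count differs from the raw Poisson mean (30) by the
  # expected overlap fraction; a 99% CI on the mean of 200 Poisson(30) draws
  # is ~ +-1, widened to +-3 for the merge deficit
  expect_gt(mean(counts), 30 - 3)
  expect_lt(mean(counts), 30 + 1)
})

test_that("ground-truth intervals are sorted and non-overlapping", {
  for (s in c(2, 17, 91)) {
    truth <- gen_flic_trace(flic_sim_config(seed = s))$truth
    expect_true(all(truth$end_s > truth$start_s))
    if (nrow(truth) > 1) {
      expect_true(all(diff(truth$start_s) > 0))
      expect_true(all(truth$start_s[-1] > truth$end_s[-nrow(truth)]))
    }
  }
})

test_that("a fixed seed reproduces traces bit-identically", {
  a <- gen_flic_trace(flic_sim_config(seed = 99))
  b <- gen_flic_trace(flic_sim_config(seed = 99))
  expect_identical(a, b)
  ca <- gen_pumping_cohort(pump_sim_config(seed = 5))
  cb <- gen_pumping_cohort(pump_sim_config(seed = 5))
  expect_identical(ca, cb)
  fa <- gen_fluorescence_trace(ca_sim_config(noise_sd = 2, seed = 5))
  fb <- gen_fluorescence_trace(ca_sim_config(noise_sd = 2, seed = 5))
  expect_identical(fa, fb)
})

test_that("fluorescence peak latency matches the closed form when noiseless", {
  # argmax of (1 - exp(-u/tr)) exp(-u/td) is at u = tr log(1 + td/tr)
  tr <- 13; td <- 120
  u_star <- tr * log(1 + td / tr)
  expect_equal(u_star, 30.23, tolerance = 1e-3)
  # numerical verification of the closed form on a fine grid
  u <- seq(0, 300, by = 0.001)
  g <- (1 - exp(-u / tr)) * exp(-u / td)
  expect_equal(u[which.max(g)], u_star, tolerance = 1e-2)
  # simulated noiseless trace peaks within one frame of it
  trace <- gen_fluorescence_trace(ca_sim_config())
  peak_t <- trace$time_s[which.max(trace$intensity)] - 30
  expect_lte(abs(peak_t - u_star), 1)
})

test_that("zero-amplitude fluorescence traces are flat at f0", {
  trace <- gen_fluorescence_trace(ca_sim_config(response_amplitude = 0))
  expect_true(all(trace$intensity == 100))
})

test_that("refocus gaps flag the covered frames as excluded", {
  trace <- gen_fluorescence_trace(
    ca_sim_config(refocus_gaps = list(c(100, 108))))
  expect_true(all(trace$excluded[trace$time_s >= 100 & trace$time_s < 108]))
  expect_false(any(trace$excluded[trace$time_s < 100 | trace$time_s >= 108]))
})

test_that("noiseless pumping cohort is exactly linear", {
  cfg <- pump_sim_config(n_flies = 10, ingestion_rate_cv = 0,
                         pump_rate_cv = 0, od_noise_sd = 0, seed = 8)
  co <- gen_pumping_cohort(cfg)
  expect_equal(co$true_volume_nl, 8 * co$feeding_time_s)
  expect_equal(co$swallow_count, round(2 * co$feeding_time_s))
  expect_equal(co$od_reading,
               0.14 * co$true_volume_nl / 1000 + 0.07)
})

test_that("cohort defaults give the pooled size and calibrated correlation", {
  co <- gen_pumping_cohort(pump_sim_config(seed = 12))
  expect_equal(nrow(co), 140)
  # variance-decomposition oracle for the pooled swallow-vs-time R^2
  r2_expected <- expected_pooled_r2(2, 0.13, 5, 60)
  expect_equal(r2_expected, 0.919, tolerance = 1e-3)
  r2 <- vapply(1:20, function(s) {
    x <- gen_pumping_cohort(pump_sim_config(seed = 100 + s))
    stats::cor(x$feeding_time_s, x$swallow_count)^2
  }, numeric(1))
  expect_equal(mean(r2), r2_expected, tolerance = 0.02)
})

test_that("invalid simulator configurations name the offending field", {
  expect_error(flic_sim_config(duration_s = -1), "duration_s")
  expect_error(flic_sim_config(noise_sd = -2), "noise_sd")
  expect_error(ca_sim_config(tau_rise_s = 120, tau_decay_s = 13),
               "tau_rise_s")
  expect_error(ca_sim_config(refocus_gaps = list(c(400, 300))),
               "refocus_gaps")
  expect_error(pump_sim_config(n_flies = 0), "n_flies")
  expect_error(pump_sim_config(feeding_time_range_s = c(60, 10)),
               "feeding_time_range_s")
})

test_that("dilution standard generator follows the two-fold series", {
  std <- gen_dilution_standard(noise_sd = 0)
  expect_equal(sort(unique(std$level), decreasing = TRUE),
               1 / 2^(0:9))
  expect_equal(nrow(std), 30)
  expect_equal(std$od, 0.14 * std$level)
})
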