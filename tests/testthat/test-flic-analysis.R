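make_trace <- function(signal, fs = 5, well = "W1") {
  new_flic_trace((seq_along(signal) - 1) / fs, signal, well_id = well)
}

test_that("flic CSV round trip preserves traces and rejects malformed files", {
  d <- withr::local_tempdir()
  # minimal 2-column file
  f1 <- file.path(d, "one.csv")
  writeLines(c("time_s,W1", paste(seq(0, 1.8, by = 0.2), 1:10, sep = ",")), f1)
  traces <- read_flic_csv(f1)
  expect_length(traces, 1)
  expect_equal(nrow(traces[[1]]), 10)
  expect_equal(traces[[1]]$signal, as.numeric(1:10))

  # 12-well file sharing one time axis
  t <- seq(0, 1.8, by = 0.2)
  wide <- data.frame(time_s = t)
  for (w in 1:12) wide[[paste0("W", w)]] <- rnorm(10)
  f2 <- file.path(d, "wide.csv")
  write.csv(wide, f2, row.names = FALSE)
  traces <- read_flic_csv(f2)
  expect_length(traces, 12)
  expect_equal(vapply(traces, function(x) attr(x, "well_id"), character(1)),
               paste0("W", 1:12))

  # non-monotone time column errors, citing the offending row
  bad <- wide
  bad$time_s[5] <- bad$time_s[4] - 0.1
  f3 <- file.path(d, "bad.csv")
  write.csv(bad, f3, row.names = FALSE)
  expect_error(read_flic_csv(f3), "row 5")

  # writer output is readable again, with the seed comment ignored
  f4 <- file.path(d, "rt.csv")
  write_flic_csv(traces[[1]], f4, seed = 7)
  expect_equal(readLines(f4, n = 1), "# seed: 7")
  back <- read_flic_csv(f4)
  expect_equal(back[[1]]$signal, traces[[1]]$signal)
})

test_that("baseline estimation matches a direct rolling-median oracle", {
  # constant signal: baseline is the constant everywhere
  tr <- make_trace(rep(7, 100))
  expect_equal(estimate_baseline(tr, detection_params(baseline_window_s = 4)),
               rep(7, 100))

  # slow ramp: running median tracks it closely away from the edges
  fs <- 5
  t <- seq(0, 900 - 1 / fs, by = 1 / fs)
  ramp <- 10 * t / 900
  tr <- make_trace(ramp)
  bl <- estimate_baseline(tr, detection_params(baseline_window_s = 120))
  interior <- t > 60 & t < 840
  expect_lt(max(abs(bl - ramp)[interior]), 1)

  # oracle equivalence on an arbitrary noisy signal
  set.seed(42)
  x <- rnorm(500) + sin(seq(0, 6, length.out = 500))
  tr <- make_trace(x)
  bl <- estimate_baseline(tr, detection_params(baseline_window_s = 10))
  k <- 51  # 10 s at 5 Hz, rounded to odd
  expect_equal(bl, rolling_median_oracle(x, k))

  # a short large pulse barely moves the median
  x <- rep(0, 4500)
  x[1000:1004] <- 100  # 1 s pulse at 5 Hz
  tr <- make_trace(x)
  bl <- estimate_baseline(tr, detection_params(baseline_window_s = 120))
  expect_lt(max(abs(bl[1000:1004])), 0.5)

  expect_error(
    estimate_baseline(make_trace(rep(0, 10)),
                      detection_params(baseline_window_s = 100)),
    "longer than the trace")
})

test_that("detect_events recovers a clean square pulse", {
  x <- rep(0, 150)
  t <- (seq_along(x) - 1) / 5
  x[t >= 2 & t <= 3] <- 100
  tr <- make_trace(x)
  ev <- detect_events(tr, detection_params(baseline_window_s = 20,
                                           threshold = 20,
                                           min_event_duration_s = 0.4))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 2, tolerance = 0.21)
  expect_equal(ev$end_s, 3, tolerance = 0.21)
  expect_equal(ev$peak_amplitude, 100)
  expect_equal(ev$duration_s, ev$end_s - ev$start_s)
})

test_that("a flat or empty trace yields no events", {
  expect_equal(nrow(detect_events(make_trace(rep(0, 200)),
                                  detection_params(baseline_window_s = 10,
                                                   threshold = 5))), 0)
  expect_equal(nrow(detect_events(new_flic_trace(numeric(0), numeric(0)))), 0)
})

test_that("detection equals the brute-force run scanner on noiseless traces", {
  for (s in c(3, 14, 159)) {
    sim <- gen_flic_trace(flic_sim_config(noise_sd = 0, drift_amplitude = 0,
                                          seed = s))
    params <- detection_params(threshold = 50)
    ev <- detect_events(sim$trace, params)
    oracle <- brute_force_events(sim$trace$time_s, sim$trace$signal,
                                 threshold = 50,
                                 merge_gap_s = params$merge_gap_s,
                                 min_duration_s = params$min_event_duration_s,
                                 dt = 0.2)
    expect_equal(ev$start_s, oracle$start_s)
    expect_equal(ev$end_s, oracle$end_s)
  }
})

test_that("raising the threshold or duration floor never adds events", {
  sim <- gen_flic_trace(flic_sim_config(seed = 23))
  n_by_thr <- vapply(c(20, 40, 60, 90), function(thr) {
    nrow(detect_events(sim$trace, detection_params(threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
  n_by_dur <- vapply(c(0, 0.4, 1, 2, 4), function(md) {
    nrow(detect_events(sim$trace,
                       detection_params(threshold = 40,
                                        min_event_duration_s = md)))
  }, numeric(1))
  expect_true(all(diff(n_by_dur) <= 0))
})

test_that("shifting the time axis shifts event boundaries exactly", {
  sim <- gen_flic_trace(flic_sim_config(seed = 31))
  ev <- detect_events(sim$trace)
  shifted <- new_flic_trace(sim$trace$time_s + 123.4, sim$trace$signal)
  ev2 <- detect_events(shifted)
  expect_equal(ev2$start_s, ev$start_s + 123.4)
  expect_equal(ev2$end_s, ev$end_s + 123.4)
})

test_that("contact summaries count, clip and average as specified", {
  # no events
  none <- summarize_contacts(
    data.frame(well_id = character(0), start_s = numeric(0),
               end_s = numeric(0)), c(0, 900))
  expect_equal(none$n_contacts, 0)
  expect_equal(none$total_contact_time_s, 0)
  expect_equal(none$mean_contact_duration_s, 0)

  # durations 1, 2, 3 inside the window
  ev <- data.frame(well_id = "W1", start_s = c(10, 20, 30),
                   end_s = c(11, 22, 33))
  s <- summarize_contacts(ev, c(0, 900))
  expect_equal(s$n_contacts, 3)
  expect_equal(s$total_contact_time_s, 6)
  expect_equal(s$mean_contact_duration_s, 2)

  # event straddling the window end is clipped
  ev <- data.frame(well_id = "W1", start_s = 899, end_s = 905)
  expect_equal(summarize_contacts(ev, c(0, 900))$total_contact_time_s, 1)

  # total always equals the clipped duration sum
  sim <- gen_flic_trace(flic_sim_config(seed = 77))
  ev <- detect_events(sim$trace)
  s <- summarize_contacts(ev, c(0, 450))
  clipped <- pmin(ev$end_s, 450) - pmax(ev$start_s, 0)
  expect_equal(s$total_contact_time_s, sum(clipped[clipped > 0]))

  expect_error(summarize_contacts(ev, c(900, 0)), "window")
})

test_that("validation matches greedily one-to-one with the stated conventions", {
  iv <- function(s, e) data.frame(start_s = s, end_s = e)
  # identity
  v <- validate_events(iv(c(1, 5), c(2, 6)), iv(c(1, 5), c(2, 6)), tol = 0.5)
  expect_equal(v$detection_rate, 1)
  expect_equal(v$false_positive_rate, 0)

  # hand-worked partial match
  v <- validate_events(iv(c(1.05, 10), c(2.1, 11)), iv(c(1, 5), c(2, 6)),
                       tol = 0.5)
  expect_equal(v$n_matched, 1)
  expect_equal(v$detection_rate, 0.5)
  expect_equal(v$false_positive_rate, 0.5)

  # nothing detected: detection rate 0, FP 0 by convention
  v <- validate_events(iv(numeric(0), numeric(0)), iv(1, 2), tol = 0.5)
  expect_equal(v$detection_rate, 0)
  expect_equal(v$false_positive_rate, 0)

  expect_error(validate_events(iv(1, 2), iv(1, 2), tol = -1), "tol")

  # rates stay in [0, 1] and matches bounded on random interval sets
  set.seed(6)
  for (i in 1:20) {
    ts <- sort(runif(10, 0, 100)); te <- ts + runif(10, 0.1, 2)
    ds <- sort(runif(8, 0, 100)); de <- ds + runif(8, 0.1, 2)
    v <- validate_events(iv(ds, de), iv(ts, te), tol = 0.5)
    expect_lte(v$n_matched, min(v$n_true, v$n_detected))
    expect_true(v$detection_rate >= 0 && v$detection_rate <= 1)
    expect_true(v$false_positive_rate >= 0 && v$false_positive_rate <= 1)
  }
})

test_that("detection parameter validation enforces one threshold mode", {
  expect_error(detection_params(threshold = 10, threshold_mads = 6),
               "exactly one")
  expect_error(detection_params(threshold = NULL, threshold_mads = NULL),
               "exactly one")
  expect_error(detection_params(merge_gap_s = -1), "merge_gap_s")
})
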