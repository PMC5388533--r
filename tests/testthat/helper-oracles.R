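# Independent oracles used across test files. These deliberately re-derive
# results by brute force or closed form, without calling the implementation
# paths they check.

# brute-force event scanner: maximal supra-threshold runs with merge and
# minimum-duration post-rules, written as a plain sample-by-sample loop
brute_force_events <- function(time_s, resid, threshold, merge_gap_s,
                               min_duration_s, dt) {
  above <- resid > threshold
  events <- list()
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      events[[length(events) + 1]] <- c(time_s[i], time_s[j] + dt)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  m <- do.call(rbind, events)
  guard <- 1 - 1e-9  # same float-tie guard as the detector contract
  merged <- list(m[1, ])
  for (k in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[k, 1] - last[2] < merge_gap_s * guard) {
      merged[[length(merged)]] <- c(last[1], m[k, 2])
    } else {
      merged[[length(merged) + 1]] <- m[k, ]
    }
  }
  m <- do.call(rbind, merged)
  m <- m[(m[, 2] - m[, 1]) >= min_duration_s * guard, , drop = FALSE]
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

# rolling median with reflected ends, computed directly window by window
rolling_median_oracle <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  padded <- c(x[seq(h + 1, 2, by = -1)], x, x[seq(n - 1, n - h, by = -1)])
  vapply(seq_len(n), function(i) {
    stats::median(padded[i:(i + k - 1)])
  }, numeric(1))
}

# expected pooled R^2 of swallow count vs feeding time under the cohort
# model, by variance decomposition: R^2 = rbar^2 Var(t) / (rbar^2 Var(t) +
# E[t^2] sigma_r^2) for t ~ U(a, b) and per-fly rate with mean rbar, sd
# sigma_r
expected_pooled_r2 <- function(rbar, cv, a, b) {
  var_t <- (b - a)^2 / 12
  e_t2 <- var_t + ((a + b) / 2)^2
  sr2 <- (rbar * cv)^2
  rbar^2 * var_t / (rbar^2 * var_t + e_t2 * sr2)
}

# analytic standard error of the OLS slope of volume on time for the cohort
# model (residual variance sigma_r^2 t^2 averaged over t ~ U(a, b))
slope_se_oracle <- function(rate, cv, a, b, n) {
  var_t <- (b - a)^2 / 12
  e_t2 <- var_t + ((a + b) / 2)^2
  sigma2 <- (rate * cv)^2 * e_t2
  sqrt(sigma2 / ((n - 1) * var_t))
}

run_flic_benchmark <- function(n_traces = 50, seed_base = 1000,
                               params = detection_params(), tol = 0.5) {
  nt <- nd <- nm <- 0
  for (i in seq_len(n_traces)) {
    sim <- gen_flic_trace(flic_sim_config(seed = seed_base + i))
    ev <- detect_events(sim$trace, params)
    v <- validate_events(ev, sim$truth, tol = tol)
    nt <- nt + v$n_true
    nd <- nd + v$n_detected
    nm <- nm + v$n_matched
  }
  list(detection_rate = nm / nt,
       false_positive_rate = if (nd > 0) (nd - nm) / nd else 0,
       n_true = nt, n_detected = nd, n_matched = nm)
}
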