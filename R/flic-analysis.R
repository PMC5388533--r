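#' Construct a FLIC trace object
#'
#' A `flic_trace` is a data frame with columns `time_s` (strictly increasing
#' seconds) and `signal` (arbitrary sensor units), carrying `well_id` and
#' optional `genotype` attributes. Most users obtain traces from
#' [read_flic_csv()] or [gen_flic_trace()] rather than calling this directly.
#'
#' @param time_s Strictly increasing numeric vector of sample times, seconds.
#' @param signal Numeric vector of sensor readings, same length as `time_s`.
#' @param well_id Identifier of the recording well.
#' @param genotype Optional genotype label.
#' @return A `flic_trace` data frame.
#' @export
new_flic_trace <- function(time_s, signal, well_id = "W1", genotype = NA_character_) {
  if (length(time_s) != length(signal)) {
    stop("time_s and signal must have equal length", call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(signal)) {
    stop("flic_trace must not contain missing values", call. = FALSE)
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop(sprintf("time_s must be strictly increasing (violated at row %d)", bad),
         call. = FALSE)
  }
  structure(
    data.frame(time_s = as.numeric(time_s), signal = as.numeric(signal)),
    well_id = as.character(well_id),
    genotype = as.character(genotype),
    class = c("flic_trace", "data.frame"))
}

# median sample spacing; FLIC monitors sample on a regular clock, but minor
# jitter is tolerated
trace_dt <- function(trace) {
  if (nrow(trace) < 2L) return(NA_real_)
  stats::median(diff(trace$time_s))
}

#' Event-detection parameters for FLIC traces
#'
#' Exactly one of `threshold` (an absolute height above the local baseline,
#' a.u.) or `threshold_mads` (a robust multiple of the median absolute
#' deviation of the baseline-subtracted residual) must be supplied; the
#' default is the robust mode at 6 MADs.
#'
#' @param baseline_window_s Width, seconds, of the running-median window used
#'   to track baseline drift (default 120 s).
#' @param threshold Absolute detection threshold above baseline, a.u., or
#'   `NULL` to use `threshold_mads`.
#' @param threshold_mads Threshold as a multiple of the MAD of the residual
#'   signal, or `NULL` to use `threshold`.
#' @param min_event_duration_s Candidate events shorter than this are
#'   discarded (default 0.4 s).
#' @param merge_gap_s Adjacent supra-threshold runs separated by less than
#'   this gap are merged into one event (default 0.4 s, enough to bridge a
#'   single dropped sample at typical sampling rates while keeping distinct
#'   contacts separate).
#' @param match_tolerance_s Boundary tolerance used when matching detections
#'   to ground truth in [validate_events()] (default 0.5 s).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(baseline_window_s = 120,
                             threshold = NULL,
                             threshold_mads = if (is.null(threshold)) 6 else NULL,
                             min_event_duration_s = 0.4,
                             merge_gap_s = 0.4,
                             match_tolerance_s = 0.5) {
  check_number(baseline_window_s, "baseline_window_s",
               lower = 0, strict_lower = TRUE)
  if (is.null(threshold) == is.null(threshold_mads)) {
    stop("exactly one of 'threshold' or 'threshold_mads' must be set",
         call. = FALSE)
  }
  if (!is.null(threshold)) {
    check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  }
  if (!is.null(threshold_mads)) {
    check_number(threshold_mads, "threshold_mads",
                 lower = 0, strict_lower = TRUE)
  }
  check_number(min_event_duration_s, "min_event_duration_s", lower = 0)
  check_number(merge_gap_s, "merge_gap_s", lower = 0)
  check_number(match_tolerance_s, "match_tolerance_s", lower = 0)
  structure(
    list(baseline_window_s = baseline_window_s,
         threshold = threshold, threshold_mads = threshold_mads,
         min_event_duration_s = min_event_duration_s,
         merge_gap_s = merge_gap_s,
         match_tolerance_s = match_tolerance_s),
    class = "detection_params")
}

#' Read FLIC traces from a wide-format CSV
#'
#' Expects a header row with a `time_s` column followed by one column per
#' well, as written by monitor exports or [write_flic_csv()]. Lines starting
#' with `#` (e.g. a recorded seed) are ignored.
#'
#' @param path Path to the CSV file.
#' @return A list of [new_flic_trace()] objects, one per well column, sharing
#'   the file's time axis.
#' @export
read_flic_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("format error: missing 'time_s' column", call. = FALSE)
  }
  if (ncol(df) < 2L) {
    stop("format error: no well columns after 'time_s'", call. = FALSE)
  }
  t <- df$time_s
  if (!is.numeric(t) || anyNA(t)) {
    stop("format error: non-numeric or missing value in 'time_s' column",
         call. = FALSE)
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("format error: time_s not strictly increasing at data row %d", bad),
         call. = FALSE)
  }
  wells <- setdiff(names(df), "time_s")
  lapply(wells, function(w) {
    sig <- df[[w]]
    if (!is.numeric(sig) || anyNA(sig)) {
      stop(sprintf("format error: non-numeric or missing value in column '%s'", w),
           call. = FALSE)
    }
    new_flic_trace(t, sig, well_id = w)
  })
}

#' Write FLIC traces (and optional ground truth) as CSV
#'
#' Writes a wide-format trace file (`time_s` plus one column per well) with
#' the generating seed recorded in a `#` comment header, readable by
#' [read_flic_csv()].
#'
#' @param traces A single `flic_trace` or list of traces sharing a time axis.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the header comment.
#' @return Invisibly, `path`.
#' @export
write_flic_csv <- function(traces, path, seed = NULL) {
  if (inherits(traces, "flic_trace")) traces <- list(traces)
  t <- traces[[1]]$time_s
  out <- data.frame(time_s = t)
  for (tr in traces) {
    if (!isTRUE(all.equal(tr$time_s, t))) {
      stop("all traces must share one time axis", call. = FALSE)
    }
    out[[attr(tr, "well_id")]] <- tr$signal
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Estimate the slowly drifting baseline of a FLIC trace
#'
#' Running median over a window of `baseline_window_s` seconds, with the ends
#' of the trace padded by reflection so the estimate is defined at every
#' sample. The median is robust to the brief, sparse contact pulses riding on
#' the baseline, so subtracting it from a drift-only trace leaves residuals
#' with median near zero.
#'
#' @param trace A `flic_trace`.
#' @param params A [detection_params()] object.
#' @return Numeric baseline, same length as the trace.
#' @export
estimate_baseline <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "flic_trace"))
  n <- nrow(trace)
  if (n == 0L) return(numeric(0))
  dt <- trace_dt(trace)
  if (is.na(dt)) return(trace$signal)
  if (params$baseline_window_s < 3 * dt) {
    stop("parameter 'baseline_window_s' must span at least 3 samples",
         call. = FALSE)
  }
  k <- round(params$baseline_window_s / dt)
  if (k %% 2 == 0) k <- k + 1
  if (k > n) {
    stop("parameter 'baseline_window_s' is longer than the trace",
         call. = FALSE)
  }
  if (k < 3) k <- 3
  h <- (k - 1) / 2
  x <- trace$signal
  # reflect h samples at each end so runmed's central rule applies everywhere
  left <- x[seq(h + 1, 2, by = -1)]
  right <- x[seq(n - 1, n - h, by = -1)]
  padded <- c(left, x, right)
  bl <- stats::runmed(padded, k, endrule = "keep")
  as.numeric(bl[(h + 1):(h + n)])
}

#' Detect feeding-contact events in a FLIC trace
#'
#' Subtracts the running-median baseline, thresholds the residual (either at
#' a fixed height or at a robust multiple of its MAD), takes maximal
#' supra-threshold runs of samples as candidate events, merges runs separated
#' by less than `merge_gap_s`, and discards events shorter than
#' `min_event_duration_s`. Event end times extend one sample period past the
#' last supra-threshold sample so a run's duration equals its sample count
#' times the sampling period.
#'
#' @param trace A `flic_trace`.
#' @param params A [detection_params()] object.
#' @return A data frame of events with columns `well_id`, `start_s`, `end_s`,
#'   `duration_s`, `peak_amplitude` (baseline-subtracted peak height), sorted
#'   and non-overlapping; zero rows when nothing crosses threshold.
#' @examples
#' sim <- gen_flic_trace(flic_sim_config(duration_s = 120, seed = 7))
#' detect_events(sim$trace)
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "flic_trace"))
  empty <- data.frame(well_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak_amplitude = numeric(0))
  if (nrow(trace) == 0L) return(empty)
  baseline <- estimate_baseline(trace, params)
  resid <- trace$signal - baseline
  thr <- if (!is.null(params$threshold)) {
    params$threshold
  } else {
    params$threshold_mads * stats::mad(resid)
  }
  above <- resid > thr
  if (!any(above)) return(empty)
  dt <- trace_dt(trace)
  if (is.na(dt)) dt <- 0

  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values)
  starts <- trace$time_s[idx_start[runs]]
  ends <- trace$time_s[idx_end[runs]] + dt
  i1 <- idx_start[runs]
  i2 <- idx_end[runs]

  # merge runs separated by short sub-threshold gaps; the relative guard
  # keeps gap comparisons stable under time-axis shifts (float ties)
  guard <- 1 - 1e-9
  ms <- starts[1]; me <- ends[1]; mi1 <- i1[1]; mi2 <- i2[1]
  out <- list()
  for (j in seq_along(starts)[-1]) {
    if (starts[j] - me < params$merge_gap_s * guard) {
      me <- ends[j]
      mi2 <- i2[j]
    } else {
      out[[length(out) + 1L]] <- c(ms, me, mi1, mi2)
      ms <- starts[j]; me <- ends[j]; mi1 <- i1[j]; mi2 <- i2[j]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me, mi1, mi2)
  m <- do.call(rbind, out)

  keep <- (m[, 2] - m[, 1]) >= params$min_event_duration_s * guard
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)

  peak <- vapply(seq_len(nrow(m)),
                 function(i) max(resid[m[i, 3]:m[i, 4]]), numeric(1))
  data.frame(well_id = attr(trace, "well_id"),
             start_s = m[, 1], end_s = m[, 2],
             duration_s = m[, 2] - m[, 1],
             peak_amplitude = peak,
             stringsAsFactors = FALSE)
}

#' Summarize feeding contacts for one fly
#'
#' Restricts events to those intersecting the analysis window, clips them at
#' the window edges, and reports the number of contacts, total contact time,
#' and mean contact duration (0 when there are no contacts).
#'
#' @param events Event data frame as returned by [detect_events()].
#' @param window Length-2 numeric, analysis window `(start_s, end_s)`.
#' @return A one-row data frame with columns `well_id`, `n_contacts`,
#'   `total_contact_time_s`, `mean_contact_duration_s`.
#' @export
summarize_contacts <- function(events, window = c(0, 900)) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("parameter 'window' must be an ordered (start_s, end_s) pair",
         call. = FALSE)
  }
  well <- if (nrow(events) > 0) events$well_id[1] else NA_character_
  s <- pmax(events$start_s, window[1])
  e <- pmin(events$end_s, window[2])
  keep <- s < e
  durations <- (e - s)[keep]
  n <- length(durations)
  total <- sum(durations)
  data.frame(well_id = well,
             n_contacts = n,
             total_contact_time_s = total,
             mean_contact_duration_s = if (n > 0) total / n else 0,
             stringsAsFactors = FALSE)
}

#' Validate detected events against ground truth
#'
#' Greedy one-to-one matching in time order: walking both sorted lists, a
#' detection and a truth interval match when they overlap or their boundary
#' distance is at most `tol` seconds; ties are resolved earliest-start first.
#' Reports the detection rate (matched over true) and false-positive rate
#' (unmatched detections over detections; defined as 0 when nothing was
#' detected).
#'
#' @param detected Event data frame (columns `start_s`, `end_s`), sorted.
#' @param truth Ground-truth data frame (columns `start_s`, `end_s`), sorted.
#' @param tol Matching tolerance in seconds (default 0.5).
#' @return An object of class `flic_validation`: a list with `n_true`,
#'   `n_detected`, `n_matched`, `detection_rate`, `false_positive_rate`.
#' @export
validate_events <- function(detected, truth, tol = 0.5) {
  check_number(tol, "tol", lower = 0)
  nd <- nrow(detected)
  nt <- nrow(truth)
  i <- 1L  # truth pointer
  j <- 1L  # detection pointer
  matched <- 0L
  while (i <= nt && j <= nd) {
    gap <- max(truth$start_s[i] - detected$end_s[j],
               detected$start_s[j] - truth$end_s[i])
    if (gap <= tol) {
      matched <- matched + 1L
      i <- i + 1L
      j <- j + 1L
    } else if (truth$end_s[i] < detected$end_s[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  structure(
    list(n_true = nt, n_detected = nd, n_matched = matched,
         detection_rate = if (nt > 0) matched / nt else 1,
         false_positive_rate = if (nd > 0) (nd - matched) / nd else 0),
    class = "flic_validation")
}

#' @export
print.flic_validation <- function(x, ...) {
  cat(sprintf(
    "FLIC validation: %d true, %d detected, %d matched\n  detection rate %.1f%%, false-positive rate %.1f%%\n",
    x$n_true, x$n_detected, x$n_matched,
    100 * x$detection_rate, 100 * x$false_positive_rate))
  invisible(x)
}
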