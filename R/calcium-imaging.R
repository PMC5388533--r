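#' Construct an ROI fluorescence trace
#'
#' A `roi_trace` is a data frame of per-frame mean ROI intensities with
#' columns `frame`, `time_s`, `intensity`, and a logical `excluded` flag for
#' frames unusable because the preparation was out of focus. The stimulus
#' onset time can be carried as an attribute for convenience.
#'
#' @param frame Integer frame indices.
#' @param time_s Increasing frame times, seconds (nominally one frame per
#'   second).
#' @param intensity Non-negative mean ROI intensity per frame, a.u.
#' @param excluded Logical flag per frame; `TRUE` frames are dropped from all
#'   delta-F/F computations.
#' @param onset_s Optional stimulus onset, seconds.
#' @return A `roi_trace` data frame.
#' @export
new_roi_trace <- function(frame, time_s, intensity, excluded = FALSE,
                          onset_s = NA_real_) {
  n <- length(time_s)
  excluded <- rep_len(as.logical(excluded), n)
  if (length(frame) != n || length(intensity) != n) {
    stop("frame, time_s and intensity must have equal length", call. = FALSE)
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensity must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(frame = as.integer(frame), time_s = as.numeric(time_s),
               intensity = as.numeric(intensity), excluded = excluded),
    onset_s = onset_s,
    class = c("roi_trace", "data.frame"))
}

#' Read an ROI fluorescence CSV
#'
#' Expects columns `frame`, `time_s`, `intensity`, `excluded` (0/1); lines
#' starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @param onset_s Optional stimulus onset to attach to the trace.
#' @return A `roi_trace`.
#' @export
read_roi_csv <- function(path, onset_s = NA_real_) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "time_s", "intensity", "excluded")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  new_roi_trace(df$frame, df$time_s, df$intensity, df$excluded != 0,
                onset_s = onset_s)
}

resolve_onset <- function(trace, onset_s) {
  if (is.null(onset_s) || is.na(onset_s)) onset_s <- attr(trace, "onset_s")
  if (is.null(onset_s) || is.na(onset_s)) {
    stop("stimulus onset_s must be supplied (argument or trace attribute)",
         call. = FALSE)
  }
  if (onset_s <= min(trace$time_s) || onset_s > max(trace$time_s)) {
    stop("parameter 'onset_s' must lie within the recording", call. = FALSE)
  }
  onset_s
}

#' Baseline fluorescence before stimulus delivery
#'
#' Mean of the `n_baseline_frames` usable (non-excluded) frames nearest to,
#' and strictly before, the stimulus onset. When flagged frames fall in the
#' nominal baseline window, the window slides earlier until the required
#' number of usable frames is collected.
#'
#' @param trace A `roi_trace`.
#' @param onset_s Stimulus onset, seconds; defaults to the trace attribute.
#' @param n_baseline_frames Number of baseline frames averaged (default 10).
#' @return Baseline fluorescence F0, a.u.
#' @examples
#' tr <- gen_fluorescence_trace(ca_sim_config())
#' compute_f0(tr)
#' @export
compute_f0 <- function(trace, onset_s = NA_real_, n_baseline_frames = 10) {
  stopifnot(inherits(trace, "roi_trace"))
  onset_s <- resolve_onset(trace, onset_s)
  check_number(n_baseline_frames, "n_baseline_frames", lower = 1)
  pre <- trace$intensity[!trace$excluded & trace$time_s < onset_s]
  if (length(pre) < n_baseline_frames) {
    stop(sprintf(
      "insufficient baseline: %d usable pre-stimulus frames, need %d",
      length(pre), n_baseline_frames), call. = FALSE)
  }
  mean(utils::tail(pre, n_baseline_frames))
}

#' Per-bin maximum delta-F/F after stimulus onset
#'
#' Splits the post-stimulus recording into complete bins of `bin_width_s`
#' seconds aligned to the stimulus application time and reports, per bin, the
#' maximum fractional fluorescence change `(max F - F0) / F0` over the bin's
#' usable frames. Excluded (out-of-focus) frames are dropped; a bin whose
#' usable-frame fraction falls below `min_frame_fraction` is flagged
#' `low_coverage`, and a bin with no usable frames at all reports a missing
#' `dff` (never zero) with `n_frames_used = 0`.
#'
#' `bin_start_s` is expressed relative to stimulus onset, so 0 labels the
#' 0-29 s bin, 30 the 30-59 s bin, and so on.
#'
#' @param trace A `roi_trace`.
#' @param onset_s Stimulus onset, seconds; defaults to the trace attribute.
#' @param bin_width_s Bin width in seconds (default 30).
#' @param min_frame_fraction Minimum usable fraction of a bin's nominal frame
#'   count before it is flagged (default 2/3).
#' @param n_baseline_frames Baseline frames for F0 (default 10).
#' @return A data frame with columns `bin_start_s`, `dff`, `n_frames_used`,
#'   `low_coverage`.
#' @examples
#' tr <- gen_fluorescence_trace(ca_sim_config())
#' bin_dff(tr)
#' @export
bin_dff <- function(trace, onset_s = NA_real_, bin_width_s = 30,
                    min_frame_fraction = 2 / 3, n_baseline_frames = 10) {
  stopifnot(inherits(trace, "roi_trace"))
  onset_s <- resolve_onset(trace, onset_s)
  check_number(bin_width_s, "bin_width_s", lower = 0, strict_lower = TRUE)
  check_number(min_frame_fraction, "min_frame_fraction", lower = 0, upper = 1)
  f0 <- compute_f0(trace, onset_s, n_baseline_frames)
  if (f0 <= 0) stop("baseline fluorescence F0 must be positive", call. = FALSE)

  dt <- stats::median(diff(trace$time_s))
  t_end <- max(trace$time_s) + dt
  n_bins <- floor((t_end - onset_s) / bin_width_s)
  if (n_bins < 1L) {
    stop("recording too short for one complete bin after onset",
         call. = FALSE)
  }
  nominal <- round(bin_width_s / dt)

  res <- lapply(seq_len(n_bins) - 1L, function(k) {
    lo <- onset_s + k * bin_width_s
    hi <- lo + bin_width_s
    in_bin <- trace$time_s >= lo & trace$time_s < hi
    usable <- in_bin & !trace$excluded
    n_used <- sum(usable)
    dff <- if (n_used > 0) {
      (max(trace$intensity[usable]) - f0) / f0
    } else {
      NA_real_
    }
    data.frame(bin_start_s = k * bin_width_s, dff = dff,
               n_frames_used = n_used,
               low_coverage = n_used < min_frame_fraction * nominal)
  })
  do.call(rbind, res)
}

#' Group time course of binned delta-F/F responses
#'
#' Aggregates per-fly binned responses (all computed with the same bin
#' width) into a per-bin group mean, standard deviation, standard error, and
#' the number of flies contributing a non-missing value.
#'
#' @param responses A named list of per-fly data frames from [bin_dff()], or
#'   a single long data frame with a `fly_id` column.
#' @return A data frame with columns `bin_start_s`, `mean_dff`, `sd_dff`,
#'   `sem_dff`, `n`.
#' @export
response_timecourse <- function(responses) {
  if (is.data.frame(responses)) {
    if (!"fly_id" %in% names(responses)) {
      stop("long-format responses need a 'fly_id' column", call. = FALSE)
    }
    long <- responses
  } else {
    if (is.null(names(responses))) {
      names(responses) <- sprintf("fly_%02d", seq_along(responses))
    }
    widths <- vapply(responses, function(r) {
      b <- sort(unique(r$bin_start_s))
      if (length(b) > 1) b[2] - b[1] else NA_real_
    }, numeric(1))
    if (length(unique(stats::na.omit(widths))) > 1L) {
      stop("parameter error: all flies must be binned with the same width",
           call. = FALSE)
    }
    long <- do.call(rbind, Map(function(r, id) {
      r$fly_id <- id
      r
    }, responses, names(responses)))
  }
  bins <- sort(unique(long$bin_start_s))
  res <- lapply(bins, function(b) {
    v <- long$dff[long$bin_start_s == b]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(bin_start_s = b,
               mean_dff = if (n > 0) mean(v) else NA_real_,
               sd_dff = if (n > 1) stats::sd(v) else NA_real_,
               sem_dff = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, res)
}
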