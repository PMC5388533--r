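#' Configuration for simulated FLIC traces
#'
#' Bundles the parameters of the FLIC trace simulator. A simulated trace is
#' the sum of a constant baseline, a slow sinusoidal drift, per-sample
#' Gaussian noise, and square contact pulses of fixed amplitude. Contact
#' events arrive as a Poisson process in time and have lognormal durations,
#' so that genotypes differing in bout duration can be emulated by changing
#' the duration median alone.
#'
#' @param duration_s Recording length in seconds. The default, 900 s, is the
#'   15-minute analysis window used for freely feeding flies.
#' @param fs_hz Sampling rate of the sensor in samples per second.
#' @param baseline_level Constant signal offset, arbitrary units.
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift
#'   (a.u.); the drift period and phase are randomized per trace.
#' @param noise_sd Standard deviation of per-sample Gaussian noise (a.u.).
#' @param event_rate_per_min Expected number of contact events per minute.
#' @param bout_duration_median_s Median contact-event duration in seconds
#'   (lognormal location).
#' @param bout_duration_sigma Lognormal shape parameter of bout durations.
#' @param event_amplitude Height of the square contact pulse (a.u.).
#' @param genotype_label Free-text label carried through to outputs.
#' @param seed Integer seed making the trace reproducible; `NULL` uses the
#'   current RNG stream.
#'
#' @return An object of class `flic_sim_config` (a named list).
#' @seealso [gen_flic_trace()]
#' @export
flic_sim_config <- function(duration_s = 900,
                            fs_hz = 5,
                            baseline_level = 0,
                            drift_amplitude = 10,
                            noise_sd = 5,
                            event_rate_per_min = 2,
                            bout_duration_median_s = 2,
                            bout_duration_sigma = 0.5,
                            event_amplitude = 100,
                            genotype_label = "control",
                            seed = NULL) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  check_number(drift_amplitude, "drift_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(event_rate_per_min, "event_rate_per_min", lower = 0)
  check_number(bout_duration_median_s, "bout_duration_median_s",
               lower = 0, strict_lower = TRUE)
  check_number(bout_duration_sigma, "bout_duration_sigma", lower = 0)
  check_number(event_amplitude, "event_amplitude", lower = 0)
  check_number(baseline_level, "baseline_level")
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(duration_s = duration_s, fs_hz = fs_hz,
         baseline_level = baseline_level,
         drift_amplitude = drift_amplitude, noise_sd = noise_sd,
         event_rate_per_min = event_rate_per_min,
         bout_duration_median_s = bout_duration_median_s,
         bout_duration_sigma = bout_duration_sigma,
         event_amplitude = event_amplitude,
         genotype_label = as.character(genotype_label), seed = seed),
    class = "flic_sim_config")
}

#' Simulate one FLIC trace with known ground truth
#'
#' Generates a well's worth of capacitive-sensor signal plus the list of true
#' contact intervals that produced it. Event count is Poisson with mean
#' `event_rate_per_min / 60 * duration_s`, event starts are uniform over the
#' recording, and durations are lognormal. Simulated events that overlap are
#' merged into a single ground-truth interval (a fly cannot be in two
#' contacts at once), and events are clipped at the end of the recording.
#'
#' @param config A [flic_sim_config()] object.
#'
#' @return A list with components:
#'   \describe{
#'     \item{trace}{A `flic_trace` data frame with columns `time_s`, `signal`
#'       and attributes `well_id` and `genotype`.}
#'     \item{truth}{Data frame of merged true contact intervals with columns
#'       `start_s`, `end_s`.}
#'   }
#' @examples
#' sim <- gen_flic_trace(flic_sim_config(duration_s = 60, seed = 1))
#' nrow(sim$trace)   # 60 s * 5 Hz = 300 samples
#' @export
gen_flic_trace <- function(config) {
  if (!inherits(config, "flic_sim_config")) {
    stop("parameter 'config' must be a flic_sim_config object", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- round(config$duration_s * config$fs_hz)
    dt <- 1 / config$fs_hz
    time_s <- (seq_len(n) - 1) * dt

    n_ev <- stats::rpois(1, config$event_rate_per_min / 60 * config$duration_s)
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 0, config$duration_s))
      durs <- stats::rlnorm(n_ev,
                            meanlog = log(config$bout_duration_median_s),
                            sdlog = config$bout_duration_sigma)
      ends <- pmin(starts + durs, config$duration_s)
      truth <- merge_intervals(starts, ends)
    } else {
      truth <- data.frame(start_s = numeric(0), end_s = numeric(0))
    }

    if (config$drift_amplitude > 0) {
      period <- stats::runif(1, 200, 400)
      phase <- stats::runif(1, 0, 2 * pi)
      drift <- config$drift_amplitude * sin(2 * pi * time_s / period + phase)
    } else {
      drift <- numeric(n)
    }
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(n, 0, config$noise_sd)
    } else {
      numeric(n)
    }

    in_event <- rep(FALSE, n)
    for (i in seq_len(nrow(truth))) {
      in_event <- in_event |
        (time_s >= truth$start_s[i] & time_s < truth$end_s[i])
    }

    signal <- config$baseline_level + drift + noise +
      config$event_amplitude * as.numeric(in_event)

    trace <- new_flic_trace(time_s, signal,
                            well_id = paste0(config$genotype_label, "_w1"),
                            genotype = config$genotype_label)
    list(trace = trace, truth = truth)
  })
}

#' Configuration for simulated ROI fluorescence traces
#'
#' Parameters of the calcium-imaging trace simulator. The underlying response
#' model is `F(t) = f0 * (1 + A * g(t - onset)) + noise` with
#' `g(u) = (1 - exp(-u/tau_rise)) * exp(-u/tau_decay)` for `u >= 0` (zero
#' before onset), normalized to unit maximum, so `A` is the peak fractional
#' change in fluorescence. With the default kinetics (`tau_rise_s = 13`,
#' `tau_decay_s = 120`) the noiseless response peaks about 30 s after
#' stimulus onset. Frames falling in `refocus_gaps` are flagged excluded,
#' mimicking the 5-10 s windows lost to refocusing an imaging preparation.
#'
#' The recording spans `onset_s + duration_s` seconds: a pre-stimulus
#' segment long enough to supply the 10 baseline frames, followed by
#' `duration_s` (default 300 s, i.e. 5 min) of post-stimulus recording.
#'
#' @param frame_rate_hz Frames per second (default 1, one confocal frame per
#'   second).
#' @param duration_s Post-stimulus recording length in seconds (default 300).
#' @param f0 True baseline fluorescence, a.u.; must be positive.
#' @param response_amplitude Peak delta-F/F of the response (0 emulates a
#'   water-like null stimulus).
#' @param onset_s Stimulus application time; also the length of the
#'   pre-stimulus baseline segment.
#' @param tau_rise_s,tau_decay_s Rise and decay time constants, seconds;
#'   rise must be shorter than decay.
#' @param noise_sd Per-frame Gaussian noise, a.u.
#' @param refocus_gaps List of `c(start_s, end_s)` windows whose frames are
#'   marked excluded.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#'
#' @return An object of class `ca_sim_config`.
#' @seealso [gen_fluorescence_trace()]
#' @export
ca_sim_config <- function(frame_rate_hz = 1,
                          duration_s = 300,
                          f0 = 100,
                          response_amplitude = 1,
                          onset_s = 30,
                          tau_rise_s = 13,
                          tau_decay_s = 120,
                          noise_sd = 0,
                          refocus_gaps = list(),
                          seed = NULL) {
  check_number(frame_rate_hz, "frame_rate_hz", lower = 0, strict_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(f0, "f0", lower = 0, strict_lower = TRUE)
  check_number(response_amplitude, "response_amplitude", lower = 0)
  check_number(onset_s, "onset_s", lower = 0, strict_lower = TRUE)
  check_number(tau_rise_s, "tau_rise_s", lower = 0, strict_lower = TRUE)
  check_number(tau_decay_s, "tau_decay_s", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (tau_rise_s >= tau_decay_s) {
    stop("parameter 'tau_rise_s' must be smaller than 'tau_decay_s'",
         call. = FALSE)
  }
  total <- onset_s + duration_s
  for (g in refocus_gaps) {
    if (length(g) != 2L || g[1] >= g[2] || g[1] < 0 || g[2] > total) {
      stop("parameter 'refocus_gaps' entries must be ordered (start_s, end_s) pairs inside the recording",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(frame_rate_hz = frame_rate_hz, duration_s = duration_s, f0 = f0,
         response_amplitude = response_amplitude, onset_s = onset_s,
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         noise_sd = noise_sd, refocus_gaps = refocus_gaps, seed = seed),
    class = "ca_sim_config")
}

# closed-form peak latency of the rise-decay kernel, seconds after onset
ca_peak_latency <- function(tau_rise_s, tau_decay_s) {
  tau_rise_s * log(1 + tau_decay_s / tau_rise_s)
}

#' Simulate an ROI fluorescence trace
#'
#' Produces a per-frame intensity time series following the rise-decay
#' response model of [ca_sim_config()], with frames inside the configured
#' refocusing gaps flagged as excluded.
#'
#' @param config A [ca_sim_config()] object.
#' @return A `roi_trace` data frame with columns `frame`, `time_s`,
#'   `intensity`, `excluded` and attribute `onset_s`.
#' @examples
#' tr <- gen_fluorescence_trace(ca_sim_config(seed = 1))
#' head(tr)
#' @export
gen_fluorescence_trace <- function(config) {
  if (!inherits(config, "ca_sim_config")) {
    stop("parameter 'config' must be a ca_sim_config object", call. = FALSE)
  }
  with_seed(config$seed, {
    dt <- 1 / config$frame_rate_hz
    total <- config$onset_s + config$duration_s
    n <- round(total * config$frame_rate_hz)
    time_s <- (seq_len(n) - 1) * dt

    u <- time_s - config$onset_s
    g <- ifelse(u >= 0,
                (1 - exp(-u / config$tau_rise_s)) *
                  exp(-u / config$tau_decay_s),
                0)
    upeak <- ca_peak_latency(config$tau_rise_s, config$tau_decay_s)
    gmax <- (1 - exp(-upeak / config$tau_rise_s)) *
      exp(-upeak / config$tau_decay_s)
    g <- g / gmax

    noise <- if (config$noise_sd > 0) {
      stats::rnorm(n, 0, config$noise_sd)
    } else {
      numeric(n)
    }
    intensity <- config$f0 * (1 + config$response_amplitude * g) + noise

    excluded <- rep(FALSE, n)
    for (gap in config$refocus_gaps) {
      excluded <- excluded | (time_s >= gap[1] & time_s < gap[2])
    }

    new_roi_trace(frame = seq_len(n) - 1L, time_s = time_s,
                  intensity = intensity, excluded = excluded,
                  onset_s = config$onset_s)
  })
}

#' Configuration for simulated pharyngeal-pumping cohorts
#'
#' Parameters of the dye-feeding cohort simulator. Each fly feeds for a
#' uniformly drawn time, swallows at a per-fly rate, and ingests volume at a
#' per-fly ingestion rate; both per-fly rates are lognormal with the stated
#' mean and coefficient of variation. The dye readout is linear in ingested
#' volume: `OD = absorptivity * volume_ul + background + noise`.
#'
#' Defaults mirror a wild-type sucrose cohort: 140 flies pooled across
#' concentrations, mean ingestion rate 8 nl/s (use 7.8 nl/s to emulate the
#' overconsuming mutant), pump rate 2 swallows/s with CV 0.13, and the
#' erioglaucine calibration slope 0.14 OD per microliter.
#'
#' @param n_flies Number of flies in the cohort.
#' @param ingestion_rate_nl_s Mean per-fly ingestion rate, nanoliters per
#'   second.
#' @param ingestion_rate_cv Coefficient of variation of the per-fly
#'   ingestion rate.
#' @param pump_rate_hz Mean per-fly swallowing rate, swallows per second.
#' @param pump_rate_cv Coefficient of variation of the per-fly pump rate.
#' @param feeding_time_range_s Length-2 vector, uniform bounds on per-fly
#'   total feeding time, seconds.
#' @param dye_absorptivity_od_per_ul Calibration slope converting microliters
#'   of dyed food into OD630 units.
#' @param background_od Endogenous extract absorbance added to every reading.
#' @param od_noise_sd Gaussian noise on the OD reading.
#' @param genotype_label Label carried into the output table.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#'
#' @return An object of class `pump_sim_config`.
#' @seealso [gen_pumping_cohort()]
#' @export
pump_sim_config <- function(n_flies = 140,
                            ingestion_rate_nl_s = 8,
                            ingestion_rate_cv = 0.21,
                            pump_rate_hz = 2,
                            pump_rate_cv = 0.13,
                            feeding_time_range_s = c(5, 60),
                            dye_absorptivity_od_per_ul = 0.14,
                            background_od = 0.07,
                            od_noise_sd = 0.005,
                            genotype_label = "control",
                            seed = NULL) {
  check_number(n_flies, "n_flies", lower = 0, strict_lower = TRUE)
  check_number(ingestion_rate_nl_s, "ingestion_rate_nl_s",
               lower = 0, strict_lower = TRUE)
  check_number(ingestion_rate_cv, "ingestion_rate_cv", lower = 0)
  check_number(pump_rate_hz, "pump_rate_hz", lower = 0, strict_lower = TRUE)
  check_number(pump_rate_cv, "pump_rate_cv", lower = 0)
  if (length(feeding_time_range_s) != 2L ||
      !all(is.finite(feeding_time_range_s)) ||
      feeding_time_range_s[1] <= 0 ||
      feeding_time_range_s[1] > feeding_time_range_s[2]) {
    stop("parameter 'feeding_time_range_s' must be positive ordered bounds",
         call. = FALSE)
  }
  check_number(dye_absorptivity_od_per_ul, "dye_absorptivity_od_per_ul",
               lower = 0, strict_lower = TRUE)
  check_number(background_od, "background_od", lower = 0)
  check_number(od_noise_sd, "od_noise_sd", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(n_flies = as.integer(n_flies),
         ingestion_rate_nl_s = ingestion_rate_nl_s,
         ingestion_rate_cv = ingestion_rate_cv,
         pump_rate_hz = pump_rate_hz, pump_rate_cv = pump_rate_cv,
         feeding_time_range_s = feeding_time_range_s,
         dye_absorptivity_od_per_ul = dye_absorptivity_od_per_ul,
         background_od = background_od, od_noise_sd = od_noise_sd,
         genotype_label = as.character(genotype_label), seed = seed),
    class = "pump_sim_config")
}

# lognormal draws with a given arithmetic mean and CV; CV 0 degenerates to
# the mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate a pharyngeal-pumping / dye-feeding cohort
#'
#' Draws per-fly feeding times, swallow counts, ingested volumes and dye
#' OD630 readings under the model of [pump_sim_config()].
#'
#' @param config A [pump_sim_config()] object.
#' @return A data frame with one row per fly and columns `fly_id`,
#'   `genotype`, `feeding_time_s`, `swallow_count`, `true_volume_nl`,
#'   `od_reading`, plus the latent per-fly rates `true_pump_rate_hz` and
#'   `true_ingestion_rate_nl_s` for ground-truth checks.
#' @examples
#' cohort <- gen_pumping_cohort(pump_sim_config(n_flies = 5, seed = 1))
#' cohort$true_volume_nl / cohort$feeding_time_s  # per-fly ingestion rates
#' @export
gen_pumping_cohort <- function(config) {
  if (!inherits(config, "pump_sim_config")) {
    stop("parameter 'config' must be a pump_sim_config object", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_flies
    t_feed <- stats::runif(n, config$feeding_time_range_s[1],
                           config$feeding_time_range_s[2])
    pump_rate <- rlnorm_mean_cv(n, config$pump_rate_hz, config$pump_rate_cv)
    ingest_rate <- rlnorm_mean_cv(n, config$ingestion_rate_nl_s,
                                  config$ingestion_rate_cv)
    swallows <- round(pump_rate * t_feed)
    volume_nl <- ingest_rate * t_feed
    od <- config$dye_absorptivity_od_per_ul * (volume_nl / 1000) +
      config$background_od +
      (if (config$od_noise_sd > 0) stats::rnorm(n, 0, config$od_noise_sd)
       else 0)
    data.frame(
      fly_id = sprintf("%s_%03d", config$genotype_label, seq_len(n)),
      genotype = config$genotype_label,
      feeding_time_s = t_feed,
      swallow_count = swallows,
      true_volume_nl = volume_nl,
      od_reading = od,
      true_pump_rate_hz = pump_rate,
      true_ingestion_rate_nl_s = ingest_rate,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a two-fold dye dilution standard
#'
#' Generates replicate OD630 readings for a serial two-fold dilution series
#' of the reference dye, the input expected by [fit_standard_curve()]. Levels
#' run from `top_level` down by factors of two; each replicate reading is the
#' true linear response plus Gaussian noise.
#'
#' @param absorptivity_od_per_ul True calibration slope, OD per microliter
#'   equivalent of the reference dye solution.
#' @param n_levels Number of dilution levels (default 10).
#' @param n_replicates Readings per level (default 3).
#' @param top_level Highest level, in microliter-equivalents (default 1).
#' @param noise_sd Gaussian noise on each reading, OD units.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A data frame with columns `level`, `replicate`, `od`.
#' @export
gen_dilution_standard <- function(absorptivity_od_per_ul = 0.14,
                                  n_levels = 10,
                                  n_replicates = 3,
                                  top_level = 1,
                                  noise_sd = 0.005,
                                  seed = NULL) {
  check_number(absorptivity_od_per_ul, "absorptivity_od_per_ul",
               lower = 0, strict_lower = TRUE)
  check_number(n_levels, "n_levels", lower = 1)
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(top_level, "top_level", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    levels <- top_level / 2^(seq_len(n_levels) - 1)
    grid <- expand.grid(replicate = seq_len(n_replicates), level = levels)
    od <- absorptivity_od_per_ul * grid$level +
      (if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0)
    data.frame(level = grid$level, replicate = grid$replicate, od = od)
  })
}
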