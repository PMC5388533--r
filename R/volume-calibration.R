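#' Fit the dye-absorbance standard curve
#'
#' Through-origin least-squares fit of mean OD630 against dilution level for
#' a serial two-fold dilution standard of the reference dye. The slope alone
#' is used downstream to convert extract absorbances into ingested volumes,
#' so no intercept is fitted; the root-mean-square residual of the level
#' means about the fitted line is recorded so the through-origin choice can
#' be audited.
#'
#' @param standard Data frame with columns `level` (microliter-equivalents of
#'   the reference dye solution, a two-fold series) and `od` (replicate OD630
#'   readings; at least 3 per level), e.g. from [gen_dilution_standard()].
#' @return An object of class `standard_curve`: list with `slope` (OD per
#'   microliter), `fit_residual` (RMS of level-mean residuals), `n_levels`.
#' @examples
#' std <- gen_dilution_standard(seed = 3)
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(standard) {
  if (!is.data.frame(standard) || !all(c("level", "od") %in% names(standard))) {
    stop("parameter 'standard' must have columns 'level' and 'od'",
         call. = FALSE)
  }
  levels <- sort(unique(standard$level), decreasing = TRUE)
  if (any(levels <= 0)) {
    stop("parameter 'standard' levels must be positive", call. = FALSE)
  }
  if (length(levels) > 1L) {
    ratios <- levels[-length(levels)] / levels[-1]
    if (any(abs(ratios - 2) > 1e-6)) {
      warning("dilution levels are not a two-fold series", call. = FALSE)
    }
  }
  mean_od <- vapply(levels, function(l) mean(standard$od[standard$level == l]),
                    numeric(1))
  if (all(mean_od == 0)) {
    stop("degenerate fit: all OD readings are zero", call. = FALSE)
  }
  slope <- sum(levels * mean_od) / sum(levels^2)
  resid <- mean_od - slope * levels
  structure(
    list(slope = slope,
         fit_residual = sqrt(mean(resid^2)),
         n_levels = length(levels)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f OD/ul (%d levels, RMS residual %.4g)\n",
              x$slope, x$n_levels, x$fit_residual))
  invisible(x)
}

#' Endogenous-absorbance background from dye-free control flies
#'
#' Mean of the per-fly mean OD630 readings of control flies fed without dye;
#' this standard value is subtracted from every dyed-fly reading before
#' volume conversion.
#'
#' @param control_ods Numeric vector of per-fly mean OD630 values (one per
#'   control fly; at least one required).
#' @return Background OD630, a single number.
#' @export
background_od <- function(control_ods) {
  if (length(control_ods) < 1L || !is.numeric(control_ods) ||
      anyNA(control_ods)) {
    stop("parameter 'control_ods' must be a non-empty numeric vector",
         call. = FALSE)
  }
  mean(control_ods)
}

#' Convert an extract OD reading into ingested volume
#'
#' `volume_ul = (mean_od - background) / slope`, clamped at zero: a reading
#' below the dye-free background is unphysical as a volume, so it converts to
#' 0 with a `below_background` flag (and a warning) rather than a negative
#' volume.
#'
#' @param mean_od Per-fly mean OD630 (average of >= 4 replicate readings of
#'   the extract).
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param background Background OD630 from [background_od()] (default 0).
#' @param fly_id Optional identifier carried into the result.
#' @return A one-row data frame with columns `fly_id`, `volume_ul`,
#'   `below_background`.
#' @examples
#' curve <- fit_standard_curve(data.frame(level = c(1, 0.5), od = c(0.28, 0.14)))
#' od_to_volume(0.35, curve, background = 0.07)
#' @export
od_to_volume <- function(mean_od, curve, background = 0,
                         fly_id = NA_character_) {
  if (!inherits(curve, "standard_curve")) {
    stop("parameter 'curve' must be a standard_curve object", call. = FALSE)
  }
  if (curve$slope <= 0) {
    stop("parameter 'curve' slope must be positive", call. = FALSE)
  }
  check_number(mean_od, "mean_od")
  check_number(background, "background")
  net <- mean_od - background
  below <- net < 0
  if (below) {
    warning(sprintf("reading %.4g is below background %.4g; volume clamped to 0",
                    mean_od, background), call. = FALSE)
  }
  data.frame(fly_id = fly_id,
             volume_ul = max(0, net) / curve$slope,
             below_background = below,
             stringsAsFactors = FALSE)
}

#' Regress ingested volume on feeding time
#'
#' Ordinary least-squares fit of per-fly ingested volume (nanoliters)
#' against total feeding time (seconds). The slope estimates the cohort's
#' ingestion rate in nl/s; `r_squared` is the squared Pearson correlation.
#'
#' @param feeding_time_s Numeric vector of per-fly feeding times, seconds
#'   (all positive).
#' @param volume_nl Numeric vector of per-fly ingested volumes, nanoliters.
#' @return An object of class `rate_fit`: list with `slope_nl_per_s`,
#'   `intercept_nl`, `r_squared`, `n`.
#' @examples
#' t <- c(10, 20, 30); v <- c(60, 140, 260)
#' fit_rate(t, v)$slope_nl_per_s  # 10 nl/s
#' @export
fit_rate <- function(feeding_time_s, volume_nl) {
  if (length(feeding_time_s) != length(volume_nl)) {
    stop("feeding_time_s and volume_nl must have equal length", call. = FALSE)
  }
  if (length(feeding_time_s) < 3L) {
    stop("parameter error: need at least 3 flies to fit a rate",
         call. = FALSE)
  }
  if (any(feeding_time_s <= 0)) {
    stop("parameter 'feeding_time_s' must be positive", call. = FALSE)
  }
  if (stats::var(feeding_time_s) == 0) {
    stop("degenerate fit: feeding times have zero variance", call. = FALSE)
  }
  fit <- stats::lm(volume_nl ~ feeding_time_s)
  r2 <- if (stats::var(volume_nl) == 0) {
    0
  } else {
    stats::cor(feeding_time_s, volume_nl)^2
  }
  structure(
    list(slope_nl_per_s = unname(stats::coef(fit)[2]),
         intercept_nl = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n = length(feeding_time_s)),
    class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Ingestion-rate fit: %.2f nl/s (R^2 = %.2f, n = %d)\n",
              x$slope_nl_per_s, x$r_squared, x$n))
  invisible(x)
}
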