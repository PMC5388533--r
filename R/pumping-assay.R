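#' Construct a pharyngeal-pumping session record
#'
#' One immobilized fly's session: the pre-test water consumption time, the
#' ordered outcomes of the food presentations, and the scored feeding bouts
#' (duration and swallow count per bout, scored manually from video).
#'
#' Presentation outcomes are encoded as a single string, one character per
#' presentation: `I` or `Y` for an initiated bout, `N` for a refusal (e.g.
#' `"NNIY"`). The 2 s offer / 3 s rest presentation timing is metadata only
#' and enters no computation.
#'
#' @param fly_id Fly identifier.
#' @param genotype Genotype label.
#' @param stimulus Stimulus description (e.g. `"sucrose"`).
#' @param stimulus_mM Stimulus concentration, millimolar.
#' @param water_test_s Seconds the fly drank water in the pre-test.
#' @param presentations Outcome string as above; must be non-empty.
#' @param bout_duration_s Numeric vector of bout durations, seconds.
#' @param swallow_count Integer vector of swallows per bout, same length.
#' @return An object of class `pump_session`.
#' @export
pump_session <- function(fly_id, genotype = NA_character_,
                         stimulus = "sucrose", stimulus_mM = NA_real_,
                         water_test_s = 0, presentations = "I",
                         bout_duration_s = numeric(0),
                         swallow_count = integer(0)) {
  check_number(water_test_s, "water_test_s", lower = 0)
  presentations <- toupper(as.character(presentations))
  if (is.na(presentations) || nchar(presentations) == 0L) {
    stop("parameter 'presentations' must be a non-empty outcome string",
         call. = FALSE)
  }
  if (grepl("[^INY]", presentations)) {
    stop("parameter 'presentations' may contain only I, Y (initiated) or N (refused)",
         call. = FALSE)
  }
  if (length(bout_duration_s) != length(swallow_count)) {
    stop("bout_duration_s and swallow_count must have equal length",
         call. = FALSE)
  }
  if (any(bout_duration_s <= 0)) {
    stop("parameter 'bout_duration_s' must be positive", call. = FALSE)
  }
  if (any(swallow_count < 1)) {
    stop("parameter 'swallow_count' must be >= 1 within accepted bouts",
         call. = FALSE)
  }
  structure(
    list(fly_id = as.character(fly_id), genotype = as.character(genotype),
         stimulus = as.character(stimulus), stimulus_mM = stimulus_mM,
         water_test_s = water_test_s, presentations = presentations,
         bout_duration_s = as.numeric(bout_duration_s),
         swallow_count = as.integer(swallow_count)),
    class = "pump_session")
}

#' Apply session inclusion rules
#'
#' A session is excluded when the fly consumed water for longer than 10 s in
#' the pre-test (strictly greater; exactly 10 s passes), or when it failed to
#' initiate feeding within the first four food presentations
#' (a non-responder). Otherwise it is included.
#'
#' @param session A [pump_session()].
#' @param water_limit_s Water pre-test cutoff, seconds (default 10).
#' @param max_presentations Number of refused presentations that marks a
#'   non-responder (default 4).
#' @return A list with `included` (logical) and `reason` (one of `"none"`,
#'   `"water_over_10s"`, `"non_responder"`).
#' @export
apply_inclusion_rules <- function(session, water_limit_s = 10,
                                  max_presentations = 4) {
  stopifnot(inherits(session, "pump_session"))
  if (session$water_test_s < 0) {
    stop("data error: negative water_test_s", call. = FALSE)
  }
  if (session$water_test_s > water_limit_s) {
    return(list(included = FALSE, reason = "water_over_10s"))
  }
  outcomes <- strsplit(session$presentations, "")[[1]]
  first <- utils::head(outcomes, max_presentations)
  initiated <- any(first %in% c("I", "Y"))
  if (!initiated) {
    return(list(included = FALSE, reason = "non_responder"))
  }
  list(included = TRUE, reason = "none")
}

#' Summarize one included pumping session
#'
#' Total feeding time is the sum of bout durations, total swallows the sum of
#' per-bout counts, and the pumping rate their ratio in swallows per second.
#' Calling this on an excluded session, or on a session without bouts, is a
#' usage error; filter with [apply_inclusion_rules()] first.
#'
#' @param session A [pump_session()] that passes the inclusion rules.
#' @return A one-row data frame with columns `fly_id`, `genotype`,
#'   `stimulus_mM`, `included`, `exclusion_reason`, `total_feeding_time_s`,
#'   `total_swallows`, `pumping_rate_hz`.
#' @export
summarize_session <- function(session) {
  stopifnot(inherits(session, "pump_session"))
  incl <- apply_inclusion_rules(session)
  if (!incl$included) {
    stop(sprintf("usage error: session %s is excluded (%s)",
                 session$fly_id, incl$reason), call. = FALSE)
  }
  if (length(session$bout_duration_s) == 0L) {
    stop(sprintf("usage error: included session %s has no scored bouts",
                 session$fly_id), call. = FALSE)
  }
  total_t <- sum(session$bout_duration_s)
  total_sw <- sum(session$swallow_count)
  data.frame(fly_id = session$fly_id, genotype = session$genotype,
             stimulus_mM = session$stimulus_mM,
             included = TRUE, exclusion_reason = "none",
             total_feeding_time_s = total_t,
             total_swallows = total_sw,
             pumping_rate_hz = total_sw / total_t,
             stringsAsFactors = FALSE)
}

#' Summarize a list of sessions, applying inclusion rules
#'
#' Excluded sessions appear in the output with their exclusion reason and
#' missing summary fields, so they never contribute to aggregates but remain
#' auditable.
#'
#' @param sessions List of [pump_session()] objects.
#' @return A data frame with one row per session (columns as in
#'   [summarize_session()]).
#' @export
summarize_sessions <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    incl <- apply_inclusion_rules(s)
    if (incl$included) {
      summarize_session(s)
    } else {
      data.frame(fly_id = s$fly_id, genotype = s$genotype,
                 stimulus_mM = s$stimulus_mM,
                 included = FALSE, exclusion_reason = incl$reason,
                 total_feeding_time_s = NA_real_,
                 total_swallows = NA_integer_,
                 pumping_rate_hz = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Pooled correlation across included flies
#'
#' Squared Pearson correlation between two summary fields over the included
#' sessions only (e.g. total swallows against total feeding time, pooled
#' across stimulus concentrations).
#'
#' @param summaries Data frame from [summarize_sessions()] (or any data frame
#'   with an `included` column and the two fields).
#' @param x,y Column names to correlate.
#' @return A list with `r_squared` and `n` (number of included flies used).
#' @export
pooled_correlation <- function(summaries, x = "total_feeding_time_s",
                               y = "total_swallows") {
  if (!all(c(x, y, "included") %in% names(summaries))) {
    stop(sprintf("summaries must contain columns '%s', '%s', 'included'",
                 x, y), call. = FALSE)
  }
  keep <- summaries$included & !is.na(summaries[[x]]) & !is.na(summaries[[y]])
  xs <- summaries[[x]][keep]
  ys <- summaries[[y]][keep]
  if (length(xs) < 3L) {
    stop("parameter error: need at least 3 included flies", call. = FALSE)
  }
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("degenerate correlation: zero variance", call. = FALSE)
  }
  list(r_squared = stats::cor(xs, ys)^2, n = length(xs))
}

#' Read pumping sessions from CSV
#'
#' One row per bout, with fly-level fields repeated on each row: `fly_id`,
#' `genotype`, `stimulus_mM`, `water_test_s`, `presentations` (outcome
#' string, e.g. `"NNIY"`), `bout_duration_s`, `swallow_count`. Flies without
#' bouts carry a single row with empty bout fields.
#'
#' @param path Path to the CSV file.
#' @return A list of [pump_session()] objects.
#' @export
read_sessions_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(presentations = "character"))
  need <- c("fly_id", "water_test_s", "presentations",
            "bout_duration_s", "swallow_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- unique(df$fly_id)
  lapply(ids, function(id) {
    rows <- df[df$fly_id == id, , drop = FALSE]
    has_bouts <- !all(is.na(rows$bout_duration_s))
    pump_session(
      fly_id = id,
      genotype = if ("genotype" %in% names(rows)) rows$genotype[1] else NA,
      stimulus_mM = if ("stimulus_mM" %in% names(rows)) rows$stimulus_mM[1] else NA_real_,
      water_test_s = rows$water_test_s[1],
      presentations = rows$presentations[1],
      bout_duration_s = if (has_bouts) rows$bout_duration_s else numeric(0),
      swallow_count = if (has_bouts) rows$swallow_count else integer(0))
  })
}
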