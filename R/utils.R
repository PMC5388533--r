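# internal helpers shared across modules

# scalar validation; `what` names the offending field in the error message
check_number <- function(x, what, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("parameter '%s' must be supplied", what), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", what),
         call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) {
      stop(sprintf("parameter '%s' must be > %g (got %g)", what, lower, x),
           call. = FALSE)
    }
  } else if (x < lower) {
    stop(sprintf("parameter '%s' must be >= %g (got %g)", what, lower, x),
         call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("parameter '%s' must be <= %g (got %g)", what, upper, x),
         call. = FALSE)
  }
  invisible(NULL)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state;
# a NULL seed leaves the RNG stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# merge sorted/unsorted intervals that overlap or touch; returns a data.frame
# with strictly separated, ordered intervals
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}
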