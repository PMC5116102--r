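# Internal helpers shared across modules.
#
# All minute indices used in scoring output are 0-based and intervals are
# half-open [start, end), so duration = end - start with no off-by-one
# adjustments anywhere.

# Maximal runs of TRUE/FALSE in a logical vector.
# Returns a data.frame with 0-based half-open [start, end) and the run value.
logical_runs <- function(x) {
  stopifnot(is.logical(x))
  if (length(x) == 0L) {
    return(data.frame(start = integer(), end = integer(), value = logical()))
  }
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(start = c(0L, end[-length(end)]), end = end, value = r$values)
}

# Half-open interval overlap test (vectorised over the first pair).
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format minutes-from-start as ISO 8601 given a POSIXct origin.
minutes_to_iso <- function(start_time, minute_idx) {
  format(start_time + 60 * minute_idx, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
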