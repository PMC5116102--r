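# Construction of model-ready labeled instances from scored recordings.
#
# Each instance pairs one continuous awake-activity vector X = (x_1 ... x_T)
# with the good/poor label of the immediately following sleep period; a
# subject contributes one instance per scored night.

#' Segment awake/sleep pairs into labeled instances
#'
#' For each scored sleep period, the activity between the previous period's
#' awakening (or the series start) and this period's bedtime becomes the
#' input vector; the period's quality label becomes the target. Instances
#' shorter than `min_awake_min` are dropped, as are periods flagged as
#' nonwear when the periods were scored in `"exclude"` mode.
#'
#' @param periods A `sleep_periods` data frame from [score_recording()].
#' @param series The [minute_series()] the periods were scored from.
#' @param min_awake_min Minimum awake-vector length in minutes (default 60).
#' @return List of instances, each a list with `subject_id`, `x` (numeric
#'   awake-activity vector), `label` (`"good"`/`"poor"`) and `T` (length).
#' @export
segment_awake_pairs <- function(periods, series, min_awake_min = 60L) {
  stopifnot(inherits(series, "minute_series"))
  exclude_nonwear <- identical(attr(periods, "nonwear_mode"), "exclude")
  out <- list()
  prev_awakening <- 0L
  for (i in seq_len(nrow(periods))) {
    start <- prev_awakening
    end <- periods$bedtime[i]
    prev_awakening <- periods$awakening[i]
    if (exclude_nonwear && periods$nonwear_flag[i]) next
    if (end - start < min_awake_min) next
    out[[length(out) + 1L]] <- list(
      subject_id = periods$subject_id[i],
      x = series$counts[(start + 1L):end],
      label = periods$label[i],
      T = end - start)
  }
  out
}

# Largest-remainder allocation of n items to ratio-sized groups.
allocate_counts <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Assigns instances to partitions at random while keeping the class mix of
#' the target label even across partitions: within each class, the shuffled
#' instances are allocated to the three partitions by largest-remainder
#' rounding of the ratios, so per-class counts match the ratios to within
#' one instance.
#'
#' With `unit = "subject"` whole subjects are assigned to one partition
#' (shuffled subjects fill the partitions up to the ratio targets), so no
#' individual contributes instances to more than one set. This avoids
#' within-subject leakage at the price of only approximate ratios and class
#' balance.
#'
#' @param instances List of instances from [segment_awake_pairs()].
#' @param ratios Length-3 numeric vector of train/validation/test fractions
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed making the assignment reproducible.
#' @param min_per_class Minimum instances required per class (default 10).
#' @param unit `"instance"` (default) or `"subject"`.
#' @return List of class `data_split` with integer index vectors `train`,
#'   `validation`, `test`, plus `ratios` and `seed`.
#' @export
stratified_split <- function(instances, ratios = c(0.70, 0.15, 0.15), seed = 1L,
                             min_per_class = 10L,
                             unit = c("instance", "subject")) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  unit <- match.arg(unit)
  labels <- vapply(instances, function(z) z$label, character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present to split")
  tab <- table(labels)
  if (any(tab < min_per_class)) {
    stop("need at least ", min_per_class, " instances per class; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  set.seed(seed)
  parts <- list(train = integer(), validation = integer(), test = integer())
  if (unit == "instance") {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      counts <- allocate_counts(length(idx), ratios)
      grp <- rep.int(1:3, counts)
      parts$train <- c(parts$train, idx[grp == 1L])
      parts$validation <- c(parts$validation, idx[grp == 2L])
      parts$test <- c(parts$test, idx[grp == 3L])
    }
  } else {
    subj <- vapply(instances, function(z) z$subject_id, character(1))
    ids <- sample(unique(subj))
    targets <- length(instances) * ratios / sum(ratios)
    filled <- c(0, 0, 0)
    for (id in ids) {
      k <- which.max(targets - filled)
      idx <- which(subj == id)
      parts[[k]] <- c(parts[[k]], idx)
      filled[k] <- filled[k] + length(idx)
    }
  }
  structure(list(train = sort(parts$train), validation = sort(parts$validation),
                 test = sort(parts$test), ratios = ratios, seed = seed),
            class = "data_split")
}

#' Pad or truncate instances to a fixed input length
#'
#' Fixed-input models (logistic regression, MLP, CNN) need equal-length
#' vectors. Shorter vectors are left-padded with zeros (the oldest end);
#' longer vectors keep their most recent `fixed_length_min` minutes — the
#' activity closest to bedtime is the plausibly informative tail.
#'
#' @param instances List of instances from [segment_awake_pairs()].
#' @param fixed_length_min Target length in minutes (default 960, i.e. 16 h).
#' @return List with numeric matrix `x` (instances by minutes), logical
#'   matrix `mask` (`TRUE` on real minutes), and character vector `label`.
#' @export
pad_or_truncate <- function(instances, fixed_length_min = 960L) {
  stopifnot(fixed_length_min > 0)
  n <- length(instances)
  x <- matrix(0, n, fixed_length_min)
  mask <- matrix(FALSE, n, fixed_length_min)
  for (i in seq_len(n)) {
    v <- instances[[i]]$x
    if (length(v) >= fixed_length_min) {
      x[i, ] <- utils::tail(v, fixed_length_min)
      mask[i, ] <- TRUE
    } else {
      pad <- fixed_length_min - length(v)
      x[i, (pad + 1L):fixed_length_min] <- v
      mask[i, (pad + 1L):fixed_length_min] <- TRUE
    }
  }
  list(x = x, mask = mask,
       label = vapply(instances, function(z) z$label, character(1)))
}

#' Merge consecutive minutes into time-batched step vectors
#'
#' Recurrent models over minute-resolution awake periods face sequences a
#' thousand steps long. Time-batching merges `window_min` consecutive
#' minutes into one per-step input vector, shortening the sequence to
#' `ceiling(T / window_min)` steps; the final partial window is zero-padded.
#'
#' @param x Numeric awake-activity vector.
#' @param window_min Window length in minutes (default 15).
#' @return Numeric matrix with one row per step and `window_min` columns.
#' @export
time_batch <- function(x, window_min = 15L) {
  stopifnot(window_min >= 1)
  n_steps <- ceiling(length(x) / window_min)
  padded <- c(x, rep(0, n_steps * window_min - length(x)))
  matrix(padded, nrow = n_steps, ncol = window_min, byrow = TRUE)
}
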