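#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used in
#' printed results tables), unlike [round()]'s round-half-even. A tiny
#' guard (1e-9) absorbs binary representation error so that values printed
#' as exact ties round as a reader would expect.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

cv_from <- function(sd, mean, rounding) {
  if (rounding == "printed-table") {
    m <- round_half_up(mean, 2L)
    s <- round_half_up(sd, 2L)
    ifelse(m == 0, NA_real_, round_half_up(100 * s / m, 2L))
  } else {
    ifelse(mean == 0, NA_real_, 100 * sd / mean)
  }
}

#' Summary statistics of a measurement series
#'
#' The per-metric summary reported after multi-frame aggregation: count,
#' arithmetic mean, sample standard deviation (denominator n - 1),
#' coefficient of variation in percent, and the raw extremes.
#'
#' Under the default \code{"printed-table"} rounding policy the CV is formed
#' from the mean and SD each pre-rounded (half-up) to two decimals and is
#' itself reported to two decimals — this reproduces how CVs in printed
#' validation tables are derived from their printed operands. The
#' \code{"exact"} policy computes \code{100 * sd / mean} at full precision
#' for scientific use; on well-behaved series the two agree to within a few
#' hundredths of a percentage point.
#'
#' @param values numeric vector of measurements (length >= 2).
#' @param rounding \code{"printed-table"} (default) or \code{"exact"}.
#' @return An object of class \code{summary_stats}: list with \code{n},
#'   \code{mean}, \code{sd}, \code{cv}, \code{min}, \code{max},
#'   \code{rounding}. \code{mean}, \code{sd}, \code{min}, \code{max} are
#'   full precision; only \code{cv} is policy-dependent.
#' @export
summary_stats <- function(values, rounding = c("printed-table", "exact")) {
  rounding <- match.arg(rounding)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("insufficient data: summary statistics need at least 2 values, got ",
         length(values))
  }
  if (anyNA(values)) stop("values must not contain NA")
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(n = length(values), mean = m, sd = s,
         cv = cv_from(s, m, rounding),
         min = min(values), max = max(values), rounding = rounding),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d  mean = %.2f  sd = %.2f  cv = %.2f%%  range = [%g, %g]\n",
              x$n, x$mean, x$sd, x$cv, x$min, x$max))
  invisible(x)
}

#' Accumulated (running) statistics of a measurement series
#'
#' For each k the accumulated mean is the mean of the first k values. The
#' accumulated standard deviation is the \emph{sample SD of the running
#' means} \eqn{\bar{X}(1), \ldots, \bar{X}(k)} — a measure of how much the
#' running estimate is still moving — defined as 0 at k = 1. The
#' accumulated CV is \code{100 * sd_accum / mean_accum} under the rounding
#' policy of [summary_stats()]. The accumulated CV series is the input to
#' the repetitions-needed stabilization rule.
#'
#' @inheritParams summary_stats
#' @return data frame of class \code{accumulated_stats} with columns
#'   \code{k}, \code{mean_accum}, \code{sd_accum} (both full precision) and
#'   \code{cv_accum} (policy-dependent).
#' @seealso [repetitions_needed()]
#' @export
accumulated_stats <- function(values, rounding = c("printed-table", "exact")) {
  rounding <- match.arg(rounding)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("insufficient data: empty series")
  if (anyNA(values)) stop("values must not contain NA")
  means <- cumsum(values) / seq_len(n)
  sds <- vapply(seq_len(n), function(k) {
    if (k == 1L) 0 else stats::sd(means[seq_len(k)])
  }, numeric(1L))
  out <- data.frame(k = seq_len(n), mean_accum = means, sd_accum = sds,
                    cv_accum = cv_from(sds, means, rounding))
  class(out) <- c("accumulated_stats", "data.frame")
  attr(out, "rounding") <- rounding
  out
}

#' Number of repetitions needed to stabilize a measurement
#'
#' Applies a stabilization rule to an accumulated-CV series to find the
#' smallest number of repeated measurements (frames) after which the
#' accumulated coefficient of variation no longer changes materially — the
#' number of frames that must be averaged before the instrument's reading
#' can be accepted.
#'
#' Rules:
#' \describe{
#'   \item{\code{terminal-plateau}}{the smallest k >= 2 such that the CV,
#'     rounded half-up to two decimals, is identical for every repetition
#'     from k through the last. This is the reading a practitioner takes
#'     off a printed accumulated-CV table: the start of the final flat
#'     stretch.}
#'   \item{\code{delta-threshold}}{the smallest k such that max - min of
#'     the CV over the window \code{[k, k + window]} is at most
#'     \code{epsilon}.}
#' }
#'
#' @param x an [accumulated_stats()] data frame, or a numeric accumulated-CV
#'   series.
#' @param rule stabilization rule name.
#' @param epsilon,window parameters of the \code{delta-threshold} rule
#'   (CV percentage points; window length in repetitions).
#' @return An object of class \code{stabilization_result}: list with
#'   \code{k_stable} (NA when not stabilized), \code{stabilized},
#'   \code{rule}, \code{params} and \code{cv_series}.
#' @export
repetitions_needed <- function(x,
                               rule = c("terminal-plateau", "delta-threshold"),
                               epsilon = 0.05, window = 4L) {
  rule <- match.arg(rule)
  cv <- if (inherits(x, "accumulated_stats") || is.data.frame(x)) {
    x$cv_accum
  } else {
    as.numeric(x)
  }
  n <- length(cv)
  if (n < 2L) stop("insufficient data: need at least 2 accumulated rows")
  cvr <- round_half_up(cv, 2L)

  k_stable <- NA_integer_
  if (rule == "terminal-plateau") {
    plateau <- cvr[n]
    k <- n
    while (k > 2L && isTRUE(cvr[k - 1L] == plateau)) k <- k - 1L
    k_stable <- k
    params <- list()
  } else {
    window <- as.integer(window)
    for (k in 2:max(2L, n - window)) {
      hi <- min(n, k + window)
      if (max(cvr[k:hi]) - min(cvr[k:hi]) <= epsilon) { k_stable <- k; break }
    }
    params <- list(epsilon = epsilon, window = window)
  }

  structure(
    list(k_stable = k_stable, stabilized = !is.na(k_stable),
         rule = rule, params = params, cv_series = cv),
    class = "stabilization_result"
  )
}

#' @export
print.stabilization_result <- function(x, ...) {
  if (x$stabilized) {
    cat(sprintf("stabilized after %d repetitions (rule: %s)\n",
                x$k_stable, x$rule))
  } else {
    cat(sprintf("not stabilized within %d repetitions (rule: %s)\n",
                length(x$cv_series), x$rule))
  }
  invisible(x)
}

#' Absolute percent error against a known truth
#'
#' @param measured measured value(s).
#' @param truth reference value(s), nonzero.
#' @return \code{100 * |measured - truth| / |truth|}.
#' @export
percent_error <- function(measured, truth) {
  if (any(truth == 0)) stop("undefined reference: truth must be nonzero")
  100 * abs(measured - truth) / abs(truth)
}

#' Aggregate per-frame metrics across frames
#'
#' Collects the outputs of [measure_frame()] over the selected frames and
#' produces, per metric, the summary statistics and the accumulated
#' mean/SD/CV table (in frame order). Frames where a metric is missing are
#' skipped for that metric and counted; a metric observed in fewer than two
#' frames is flagged insufficient instead of erroring, so one bad landmark
#' does not sink the whole report.
#'
#' @param per_frame a list of [measure_frame()] data frames, or a single
#'   long data frame with columns \code{frame_index}, \code{metric},
#'   \code{value} (and optionally \code{missing}).
#' @inheritParams summary_stats
#' @return named list (one element per metric) of lists with
#'   \code{summary} ([summary_stats()] or NULL), \code{accumulated}
#'   ([accumulated_stats()] or NULL), \code{n_used}, \code{n_skipped} and
#'   \code{insufficient}.
#' @export
aggregate_metrics <- function(per_frame,
                              rounding = c("printed-table", "exact")) {
  rounding <- match.arg(rounding)
  long <- if (is.data.frame(per_frame)) per_frame else do.call(rbind, per_frame)
  if (is.null(long$missing)) long$missing <- is.na(long$value)
  if (is.null(long$frame_index)) long$frame_index <- seq_len(nrow(long))
  n_frames <- length(unique(long$frame_index))
  if (n_frames < 2L) {
    stop("insufficient data: aggregation needs at least 2 frames")
  }
  long <- long[order(long$frame_index), , drop = FALSE]

  metrics <- unique(long$metric)
  out <- lapply(metrics, function(m) {
    sub <- long[long$metric == m, , drop = FALSE]
    vals <- sub$value[!sub$missing & !is.na(sub$value)]
    n_skipped <- n_frames - length(vals)
    if (length(vals) < 2L) {
      list(summary = NULL, accumulated = NULL, n_used = length(vals),
           n_skipped = n_skipped, insufficient = TRUE)
    } else {
      list(summary = summary_stats(vals, rounding),
           accumulated = accumulated_stats(vals, rounding),
           n_used = length(vals), n_skipped = n_skipped,
           insufficient = FALSE)
    }
  })
  names(out) <- metrics
  out
}
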