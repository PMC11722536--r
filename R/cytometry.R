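# Rare low-GTP (bright-reporter) subpopulation quantification from cytometry
# event tables: autofluorescence subtraction, k-fold-above-mean tail gating,
# induced-fraction subtraction, tail-heaviness summaries, and the Pearson
# correlations used to decouple persistence from tolerance.

#' Cytometry event-table container
#'
#' @param data data frame with columns `sample` and `value` (one
#'   fluorescence value per event, a.u.), or a numeric vector.
#' @param sample sample label (when `data` is a vector).
#' @param corrected has autofluorescence already been subtracted?
#' @return An object of class `event_table`.
#' @export
event_table <- function(data, sample = "sample", corrected = FALSE) {
  if (is.numeric(data)) {
    values <- data
  } else {
    if (!all(c("sample", "value") %in% names(data))) {
      stop("need columns sample, value")
    }
    if (length(unique(data$sample)) != 1L) stop("event_table holds one sample")
    sample <- as.character(data$sample[1])
    values <- data$value
  }
  if (length(values) < 100) {
    stop("need at least 100 events (got ", length(values), ")")
  }
  if (any(!is.finite(values))) stop("all event values must be finite")
  if (corrected && any(values < 0)) stop("corrected values must be >= 0")
  structure(list(sample = sample, values = values,
                 n_events = length(values), corrected = corrected),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %s: %d events, corrected = %s, mean = %.3g\n",
              x$sample, x$n_events, x$corrected, mean(x$values)))
  invisible(x)
}

#' Subtract autofluorescence measured on a reporterless control
#'
#' Corrected values are `max(0, value - mean(control))`; the control is an
#' event table from an isogenic strain without the reporter, acquired with
#' the same settings.
#'
#' @param sample,control [event_table()] objects.
#' @return A corrected `event_table`.
#' @export
subtract_autofluorescence <- function(sample, control) {
  if (!inherits(control, "event_table") || control$n_events == 0) {
    stop("empty or invalid control event table")
  }
  event_table(clip0(sample$values - mean(control$values)),
              sample = sample$sample, corrected = TRUE)
}

#' Gate the bright tail at k-fold above the mean
#'
#' The gate threshold is `k` times the mean of the (autofluorescence-
#' corrected) values; the result is the count and fraction of events at or
#' above it. The rule is scale-invariant: multiplying all values by a
#' positive constant leaves the fraction unchanged.
#'
#' @param events a corrected [event_table()].
#' @param k fold multiplier (> 1; default 5, the standard bright-cell gate).
#' @return An object of class `tail_gate`: `sample`, `k`, `threshold`,
#'   `n_events`, `n_high`, `fraction_high`.
#' @export
gate_high_fraction <- function(events, k = 5) {
  stopifnot(inherits(events, "event_table"), k > 1)
  if (!events$corrected) {
    warning("gating uncorrected events; subtract autofluorescence first")
  }
  m <- mean(events$values)
  if (m <= 0) stop("mean fluorescence is not positive; gate undefined")
  thr <- k * m
  n_high <- sum(events$values >= thr)
  structure(list(sample = events$sample, k = k, threshold = thr,
                 n_events = events$n_events, n_high = n_high,
                 fraction_high = n_high / events$n_events),
            class = "tail_gate")
}

#' @export
print.tail_gate <- function(x, ...) {
  cat(sprintf("<tail_gate> %s: k = %g, threshold = %.3g, %d/%d high (%.3g)\n",
              x$sample, x$k, x$threshold, x$n_high, x$n_events,
              x$fraction_high))
  invisible(x)
}

#' Antibiotic-induced low-GTP fraction
#'
#' Difference of bright-tail fractions after minus before induction, both
#' gated with the same `k`. Negative deltas are returned as-is with a
#' warning flag (no information destroyed).
#'
#' @param after,before [gate_high_fraction()] results.
#' @return A tibble with `delta`, `after`, `before`, `negative` (flag).
#' @export
induced_low_gtp_fraction <- function(after, before) {
  stopifnot(inherits(after, "tail_gate"), inherits(before, "tail_gate"))
  if (after$k != before$k) {
    stop("gates use different k (", after$k, " vs ", before$k, ")")
  }
  delta <- after$fraction_high - before$fraction_high
  if (delta < 0) warning("induced fraction is negative")
  tibble::tibble(delta = delta, after = after$fraction_high,
                 before = before$fraction_high, negative = delta < 0)
}

#' Tail-heaviness summary of a fluorescence distribution
#'
#' Reports the 99.9th-percentile-to-median ratio and the excess kurtosis of
#' the corrected values. For a degenerate (constant) distribution the
#' kurtosis is undefined and reported as 0 with a flag.
#'
#' @param events an [event_table()] with at least 1000 events.
#' @return A tibble with `p999_over_median`, `excess_kurtosis`, `degenerate`.
#' @export
tail_heaviness <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (events$n_events < 1000) {
    stop("need at least 1000 events (got ", events$n_events, ")")
  }
  v <- events$values
  med <- median(v)
  ratio <- if (med == 0) Inf else unname(quantile(v, 0.999) / med)
  s2 <- mean((v - mean(v))^2)
  degen <- s2 == 0
  kurt <- if (degen) 0 else mean((v - mean(v))^4) / s2^2 - 3
  if (degen) ratio <- 1
  tibble::tibble(p999_over_median = ratio, excess_kurtosis = kurt,
                 degenerate = degen)
}

#' Pearson correlation across conditions
#'
#' Standard Pearson `r` with its two-sided t-distribution p value, used to
#' relate the bright-tail fraction to survival (persistence) and to growth
#' rate (tolerance decoupling) across conditions.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
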