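# Behavioural estimators: performance curves, the cubic local-maximum
# optimal-tempo estimator, guided-tapping precision and CV, sensorimotor
# simultaneity in phase units, median splits and AIC-based Bayes factors.

#' Aggregate trials into a per-condition performance curve
#'
#' @param trials A trials data.frame with columns `condition_hz` and
#'   `response_correct` (0/1).
#' @param conditions Optional vector of beat frequencies that must all be
#'   present; a condition with no trials is an error.
#' @return An object of class `performance_curve`: data.frame with
#'   `condition_hz` (strictly increasing), `prop_correct` and `n`.
#' @export
performance_curve <- function(trials, conditions = NULL) {
  if (!is.data.frame(trials) ||
      !all(c("condition_hz", "response_correct") %in% names(trials))) {
    stop_invalid("trials must have condition_hz and response_correct columns")
  }
  if (nrow(trials) == 0L) stop_invalid("no trials to aggregate")
  agg <- stats::aggregate(response_correct ~ condition_hz, data = trials,
                          FUN = function(x) c(mean(x), length(x)))
  out <- data.frame(condition_hz = agg$condition_hz,
                    prop_correct = agg$response_correct[, 1],
                    n = as.integer(agg$response_correct[, 2]))
  out <- out[order(out$condition_hz), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, out$condition_hz)
    if (length(missing)) {
      stop_invalid("condition with 0 trials: ", paste(missing, collapse = ", "))
    }
    out <- out[out$condition_hz %in% conditions, , drop = FALSE]
  }
  class(out) <- c("performance_curve", "data.frame")
  out
}

#' Estimate an optimal tempo by a cubic local-maximum fit
#'
#' Fits a third-order polynomial f(x) = ax^3 + bx^2 + cx + d by least
#' squares to values (performance, PLV, or any tuning measure) sampled over
#' beat frequencies, and extracts the local maximum
#' \deqn{\alpha = \frac{-b - \sqrt\delta}{3a}, \qquad
#'       \beta = \frac{-b + \sqrt\delta}{3a}, \qquad \delta = b^2 - 3ac,}
#' defined when \eqn{\delta > 0} and \eqn{a \ne 0}. The cubic is the
#' lowest-order polynomial admitting exactly one unambiguous local maximum.
#' \eqn{\alpha} is always the maximum (the second derivative there is
#' \eqn{-2\sqrt\delta < 0}) and \eqn{\beta} the minimum.
#'
#' @param freqs Beat frequencies (Hz), at least 4 distinct values.
#' @param values Measure at each frequency.
#' @param log_axis Fit on the log2-frequency axis instead of linear Hz
#'   (default FALSE; `alpha` and `beta` are mapped back to Hz).
#' @return An object of class `cubic_fit`: coefficients `a`, `b`, `c`, `d`,
#'   discriminant `delta`, `alpha` (local-max abscissa in Hz or `NA`), `beta`
#'   (local min or `NA`), `has_optimum` (FALSE when `delta <= 0` or the cubic
#'   term vanishes: a no-optimum signal, distinct from an error),
#'   `alpha_in_range` (is the maximum inside the sampled frequency range?)
#'   and `r_squared`.
#' @examples
#' x <- c(-2, -1, 0, 1, 2)
#' fit_cubic_optimal_tempo(x, -x^3 + 3 * x)  # alpha = 1 exactly
#' @export
fit_cubic_optimal_tempo <- function(freqs, values, log_axis = FALSE) {
  if (length(freqs) != length(values)) stop_invalid("freqs/values length mismatch")
  keep <- is.finite(freqs) & is.finite(values)
  freqs <- freqs[keep]; values <- values[keep]
  if (length(unique(freqs)) < 4L) {
    stop_invalid("need at least 4 distinct frequencies for a cubic fit")
  }
  x <- if (log_axis) log2(freqs) else freqs
  fit <- stats::lm(values ~ x + I(x^2) + I(x^3))
  co <- stats::coef(fit)
  d <- unname(co[1]); c_ <- unname(co[2]); b <- unname(co[3]); a <- unname(co[4])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  # A cubic term that is numerically nil relative to the data scale means a
  # lower-order shape (line/parabola): no unambiguous local maximum exists.
  dx <- diff(range(x))
  scale_ref <- max(diff(range(values)), .Machine$double.eps)
  a_negligible <- abs(a) * dx^3 < 1e-8 * scale_ref
  delta <- b^2 - 3 * a * c_

  if (a_negligible || delta <= 0) {
    out <- list(a = a, b = b, c = c_, d = d, delta = delta,
                alpha = NA_real_, beta = NA_real_,
                has_optimum = FALSE, alpha_in_range = NA,
                r_squared = r2, log_axis = log_axis)
    return(structure(out, class = "cubic_fit"))
  }
  alpha <- (-b - sqrt(delta)) / (3 * a)
  beta <- (-b + sqrt(delta)) / (3 * a)
  if (log_axis) { alpha <- 2^alpha; beta <- 2^beta }
  in_range <- alpha >= min(freqs) && alpha <= max(freqs)
  structure(list(a = a, b = b, c = c_, d = d, delta = delta,
                 alpha = alpha, beta = beta,
                 has_optimum = TRUE, alpha_in_range = in_range,
                 r_squared = r2, log_axis = log_axis),
            class = "cubic_fit")
}

#' Evaluate a fitted cubic
#' @param fit A `cubic_fit`.
#' @param x Abscissae (Hz, or log2 Hz is handled internally when the fit used
#'   the log axis).
#' @return Fitted values.
#' @export
predict_cubic <- function(fit, x) {
  stopifnot(inherits(fit, "cubic_fit"))
  if (isTRUE(fit$log_axis)) x <- log2(x)
  fit$a * x^3 + fit$b * x^2 + fit$c * x + fit$d
}

#' @export
print.cubic_fit <- function(x, ...) {
  cat(sprintf("<cubic_fit> a=%.4g b=%.4g c=%.4g d=%.4g, delta=%.4g, R2=%.3f\n",
              x$a, x$b, x$c, x$d, x$delta, x$r_squared))
  if (x$has_optimum) {
    cat(sprintf("  local max alpha = %.4g Hz%s, local min beta = %.4g Hz\n",
                x$alpha, if (isTRUE(x$alpha_in_range)) "" else " (outside data range)",
                x$beta))
  } else cat("  no optimum (delta <= 0 or vanishing cubic term)\n")
  invisible(x)
}

tap_times_of <- function(taps) {
  if (inherits(taps, "tap_record")) taps$tap_times else as.numeric(taps)
}

#' Guided tapping precision
#'
#' The ratio, in percent, between the produced tapping frequency (reciprocal
#' of the mean inter-tap interval) and the tempo: 100% is tapping exactly at
#' the beat rate, above 100% is faster than the beat.
#'
#' @param taps A `tap_record` or numeric vector of tap times (>= 2 taps).
#' @param period Beat period T in seconds (taken from a `tap_record` if
#'   omitted).
#' @return Precision in percent.
#' @export
tapping_precision <- function(taps, period = NULL) {
  if (is.null(period) && inherits(taps, "tap_record")) period <- taps$period
  tt <- tap_times_of(taps)
  if (length(tt) < 2L) stop_invalid("tapping precision needs at least 2 taps")
  if (is.null(period) || period <= 0) stop_invalid("period must be positive")
  100 * (1 / mean(diff(tt))) / (1 / period)
}

#' Coefficient of variation of inter-tap intervals
#'
#' Sample standard deviation (n-1 denominator) of the inter-tap intervals
#' divided by the beat period; 0 is perfectly rhythmic tapping.
#'
#' @inheritParams tapping_precision
#' @return Dimensionless CV (>= 0). Requires at least 3 taps (2 intervals).
#' @export
tapping_cv <- function(taps, period = NULL) {
  if (is.null(period) && inherits(taps, "tap_record")) period <- taps$period
  tt <- tap_times_of(taps)
  if (length(tt) < 3L) stop_invalid("tapping CV needs at least 3 taps (2 intervals)")
  if (is.null(period) || period <= 0) stop_invalid("period must be positive")
  stats::sd(diff(tt)) / period
}

#' Sensorimotor simultaneity (tap-beat phase distance)
#'
#' Assigns each tap to its nearest beat and expresses the signed temporal
#' distance as a phase in a 2*pi space normalised to the beat period:
#' \eqn{\Phi = 2\pi (t_{tap} - t_{beat}) / T}, wrapped to (-pi, pi]. Zero is
#' perfect simultaneity; negative values are anticipatory taps. The signed
#' index averages \eqn{\Phi} arithmetically (values live near zero); the
#' absolute index averages \eqn{|\Phi|} and quantifies the degree of
#' simultaneity regardless of direction.
#'
#' @param taps A `tap_record` or numeric tap times (>= 1 tap).
#' @param beat_times Beat onset times in seconds (taken from a `tap_record`
#'   if omitted); >= 1 beat.
#' @param period Beat period T in seconds.
#' @return A list of class `tap_metrics`: `phi` (per-tap signed phase),
#'   `phi_signed` (trial mean), `phi_abs` (trial mean of |phi|),
#'   `nearest_beat` (index of each tap's assigned beat).
#' @export
sensorimotor_simultaneity <- function(taps, beat_times = NULL, period = NULL) {
  if (inherits(taps, "tap_record")) {
    if (is.null(beat_times)) beat_times <- taps$beat_times
    if (is.null(period)) period <- taps$period
  }
  tt <- tap_times_of(taps)
  if (length(tt) < 1L || length(beat_times) < 1L) {
    stop_invalid("need at least one tap and one beat")
  }
  if (is.null(period) || period <= 0) stop_invalid("period must be positive")
  nearest <- vapply(tt, function(t) which.min(abs(beat_times - t)), 0L)
  phi <- wrap_pi(2 * pi * (tt - beat_times[nearest]) / period)
  structure(list(phi = phi,
                 phi_signed = mean(phi),
                 phi_abs = mean(abs(phi)),
                 nearest_beat = nearest),
            class = "tap_metrics")
}

#' Split trials into low and high groups at the sample median
#'
#' With an odd number of trials the median trial joins the low group; ties at
#' the median follow their side of a stable sort of the key.
#'
#' @param trials A data.frame.
#' @param key Column name holding the (finite, numeric) split variable.
#' @return List with elements `low` and `high` (data.frames) and `median`.
#'   An all-identical key is a degenerate split and raises a classed error.
#' @export
median_split <- function(trials, key) {
  if (!is.data.frame(trials) || !key %in% names(trials)) {
    stop_invalid("key column not found")
  }
  x <- trials[[key]]
  keep <- is.finite(x)
  trials <- trials[keep, , drop = FALSE]
  x <- x[keep]
  if (length(x) < 2L) stop_invalid("median split needs at least 2 finite values")
  if (length(unique(x)) == 1L) {
    stop_degenerate("all key values identical: degenerate median split")
  }
  ord <- order(x)                      # stable in R
  n_low <- as.integer(ceiling(length(x) / 2))
  list(low = trials[ord[seq_len(n_low)], , drop = FALSE],
       high = trials[ord[-seq_len(n_low)], , drop = FALSE],
       median = stats::median(x))
}

#' AIC-based Bayes factor for an effect versus the null
#'
#' Converts an AIC difference into an approximate Bayes factor,
#' \eqn{BF = \exp((AIC_{null} - AIC_{effect}) / 2)}. A Bayes factor below 1/3
#' is taken as significant evidence in favour of the null hypothesis.
#'
#' @param aic_null AIC of the null model.
#' @param aic_effect AIC of the effect model.
#' @return A list of class `bf_aic`: `bf` and `evidence_for_null`
#'   (`bf < 1/3`).
#' @examples
#' bayes_factor_aic(100, 104)$bf   # ~0.135, evidence for the null
#' @export
bayes_factor_aic <- function(aic_null, aic_effect) {
  if (!is.finite(aic_null) || !is.finite(aic_effect)) {
    stop_invalid("AIC values must be finite")
  }
  bf <- exp((aic_null - aic_effect) / 2)
  structure(list(bf = bf, evidence_for_null = bf < 1 / 3), class = "bf_aic")
}
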