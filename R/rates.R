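#' Biomass-corrected dissolved organic carbon (DOC*)
#'
#' Subtracts bacterioplankton biomass carbon from a measured bulk organic
#' carbon concentration. The remainder, termed DOC*, still contains an
#' unconstrained contribution of non-cellular carbon smaller than the 3 um
#' pre-filter, hence the asterisk.
#'
#' @param oc Organic carbon, umol C L^-1, > 0.
#' @param bb Bacterioplankton biomass, umol C L^-1, >= 0 and < `oc`.
#' @return DOC* = `oc - bb`, umol C L^-1.
#' @export
doc_star <- function(oc, bb) {
  if (any(oc <= 0)) stop("organic carbon must be positive", call. = FALSE)
  if (any(bb < 0)) stop("biomass must be non-negative", call. = FALSE)
  if (any(bb >= oc)) {
    stop("biomass >= organic carbon: implausible biomass estimate",
         call. = FALSE)
  }
  oc - bb
}

#' Resolvability gates for rate and growth-efficiency reporting
#'
#' Growth efficiencies are only reported when the DOC* drawdown between T0
#' and stationary phase exceeds twice the instrument precision and both the
#' production and removal regressions are individually significant. Defaults
#' encode a 0.7 umol C L^-1 analytical precision, hence a 1.4 umol C L^-1
#' minimum drawdown, at alpha = 0.05.
#'
#' @param instrument_precision Analytical precision of the organic carbon
#'   measurement, umol C L^-1.
#' @param min_delta_doc Minimum resolvable DOC* change; defaults to twice the
#'   instrument precision.
#' @param alpha Two-tailed significance level for the slope tests.
#' @return A list of class `detection_gates`.
#' @export
detection_gates <- function(instrument_precision = 0.7,
                            min_delta_doc = 2 * instrument_precision,
                            alpha = 0.05) {
  stopifnot(instrument_precision > 0, min_delta_doc > 0,
            alpha > 0, alpha < 1)
  structure(list(instrument_precision = instrument_precision,
                 min_delta_doc = min_delta_doc,
                 alpha = alpha),
            class = "detection_gates")
}

#' Detect the onset of stationary growth phase
#'
#' Stationary phase is the period demonstrating no net cell growth with
#' time. The detector smooths ln(abundance) with a centered three-point
#' rolling mean, takes the plateau level as the maximum of the smoothed
#' series (which, in experiments with a post-stationary death phase, is
#' reached at the end of growth), and reports the earliest time whose
#' smoothed value comes within `plateau_tol` log units of that plateau.
#' Two guards apply: the OLS slope of ln(abundance) from T0 up to the onset
#' must be significantly positive (one-sided t-test at `alpha`), confirming
#' a preceding growth phase — otherwise a no-growth error is raised — and
#' an onset falling within the last `min_tail` points means growth
#' continued through the series, reported as `NA` (no stationary phase).
#'
#' @param times Strictly increasing sampling times in days.
#' @param abundance Cell abundances (cells mL^-1), positive, same length.
#' @param plateau_tol Log-units tolerance for "having reached" the plateau
#'   (0.1 corresponds to about a 10% abundance deficit).
#' @param min_tail Minimum number of points that must lie at or beyond the
#'   onset for a stationary phase to be declared (>= 2).
#' @param alpha One-sided significance level for the prior-growth check.
#' @return Stationary onset time in days, or `NA_real_` when growth
#'   continues through the end of the series (no stationary phase).
#' @export
detect_stationary <- function(times, abundance, plateau_tol = 0.1,
                              min_tail = 3, alpha = 0.05) {
  stopifnot(length(times) == length(abundance), min_tail >= 2)
  n <- length(times)
  if (n < 5) stop("need at least 5 time points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(abundance <= 0)) stop("abundance must be positive", call. = FALSE)
  la <- log(abundance)
  smoothed <- vapply(seq_len(n), function(k) {
    mean(la[max(1, k - 1):min(n, k + 1)])
  }, numeric(1))
  i <- which(smoothed >= max(smoothed) - plateau_tol)[1]
  if (i < 3 || .slope_positive_p(times[1:i], la[1:i]) >= alpha) {
    stop("no interval of significant net growth in the series",
         call. = FALSE)
  }
  if (i > n - min_tail + 1) return(NA_real_)
  times[i]
}

# One-sided p-value for slope > 0 in an OLS fit; degenerate fits (zero
# residual variance) count as growth only if the slope is positive.
.slope_positive_p <- function(x, y) {
  fit <- .ols(x, y)
  if (fit$se == 0) return(if (fit$slope > 0) 0 else 1)
  pt(fit$slope / fit$se, df = fit$n - 2, lower.tail = FALSE)
}

# Closed-form simple OLS used by all rate fits.
.ols <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a rate fit", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in time: degenerate design", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  list(slope = slope, intercept = intercept, se = se, n = n)
}

#' Model-I (ordinary least squares) rate fit
#'
#' Fits `values ~ times` by OLS and reports the slope, its standard error and
#' the two-tailed t-test p-value on the slope. Used both for bacterial
#' production (biomass vs time, positive slope) and DOC* removal (negative
#' slope whose magnitude is the removal rate); set `sign = "removal"` to
#' report the negated slope so removal is positive.
#'
#' @param times Sampling times, days. Replicate observations may share times.
#' @param values Observed values (umol C L^-1).
#' @param window Label for the fitted interval, e.g. `"short_term"`
#'   (T0 to stationary) or `"long_term"` (stationary to final).
#' @param sign `"production"` reports the raw slope; `"removal"` negates it.
#' @return A tibble with `slope`, `slope_se`, `intercept`, `n`,
#'   `p_two_tailed` and `window`.
#' @export
fit_rate <- function(times, values, window = "short_term",
                     sign = c("production", "removal")) {
  sign <- match.arg(sign)
  keep <- is.finite(times) & is.finite(values)
  fit <- .ols(times[keep], values[keep])
  p <- if (fit$se == 0) {
    if (fit$slope == 0) 1 else 0
  } else {
    2 * pt(abs(fit$slope / fit$se), df = fit$n - 2, lower.tail = FALSE)
  }
  slope <- if (sign == "removal") -fit$slope else fit$slope
  tibble::tibble(slope = slope, slope_se = fit$se, intercept = fit$intercept,
                 n = fit$n, p_two_tailed = p, window = window)
}

#' Apply resolvability gates
#'
#' @param delta_doc Observed DOC* change between T0 and stationary phase,
#'   umol C L^-1 (magnitude).
#' @param p_bp,p_doc Two-tailed p-values of the production and removal fits.
#' @param gates A [detection_gates()].
#' @return A list with logical elements `delta_doc`, `p_bp`, `p_doc` and
#'   their conjunction `overall`.
#' @export
resolvable <- function(delta_doc, p_bp, p_doc, gates = detection_gates()) {
  g <- list(delta_doc = isTRUE(delta_doc > gates$min_delta_doc),
            p_bp = isTRUE(p_bp < gates$alpha),
            p_doc = isTRUE(p_doc < gates$alpha))
  g$overall <- g$delta_doc && g$p_bp && g$p_doc
  g
}

#' Bacterial growth efficiency
#'
#' The fraction of removed organic carbon converted into bacterial biomass:
#' \deqn{BGE = BP / DOC^{*}\,removal\,rate} where both rates are positive
#' magnitudes in umol C L^-1 d^-1 over the same (T0 to stationary) window.
#'
#' @param bp_rate Bacterial production rate, > 0.
#' @param doc_removal_rate DOC* removal rate, > 0.
#' @return Dimensionless fraction; scale invariant in its two arguments.
#' @examples
#' bge(0.05, 0.11)   # 0.45
#' @export
bge <- function(bp_rate, doc_removal_rate) {
  if (any(bp_rate <= 0) || any(doc_removal_rate <= 0)) {
    stop("BGE is undefined for non-positive rates", call. = FALSE)
  }
  bp_rate / doc_removal_rate
}

#' Propagated uncertainty of a growth efficiency
#'
#' The default (`mode = "standard"`) propagates the relative errors of the
#' two rates,
#' \deqn{\sigma_{BGE} = BGE\sqrt{(\sigma_{rate}/rate)^2 + (\sigma_{BP}/BP)^2}.}
#' `mode = "literal"` instead evaluates the same expression with each ratio
#' inverted (value over error). That inverted form appears in some published
#' method descriptions but yields errors roughly two orders of magnitude too
#' large to match any tabulated uncertainty; it is retained only so the
#' inconsistency can be demonstrated, and should not be used for reporting.
#'
#' @param bge_value The growth efficiency.
#' @param doc_rate,doc_rate_se DOC* removal rate and its standard error.
#' @param bp,bp_se Production rate and its standard error.
#' @param mode `"standard"` (relative-error propagation) or `"literal"`.
#' @return The propagated BGE uncertainty.
#' @examples
#' bge_error(0.389, 0.18, 0.03, 0.07, 0.01)   # ~0.085
#' @export
bge_error <- function(bge_value, doc_rate, doc_rate_se, bp, bp_se,
                      mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (any(doc_rate <= 0) || any(bp <= 0)) {
    stop("rates must be positive", call. = FALSE)
  }
  if (any(doc_rate_se < 0) || any(bp_se < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  if (mode == "standard") {
    bge_value * sqrt((doc_rate_se / doc_rate)^2 + (bp_se / bp)^2)
  } else {
    bge_value * sqrt((doc_rate / doc_rate_se)^2 + (bp / bp_se)^2)
  }
}
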