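#' Standardized major axis (model II) regression
#'
#' Symmetric-error linear fit appropriate when both variables carry
#' measurement error: slope = `sign(r) * sd(y) / sd(x)`, intercept through
#' the centroid, with significance taken from the Pearson correlation test.
#' Swapping x and y inverts the slope exactly.
#'
#' @param x,y Numeric vectors, n >= 3, both with positive variance.
#' @return Tibble with `model = "sma"`, `slope`, `intercept`, `r_squared`,
#'   `p`, `n`.
#' @export
sma_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: degenerate fit", call. = FALSE)
  }
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (slope == 0) slope <- sd(y) / sd(x)  # r exactly 0: sign convention +
  intercept <- mean(y) - slope * mean(x)
  p <- cor.test(x, y)$p.value
  tibble::tibble(model = "sma", slope = slope, intercept = intercept,
                 r_squared = r^2, p = p, n = length(x))
}

#' Exponential fit by least squares on the log scale
#'
#' Fits \eqn{y = a e^{bx}} by ordinary least squares on
#' \eqn{\ln y = \ln a + b x}; `r_squared` and `p` refer to the transformed
#' (linear) scale.
#'
#' @param x Predictor.
#' @param y Response, strictly positive.
#' @return Tibble with `model = "exponential"`, `a`, `b`, `r_squared`, `p`,
#'   `n`.
#' @export
exponential_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (any(y <= 0)) {
    stop("y must be positive for the log transform", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- .ols(x, log(y))
  p <- if (fit$se == 0) {
    if (fit$slope == 0) 1 else 0
  } else {
    2 * pt(abs(fit$slope / fit$se), df = fit$n - 2, lower.tail = FALSE)
  }
  r2 <- cor(x, log(y))^2
  tibble::tibble(model = "exponential", a = exp(fit$intercept), b = fit$slope,
                 r_squared = r2, p = p, n = fit$n)
}

#' Normality-routed two-sample comparison
#'
#' Routes a two-sample location comparison through a Shapiro-Wilk normality
#' check on each sample: when both pass at `alpha_normality` the comparison
#' is a two-sample t-test (pooled variance); otherwise a Mann-Whitney
#' (Wilcoxon rank-sum) test. The method actually used is returned so it can
#' be reported alongside the p-value. Samples that are constant (zero
#' variance, where Shapiro-Wilk is undefined) route to Mann-Whitney.
#'
#' @param sample_a,sample_b Numeric vectors, each n >= 3.
#' @param alpha_normality Significance level of the normality check.
#' @return A list with `method` (`"t_test"` or `"mann_whitney"`),
#'   `statistic`, `p`.
#' @export
two_sample_compare <- function(sample_a, sample_b, alpha_normality = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("need at least 3 observations per sample", call. = FALSE)
  }
  normal <- function(x) {
    if (sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= alpha_normality
  }
  if (normal(sample_a) && normal(sample_b)) {
    tt <- t.test(sample_a, sample_b, var.equal = TRUE)
    list(method = "t_test", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(sample_a, sample_b))
    list(method = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value)
  }
}
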