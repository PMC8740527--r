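# Shared fixtures built in code.

# Equal-concentration profile over the default 18-analyte set.
flat_profile <- function(value = 10) {
  setNames(rep(value, 18), names(aa_carbon_atoms()))
}

# Closed-form OLS oracle, written directly from the textbook formulas and
# kept independent of the package's fitting code.
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  p <- 2 * pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  list(slope = b, intercept = a, se = se, p = p)
}

# Shannon H / variance oracle evaluated directly from the formulas.
shannon_oracle <- function(counts) {
  N <- sum(counts)
  p <- counts[counts > 0] / N
  H <- -sum(p * log(p))
  S <- length(p)
  list(H = H, v = (sum(p * log(p)^2) - H^2) / N + (S - 1) / (2 * N^2), N = N)
}
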