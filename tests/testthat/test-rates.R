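test_that("DOC* subtracts biomass and rejects implausible values", {
  expect_equal(doc_star(59.6, 0.5), 59.1)
  expect_equal(doc_star(58, 0), 58)
  expect_error(doc_star(58, 58), "implausible")
  expect_error(doc_star(0, 0), "positive")
})

test_that("stationary onset is recovered on a plateauing curve and sentinels fire", {
  # noiseless logistic that plateaus at day 7, sampled daily
  tt <- 0:12
  C <- 9
  r <- log(C / (1 / 0.95 - 1)) / 7
  n <- 1e5 * (1 + C) / (1 + C * exp(-r * pmin(tt, 7)))
  expect_lte(abs(detect_stationary(tt, n) - 7), 1)
  # strictly exponential growth: no stationary phase
  expect_true(is.na(detect_stationary(0:8, 1e5 * exp(0.5 * (0:8)))))
  # flat and declining series: no growth at all
  expect_error(detect_stationary(0:8, rep(1e5, 9)), "no interval")
  expect_error(detect_stationary(0:8, 1e5 * exp(-0.3 * (0:8))), "no interval")
  expect_error(detect_stationary(c(0, 1, 1, 2, 3), rep(1, 5)^2 * 1e5),
               "strictly increasing")
})

test_that("rate fitting equals the closed-form OLS oracle", {
  # exact lines
  f <- fit_rate(c(0, 2, 4, 6), 58 - 0.2 * c(0, 2, 4, 6), sign = "removal")
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_lt(f$p_two_tailed, 1e-6)
  f2 <- fit_rate(0:6, 0.3 + 0.08 * (0:6))
  expect_equal(f2$slope, 0.08, tolerance = 1e-12)
  # noisy instances against the hand-computed formulas
  set.seed(21)
  for (i in 1:1000) {
    n <- sample(4:9, 1)
    x <- sort(runif(n, 0, 10))
    y <- 1 + 0.3 * x + rnorm(n, 0, 0.7)
    got <- fit_rate(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$slope_se, want$se, tolerance = 1e-10)
    expect_equal(got$p_two_tailed, want$p, tolerance = 1e-10)
  }
  expect_error(fit_rate(c(0, 1), c(1, 2)), "3 points")
  expect_error(fit_rate(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("resolvability gates are a pure conjunction at the 1.4 threshold", {
  g <- detection_gates()
  expect_equal(g$min_delta_doc, 1.4)
  expect_false(resolvable(1.3, 0.01, 0.01, g)$overall)
  expect_false(resolvable(2.0, 0.01, 0.20, g)$overall)
  expect_true(resolvable(2.0, 0.01, 0.01, g)$overall)
  # flipping any single gate flips overall only when the others pass
  passing <- list(delta = 2, p_bp = 0.01, p_doc = 0.01)
  failing <- list(delta = 1.0, p_bp = 0.5, p_doc = 0.5)
  for (flip in 1:3) {
    args <- passing
    args[[flip]] <- failing[[flip]]
    expect_false(resolvable(args$delta, args$p_bp, args$p_doc, g)$overall)
  }
})

test_that("growth efficiency is the rate quotient and is scale invariant", {
  expect_equal(round(bge(0.05, 0.11), 2), 0.45)
  expect_equal(bge(0.04, 0.16), 0.25)
  expect_equal(bge(0.2, 0.2), 1)
  for (k in c(0.01, 0.5, 7)) {
    expect_equal(bge(k * 0.07, k * 0.18), bge(0.07, 0.18), tolerance = 1e-12)
  }
  expect_error(bge(0, 0.1), "non-positive")
})

test_that("standard error propagation matches hand algebra; the literal form does not", {
  # inputs consistent with a reported 0.38 +/- 0.09 growth efficiency
  e <- bge_error(0.389, 0.18, 0.03, 0.07, 0.01)
  expect_equal(e, 0.389 * sqrt((0.03 / 0.18)^2 + (0.01 / 0.07)^2),
               tolerance = 1e-12)
  expect_equal(round(e, 2), 0.09)
  expect_equal(bge_error(0.3, 0.2, 0, 0.06, 0), 0)
  # the printed formula with inverted ratios is off by orders of magnitude
  lit <- bge_error(0.389, 0.18, 0.03, 0.07, 0.01, mode = "literal")
  expect_equal(round(lit, 2), 3.59)
  expect_gt(lit, 0.389)
  # standard propagation stays below the value whenever relative errors < 1
  set.seed(3)
  for (i in 1:50) {
    rate <- runif(1, 0.05, 0.5); bp <- runif(1, 0.02, 0.3)
    b <- bge(bp, rate)
    err <- bge_error(b, rate, runif(1, 0, 0.6) * rate, bp,
                     runif(1, 0, 0.6) * bp)
    expect_lt(err, b)
  }
})

test_that("experiment_rates wires fits and gates into a growth efficiency", {
  tt <- 0:10
  bb <- 0.3 + 0.1 * pmin(tt, 7)
  oct <- rep(c(0, 2, 4, 6, 7, 30, 60), each = 3)
  oc <- 58 + 0.1 * pmin(oct, 7) - (0.1 / 0.25) * pmin(oct, 7)
  r <- experiment_rates(oct, oc, tt, bb, 7)
  expect_true(r$resolvable)
  expect_equal(r$bge, 0.25, tolerance = 1e-9)
  expect_equal(r$bp, 0.1, tolerance = 1e-9)
  # with an impossible gate the BGE is withheld
  strict <- detection_gates(min_delta_doc = 10)
  r2 <- experiment_rates(oct, oc, tt, bb, 7, gates = strict)
  expect_false(r2$resolvable)
  expect_true(is.na(r2$bge))
})
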