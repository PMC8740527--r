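test_that("relative abundances sum to one per sample", {
  m <- matrix(c(10, 30, 60, 5, 0, 15), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ra <- relative_abundance(m)
  expect_equal(unname(ra[, "s1"]), c(0.1, 0.3, 0.6))
  expect_equal(unname(colSums(ra)), c(1, 1))
  expect_equal(unname(relative_abundance(matrix(7, 1, 1,
    dimnames = list("a", "s")))), matrix(1, 1, 1), ignore_attr = TRUE)
  m0 <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(relative_abundance(m0), "zero total")
})

test_that("top-N selection orders by mean abundance and reports coverage", {
  ra <- matrix(c(0.4, 0.3, 0.2, 0.07, 0.03), 5, 1,
               dimnames = list(paste0("asv", 1:5), "s1"))
  top <- top_n_asvs(ra, 3)
  expect_equal(top$asv_ids, c("asv1", "asv2", "asv3"))
  expect_equal(top$mean_coverage, 0.9)
  expect_equal(top_n_asvs(ra, 5)$mean_coverage, 1)
  expect_warning(clipped <- top_n_asvs(ra, 10), "exceeds")
  expect_equal(length(clipped$asv_ids), 5)
})

test_that("log2 fold changes flag threefold responders and are antisymmetric", {
  r <- log2_fold_change(0.01, 0.03)
  expect_equal(r$log2fc, log2(3), tolerance = 1e-12)
  expect_true(r$responder)
  expect_equal(round(r$log2fc, 2), 1.58)
  expect_false(log2_fold_change(0.02, 0.02)$responder)
  r2 <- log2_fold_change(0.04, 0.01)
  expect_equal(r2$log2fc, -2)
  expect_false(r2$responder)
  # both zero without pseudocounts: undefined
  expect_true(is.na(log2_fold_change(0, 0)$log2fc))
  # detection-limit pseudocount keeps zeros finite
  r3 <- log2_fold_change(0, 0.001, depth_initial = 20000,
                         depth_stationary = 20000)
  expect_true(is.finite(r3$log2fc))
  # antisymmetry under phase swap with symmetric pseudocounts
  set.seed(8)
  a <- runif(50, 0, 0.05); b <- runif(50, 0, 0.05)
  fwd <- log2_fold_change(a, b, pseudocount = c(1e-4, 1e-4))
  rev <- log2_fold_change(b, a, pseudocount = c(1e-4, 1e-4))
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
})

test_that("Shannon H matches its formula, its bounds and vegan", {
  expect_equal(shannon(c(10))$H, 0)
  expect_equal(shannon(rep(25, 4))$H, log(4), tolerance = 1e-12)
  expect_equal(round(shannon(c(5, 3, 2))$H, 4), 1.0297)
  set.seed(10)
  for (i in 1:25) {
    counts <- rpois(40, lambda = runif(1, 1, 60))
    counts[1] <- counts[1] + 1  # ensure non-empty
    d <- shannon(counts)
    o <- shannon_oracle(counts)
    expect_equal(d$H, o$H, tolerance = 1e-12)
    expect_equal(d$variance, o$v, tolerance = 1e-12)
    expect_equal(d$H, vegan::diversity(counts), tolerance = 1e-10)
    expect_gte(d$H, 0)
    expect_lte(d$H, log(d$n_asvs) + 1e-12)
    # relabeling invariance
    expect_equal(shannon(sample(counts))$H, d$H, tolerance = 1e-12)
  }
  # maximal at the uniform composition
  expect_gt(shannon(rep(10, 8))$H, shannon(c(30, 10, 10, 10, 10, 5, 3, 2))$H)
})

test_that("Hutcheson's t matches the closed-form oracle", {
  a <- c(50, 30, 20); b <- c(90, 5, 5)
  da <- shannon(a); db <- shannon(b)
  got <- hutcheson_t(da, db)
  oa <- shannon_oracle(a); ob <- shannon_oracle(b)
  t_want <- (oa$H - ob$H) / sqrt(oa$v + ob$v)
  df_want <- (oa$v + ob$v)^2 / (oa$v^2 / oa$N + ob$v^2 / ob$N)
  expect_equal(got$t, t_want, tolerance = 1e-9)
  expect_equal(got$df, df_want, tolerance = 1e-9)
  expect_equal(got$p, 2 * pt(abs(t_want), df_want, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical samples: t = 0, p = 1
  same <- hutcheson_t(shannon(a), shannon(a))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # clearly different diversities at large N: tiny p
  big1 <- shannon(rep(100, 50))
  big2 <- shannon(c(rep(2, 25), 4950))
  expect_lt(hutcheson_t(big1, big2)$p, 0.01)
})
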