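test_that("mol percent normalizes to 100 and rejects empty profiles", {
  expect_equal(unname(mol_percent(c(GLY = 5, ALA = 5))), c(50, 50))
  expect_equal(unname(mol_percent(flat_profile())), rep(100 / 18, 18),
               tolerance = 1e-12)
  mp <- mol_percent(c(GLY = 300, ALA = 100, SER = 0))
  expect_equal(unname(mp), c(75, 25, 0))
  expect_error(mol_percent(c(GLY = 0, ALA = 0)), "all-zero")
  # property: sums to 100 for random positive profiles
  set.seed(7)
  for (i in 1:200) {
    conc <- setNames(runif(18, 0, 50), names(aa_carbon_atoms()))
    expect_equal(sum(mol_percent(conc)), 100, tolerance = 1e-9)
  }
})

test_that("THAA carbon weights concentrations by carbon atoms, linearly", {
  expect_equal(thaa_carbon(c(GLY = 100)), 0.2)
  expect_equal(thaa_carbon(c(GLY = 100, ALA = 100)), 0.5)
  expect_error(thaa_carbon(numeric(0)), "empty")
  expect_error(thaa_carbon(c(XXX = 5)), "no carbon count")
  a <- setNames(runif(18, 0, 30), names(aa_carbon_atoms()))
  b <- setNames(runif(18, 0, 30), names(aa_carbon_atoms()))
  expect_equal(thaa_carbon(a + b), thaa_carbon(a) + thaa_carbon(b),
               tolerance = 1e-12)
})

test_that("degradation index standardizes against the reference composition", {
  coefs <- synthetic_di_coefficients()
  # a profile sitting exactly at the reference means scores zero
  mp <- setNames(coefs$ref_mean, coefs$amino_acid)
  expect_equal(degradation_index(mp, coefs), 0, tolerance = 1e-12)
  # single-analyte toy table: (14 - 10) / 2 * 1 = 2
  toy <- di_coefficients("AAX", 1, 10, 2, provenance = "test")
  expect_equal(degradation_index(c(AAX = 14), toy), 2)
  # invariant under uniform concentration rescaling
  set.seed(9)
  conc <- setNames(runif(18, 1, 40), names(aa_carbon_atoms()))
  expect_equal(degradation_index(mol_percent(conc), coefs),
               degradation_index(mol_percent(3.7 * conc), coefs),
               tolerance = 1e-9)
  # monotone in each mol% with the sign of its coefficient (direct input)
  for (j in c(1, 5, 12)) {
    up <- mp
    up[j] <- up[j] + 1
    dd <- degradation_index(up, coefs) - degradation_index(mp, coefs)
    expect_equal(sign(dd), sign(coefs$coefficient[j]))
  }
  expect_error(degradation_index(c(GLY = 50), coefs), "missing analytes")
})

test_that("GABA + beta-alanine mol% sums the non-protein amino acids", {
  expect_equal(gaba_bala_molpct(c(GABA = 1.2, BALA = 0.8, GLY = 98)), 2)
  expect_warning(out <- gaba_bala_molpct(c(GABA = 1.5, GLY = 98.5)),
                 "not present")
  expect_equal(out, 1.5)
  expect_equal(suppressWarnings(gaba_bala_molpct(c(GLY = 100))), 0)
  expect_equal(suppressWarnings(gaba_bala_molpct(c(GABA = 100))), 100)
})

test_that("phase comparisons flag diagenetic direction via the pooled t-test", {
  # identical replicate sets: no change
  same <- compare_phases(c(1, 2, 3), c(1, 2, 3), "di")
  expect_equal(same$p, 1)
  expect_equal(same$direction, "no change")
  # textbook case: GABA+BALA rising 2.0 -> 3.0 with sd 0.1
  up <- compare_phases(c(2.0, 2.1, 1.9), c(3.0, 3.1, 2.9), "gaba_bala")
  expect_equal(up$t, -12.25, tolerance = 1e-3)
  expect_lt(up$p, 0.001)
  expect_equal(up$direction, "more degraded")
  # the same shift read as a DI increase means fresher material
  expect_equal(compare_phases(c(2.0, 2.1, 1.9), c(3.0, 3.1, 2.9),
                              "di")$direction, "less degraded")
  expect_error(compare_phases(1, c(1, 2)), "2 replicates")
})

test_that("long-format indicator tables aggregate per experiment, phase and replicate", {
  th <- simulate_thaa(simulation_params(n_experiments = 1), seed = 3)
  ind <- thaa_indicators(th)
  expect_equal(nrow(ind), 9)  # 3 phases x 3 replicates
  expect_true(all(ind$thaa_c_umol_l > 0))
  by_phase <- tapply(ind$gaba_bala_molpct, ind$phase, mean)
  expect_true(by_phase[["initial"]] < by_phase[["stationary"]])
  expect_true(by_phase[["stationary"]] < by_phase[["final"]])
})
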