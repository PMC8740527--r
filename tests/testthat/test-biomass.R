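test_that("cell biovolume follows the sphere/rod geometry with the 1.5 ratio rule", {
  # sphere of diameter 1 um
  expect_equal(cell_biovolume(1, 1), (4 / 3) * pi * 0.5^3, tolerance = 1e-12)
  expect_equal(round(cell_biovolume(1, 1), 4), 0.5236)
  # ratio 2 >= 1.5: rod with r = 0.5, h = 1
  expect_equal(round(cell_biovolume(2, 1), 4), 1.3090)
  # boundary ratio exactly 1.5 takes the rod branch (r = 0.5, h = 0.5)
  expect_equal(round(cell_biovolume(1.5, 1), 4), 0.9163)
  # just below the boundary: sphere with diameter (1.499 + 1)/2
  d <- (1.499 + 1) / 2
  expect_equal(cell_biovolume(1.499, 1), (4 / 3) * pi * (d / 2)^3)
  expect_error(cell_biovolume(1, 2), "reversed")
  expect_error(cell_biovolume(1, 0), "positive")
})

test_that("biovolume matches the direct geometric formulas on random dimensions", {
  set.seed(11)
  mn <- runif(1000, 0.2, 1.5)
  mx <- mn * runif(1000, 1, 3)
  got <- cell_biovolume(mx, mn)
  for (i in seq_len(1000)) {
    expected <- if (mx[i] / mn[i] < 1.5) {
      r <- ((mx[i] + mn[i]) / 2) / 2
      (4 / 3) * pi * r^3
    } else {
      r <- mn[i] / 2
      (4 / 3) * pi * r^3 + pi * r^2 * (mx[i] - mn[i])
    }
    expect_equal(got[i], expected, tolerance = 1e-12)
  }
  # monotone in each dimension within a branch
  expect_true(cell_biovolume(2.2, 1) > cell_biovolume(2, 1))
  expect_true(cell_biovolume(1.2, 1.1) > cell_biovolume(1.1, 1))
})

test_that("cell carbon applies the configured power law", {
  expect_equal(cell_carbon(1, "EXPORTS"), 91.71)
  expect_equal(cell_carbon(1, "Malfatti"), 103.02)
  expect_equal(round(cell_carbon(0.05, "EXPORTS"), 2), 11.75)
  # power-law scaling: C(V)/C(kV) = k^-b
  conv <- carbon_conversion("Gundersen")
  for (k in c(0.1, 0.5, 2, 10)) {
    expect_equal(cell_carbon(0.04, conv) / cell_carbon(k * 0.04, conv),
                 k^(-conv$b), tolerance = 1e-12)
  }
  expect_error(cell_carbon(0), "positive")
  expect_error(carbon_conversion("nope"), "unknown conversion")
  custom <- carbon_conversion("mine", a = 50, b = 1)
  expect_equal(cell_carbon(2, custom), 100)
})

test_that("biomass concentration is the exact unit bridge and is linear", {
  expect_equal(biomass_concentration(1e6, 12.011), 1, tolerance = 1e-12)
  expect_equal(biomass_concentration(0, 5), 0)
  expect_equal(biomass_concentration(2e6, 12.011), 2, tolerance = 1e-12)
  x <- 3.1e5; y <- 8.7e5
  expect_equal(biomass_concentration(x + y, 9.7),
               biomass_concentration(x, 9.7) + biomass_concentration(y, 9.7),
               tolerance = 1e-12)
  expect_error(biomass_concentration(-1, 10), "non-negative")
})

test_that("filter carbon correction subtracts the blank and rescales by retention", {
  expect_equal(round(correct_filter_carbon(20), 2), 18.77)
  expect_equal(correct_filter_carbon(5.3), 0)
  expect_equal(correct_filter_carbon(4.0), 0)  # floors at zero
  fc <- filter_correction(blank_ug_c_per_l = 0, retention_fraction = 1)
  expect_equal(correct_filter_carbon(7, fc), 7)
  expect_error(filter_correction(retention_fraction = 0), "retention")
})

test_that("biomass estimation uses the mean biovolume, not the mean of carbons", {
  cells <- tibble::tibble(
    experiment_id = "e1", time_days = 0, image_id = 1,
    max_dim_um = c(0.4, 0.6), min_dim_um = c(0.4, 0.6))
  ab <- tibble::tibble(experiment_id = "e1", time_days = c(0, 1),
                       replicate = 1, cells_per_ml = c(1e5, 2e5))
  out <- estimate_biomass(cells, ab)
  vbar <- mean(cell_biovolume(c(0.4, 0.6), c(0.4, 0.6)))
  expect_equal(out$cell_carbon_fg, rep(cell_carbon(vbar), 2))
  expect_false(isTRUE(all.equal(out$cell_carbon_fg[1],
                                mean(cell_carbon(cell_biovolume(c(0.4, 0.6),
                                                                c(0.4, 0.6)))))))
  expect_equal(out$bb_umol_c_per_l[2] / out$bb_umol_c_per_l[1], 2)
})
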