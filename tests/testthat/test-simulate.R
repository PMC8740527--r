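test_that("generators are pure functions of parameters and seed", {
  p <- simulation_params(n_experiments = 2)
  expect_identical(simulate_growth(p, 5), simulate_growth(p, 5))
  expect_identical(simulate_doc(p, 5), simulate_doc(p, 5))
  expect_identical(simulate_asv(p, 5)$counts, simulate_asv(p, 5)$counts)
  expect_false(identical(simulate_growth(p, 5)$abundance$cells_per_ml,
                         simulate_growth(p, 6)$abundance$cells_per_ml))
})

test_that("simulated growth plateaus at the configured stationary day", {
  p <- simulation_params(n_experiments = 2,
                         treatments = c("diluted", "undiluted"))
  hits <- unlist(lapply(1:12, function(s) {
    g <- simulate_growth(p, s)
    vapply(split(g$abundance, g$abundance$experiment_id), function(d)
      detect_stationary(d$time_days, d$cells_per_ml), numeric(1))
  }))
  expect_true(all(abs(hits - p$stationary_day) <= 2))
  expect_gte(mean(abs(hits - p$stationary_day) <= 1), 0.75)
  # undiluted experiments decline after stationary phase
  g <- simulate_growth(p, 3)
  u <- subset(g$abundance, experiment_id == "exp02_u_5m")
  curve_end <- mean(u$cells_per_ml[u$time_days >= 10])
  curve_peak <- max(u$cells_per_ml)
  expect_lt(curve_end, curve_peak)
  # biovolumes land in the configured range
  v <- cell_biovolume(g$cells$max_dim_um, g$cells$min_dim_um)
  expect_true(all(v > 0.9 * p$biovolume_range[1] &
                    v < 1.1 * p$biovolume_range[2]))
})

test_that("noiseless organic carbon closes the loop on the true growth efficiency", {
  p <- simulation_params(n_experiments = 1, bge_true = 0.3, doc_noise_sd = 0,
                         abundance_cv = 0)
  g <- simulate_growth(p, 2)
  oc <- simulate_doc(p, 2)
  bb <- estimate_biomass(g$cells, g$abundance)
  r <- experiment_rates(oc$time_days, oc$oc_umol_l, bb$time_days,
                        bb$bb_umol_c_per_l, p$stationary_day)
  expect_equal(r$bp / r$short_rate, 0.3, tolerance = 0.02)
  # bge_true = 1 leaves DOC* flat over the growth window
  p1 <- simulation_params(n_experiments = 1, bge_true = 0.999,
                          doc_noise_sd = 0, abundance_cv = 0)
  oc1 <- simulate_doc(p1, 2)
  g1 <- simulate_growth(p1, 2)
  bb1 <- estimate_biomass(g1$cells, g1$abundance)
  r1 <- experiment_rates(oc1$time_days, oc1$oc_umol_l, bb1$time_days,
                         bb1$bb_umol_c_per_l, p1$stationary_day)
  expect_lt(abs(r1$short_rate - p1$bp_rate_true), 0.05)
})

test_that("amino-acid trajectories move monotonically toward the degraded endmember", {
  p <- simulation_params(n_experiments = 1)
  em_fresh <- simulate_thaa(
    simulation_params(n_experiments = 1,
                      thaa_mix = c(initial = 0, stationary = 0.5,
                                   final = 1), thaa_cv = 0), 4)
  ind <- thaa_indicators(em_fresh)
  by_phase <- tapply(ind$gaba_bala_molpct, ind$phase, mean)
  expect_lt(by_phase[["initial"]], by_phase[["stationary"]])
  expect_lt(by_phase[["stationary"]], by_phase[["final"]])
  di <- tapply(ind$di_score, ind$phase, mean)
  expect_gt(di[["initial"]], di[["stationary"]])
  expect_gt(di[["stationary"]], di[["final"]])
})

test_that("MS simulation plants a decaying labile class and removable contaminants", {
  p <- simulation_params(n_experiments = 4, n_features = 600)
  ms <- simulate_ms(p, 9)
  kept <- blank_filter(ms$areas, ms$blank)
  expect_false(any(ms$truth$contaminant %in% rownames(kept)))
  z <- zscore_matrix(kept)
  zc <- zscore_change(z, ms$samples$phase[match(colnames(z),
                                                ms$samples$sample_id)])
  cs <- class_change_summary(zc$delta_z,
                             ms$classes[zc$feature_id])
  aa <- cs[cs$compound_class == "amino acid-like", ]
  expect_lt(aa$mean_delta_z, -0.5)
  expect_lt(aa$p, 0.05)
  # stable classes stay near zero
  terp <- cs[cs$compound_class == "terpenoid-like", ]
  expect_lt(abs(terp$mean_delta_z), 0.3)
})

test_that("ASV simulation respects read depths and plants detectable responders", {
  p <- simulation_params(n_experiments = 3)
  a <- simulate_asv(p, 21)
  depths <- colSums(a$counts)
  expect_true(all(depths >= p$read_depth_range[1] &
                    depths <= p$read_depth_range[2]))
  expect_equal(nrow(a$counts), p$n_asvs)
  ra <- relative_abundance(a$counts)
  top <- top_n_asvs(ra, 100)
  si <- a$samples$sample_id[a$samples$phase == "initial"][1]
  ss <- a$samples$sample_id[a$samples$phase == "stationary"][1]
  lfc <- log2_fold_change(setNames(ra[top$asv_ids, si], top$asv_ids),
                          ra[top$asv_ids, ss],
                          depth_initial = depths[[si]],
                          depth_stationary = depths[[ss]])
  flagged <- lfc$asv_id[lfc$responder]
  planted <- intersect(a$truth$responders, top$asv_ids)
  expect_gte(length(intersect(flagged, planted)) / length(planted), 0.85)
  # diversity rises toward stationary phase as responders spread the mass
  h <- vapply(c(si, ss), function(s) shannon(a$counts[, s])$H, numeric(1))
  expect_gt(h[2], h[1])
})
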