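#' Rates, gates and growth efficiency for one experiment
#'
#' Wires the per-experiment calculation together: fits bacterial production
#' (biomass vs time, T0 to stationary), forms DOC* by subtracting the
#' (interpolated) biomass trajectory from each organic-carbon observation,
#' fits the short-term (T0 to stationary) and long-term (stationary to
#' final) removal rates, applies the resolvability gates and, when all gates
#' pass, reports the growth efficiency with propagated uncertainty.
#'
#' @param oc_times,oc_values Organic carbon observations (replicate vials as
#'   independent points), umol C L^-1.
#' @param bb_times,bb_values Biomass estimates, umol C L^-1.
#' @param t_stationary Stationary onset day (e.g. from
#'   [detect_stationary()]).
#' @param gates A [detection_gates()].
#' @param conversion_name Label recorded with the result.
#' @return One-row tibble: DOC* endpoints, short/long removal fits, BP fit,
#'   gate flags, `bge` and `bge_error` (NA unless all gates pass).
#' @export
experiment_rates <- function(oc_times, oc_values, bb_times, bb_values,
                             t_stationary, gates = detection_gates(),
                             conversion_name = "EXPORTS") {
  bb_at <- stats::approx(bb_times, bb_values, xout = oc_times, rule = 2)$y
  ds <- doc_star(oc_values, bb_at)
  tol <- 1e-9
  short <- oc_times <= t_stationary + tol
  long <- oc_times >= t_stationary - tol
  bp_win <- bb_times <= t_stationary + tol

  bp_fit <- fit_rate(bb_times[bp_win], bb_values[bp_win], "short_term",
                     sign = "production")
  short_fit <- fit_rate(oc_times[short], ds[short], "short_term",
                        sign = "removal")
  long_fit <- if (sum(long) >= 3 && length(unique(oc_times[long])) >= 2) {
    fit_rate(oc_times[long], ds[long], "long_term", sign = "removal")
  } else {
    tibble::tibble(slope = NA_real_, slope_se = NA_real_,
                   intercept = NA_real_, n = sum(long),
                   p_two_tailed = NA_real_, window = "long_term")
  }

  t0 <- min(oc_times)
  t_near_stat <- max(oc_times[short])
  delta_doc <- mean(ds[oc_times == t0]) - mean(ds[oc_times == t_near_stat])
  g <- resolvable(delta_doc, bp_fit$p_two_tailed, short_fit$p_two_tailed,
                  gates)
  ok <- g$overall && bp_fit$slope > 0 && short_fit$slope > 0
  bge_val <- if (ok) bge(bp_fit$slope, short_fit$slope) else NA_real_
  bge_err <- if (ok) {
    bge_error(bge_val, short_fit$slope, short_fit$slope_se,
              bp_fit$slope, bp_fit$slope_se)
  } else NA_real_

  tibble::tibble(
    t_stationary = t_stationary,
    doc0 = mean(ds[oc_times == t0]),
    doc_final = mean(ds[oc_times == max(oc_times)]),
    delta_doc = delta_doc,
    short_rate = short_fit$slope, short_rate_se = short_fit$slope_se,
    short_n = short_fit$n, short_p = short_fit$p_two_tailed,
    long_rate = long_fit$slope, long_n = long_fit$n,
    long_p = long_fit$p_two_tailed,
    bp = bp_fit$slope, bp_se = bp_fit$slope_se, bp_p = bp_fit$p_two_tailed,
    gate_delta_doc = g$delta_doc, gate_p_bp = g$p_bp, gate_p_doc = g$p_doc,
    resolvable = g$overall,
    bge = bge_val, bge_error = bge_err,
    conversion_name = conversion_name)
}

#' Pipeline configuration
#'
#' Collects the thresholds and options of the full analysis. All constants
#' default to the study's reporting conventions: 0.7 umol C L^-1 instrument
#' precision (so a 1.4 umol C L^-1 resolvability gate), log2(3) ~ 1.58
#' responder threshold, 3x process-blank filter, top 100 ASVs, alpha 0.05.
#'
#' @param input_dir Directory containing the input tables (the schemas
#'   written by [simulate_bundle()]).
#' @param conversion Biovolume-to-carbon conversion name.
#' @param gates A [detection_gates()].
#' @param lfc_threshold Responder threshold on the log2 scale.
#' @param blank_factor Process-blank multiplier.
#' @param top_n ASVs retained for the responder analysis.
#' @param alpha Significance level used throughout.
#' @param n_permutations Permutations for the indicator test.
#' @param seed Seed recorded in, and used by, every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, conversion = "EXPORTS",
                            gates = detection_gates(),
                            lfc_threshold = log2(3), blank_factor = 3,
                            top_n = 100, alpha = 0.05,
                            n_permutations = 999, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may set any argument of [pipeline_config()]; `gates` is
#' given as a mapping with keys `instrument_precision`, `min_delta_doc`,
#' `alpha`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gates)) y$gates <- do.call(detection_gates, y$gates)
  do.call(pipeline_config, y)
}

#' Run the full remineralization analysis pipeline
#'
#' Reads the input bundle, runs every analysis stage and writes the report
#' tables: `table2.csv` (per-experiment rates, gates and growth
#' efficiencies), `thaa_indicators.csv` and `thaa_phase_tests.csv`,
#' `class_changes.csv` and `correlations.csv` (MS1 z-score analysis),
#' `diversity.csv`, `responders.csv`, `indicators.csv` (ASV analysis) and
#' `run_log.yml` (seed, configuration and input hashes). Outputs are
#' deterministic given the configuration seed and are written atomically
#' (to a temporary directory first), so a failing stage leaves no partial
#' output.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the output tibbles.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  rd <- function(f) readr::read_csv(file.path(config$input_dir, f),
                                    show_col_types = FALSE)
  abundance <- rd("abundance.csv")
  cells <- rd("cells.csv")
  oc <- rd("oc.csv")
  experiments <- rd("experiments.csv")
  thaa <- rd("thaa.csv")
  ms_features <- rd("ms_features.csv")
  ms_blanks <- rd("ms_blanks.csv")
  ms_samples <- rd("ms_samples.csv")
  asv_counts <- rd("asv_counts.csv")
  asv_samples <- rd("asv_samples.csv")

  ## rates and growth efficiency ------------------------------------------
  bb <- estimate_biomass(cells, abundance, config$conversion)
  rates <- dplyr::bind_rows(lapply(experiments$experiment_id, function(id) {
    bbi <- bb[bb$experiment_id == id, ]
    oci <- oc[oc$experiment_id == id, ]
    meta <- experiments[experiments$experiment_id == id, ]
    t_stat <- if ("days_to_stationary" %in% names(meta) &&
                  is.finite(meta$days_to_stationary)) {
      meta$days_to_stationary
    } else {
      detect_stationary(bbi$time_days, bbi$cells_per_ml)
    }
    res <- experiment_rates(oci$time_days, oci$oc_umol_l,
                            bbi$time_days, bbi$bb_umol_c_per_l,
                            t_stat, config$gates, config$conversion)
    dplyr::bind_cols(tibble::tibble(experiment_id = id,
                                    depth_m = meta$depth_m,
                                    treatment = meta$treatment), res)
  }))

  ## amino acid indicators -------------------------------------------------
  ind <- thaa_indicators(thaa)
  phase_tests <- dplyr::bind_rows(lapply(
    unique(ind$experiment_id), function(id) {
      d <- ind[ind$experiment_id == id, ]
      pairs <- list(c("initial", "stationary"), c("initial", "final"))
      dplyr::bind_rows(lapply(pairs, function(pr) {
        a <- d[d$phase == pr[1], ]; b <- d[d$phase == pr[2], ]
        if (nrow(a) < 2 || nrow(b) < 2) return(NULL)
        di <- compare_phases(a$di_score, b$di_score, "di", config$alpha)
        gb <- compare_phases(a$gaba_bala_molpct, b$gaba_bala_molpct,
                             "gaba_bala", config$alpha)
        tibble::tibble(experiment_id = id, phase_a = pr[1], phase_b = pr[2],
                       di_delta = di$delta, di_p = di$p,
                       di_direction = di$direction,
                       gaba_bala_delta = gb$delta, gaba_bala_p = gb$p,
                       gaba_bala_direction = gb$direction)
      }))
    }))

  ## MS1 feature z-scores ---------------------------------------------------
  areas <- tidyr::pivot_wider(ms_features[, c("feature_id", "sample_id",
                                              "peak_area")],
                              names_from = "sample_id",
                              values_from = "peak_area")
  amat <- as.matrix(areas[, -1])
  rownames(amat) <- areas$feature_id
  amat <- amat[, ms_samples$sample_id, drop = FALSE]
  blank <- setNames(ms_blanks$blank_area, ms_blanks$feature_id)
  kept <- blank_filter(amat, blank, config$blank_factor)
  z <- suppressWarnings(zscore_matrix(kept))
  classes <- setNames(ms_features$compound_class, ms_features$feature_id)
  classes <- classes[!duplicated(names(classes))]
  dz_by_exp <- vapply(unique(ms_samples$experiment_id), function(id) {
    sel <- ms_samples$experiment_id == id
    zc <- zscore_change(z[, ms_samples$sample_id[sel], drop = FALSE],
                        ms_samples$phase[sel])
    zc$delta_z
  }, numeric(nrow(z)))
  rownames(dz_by_exp) <- rownames(z)
  class_changes <- class_change_summary(rowMeans(dz_by_exp),
                                        classes[rownames(z)])
  covariates <- list(
    initial_di = {
      v <- ind[ind$phase == "initial", ]
      agg <- tapply(v$di_score, v$experiment_id, mean)
      as.numeric(agg[colnames(dz_by_exp)])
    },
    short_rate = rates$short_rate[match(colnames(dz_by_exp),
                                        rates$experiment_id)])
  correlations <- dplyr::bind_rows(lapply(names(covariates), function(nm) {
    cv <- covariates[[nm]]
    if (all(is.na(cv)) || sd(cv, na.rm = TRUE) == 0) return(NULL)
    res <- correlate_feature_changes(dz_by_exp, cv, classes[rownames(z)],
                                     alpha = config$alpha)
    dplyr::bind_cols(tibble::tibble(covariate = nm), res$features)
  }))

  ## ASV community -----------------------------------------------------------
  cmat <- tidyr::pivot_wider(asv_counts, names_from = "sample_id",
                             values_from = "count")
  cm <- as.matrix(cmat[, -1])
  rownames(cm) <- cmat$asv_id
  cm <- cm[, asv_samples$sample_id, drop = FALSE]
  ra <- relative_abundance(cm)
  diversity <- dplyr::bind_rows(lapply(seq_len(ncol(cm)), function(j) {
    dplyr::bind_cols(asv_samples[j, ], shannon(cm[, j]))
  }))
  top <- top_n_asvs(ra, min(config$top_n, nrow(ra)))
  responders <- dplyr::bind_rows(lapply(
    unique(asv_samples$experiment_id), function(id) {
      si <- asv_samples$sample_id[asv_samples$experiment_id == id &
                                    asv_samples$phase == "initial"]
      ss <- asv_samples$sample_id[asv_samples$experiment_id == id &
                                    asv_samples$phase == "stationary"]
      if (length(si) != 1 || length(ss) != 1) return(NULL)
      lfc <- log2_fold_change(
        setNames(ra[top$asv_ids, si], top$asv_ids), ra[top$asv_ids, ss],
        depth_initial = sum(cm[, si]), depth_stationary = sum(cm[, ss]),
        threshold = config$lfc_threshold)
      dplyr::bind_cols(tibble::tibble(experiment_id = id), lfc)
    }))
  indicators <- indicator_rg(ra[top$asv_ids, , drop = FALSE],
                             asv_samples$phase,
                             n_permutations = config$n_permutations,
                             seed = config$seed)

  out <- list(table2 = rates, thaa_indicators = ind,
              thaa_phase_tests = phase_tests, class_changes = class_changes,
              correlations = correlations, diversity = diversity,
              responders = responders, indicators = indicators)

  ## atomic write ------------------------------------------------------------
  tmp <- tempfile("omrex_out_")
  dir.create(tmp, recursive = TRUE)
  for (nm in names(out)) {
    readr::write_csv(out[[nm]], file.path(tmp, paste0(nm, ".csv")))
  }
  cfg_flat <- config
  cfg_flat$gates <- unclass(config$gates)
  yaml::write_yaml(list(seed = config$seed,
                        config = lapply(unclass(cfg_flat), function(x)
                          if (is.list(x)) x else as.character(x)),
                        n_experiments = nrow(experiments)),
                   file.path(tmp, "run_log.yml"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(tmp)) {
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(tmp, recursive = TRUE)
  invisible(out)
}
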