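#' Parameters for the synthetic experiment generator
#'
#' Defaults emulate the conditions of the 2018 Station Papa dilution
#' incubations: initial DOC* between 54 and 61 umol C L^-1 with 0.7 umol C
#' L^-1 analytical noise on triplicate vials, growth reaching stationary
#' phase within 6-10 days and monitored to ~90 days, growth efficiencies in
#' the 0.15-0.45 range, cell biovolumes of 0.03-0.09 um^3, amino-acid
#' compositions drifting from a fresh toward a degraded endmember with total
#' THAA carbon declining by about a third of the DOC* decline, ~1800 MS1
#' features with a decaying amino-acid-like subset and a sub-blank
#' contaminant subset, and ASV tables of ~492 variants at read depths of
#' 10,951-44,686 with a dominant stable fraction and planted responders of
#' at least threefold.
#'
#' @param n_experiments Number of incubation experiments.
#' @param depths,treatments Depth (m) and treatment (`"diluted"` /
#'   `"undiluted"`) per experiment, recycled.
#' @param doc0_range Initial DOC* range, umol C L^-1.
#' @param bge_true True growth efficiency per experiment, recycled, in (0,1).
#' @param bp_rate_true True bacterial production rate, umol C L^-1 d^-1.
#' @param stationary_day Day growth effectively plateaus (6-10).
#' @param final_day Final long-term observation day.
#' @param doc_noise_sd Analytical noise of organic carbon, umol C L^-1.
#' @param doc_replicates Vials per organic-carbon time point.
#' @param n_short_times Organic-carbon time points from T0 to stationary.
#' @param n0_cells_ml Inoculum abundance, cells mL^-1.
#' @param abundance_cv Lognormal coefficient of variation of abundance
#'   observations.
#' @param death_rate Post-stationary exponential decline rate (d^-1) applied
#'   in undiluted experiments (grazing-enhanced death phase).
#' @param biovolume_range Cell biovolume range, um^3.
#' @param cells_per_image,n_images Cell-dimension sampling design.
#' @param thaa_c0 Initial THAA carbon, umol C L^-1.
#' @param thaa_doc_fraction Fraction of the DOC* decline mirrored by the
#'   THAA-C decline.
#' @param thaa_mix Degradation mixing fraction at the initial, stationary and
#'   final phases (0 = fresh endmember, 1 = degraded endmember; strictly
#'   increasing).
#' @param thaa_cv Replicate noise of amino-acid concentrations.
#' @param n_features MS1 features before blank filtering.
#' @param class_proportions Named compound-class proportions summing to 1.
#' @param labile_classes Classes whose features decay by stationary phase.
#' @param ms_decay_log Mean log-scale decay of labile features.
#' @param ms_noise_sd Log-scale sample noise of peak areas.
#' @param contaminant_fraction Fraction of features sitting below the 3x
#'   process blank.
#' @param n_asvs Number of amplicon sequence variants.
#' @param read_depth_range Per-sample read depth range.
#' @param dirichlet_alpha Mean per-ASV Dirichlet concentration; the total
#'   concentration is `dirichlet_alpha * n_asvs`.
#' @param n_responders Number of planted responder ASVs.
#' @param responder_fold_range Fold-increase range of planted responders
#'   (>= 3).
#' @param dominant_fraction Combined relative abundance of the small stable
#'   dominant block (SAR11/SAR86-like).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_experiments = 6,
                              depths = c(5, 5, 5, 35, 50, 95),
                              treatments = c("diluted", "undiluted",
                                             "diluted", "diluted",
                                             "undiluted", "undiluted"),
                              doc0_range = c(54, 61),
                              bge_true = 0.30,
                              bp_rate_true = 0.15,
                              stationary_day = 7,
                              final_day = 90,
                              doc_noise_sd = 0.7,
                              doc_replicates = 3,
                              n_short_times = 7,
                              n0_cells_ml = 1.5e5,
                              abundance_cv = 0.05,
                              death_rate = 0.06,
                              biovolume_range = c(0.03, 0.09),
                              cells_per_image = 40,
                              n_images = 5,
                              thaa_c0 = 1.45,
                              thaa_doc_fraction = 0.33,
                              thaa_mix = c(initial = 0.05, stationary = 0.45,
                                           final = 0.70),
                              thaa_cv = 0.05,
                              n_features = 1831,
                              class_proportions = c("amino acid-like" = 0.25,
                                                    "terpenoid-like" = 0.25,
                                                    "lipid-like" = 0.10,
                                                    "steroid-like" = 0.05,
                                                    "other" = 0.10,
                                                    "unannotated" = 0.25),
                              labile_classes = "amino acid-like",
                              ms_decay_log = 0.35,
                              ms_noise_sd = 0.3,
                              contaminant_fraction = 0.10,
                              n_asvs = 492,
                              read_depth_range = c(10951, 44686),
                              dirichlet_alpha = 50,
                              n_responders = 25,
                              responder_fold_range = c(4, 12),
                              dominant_fraction = 0.45) {
  p <- as.list(environment())
  p$depths <- rep_len(p$depths, n_experiments)
  p$treatments <- rep_len(p$treatments, n_experiments)
  p$bge_true <- rep_len(p$bge_true, n_experiments)
  stopifnot(all(p$bge_true > 0), all(p$bge_true < 1),
            bp_rate_true > 0, doc_noise_sd >= 0,
            all(diff(p$thaa_mix) > 0), all(p$thaa_mix >= 0),
            all(p$thaa_mix <= 1),
            all(p$responder_fold_range >= 1))
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

# Evaluate code with a fixed RNG state, restoring the caller's state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Noiseless abundance trajectory (cells/mL): logistic rise reaching 95% of
# carrying capacity at the stationary day, flat thereafter, with an optional
# exponential death phase in undiluted experiments.
.abundance_curve <- function(t, params, experiment) {
  n0 <- params$n0_cells_ml
  # Carrying capacity chosen so the biomass gain over the growth window
  # corresponds to the target production rate under the EXPORTS conversion
  # at the mid-range biovolume.
  ccell <- cell_carbon(mean(params$biovolume_range), "EXPORTS")
  delta_bb <- params$bp_rate_true * params$stationary_day
  K <- n0 + delta_bb * .C_MOLAR_MASS * 1e6 / ccell
  C <- (K - n0) / n0
  r <- log(C / (1 / 0.95 - 1)) / params$stationary_day
  n <- K / (1 + C * exp(-r * pmin(t, params$stationary_day)))
  if (params$treatments[experiment] == "undiluted") {
    post <- t > params$stationary_day
    n[post] <- n[post] *
      exp(-params$death_rate * (t[post] - params$stationary_day))
  }
  n
}

# Noiseless biomass trajectory (umol C/L) matching .abundance_curve.
.biomass_curve <- function(t, params, experiment) {
  ccell <- cell_carbon(mean(params$biovolume_range), "EXPORTS")
  biomass_concentration(.abundance_curve(t, params, experiment), ccell)
}

#' Simulate bacterioplankton growth observations
#'
#' Generates daily abundance observations (lognormal observation noise
#' around a logistic trajectory that plateaus at the configured stationary
#' day, with a post-stationary death phase in undiluted experiments) and
#' per-cell dimension measurements whose biovolumes fall in the configured
#' range (a mix of near-spherical and rod-shaped cells).
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @return A list with tibbles `abundance` (`experiment_id`, `time_days`,
#'   `replicate`, `cells_per_ml`) and `cells` (`experiment_id`, `time_days`,
#'   `image_id`, `max_dim_um`, `min_dim_um`).
#' @export
simulate_growth <- function(params = simulation_params(), seed = 1) {
  .with_seed(seed, {
    days <- 0:ceiling(params$stationary_day + 4)
    ab <- list(); cl <- list()
    for (e in seq_len(params$n_experiments)) {
      id <- .exp_id(params, e)
      mu <- .abundance_curve(days, params, e)
      obs <- mu * rlnorm(length(days), -params$abundance_cv^2 / 2,
                         params$abundance_cv)
      ab[[e]] <- tibble::tibble(experiment_id = id, time_days = days,
                                replicate = 1L, cells_per_ml = obs)
      # dimensions measured at T0 and stationary
      for (tp in c(0, params$stationary_day)) {
        n_cells <- params$cells_per_image * params$n_images
        v <- runif(n_cells, params$biovolume_range[1],
                   params$biovolume_range[2])
        rod <- runif(n_cells) < 0.2
        d <- (6 * v / pi)^(1 / 3)
        half_spread <- d * runif(n_cells, 0, 0.18)
        mx <- d + half_spread
        mn <- d - half_spread
        # rods: fixed width, length set to match the drawn biovolume
        rr <- 0.175
        h <- pmax(0.01, (v - (4 / 3) * pi * rr^3) / (pi * rr^2))
        mx[rod] <- 2 * rr + h[rod]
        mn[rod] <- 2 * rr
        cl[[length(cl) + 1]] <- tibble::tibble(
          experiment_id = id, time_days = tp,
          image_id = rep(seq_len(params$n_images),
                         each = params$cells_per_image),
          max_dim_um = mx, min_dim_um = mn)
      }
    }
    list(abundance = dplyr::bind_rows(ab), cells = dplyr::bind_rows(cl))
  })
}

.exp_id <- function(params, e) {
  sprintf("exp%02d_%s_%gm", e, substr(params$treatments[e], 1, 1),
          params$depths[e])
}

#' Simulate organic carbon observations
#'
#' The generative inverse of the growth-efficiency quotient: organic carbon
#' is \deqn{OC(t) = DOC_0 + BB(t) - \frac{BB(t) - BB(0)}{BGE_{true}} +
#' \epsilon, \quad \epsilon \sim N(0, \sigma^2)} per replicate vial, so that
#' after biomass correction the DOC* removal rate is `bp_rate_true /
#' bge_true`. Sampling covers `n_short_times` evenly spaced points from T0
#' to the stationary day plus sparse long-term points out to `final_day`.
#'
#' @inheritParams simulate_growth
#' @return A tibble `oc` (`experiment_id`, `time_days`, `replicate`,
#'   `oc_umol_l`) plus attribute `doc0` (named per experiment).
#' @export
simulate_doc <- function(params = simulation_params(), seed = 1) {
  .with_seed(seed, {
    short_t <- seq(0, params$stationary_day, length.out = params$n_short_times)
    long_t <- unique(c(30, 60, params$final_day))
    times <- unique(c(short_t, long_t))
    out <- list()
    doc0 <- numeric(params$n_experiments)
    for (e in seq_len(params$n_experiments)) {
      id <- .exp_id(params, e)
      doc0[e] <- runif(1, params$doc0_range[1], params$doc0_range[2])
      bb <- .biomass_curve(times, params, e)
      # long-term removal continues slowly past stationary
      removed <- (bb - bb[1]) / params$bge_true[e]
      removed <- pmax(removed, 0)
      long_extra <- 0.02 * pmax(times - params$stationary_day, 0)
      oc_true <- doc0[e] + bb - removed - long_extra
      for (r in seq_len(params$doc_replicates)) {
        out[[length(out) + 1]] <- tibble::tibble(
          experiment_id = id, time_days = times, replicate = r,
          oc_umol_l = oc_true + rnorm(length(times), 0, params$doc_noise_sd))
      }
    }
    oc <- dplyr::bind_rows(out)
    names(doc0) <- vapply(seq_len(params$n_experiments),
                          function(e) .exp_id(params, e), character(1))
    attr(oc, "doc0") <- doc0
    oc
  })
}

# Fresh and degraded amino-acid mol% endmembers (normalized to 100).
.thaa_endmembers <- function() {
  fresh <- c(ASP = 9.5, GLU = 10.5, SER = 6.0, HIS = 2.0, GLY = 11.5,
             THR = 5.5, ARG = 4.5, ALA = 8.5, TYR = 3.2, MET = 1.6,
             VAL = 6.0, PHE = 3.6, ILE = 4.8, LEU = 7.5, LYS = 6.5,
             TRP = 1.1, GABA = 0.4, BALA = 0.3)
  degraded <- c(ASP = 9.2, GLU = 7.5, SER = 8.3, HIS = 1.8, GLY = 19.7,
                THR = 6.0, ARG = 3.2, ALA = 11.0, TYR = 2.0, MET = 1.1,
                VAL = 5.3, PHE = 2.2, ILE = 3.0, LEU = 4.5, LYS = 4.2,
                TRP = 0.6, GABA = 3.2, BALA = 2.2)
  list(fresh = 100 * fresh / sum(fresh),
       degraded = 100 * degraded / sum(degraded))
}

#' Simulate total hydrolyzable amino acid observations
#'
#' Phase compositions are convex mixtures moving from a fresh toward a
#' degraded endmember (so mol% GABA + beta-alanine strictly increases and
#' the degradation index decreases along the incubation), while total THAA
#' carbon declines by `thaa_doc_fraction` of the experiment's DOC* decline.
#' Triplicate profiles carry lognormal concentration noise.
#'
#' @inheritParams simulate_growth
#' @param replicates Replicate profiles per phase.
#' @return Long tibble (`experiment_id`, `phase`, `replicate`, `amino_acid`,
#'   `conc_nmol_l`).
#' @export
simulate_thaa <- function(params = simulation_params(), seed = 1,
                          replicates = 3) {
  .with_seed(seed, {
    em <- .thaa_endmembers()
    atoms <- aa_carbon_atoms()
    phases <- names(params$thaa_mix)
    out <- list()
    for (e in seq_len(params$n_experiments)) {
      id <- .exp_id(params, e)
      rate <- params$bp_rate_true / params$bge_true[e]
      doc_decline <- c(initial = 0,
                       stationary = rate * params$stationary_day,
                       final = rate * params$stationary_day +
                         0.02 * (params$final_day - params$stationary_day))
      for (ph in phases) {
        m <- params$thaa_mix[[ph]]
        molpct <- (1 - m) * em$fresh + m * em$degraded
        target_c <- max(params$thaa_c0 -
                          params$thaa_doc_fraction * doc_decline[[ph]], 0.1)
        mean_atoms <- sum(molpct / 100 * atoms[names(molpct)])
        total_nmol <- target_c * 1000 / mean_atoms
        conc <- molpct / 100 * total_nmol
        for (r in seq_len(replicates)) {
          obs <- conc * rlnorm(length(conc), -params$thaa_cv^2 / 2,
                               params$thaa_cv)
          out[[length(out) + 1]] <- tibble::tibble(
            experiment_id = id, phase = ph, replicate = r,
            amino_acid = names(conc), conc_nmol_l = unname(obs))
        }
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate an MS1 feature table with process blanks
#'
#' Lognormal base peak areas per feature; features in the labile classes
#' decay between the initial and stationary sample of every experiment by
#' `ms_decay_log` on the log scale, a contaminant subset sits below three
#' times its process blank, and all features carry lognormal sample noise.
#'
#' @inheritParams simulate_growth
#' @return A list with `areas` (feature x sample matrix), `blank` (named
#'   vector), `classes` (named vector), `samples` (tibble: `sample_id`,
#'   `experiment_id`, `phase`) and `truth` (labile and contaminant feature
#'   ids).
#' @export
simulate_ms <- function(params = simulation_params(), seed = 1) {
  .with_seed(seed, {
    nf <- params$n_features
    fid <- sprintf("ft%05d", seq_len(nf))
    classes <- sample(names(params$class_proportions), nf, replace = TRUE,
                      prob = params$class_proportions)
    names(classes) <- fid
    base <- rlnorm(nf, log(1e6), 1)
    labile <- fid[classes %in% params$labile_classes]
    contaminant <- sample(fid, round(params$contaminant_fraction * nf))
    blank <- setNames(rep(0, nf), fid)
    blank[contaminant] <- base[match(contaminant, fid)]  # max area < 3x blank
    exps <- vapply(seq_len(params$n_experiments),
                   function(e) .exp_id(params, e), character(1))
    samples <- tidyr::expand_grid(experiment_id = exps,
                                  phase = c("initial", "stationary"))
    samples$sample_id <- paste(samples$experiment_id, samples$phase, sep = ".")
    areas <- matrix(0, nf, nrow(samples),
                    dimnames = list(fid, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- log(base)
      if (samples$phase[j] == "stationary") {
        mu[fid %in% labile] <- mu[fid %in% labile] - params$ms_decay_log
      }
      areas[, j] <- rlnorm(nf, mu, params$ms_noise_sd)
    }
    list(areas = areas, blank = blank, classes = classes,
         samples = samples[, c("sample_id", "experiment_id", "phase")],
         truth = list(labile = labile, contaminant = contaminant))
  })
}

#' Simulate an ASV count table with planted responders
#'
#' Base compositions carry a small dominant stable block (mimicking the
#' SAR11/SAR86 fraction of oceanic surface communities) over a lognormal
#' abundance tail. A planted responder set is multiplied by fold factors
#' drawn from `responder_fold_range` at stationary phase before
#' renormalization. Per-sample compositions are Dirichlet-multinomial with
#' total concentration `dirichlet_alpha * n_asvs`, at read depths uniform in
#' `read_depth_range`.
#'
#' @inheritParams simulate_growth
#' @return A list with `counts` (ASV x sample integer matrix), `taxonomy`
#'   (tibble: `asv_id`, `taxonomy`), `samples` (tibble: `sample_id`,
#'   `experiment_id`, `phase`, `depth_m`) and `truth` (responder ids and
#'   folds).
#' @export
simulate_asv <- function(params = simulation_params(), seed = 1) {
  .with_seed(seed, {
    S <- params$n_asvs
    ids <- sprintf("asv%04d", seq_len(S))
    n_dom <- 6
    tail_w <- sort(rlnorm(S - n_dom, 0, 1.4), decreasing = TRUE)
    tail_w <- (1 - params$dominant_fraction) * tail_w / sum(tail_w)
    dom_w <- params$dominant_fraction *
      c(0.35, 0.2, 0.15, 0.12, 0.1, 0.08)
    base <- setNames(c(dom_w, tail_w), ids)
    # responders come from the moderately abundant mid-tail (rare enough to
    # be realistic responders, common enough to stay countable)
    hi <- min(n_dom + 144, S - 10)
    lo <- min(n_dom + 24, hi - 2 * params$n_responders)
    responders <- sample(ids[lo:hi], params$n_responders)
    folds <- setNames(runif(params$n_responders,
                            params$responder_fold_range[1],
                            params$responder_fold_range[2]), responders)
    # plant the folds on the realized relative-abundance scale: responders
    # get exactly fold x base, the stable remainder shrinks to compensate
    resp_mass <- sum(base[responders] * folds)
    if (resp_mass >= 0.6) {
      stop("planted responder mass too large; reduce folds or n_responders",
           call. = FALSE)
    }
    stat_mean <- base * (1 - resp_mass) / (1 - sum(base[responders]))
    stat_mean[responders] <- base[responders] * folds
    exps <- vapply(seq_len(params$n_experiments),
                   function(e) .exp_id(params, e), character(1))
    samples <- tidyr::expand_grid(experiment_id = exps,
                                  phase = c("initial", "stationary"))
    samples$sample_id <- paste(samples$experiment_id, samples$phase, sep = ".")
    samples$depth_m <- params$depths[match(samples$experiment_id, exps)]
    theta <- params$dirichlet_alpha * S
    counts <- matrix(0L, S, nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mean_p <- if (samples$phase[j] == "initial") base else stat_mean
      g <- rgamma(S, shape = theta * mean_p, rate = 1)
      p <- g / sum(g)
      depth <- round(runif(1, params$read_depth_range[1],
                           params$read_depth_range[2]))
      counts[, j] <- as.integer(rmultinom(1, depth, p))
    }
    taxonomy <- tibble::tibble(
      asv_id = ids,
      taxonomy = c(paste0("Bacteria;Alphaproteobacteria;SAR11-like;clade", 1:4),
                   "Bacteria;Gammaproteobacteria;SAR86-like;clade1",
                   "Bacteria;Bacteroidetes;Flavobacteriaceae-like;NS-like",
                   paste0("Bacteria;synthetic;lineage;taxon",
                          seq_len(S - n_dom))))
    list(counts = counts, taxonomy = taxonomy,
         samples = samples[, c("sample_id", "experiment_id", "phase",
                               "depth_m")],
         truth = list(responders = responders, folds = folds))
  })
}

#' Simulate a complete experiment bundle
#'
#' Runs all generators under one seed and optionally writes the input tables
#' in the schemas consumed by [run_pipeline()].
#'
#' @inheritParams simulate_growth
#' @param out_dir Optional directory; when given, writes `abundance.csv`,
#'   `cells.csv`, `oc.csv`, `experiments.csv`, `thaa.csv`,
#'   `ms_features.csv`, `ms_blanks.csv`, `ms_samples.csv`,
#'   `asv_counts.csv`, `asv_samples.csv`.
#' @return A list with elements `growth`, `oc`, `thaa`, `ms`, `asv`,
#'   `experiments` and `params`.
#' @export
simulate_bundle <- function(params = simulation_params(), seed = 1,
                            out_dir = NULL) {
  growth <- simulate_growth(params, seed)
  oc <- simulate_doc(params, seed + 1)
  thaa <- simulate_thaa(params, seed + 2)
  ms <- simulate_ms(params, seed + 3)
  asv <- simulate_asv(params, seed + 4)
  experiments <- tibble::tibble(
    experiment_id = vapply(seq_len(params$n_experiments),
                           function(e) .exp_id(params, e), character(1)),
    depth_m = params$depths,
    treatment = params$treatments,
    days_to_stationary = params$stationary_day,
    days_to_final = params$final_day)
  bundle <- list(growth = growth, oc = oc, thaa = thaa, ms = ms, asv = asv,
                 experiments = experiments, params = params, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    w(growth$abundance, "abundance.csv")
    w(growth$cells, "cells.csv")
    w(oc, "oc.csv")
    w(experiments, "experiments.csv")
    w(thaa, "thaa.csv")
    areas_long <- tibble::as_tibble(as.data.frame.table(
      ms$areas, responseName = "peak_area", stringsAsFactors = FALSE))
    names(areas_long)[1:2] <- c("feature_id", "sample_id")
    areas_long$compound_class <- ms$classes[areas_long$feature_id]
    w(areas_long, "ms_features.csv")
    w(tibble::tibble(feature_id = names(ms$blank), blank_area = ms$blank),
      "ms_blanks.csv")
    w(ms$samples, "ms_samples.csv")
    counts_long <- tibble::as_tibble(as.data.frame.table(
      asv$counts, responseName = "count", stringsAsFactors = FALSE))
    names(counts_long)[1:2] <- c("asv_id", "sample_id")
    w(counts_long, "asv_counts.csv")
    w(asv$samples, "asv_samples.csv")
  }
  bundle
}
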