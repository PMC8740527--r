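#' Default hydrolyzable amino acid analyte set
#'
#' Eighteen OPA-detectable amino acids, including the two non-protein
#' diagenesis markers gamma-aminobutyric acid (GABA) and beta-alanine (BALA),
#' with the number of carbon atoms per molecule used to express total
#' hydrolyzable amino acids (THAA) in carbon units. Both the analyte list and
#' the carbon counts are configuration: pass your own named vector wherever a
#' `carbon_atoms` argument is accepted.
#'
#' @return Named integer vector of carbon atoms per amino acid.
#' @export
aa_carbon_atoms <- function() {
  c(ASP = 4L, GLU = 5L, SER = 3L, HIS = 6L, GLY = 2L, THR = 4L,
    ARG = 6L, ALA = 3L, TYR = 9L, MET = 5L, VAL = 5L, PHE = 9L,
    ILE = 6L, LEU = 6L, LYS = 6L, TRP = 11L, GABA = 4L, BALA = 3L)
}

#' Mole percent composition of an amino acid profile
#'
#' @param concentrations Named numeric vector of concentrations (nmol L^-1),
#'   all >= 0 with a positive total.
#' @return Named vector of mol% values summing to 100.
#' @export
mol_percent <- function(concentrations) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("concentrations must be a named vector", call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  total <- sum(concentrations)
  if (total <= 0) {
    stop("all-zero profile: composition undefined", call. = FALSE)
  }
  100 * concentrations / total
}

#' THAA concentration in carbon units
#'
#' Weights each amino acid concentration (nmol L^-1) by its carbon atoms and
#' converts to umol C L^-1.
#'
#' @param concentrations Named vector of concentrations, nmol L^-1.
#' @param carbon_atoms Named vector mapping every analyte present to its
#'   carbon atom count; defaults to [aa_carbon_atoms()].
#' @return THAA carbon, umol C L^-1.
#' @export
thaa_carbon <- function(concentrations, carbon_atoms = aa_carbon_atoms()) {
  if (length(concentrations) == 0) {
    stop("empty amino acid profile", call. = FALSE)
  }
  nm <- toupper(names(concentrations))
  missing <- setdiff(nm, toupper(names(carbon_atoms)))
  if (length(missing)) {
    stop("no carbon count configured for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  atoms <- carbon_atoms[match(nm, toupper(names(carbon_atoms)))]
  sum(concentrations * as.numeric(atoms)) / 1000
}

#' Degradation index coefficient table
#'
#' The degradation index (DI) scores an amino acid mol% composition against a
#' reference data set: each amino acid's mol% is standardized by a reference
#' mean and standard deviation and weighted by a loading (factor coefficient)
#' from a principal component analysis of variously degraded organic matter.
#' Lower DI indicates more diagenetically altered material. The published
#' loading tables are not redistributed here; `di_coefficients()` validates a
#' user-supplied table, and [synthetic_di_coefficients()] provides a clearly
#' labelled synthetic stand-in for testing and simulation.
#'
#' @param amino_acid Character vector of analyte names.
#' @param coefficient Factor coefficient (PCA loading) per amino acid.
#' @param ref_mean,ref_sd Reference mol% mean and standard deviation; `ref_sd`
#'   must be positive.
#' @param provenance Single string recording where the values come from.
#' @return A tibble of class `di_coefficients`.
#' @export
di_coefficients <- function(amino_acid, coefficient, ref_mean, ref_sd,
                            provenance = "user-supplied") {
  stopifnot(length(amino_acid) == length(coefficient),
            length(amino_acid) == length(ref_mean),
            length(amino_acid) == length(ref_sd))
  if (any(ref_sd <= 0)) stop("reference sd must be positive", call. = FALSE)
  out <- tibble::tibble(amino_acid = toupper(amino_acid),
                        coefficient = coefficient,
                        ref_mean = ref_mean, ref_sd = ref_sd)
  attr(out, "provenance") <- provenance
  class(out) <- c("di_coefficients", class(out))
  out
}

#' Synthetic degradation-index coefficients
#'
#' A stand-in coefficient table for the 16 protein amino acids, built for
#' testing and simulation only: positive loadings on amino acids enriched in
#' fresh planktonic protein (e.g. PHE, GLU, LEU, ILE, TYR) and negative
#' loadings on those that accumulate with degradation (e.g. GLY, SER, ALA),
#' with reference means/sds spanning the fresh-to-degraded mixing line of the
#' synthetic generator. These are NOT the published literature loadings;
#' substitute the published table via [di_coefficients()] for real data.
#'
#' @return A `di_coefficients` table with provenance `"synthetic"`.
#' @export
synthetic_di_coefficients <- function() {
  di_coefficients(
    amino_acid  = c("ASP", "GLU", "SER", "HIS", "GLY", "THR", "ARG", "ALA",
                    "TYR", "MET", "VAL", "PHE", "ILE", "LEU", "LYS", "TRP"),
    coefficient = c(-0.10, 0.12, -0.12, 0.05, -0.18, -0.05, 0.06, -0.12,
                    0.14, 0.08, 0.07, 0.16, 0.13, 0.15, 0.06, 0.05),
    ref_mean    = c(9.4, 9.0, 7.2, 1.9, 15.6, 5.7, 3.8, 9.8,
                    2.6, 1.4, 5.7, 2.9, 3.9, 6.0, 5.4, 0.9),
    ref_sd      = c(1.0, 1.4, 1.1, 0.4, 3.2, 0.8, 0.7, 1.2,
                    0.7, 0.4, 0.8, 0.7, 0.8, 1.1, 1.0, 0.3),
    provenance  = "synthetic"
  )
}

#' Degradation index score
#'
#' \deqn{DI = \sum_i \frac{molpct_i - \mu_i}{\sigma_i} \, c_i}
#' over the amino acids in the coefficient table. Because the score is a
#' function of mol%, it is invariant to uniform rescaling of the raw
#' concentrations. Lower values indicate more degraded organic matter.
#'
#' @param molpct Named mol% vector covering every amino acid in the table
#'   (as from [mol_percent()]).
#' @param coefficients A [di_coefficients()] table.
#' @return The DI score (dimensionless).
#' @export
degradation_index <- function(molpct, coefficients = synthetic_di_coefficients()) {
  nm <- toupper(names(molpct))
  idx <- match(coefficients$amino_acid, nm)
  if (anyNA(idx)) {
    stop("mol% profile is missing analytes required by the DI table: ",
         paste(coefficients$amino_acid[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  sum((molpct[idx] - coefficients$ref_mean) / coefficients$ref_sd *
        coefficients$coefficient)
}

#' Combined mol% of GABA and beta-alanine
#'
#' The two non-protein amino acids accumulate as organic matter degrades, so
#' their combined mole fraction rises with diagenetic alteration. Analytes
#' absent from the profile count as zero, with a warning.
#'
#' @param molpct Named mol% vector.
#' @param names_gaba,names_bala Accepted spellings of the two analytes.
#' @return Combined mol%, in `[0, 100]`.
#' @export
gaba_bala_molpct <- function(molpct,
                             names_gaba = c("GABA"),
                             names_bala = c("BALA", "B-ALA", "BETA-ALA")) {
  nm <- toupper(names(molpct))
  pick <- function(cands, label) {
    i <- which(nm %in% toupper(cands))
    if (length(i) == 0) {
      warning(label, " not present in profile; counted as 0", call. = FALSE)
      return(0)
    }
    sum(molpct[i])
  }
  pick(names_gaba, "GABA") + pick(names_bala, "beta-alanine")
}

#' Compare a degradation indicator between two phases
#'
#' Two-tailed two-sample t-test (pooled variance) of replicate indicator
#' values between two incubation phases, with a diagenetic direction call:
#' the organic matter is "more degraded" in phase B when the DI decreases or
#' the GABA + beta-alanine mol% increases significantly, and "less degraded"
#' for the opposite significant shift.
#'
#' @param a,b Numeric replicate indicator values for phases A and B
#'   (each n >= 2).
#' @param indicator `"di"` (degradation decreases the value) or
#'   `"gaba_bala"` (degradation increases it).
#' @param alpha Significance level for the direction flag.
#' @return A list with `delta` (mean B - mean A), `t`, `df`, `p` and
#'   `direction` (`"more degraded"`, `"less degraded"` or `"no change"`).
#' @export
compare_phases <- function(a, b, indicator = c("di", "gaba_bala"),
                           alpha = 0.05) {
  indicator <- match.arg(indicator)
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 replicates per phase", call. = FALSE)
  }
  delta <- mean(b) - mean(a)
  if (var(a) == 0 && var(b) == 0) {
    tt <- list(statistic = c(t = if (delta == 0) 0 else sign(delta) * Inf),
               parameter = c(df = length(a) + length(b) - 2),
               p.value = if (delta == 0) 1 else 0)
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
  }
  direction <- "no change"
  if (tt$p.value < alpha) {
    degraded_up <- (indicator == "gaba_bala" && delta > 0) ||
      (indicator == "di" && delta < 0)
    direction <- if (degraded_up) "more degraded" else "less degraded"
  }
  list(delta = delta, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, direction = direction)
}

#' Per-profile degradation indicators from a long-format THAA table
#'
#' @param thaa Long data frame with columns `experiment_id`, `phase`,
#'   `replicate`, `amino_acid`, `conc_nmol_l`.
#' @param coefficients DI coefficient table.
#' @param carbon_atoms Carbon atoms per amino acid.
#' @return A tibble with one row per experiment x phase x replicate:
#'   `di_score`, `gaba_bala_molpct`, `thaa_c_umol_l`.
#' @export
thaa_indicators <- function(thaa, coefficients = synthetic_di_coefficients(),
                            carbon_atoms = aa_carbon_atoms()) {
  thaa <- tibble::as_tibble(thaa)
  grp <- dplyr::group_by(thaa, .data$experiment_id, .data$phase,
                         .data$replicate)
  dplyr::summarise(grp, {
    conc <- setNames(.data$conc_nmol_l, .data$amino_acid)
    mp <- mol_percent(conc)
    tibble::tibble(
      di_score = degradation_index(mp, coefficients),
      gaba_bala_molpct = suppressWarnings(gaba_bala_molpct(mp)),
      thaa_c_umol_l = thaa_carbon(conc, carbon_atoms))
  }, .groups = "drop")
}
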