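#' Relative abundances from an ASV count matrix
#'
#' @param counts Matrix of non-negative integer counts, ASVs x samples, with
#'   positive per-sample totals.
#' @return Matrix of fractions; each column sums to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/")
}

#' Most abundant ASVs and their coverage
#'
#' Selects the `n` ASVs with the highest mean relative abundance across
#' samples (ties broken by ASV id) and reports, per sample, the fraction of
#' the community the subset accounts for.
#'
#' @param ra Relative abundance matrix (ASVs x samples, rows named).
#' @param n Number of ASVs to keep (default 100); clipped with a warning when
#'   it exceeds the number available.
#' @return A list with `asv_ids` (ordered by decreasing mean abundance),
#'   `coverage` (per-sample fractions) and `mean_coverage`.
#' @export
top_n_asvs <- function(ra, n = 100) {
  stopifnot(is.matrix(ra), !is.null(rownames(ra)))
  if (n > nrow(ra)) {
    warning("n exceeds the number of ASVs; using all ", nrow(ra),
            call. = FALSE)
    n <- nrow(ra)
  }
  means <- rowMeans(ra)
  ord <- order(-means, rownames(ra))
  ids <- rownames(ra)[ord][seq_len(n)]
  coverage <- colSums(ra[ids, , drop = FALSE])
  list(asv_ids = ids, coverage = coverage, mean_coverage = mean(coverage))
}

#' Log2 fold change of relative abundance between phases
#'
#' \eqn{log_2((ra_{st} + \epsilon_{st}) / (ra_{in} + \epsilon_{in}))} per
#' ASV, with responder flags for increases of at least `threshold`
#' (default log2(3) ~ 1.58, a threefold increase). The pseudocounts default
#' to one read at each phase's sequencing depth (the detection limit), which
#' keeps fold changes finite for ASVs absent in one phase; set both to zero
#' to leave zeros undefined (NA where both phases are zero).
#'
#' @param ra_initial,ra_stationary Relative abundance vectors (same ASVs).
#' @param depth_initial,depth_stationary Read depths used to form the
#'   detection-limit pseudocounts `1/depth`; ignored when `pseudocount` is
#'   given.
#' @param pseudocount Optional length-2 numeric `c(initial, stationary)`
#'   overriding the depth-based pseudocounts.
#' @param threshold Responder threshold on the log2 scale.
#' @return Tibble with `ra_initial`, `ra_stationary`, `log2fc`, `responder`
#'   (plus `asv_id` when the inputs are named).
#' @export
log2_fold_change <- function(ra_initial, ra_stationary,
                             depth_initial = NULL, depth_stationary = NULL,
                             pseudocount = NULL, threshold = log2(3)) {
  stopifnot(length(ra_initial) == length(ra_stationary))
  if (any(ra_initial < 0) || any(ra_stationary < 0)) {
    stop("relative abundances must be non-negative", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    eps_in <- if (is.null(depth_initial)) 0 else 1 / depth_initial
    eps_st <- if (is.null(depth_stationary)) 0 else 1 / depth_stationary
  } else {
    eps_in <- pseudocount[1]
    eps_st <- pseudocount[2]
  }
  num <- ra_stationary + eps_st
  den <- ra_initial + eps_in
  lfc <- ifelse(num == 0 & den == 0, NA_real_,
                ifelse(den == 0, Inf, ifelse(num == 0, -Inf,
                                             log2(num / den))))
  out <- tibble::tibble(ra_initial = ra_initial,
                        ra_stationary = ra_stationary,
                        log2fc = lfc,
                        responder = !is.na(lfc) & lfc >= threshold)
  if (!is.null(names(ra_initial))) {
    out <- dplyr::bind_cols(tibble::tibble(asv_id = names(ra_initial)), out)
  }
  out
}

#' Shannon-Wiener diversity with variance and confidence interval
#'
#' Computes \eqn{H = -\sum p_i \ln p_i} (natural log by default) for one
#' sample of counts, with the large-sample variance estimator
#' \deqn{Var(H) = \frac{\sum p_i (\ln p_i)^2 - H^2}{N} + \frac{S-1}{2N^2}}
#' and the associated 95% confidence interval, as used for Hutcheson's
#' t-test on diversity indices.
#'
#' @param counts Non-negative counts for one sample, positive total.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return A tibble with `H`, `variance`, `ci95_low`, `ci95_high`,
#'   `n_reads`, `n_asvs`.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- sum(counts)
  if (N <= 0) stop("empty sample", call. = FALSE)
  p <- counts[counts > 0] / N
  lp <- log(p, base = base)
  H <- -sum(p * lp)
  S <- length(p)
  v <- (sum(p * lp^2) - H^2) / N + (S - 1) / (2 * N^2)
  v <- max(v, 0)
  tibble::tibble(H = H, variance = v,
                 ci95_low = H - 1.96 * sqrt(v), ci95_high = H + 1.96 * sqrt(v),
                 n_reads = N, n_asvs = S)
}

#' Hutcheson's t-test for two Shannon indices
#'
#' \deqn{t = \frac{H_1 - H_2}{\sqrt{V_1 + V_2}}, \quad
#'   df = \frac{(V_1 + V_2)^2}{V_1^2/N_1 + V_2^2/N_2}}
#' with a two-tailed p-value from the t distribution.
#'
#' @param div1,div2 Results of [shannon()] for the two samples.
#' @return A list with `t`, `df`, `p`.
#' @export
hutcheson_t <- function(div1, div2) {
  vsum <- div1$variance + div2$variance
  if (vsum <= 0) {
    if (div1$H == div2$H) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero combined variance with unequal H: degenerate test",
         call. = FALSE)
  }
  t <- (div1$H - div2$H) / sqrt(vsum)
  df <- vsum^2 / (div1$variance^2 / div1$n_reads +
                    div2$variance^2 / div2$n_reads)
  list(t = t, df = df, p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}
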