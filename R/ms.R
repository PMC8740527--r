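#' Process-blank filtering of an MS1 feature table
#'
#' Retains a feature only when its maximum peak area across samples exceeds
#' `factor` times its process-blank area; features with a zero blank are kept
#' whenever any sample area is positive. This is the standard "3x blank"
#' contamination screen for untargeted LC-MS feature tables.
#'
#' @param areas Numeric matrix of peak areas, features x samples, with
#'   feature ids as row names.
#' @param blank Named numeric vector of process-blank areas, one per feature
#'   (0 allowed).
#' @param factor Blank multiplier, > 0 (default 3).
#' @return The retained sub-matrix (possibly with zero rows).
#' @export
blank_filter <- function(areas, blank, factor = 3) {
  stopifnot(is.matrix(areas), factor > 0)
  if (is.null(rownames(areas))) stop("areas needs feature row names", call. = FALSE)
  blank <- blank[rownames(areas)]
  if (anyNA(blank)) stop("every feature needs a blank area", call. = FALSE)
  if (any(areas < 0) || any(blank < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  mx <- apply(areas, 1, max)
  keep <- ifelse(blank == 0, mx > 0, mx > factor * blank)
  areas[keep, , drop = FALSE]
}

#' Per-feature z-scores across samples
#'
#' Standardizes each feature's abundances across all samples: subtract the
#' feature's mean and divide by its standard deviation (sample sd, n - 1).
#' Each retained row then has mean 0 and sd 1 by construction, so a z-score
#' change of -1 between two samples is a one-standard-deviation decrease of
#' that feature. Features that are constant across samples have no defined
#' z-score and are dropped with a warning.
#'
#' @param areas Feature x sample matrix of (relative) abundances. Because
#'   z-scores are location- and scale-free per feature, raw peak areas and
#'   total-area-normalized abundances give identical results up to
#'   sample-level scaling; set `normalize = TRUE` to divide each sample by
#'   its total area first.
#' @param normalize Normalize samples to total area before standardizing.
#' @return Matrix of z-scores with constant features removed.
#' @export
zscore_matrix <- function(areas, normalize = FALSE) {
  stopifnot(is.matrix(areas), ncol(areas) >= 2)
  if (normalize) {
    totals <- colSums(areas)
    if (any(totals <= 0)) stop("sample with zero total area", call. = FALSE)
    areas <- sweep(areas, 2, totals, "/")
  }
  mu <- rowMeans(areas)
  s <- apply(areas, 1, sd)
  constant <- s == 0
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) excluded from z-scoring",
            call. = FALSE)
  }
  (areas[!constant, , drop = FALSE] - mu[!constant]) / s[!constant]
}

#' Per-feature z-score change between two phases
#'
#' @param z Z-score matrix from [zscore_matrix()].
#' @param phase Character vector over columns of `z`, with levels
#'   `"initial"` and `"stationary"`; the change is the mean stationary
#'   z-score minus the mean initial z-score per feature.
#' @return Tibble with `feature_id`, `z_initial`, `z_stationary`, `delta_z`.
#' @export
zscore_change <- function(z, phase) {
  stopifnot(ncol(z) == length(phase))
  if (!all(c("initial", "stationary") %in% phase)) {
    stop("phase must contain both 'initial' and 'stationary'", call. = FALSE)
  }
  zi <- rowMeans(z[, phase == "initial", drop = FALSE])
  zs <- rowMeans(z[, phase == "stationary", drop = FALSE])
  tibble::tibble(feature_id = rownames(z), z_initial = zi,
                 z_stationary = zs, delta_z = zs - zi)
}

#' Compound-class summary of z-score changes
#'
#' One-sample two-tailed t-test of each class's feature-level z-score changes
#' against zero. Classes with fewer than `min_features` members are reported
#' without a p-value. A class whose changes are all identical is handled as
#' exact: p = 0 when the common value is nonzero, p = 1 otherwise.
#'
#' @param delta_z Named numeric vector of per-feature z-score changes.
#' @param classes Character vector of compound classes, same order/names.
#' @param min_features Minimum class size for testing (default 2).
#' @return Tibble with `compound_class`, `n`, `mean_delta_z`, `se`, `p`.
#' @export
class_change_summary <- function(delta_z, classes, min_features = 2) {
  stopifnot(length(delta_z) == length(classes))
  if (length(delta_z) == 0) {
    return(tibble::tibble(compound_class = character(), n = integer(),
                          mean_delta_z = double(), se = double(),
                          p = double()))
  }
  dplyr::bind_rows(lapply(split(delta_z, classes), function(x) {
    n <- length(x)
    m <- mean(x)
    se <- if (n > 1) sd(x) / sqrt(n) else NA_real_
    p <- if (n < min_features) {
      NA_real_
    } else if (isTRUE(all.equal(sd(x), 0)) || sd(x) == 0) {
      if (m == 0) 1 else 0
    } else {
      t.test(x, mu = 0)$p.value
    }
    tibble::tibble(n = n, mean_delta_z = m, se = se, p = p)
  }), .id = "compound_class")[, c("compound_class", "n", "mean_delta_z",
                                  "se", "p")]
}

#' Correlate feature changes with a bioavailability covariate
#'
#' Pearson correlation of each feature's z-score change across experiments
#' with an experiment-level covariate (e.g. the initial degradation index or
#' the short-term DOC* removal rate), with two-tailed p-values, and counts of
#' significantly correlated features per compound class.
#'
#' @param delta_z Feature x experiment matrix of z-score changes (features as
#'   row names); each feature needs >= `min_n` finite paired observations.
#' @param covariate Numeric vector over experiments (columns).
#' @param classes Named character vector of compound classes per feature.
#' @param alpha Significance level for the per-class counts.
#' @param min_n Minimum paired observations per feature (default 4).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   default `"none"` (raw p-values, matching the conventional screen).
#' @return A list with `features` (tibble: `feature_id`, `compound_class`,
#'   `r`, `p`, `n`) and `class_counts` (tibble: `compound_class`,
#'   `n_significant`).
#' @export
correlate_feature_changes <- function(delta_z, covariate, classes,
                                      alpha = 0.05, min_n = 4,
                                      adjust = "none") {
  stopifnot(is.matrix(delta_z), ncol(delta_z) == length(covariate))
  if (sd(covariate, na.rm = TRUE) == 0) {
    stop("constant covariate: correlation undefined", call. = FALSE)
  }
  rows <- lapply(rownames(delta_z), function(f) {
    x <- delta_z[f, ]
    ok <- is.finite(x) & is.finite(covariate)
    if (sum(ok) < min_n || sd(x[ok]) == 0) {
      return(tibble::tibble(feature_id = f, r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- cor.test(x[ok], covariate[ok], method = "pearson")
    tibble::tibble(feature_id = f, r = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  })
  features <- dplyr::bind_rows(rows)
  features$compound_class <- unname(classes[features$feature_id])
  features$p_adj <- p.adjust(features$p, method = adjust)
  sig <- features[!is.na(features$p_adj) & features$p_adj < alpha, ]
  counts <- dplyr::count(sig, .data$compound_class, name = "n_significant")
  list(features = features[, c("feature_id", "compound_class", "r", "p",
                               "p_adj", "n")],
       class_counts = counts)
}
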