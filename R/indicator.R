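#' Group-equalized point-biserial indicator statistic with permutation test
#'
#' For each ASV, computes the group-size-corrected point-biserial correlation
#' ("r.g") between its abundance vector and membership in each group: the
#' Pearson correlation of abundance with the 0/1 membership indicator, with
#' samples weighted by `N / (K * n_g)` so every group contributes equally
#' regardless of its size (for equal group sizes this is the ordinary
#' point-biserial correlation). Each ASV is associated with its best group
#' (largest r.g) and that association is tested by permuting the sample
#' labels: the permutation statistic is the maximum r.g over groups, and
#' \deqn{p = \frac{1 + \#\{stat_{perm} \ge stat_{obs}\}}{1 + n_{perm}}.}
#' With `exhaustive = TRUE` every distinct relabelling is enumerated instead
#' and \eqn{p = \#\{stat \ge stat_{obs}\} / n_{arrangements}} (the observed
#' labelling is one of the arrangements).
#'
#' @param abundance ASV x sample matrix of (relative) abundances, rows named.
#' @param groups Character/factor vector of group labels over samples
#'   (>= 2 groups, each non-empty).
#' @param n_permutations Number of random permutations (default 9999).
#' @param seed Integer seed making the permutation test reproducible.
#' @param exhaustive Enumerate all distinct label arrangements instead of
#'   sampling; only allowed for small sample sets (<= `max_exhaustive`
#'   samples).
#' @param max_exhaustive Sample-count cap for exhaustive enumeration.
#' @return Tibble with one row per ASV x group: `asv_id`, `group`,
#'   `rg_statistic`, `best` (is this the ASV's associated group),
#'   `permutation_p` (on the best group, NA elsewhere), `n_permutations`.
#'   ASVs constant across samples get `NA` statistics.
#' @export
indicator_rg <- function(abundance, groups, n_permutations = 9999,
                         seed = NULL, exhaustive = FALSE,
                         max_exhaustive = 8) {
  abundance <- as.matrix(abundance)
  stopifnot(!is.null(rownames(abundance)),
            ncol(abundance) == length(groups))
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2) stop("need at least 2 groups", call. = FALSE)

  obs <- .rg_matrix(abundance, groups, levs)
  obs_max <- .row_max(obs)

  if (exhaustive) {
    if (ncol(abundance) > max_exhaustive) {
      stop("exhaustive enumeration limited to ", max_exhaustive, " samples",
           call. = FALSE)
    }
    perms <- .distinct_label_arrangements(groups)
    n_eff <- length(perms)
    exceed <- integer(nrow(abundance))
    for (g in perms) {
      pm <- .row_max(.rg_matrix(abundance, g, levs))
      exceed <- exceed + as.integer(!is.na(pm) & pm >= obs_max - 1e-12)
    }
    p_best <- ifelse(is.na(obs_max), NA_real_, exceed / n_eff)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
              add = TRUE)
      set.seed(seed)
    }
    n_eff <- n_permutations
    exceed <- integer(nrow(abundance))
    for (b in seq_len(n_permutations)) {
      pm <- .row_max(.rg_matrix(abundance, sample(groups), levs))
      exceed <- exceed + as.integer(!is.na(pm) & pm >= obs_max - 1e-12)
    }
    p_best <- ifelse(is.na(obs_max), NA_real_,
                     (1 + exceed) / (1 + n_permutations))
  }

  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(asv_id = rownames(abundance)),
                     tibble::as_tibble(obs)),
    -"asv_id", names_to = "group", values_to = "rg_statistic")
  best_idx <- apply(obs, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  best_group <- levs[best_idx]
  i <- match(out$asv_id, rownames(abundance))
  out$best <- !is.na(best_group[i]) & out$group == best_group[i]
  out$permutation_p <- ifelse(out$best, p_best[i], NA_real_)
  out$n_permutations <- n_eff
  out
}

# Group-equalized point-biserial correlations for all ASVs at once.
# X: m x N abundance matrix; returns m x K matrix of r.g values.
.rg_matrix <- function(X, groups, levs) {
  N <- ncol(X)
  K <- length(levs)
  sizes <- table(factor(groups, levels = levs))
  w <- N / (K * as.numeric(sizes[match(groups, levs)]))
  mx <- as.numeric(X %*% w) / N
  Xc <- X - mx                       # recycles mx down columns: row-centering
  vx <- as.numeric((Xc * Xc) %*% w)
  Tm <- vapply(levs, function(k) as.numeric(groups == k), numeric(N))
  mt <- as.numeric(crossprod(Tm, w)) / N
  Tc <- sweep(Tm, 2, mt)
  vt <- as.numeric(crossprod(Tc * Tc, w))
  covm <- Xc %*% (w * Tc)
  rg <- covm / sqrt(outer(vx, vt))
  rg[vx <= 0, ] <- NA_real_
  colnames(rg) <- levs
  rg
}

.row_max <- function(m) {
  apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
}

# All distinct arrangements of a label multiset over the sample positions.
.distinct_label_arrangements <- function(groups) {
  rec <- function(remaining) {
    if (length(remaining) == 0) return(list(character(0)))
    out <- list()
    for (lab in unique(remaining)) {
      rest <- remaining[-match(lab, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1]] <- c(lab, tail)
    }
    out
  }
  rec(sort(groups))
}
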