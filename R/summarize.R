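#' Published per-experiment rates from the Station Papa incubation study
#'
#' Loads the per-experiment results table of the 2018 EXPORTS Ocean Station
#' Papa DOM remineralization experiments (surface and subsurface, diluted and
#' undiluted): initial and final DOC*, short- and long-term DOC* removal
#' rates with fit sizes and p-values, bacterial production rates and growth
#' efficiencies under the three biovolume-to-carbon conversions. Values are
#' the published, rounded table cells; p-values printed as "< 0.001" are
#' encoded as 0.0005. Used as a worked-example fixture for
#' [summarize_experiments()].
#'
#' @return A tibble, one row per experiment x treatment.
#' @export
osp_rate_table <- function() {
  path <- system.file("extdata", "osp_rate_table.csv", package = "omrex")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Summarize experiment rates and growth efficiencies by stratum
#'
#' Computes the study-level summary statistics from a per-experiment results
#' table shaped like [osp_rate_table()]: means and sample standard deviations
#' of significant short-term DOC* removal rates, long-term rates, bacterial
#' production rates and growth efficiencies, overall and within strata
#' (surface = depth <= `surface_max_depth` m vs subsurface; diluted vs
#' undiluted). Rate means include only rows whose fit was significant at
#' `alpha`; production means pool all rows (production regressions were
#' individually significant by design); BGE means include only rows where a
#' BGE was reported, i.e. rows passing all resolvability gates.
#'
#' @param results Data frame with at least `depth_m`, `treatment`,
#'   `short_rate`, `short_p` and optionally `long_rate`, `long_p`,
#'   `bp_<conversion>` and `bge_<conversion>` columns.
#' @param conversion Which conversion's production/BGE columns to summarize
#'   (suffix of the `bp_*` / `bge_*` columns), default `"exports"`.
#' @param alpha Significance level for including a rate in rate means.
#' @param surface_max_depth Depth (m) at or above which an experiment counts
#'   as surface.
#' @return A tibble with columns `stratum`, `treatment`, `metric`, `n`,
#'   `mean`, `sd` (sd is `NA` for single entries).
#' @examples
#' summarize_experiments(osp_rate_table())
#' @export
summarize_experiments <- function(results, conversion = "exports",
                                  alpha = 0.05, surface_max_depth = 5) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    return(tibble::tibble(stratum = character(), treatment = character(),
                          metric = character(), n = integer(),
                          mean = double(), sd = double()))
  }
  bp_col <- paste0("bp_", tolower(conversion))
  bge_col <- paste0("bge_", tolower(conversion))
  results$stratum <- ifelse(results$depth_m <= surface_max_depth,
                            "surface", "subsurface")

  one <- function(x) {
    x <- x[is.finite(x)]
    tibble::tibble(n = length(x),
                   mean = if (length(x)) mean(x) else NA_real_,
                   sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  block <- function(df, stratum, treatment) {
    metrics <- list(
      short_rate = df$short_rate[!is.na(df$short_p) & df$short_p < alpha],
      long_rate = if ("long_p" %in% names(df)) {
        df$long_rate[!is.na(df$long_p) & df$long_p < alpha]
      } else numeric(),
      bp = if (bp_col %in% names(df)) df[[bp_col]] else numeric(),
      bge = if (bge_col %in% names(df)) df[[bge_col]] else numeric()
    )
    dplyr::bind_cols(
      tibble::tibble(stratum = stratum, treatment = treatment,
                     metric = names(metrics)),
      dplyr::bind_rows(lapply(metrics, one))
    )
  }

  strata <- list(all = results,
                 surface = results[results$stratum == "surface", ],
                 subsurface = results[results$stratum == "subsurface", ])
  out <- list()
  for (s in names(strata)) {
    for (tr in c("all", "diluted", "undiluted")) {
      df <- strata[[s]]
      if (tr != "all") df <- df[df$treatment == tr, ]
      out[[paste(s, tr)]] <- block(df, s, tr)
    }
  }
  dplyr::bind_rows(out)
}

#' Look up one summary cell
#'
#' Convenience accessor for a single `mean` or `sd` value in the output of
#' [summarize_experiments()].
#'
#' @param summary Output of [summarize_experiments()].
#' @param stratum,treatment,metric Row selectors.
#' @param what `"mean"`, `"sd"` or `"n"`.
#' @return A single number.
#' @export
summary_value <- function(summary, stratum, treatment, metric,
                          what = "mean") {
  row <- summary[summary$stratum == stratum & summary$treatment == treatment &
                   summary$metric == metric, ]
  if (nrow(row) != 1) stop("no unique matching summary row", call. = FALSE)
  row[[what]]
}
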