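#' Cell biovolume from maximum and minimum dimensions
#'
#' Converts epifluorescence image measurements of a cell's maximum and minimum
#' dimensions (um) into a biovolume (um^3). Cells whose max:min dimension
#' ratio is below 1.5 are treated as spheres with an assumed diameter equal to
#' the mean of the two dimensions,
#' \deqn{V = \frac{4}{3}\pi r^3, \quad r = \frac{(d_{max}+d_{min})/2}{2};}
#' cells at or above that ratio are treated as rods (cylinders with
#' hemispherical caps) of width `min_dim`,
#' \deqn{V = \frac{4}{3}\pi r^3 + \pi r^2 h, \quad r = d_{min}/2,\;
#'   h = d_{max} - d_{min}.}
#'
#' @param max_dim,min_dim Numeric vectors of cell dimensions in um;
#'   recycled to a common length. Must satisfy `max_dim >= min_dim > 0`.
#' @param sphere_ratio Max:min ratio below which a cell is treated as a
#'   sphere. Default 1.5; the boundary value itself takes the rod branch.
#' @return Numeric vector of biovolumes in um^3.
#' @examples
#' cell_biovolume(1, 1)      # sphere of diameter 1 um
#' cell_biovolume(2, 1)      # rod: ratio 2 >= 1.5
#' @export
cell_biovolume <- function(max_dim, min_dim, sphere_ratio = 1.5) {
  n <- max(length(max_dim), length(min_dim))
  max_dim <- rep_len(max_dim, n)
  min_dim <- rep_len(min_dim, n)
  if (any(!is.finite(max_dim)) || any(!is.finite(min_dim))) {
    stop("cell dimensions must be finite", call. = FALSE)
  }
  if (any(min_dim <= 0)) {
    stop("cell dimensions must be positive", call. = FALSE)
  }
  if (any(max_dim < min_dim)) {
    stop("max_dim must be >= min_dim (reversed dimensions?)", call. = FALSE)
  }
  is_sphere <- (max_dim / min_dim) < sphere_ratio
  r_sph <- ((max_dim + min_dim) / 2) / 2
  r_rod <- min_dim / 2
  h <- max_dim - min_dim
  ifelse(is_sphere,
         (4 / 3) * pi * r_sph^3,
         (4 / 3) * pi * r_rod^3 + pi * r_rod^2 * h)
}

#' Biovolume-to-carbon conversion factors
#'
#' A cell-carbon conversion is the power law
#' \eqn{C_{cell} = a V^b} with carbon in fg C per cell and biovolume V in
#' um^3. Three named conversions are built in:
#' \describe{
#'   \item{EXPORTS}{a = 91.71, b = 0.686 — derived for Station Papa
#'     bacterioplankton sampled during the EXPORTS field campaign.}
#'   \item{Gundersen}{a = 108.8, b = 0.898 — open-ocean literature value.}
#'   \item{Malfatti}{a = 103.02, b = 0.59 — coastal literature value.}
#' }
#'
#' @param name Name of a built-in conversion, or any label when `a` and `b`
#'   are supplied.
#' @param a,b Optional user-supplied coefficient (fg C um^-3b) and exponent;
#'   both must be positive.
#' @return A list of class `carbon_conversion` with elements `name`, `a`, `b`.
#' @export
carbon_conversion <- function(name = "EXPORTS", a = NULL, b = NULL) {
  builtin <- list(
    EXPORTS   = c(a = 91.71,  b = 0.686),
    Gundersen = c(a = 108.8,  b = 0.898),
    Malfatti  = c(a = 103.02, b = 0.59)
  )
  if (is.null(a) || is.null(b)) {
    if (!name %in% names(builtin)) {
      stop("unknown conversion '", name,
           "'; supply a and b for a custom conversion", call. = FALSE)
    }
    a <- builtin[[name]][["a"]]
    b <- builtin[[name]][["b"]]
  }
  if (a <= 0 || b <= 0) stop("conversion requires a > 0 and b > 0", call. = FALSE)
  structure(list(name = name, a = a, b = b), class = "carbon_conversion")
}

#' Carbon content of a cell from its biovolume
#'
#' @param biovolume Biovolume(s) in um^3, strictly positive.
#' @param conversion A [carbon_conversion()] object or the name of a built-in
#'   conversion.
#' @return Carbon per cell in fg C.
#' @examples
#' cell_carbon(0.05)                 # ~11.7 fg C for a typical oceanic cell
#' cell_carbon(1, "Malfatti")
#' @export
cell_carbon <- function(biovolume, conversion = "EXPORTS") {
  if (is.character(conversion)) conversion <- carbon_conversion(conversion)
  if (any(!is.finite(biovolume)) || any(biovolume <= 0)) {
    stop("biovolume must be positive", call. = FALSE)
  }
  conversion$a * biovolume^conversion$b
}

#' Bulk bacterioplankton biomass concentration
#'
#' Bridges cell abundance (cells mL^-1) and per-cell carbon (fg C) to a bulk
#' biomass concentration in umol C L^-1:
#' `BB = abundance * carbon_per_cell * 1e3 (mL to L) * 1e-9 (fg to ug) / 12.011`.
#'
#' @param abundance Cells mL^-1, non-negative.
#' @param carbon_per_cell fg C per cell, positive.
#' @return Biomass in umol C L^-1; exactly linear in `abundance`.
#' @export
biomass_concentration <- function(abundance, carbon_per_cell) {
  if (any(abundance < 0)) stop("abundance must be non-negative", call. = FALSE)
  if (any(carbon_per_cell <= 0)) {
    stop("carbon_per_cell must be positive", call. = FALSE)
  }
  abundance * carbon_per_cell * 1e3 * 1e-9 / .C_MOLAR_MASS
}

#' Filter blank and retention correction
#'
#' Settings for correcting particulate carbon caught on GF/75 filters:
#' a DOM-sorption blank (default 5.3 ug C L^-1, determined by passing
#' 30 kDa tangential filtrate over the filters) and the fraction of cells the
#' filter retains (default 0.783).
#'
#' @param blank_ug_c_per_l Sorption blank in ug C L^-1, >= 0.
#' @param retention_fraction Fraction of cells retained, in (0, 1].
#' @return A list of class `filter_correction`.
#' @export
filter_correction <- function(blank_ug_c_per_l = 5.3,
                              retention_fraction = 0.783) {
  if (blank_ug_c_per_l < 0) stop("blank must be >= 0", call. = FALSE)
  if (retention_fraction <= 0 || retention_fraction > 1) {
    stop("retention_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(blank_ug_c_per_l = blank_ug_c_per_l,
                 retention_fraction = retention_fraction),
            class = "filter_correction")
}

#' Blank- and retention-correct filter carbon
#'
#' `(measured - blank) / retention`, floored at zero: the blank is carbon
#' sorbed from the dissolved phase and the retention factor scales the
#' cell-associated remainder up to the whole community.
#'
#' @param measured_ug_c_per_l Measured filter carbon, ug C L^-1, >= 0.
#' @param correction A [filter_correction()].
#' @return Corrected carbon in ug C L^-1 (never negative).
#' @examples
#' correct_filter_carbon(20)   # (20 - 5.3) / 0.783
#' @export
correct_filter_carbon <- function(measured_ug_c_per_l,
                                  correction = filter_correction()) {
  if (any(measured_ug_c_per_l < 0)) {
    stop("measured carbon must be >= 0", call. = FALSE)
  }
  pmax(0, (measured_ug_c_per_l - correction$blank_ug_c_per_l) /
         correction$retention_fraction)
}

#' Biomass time series from cell measurements and abundances
#'
#' Aggregates per-cell dimension measurements to a mean biovolume (per image
#' when an `image_id` column is present, then across images), converts the
#' mean biovolume to carbon per cell, and combines it with cell abundances to
#' yield bulk biomass per experiment and time point. Cell carbon is computed
#' from the mean biovolume, not as the mean of per-cell carbons.
#'
#' @param cells Data frame with columns `experiment_id`, `time_days`,
#'   `max_dim_um`, `min_dim_um` and optionally `image_id`.
#' @param abundance Data frame with columns `experiment_id`, `time_days`,
#'   `cells_per_ml` (replicates are averaged).
#' @param conversion A [carbon_conversion()] or built-in name.
#' @param per_experiment If `TRUE` (default) a single mean biovolume is used
#'   per experiment (dimensions are typically measured at one or two time
#'   points only); otherwise biovolume is matched per time point.
#' @return A tibble with `experiment_id`, `time_days`, `mean_biovolume_um3`,
#'   `cell_carbon_fg`, `bb_umol_c_per_l` and `conversion_name`.
#' @export
estimate_biomass <- function(cells, abundance, conversion = "EXPORTS",
                             per_experiment = TRUE) {
  if (is.character(conversion)) conversion <- carbon_conversion(conversion)
  cells <- tibble::as_tibble(cells)
  cells$biovolume <- cell_biovolume(cells$max_dim_um, cells$min_dim_um)
  grp <- if (per_experiment) "experiment_id" else c("experiment_id", "time_days")
  if ("image_id" %in% names(cells)) {
    per_image <- dplyr::summarise(
      dplyr::group_by(cells, dplyr::across(dplyr::all_of(c(grp, "image_id")))),
      biovolume = mean(.data$biovolume), .groups = "drop")
  } else {
    per_image <- cells
  }
  vol <- dplyr::summarise(
    dplyr::group_by(per_image, dplyr::across(dplyr::all_of(grp))),
    mean_biovolume_um3 = mean(.data$biovolume), .groups = "drop")
  ab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(abundance),
                    .data$experiment_id, .data$time_days),
    cells_per_ml = mean(.data$cells_per_ml), .groups = "drop")
  out <- dplyr::left_join(ab, vol, by = grp)
  if (any(is.na(out$mean_biovolume_um3))) {
    stop("abundance rows without matching cell measurements", call. = FALSE)
  }
  out$cell_carbon_fg <- cell_carbon(out$mean_biovolume_um3, conversion)
  out$bb_umol_c_per_l <- biomass_concentration(out$cells_per_ml,
                                               out$cell_carbon_fg)
  out$conversion_name <- conversion$name
  out
}
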