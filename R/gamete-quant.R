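#' Sperm concentration from counting-chamber replicates
#'
#' Each replicate count converts to a concentration as
#' `cells / chamber volume x dilution factor`; the male-level estimate is
#' the unweighted mean over replicates (three subsamples in the study
#' design). Chamber volume is an explicit input — Thoma chambers vary, so
#' no grid constants are hard-coded.
#'
#' @param counts Data frame with columns `cells_counted` (non-negative
#'   integer), `chamber_volume_ul` (counting volume in microlitres, > 0)
#'   and `dilution_factor` (>= 1), one row per replicate.
#' @return Concentration in sperm per millilitre (scalar).
#' @examples
#' sperm_concentration(tibble::tibble(
#'   cells_counted = c(80, 100, 120),
#'   chamber_volume_ul = 0.1,
#'   dilution_factor = 10
#' )) # 1e7 sperm/mL
#' @export
sperm_concentration <- function(counts) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1)
  need <- c("cells_counted", "chamber_volume_ul", "dilution_factor")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(counts$chamber_volume_ul <= 0)) stop("chamber volume must be positive", call. = FALSE)
  if (any(counts$cells_counted < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts$dilution_factor < 1)) stop("dilution factor must be >= 1", call. = FALSE)
  per_ul <- counts$cells_counted / counts$chamber_volume_ul * counts$dilution_factor
  mean(per_ul) * 1e3  # uL -> mL
}

#' Default gonadosomatic index by ecotype
#'
#' Literature GSI values: 11.9% for the brook lamprey (LP) and 4.64% for
#' the river lamprey (LF).
#'
#' @param ecotype Character vector of "LF"/"LP".
#' @return GSI as a fraction of body mass.
#' @export
default_gsi <- function(ecotype) {
  stopifnot(all(ecotype %in% c("LF", "LP")))
  c(LF = 0.0464, LP = 0.119)[ecotype]
}

#' Total sperm produced per male via the gonadosomatic index
#'
#' Converts body mass to semen volume through the GSI, assuming 1 mL of
#' semen weighs 1 g, and multiplies by the sperm concentration:
#' `total = gsi x body mass (g -> mL) x concentration`.
#'
#' @param body_mass_g Body mass in grams (> 0). Vectorised.
#' @param gsi Gonadosomatic index as a fraction in (0, 1); see
#'   [default_gsi()].
#' @param concentration Sperm concentration in sperm/mL (> 0).
#' @return Estimated total sperm count.
#' @export
total_sperm <- function(body_mass_g, gsi, concentration) {
  if (any(body_mass_g <= 0)) stop("body mass must be positive", call. = FALSE)
  if (any(gsi <= 0 | gsi >= 1)) stop("gsi must lie strictly in (0, 1)", call. = FALSE)
  if (any(concentration <= 0)) stop("concentration must be positive", call. = FALSE)
  unname(gsi * body_mass_g * concentration)
}

#' Semen volumes for an equal-sperm-number competitive mix
#'
#' Solves for the two semen volumes that put the same number of sperm from
#' each male into a fixed total volume: `v_LF * conc_LF = v_LP * conc_LP`
#' with `v_LF + v_LP = total`, giving
#' `v_LF = total * conc_LP / (conc_LF + conc_LP)`.
#'
#' @param conc_LF,conc_LP Sperm concentrations of the two males (same
#'   units; > 0). Vectorised over pairs.
#' @param total Total semen volume in microlitres (default 6, the study's
#'   mix volume).
#' @return A tibble: `experiment` ("equal_number"), `v_LF`, `v_LP`,
#'   `total` (uL).
#' @export
equal_number_volumes <- function(conc_LF, conc_LP, total = 6) {
  if (any(conc_LF <= 0) || any(conc_LP <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  v_lf <- total * conc_LP / (conc_LF + conc_LP)
  tibble::tibble(
    experiment = "equal_number",
    v_LF = v_lf, v_LP = total - v_lf, total = total
  )
}

#' Mix design for a competitive fertilization trial
#'
#' Equal-volume trials split the total volume evenly; equal-number trials
#' use [equal_number_volumes()].
#'
#' @param experiment `"equal_volume"` or `"equal_number"`.
#' @inheritParams equal_number_volumes
#' @return A tibble: `experiment`, `v_LF`, `v_LP`, `total`.
#' @export
mix_design <- function(experiment, conc_LF, conc_LP, total = 6) {
  experiment <- match.arg(experiment, c("equal_volume", "equal_number"))
  if (experiment == "equal_volume") {
    tibble::tibble(experiment = experiment,
                   v_LF = total / 2, v_LP = total / 2, total = total)
  } else {
    equal_number_volumes(conc_LF, conc_LP, total)
  }
}
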