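#' Assign the sire ecotype of a larva from the diagnostic locus
#'
#' The diagnostic biallelic locus fixes river lamprey (LF) for allele `f`
#' and brook lamprey (LP) for allele `p`; hybrids are `pf`. With a
#' homozygous mother the sire's ecotype follows directly: an `ff` mother's
#' larva is `ff` if LF-sired and `pf` if LP-sired; a `pp` mother's larva is
#' `pp` if LP-sired and `pf` if LF-sired. Offspring genotypes impossible
#' under those rules (e.g. `pp` larva from an `ff` mother) are Mendelian
#' violations and return `NA` with a warning, so callers can exclude and
#' log them.
#'
#' @param mother_genotype Character vector of `"ff"`/`"pp"` (homozygous
#'   mothers only).
#' @param offspring_genotype Character vector of `"ff"`, `"pp"`, `"pf"`.
#' @return Character vector of `"LF"`, `"LP"`, or `NA` (violation).
#' @export
assign_sire <- function(mother_genotype, offspring_genotype) {
  if (!all(mother_genotype %in% c("ff", "pp"))) {
    stop("mothers must be homozygous (ff or pp)", call. = FALSE)
  }
  if (!all(offspring_genotype %in% c("ff", "pp", "pf"))) {
    stop("offspring genotypes must be ff, pp or pf", call. = FALSE)
  }
  sire <- dplyr::case_when(
    mother_genotype == "ff" & offspring_genotype == "ff" ~ "LF",
    mother_genotype == "ff" & offspring_genotype == "pf" ~ "LP",
    mother_genotype == "pp" & offspring_genotype == "pp" ~ "LP",
    mother_genotype == "pp" & offspring_genotype == "pf" ~ "LF",
    .default = NA_character_
  )
  n_bad <- sum(is.na(sire))
  if (n_bad > 0) {
    warning(n_bad, " Mendelian violation(s): larva excluded from tallies",
            call. = FALSE)
  }
  sire
}

#' Tally paternity for competitive-fertilization trials
#'
#' Joins larval genotype calls to trial metadata, assigns each larva's sire
#' with [assign_sire()], and counts per trial the larvae sired by the LP
#' male (`C`) out of the assignable larvae (`N`). Mendelian violations are
#' excluded from both counts and reported in `n_violations`; trials with no
#' assignable larva (including failed fertilizations) are dropped,
#' mirroring the exclusion of the male pair whose equal-number
#' fertilization did not work.
#'
#' @param genotypes Tibble of larval calls: `trial_id`, `larva_id`,
#'   `genotype`.
#' @param trials Trial metadata with `trial_id`, `female_id` and any design
#'   columns to carry through (`experiment`, `female_ecotype`, `pair_id`,
#'   scaled speeds, ...).
#' @param mothers Tibble `female_id`, `genotype` of the (homozygous)
#'   mothers.
#' @return A tibble with one row per retained trial: the trial design
#'   columns plus `C`, `N`, `n_violations`.
#' @export
tally_paternity <- function(genotypes, trials, mothers) {
  stopifnot(all(c("trial_id", "genotype") %in% names(genotypes)),
            all(c("trial_id", "female_id") %in% names(trials)),
            all(c("female_id", "genotype") %in% names(mothers)))
  design_cols <- setdiff(names(trials), c("N", "C_true", "p_true"))
  calls <- genotypes |>
    dplyr::inner_join(trials[, design_cols], by = "trial_id") |>
    dplyr::inner_join(mothers, by = "female_id",
                      suffix = c("", "_mother")) |>
    dplyr::mutate(sire = assign_sire(.data$genotype_mother, .data$genotype))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(design_cols))) |>
    dplyr::summarise(
      C = sum(.data$sire == "LP", na.rm = TRUE),
      N = sum(!is.na(.data$sire)),
      n_violations = sum(is.na(.data$sire)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$N > 0)
}
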