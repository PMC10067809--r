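#' Truth configuration for the synthetic study
#'
#' Bundles every parameter of the simulated experiment: how many males of
#' each ecotype, the ecotype-level sperm concentration and velocity
#' distributions, the logit-scale coefficients of the siring model that
#' generates competitive-fertilization outcomes, the random-effect spreads,
#' and the trial sizes. The defaults emulate the study conditions: 13 males
#' per ecotype, brook-lamprey (LP) sperm about twice as concentrated as
#' river-lamprey (LF) sperm, LF sperm faster (VAP 270 vs 230 um/s; VCL
#' 353.2 vs 321.56 um/s), 27 genotyped larvae per trial, one male pair
#' whose equal-number fertilization fails, and one short trial of 22
#' larvae.
#'
#' @param n_males_per_ecotype Males per ecotype (default 13).
#' @param conc_mean_LF,conc_mean_LP Lognormal *medians* of sperm
#'   concentration, sperm/mL.
#' @param conc_cv Coefficient of variation of concentration across males.
#' @param mass_mean_LF,mass_mean_LP Lognormal medians of male body mass, g
#'   (the anadromous LF is an order of magnitude heavier than the
#'   freshwater-resident LP).
#' @param mass_cv Coefficient of variation of body mass across males.
#' @param vap_mean_LF,vap_mean_LP,vcl_mean_LF,vcl_mean_LP Ecotype mean
#'   velocities, um/s.
#' @param speed_sd Between-male SD of velocities, um/s.
#' @param alpha Numeric length-7: logit-scale coefficients of the siring
#'   model — intercept, female ecotype (LP vs LF), experiment type
#'   (equal number vs equal volume), scaled LP speed, scaled LF speed, and
#'   the two experiment-by-speed interactions. Defaults follow the fitted
#'   point estimates of the study, intercept at logit(0.56).
#' @param sd_female,sd_pair Logit-scale SDs of the female-identity and
#'   male-pair random effects.
#' @param larvae_per_trial Larvae genotyped per trial (default 27).
#' @param n_females_LF,n_females_LP Females per ecotype (defaults 3 and 6,
#'   reused across male pairs as in the study).
#' @param fail_pair_equal_number If `TRUE` (default) the last male pair's
#'   equal-number fertilizations fail (N = 0), exercising the exclusion
#'   rule downstream.
#' @param short_trial If `TRUE` (default) one equal-number trial yields
#'   only 22 larvae.
#' @param eggs_mean Mean egg-batch size per Petri dish for noncompetitive
#'   crosses (default 77).
#' @param fert_p_eggs_LF,fert_p_eggs_LP Baseline fertilization
#'   probabilities of LF and LP eggs in noncompetitive crosses.
#' @param viability_p Embryo survival probability of fertilized eggs
#'   (binomial thinning).
#' @param seed Integer seed used by the `simulate_*()` functions.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_males_per_ecotype = 13,
                         conc_mean_LF = 0.5e9,
                         conc_mean_LP = 1.0e9,
                         conc_cv = 0.5,
                         mass_mean_LF = 38,
                         mass_mean_LP = 6.5,
                         mass_cv = 0.2,
                         vap_mean_LF = 270,
                         vap_mean_LP = 230,
                         vcl_mean_LF = 353.2,
                         vcl_mean_LP = 321.56,
                         speed_sd = 35,
                         alpha = c(0.25, -0.04, -0.7, -0.18, 0.13, 0.21, -0.83),
                         sd_female = 0.3,
                         sd_pair = 0.3,
                         larvae_per_trial = 27,
                         n_females_LF = 3,
                         n_females_LP = 6,
                         fail_pair_equal_number = TRUE,
                         short_trial = TRUE,
                         eggs_mean = 77,
                         fert_p_eggs_LF = 0.94,
                         fert_p_eggs_LP = 0.985,
                         viability_p = 0.8,
                         seed = 1L) {
  cfg <- list(
    n_males_per_ecotype = as.integer(n_males_per_ecotype),
    conc_mean_LF = conc_mean_LF, conc_mean_LP = conc_mean_LP,
    conc_cv = conc_cv,
    mass_mean_LF = mass_mean_LF, mass_mean_LP = mass_mean_LP,
    mass_cv = mass_cv,
    vap_mean_LF = vap_mean_LF, vap_mean_LP = vap_mean_LP,
    vcl_mean_LF = vcl_mean_LF, vcl_mean_LP = vcl_mean_LP,
    speed_sd = speed_sd,
    alpha = alpha, sd_female = sd_female, sd_pair = sd_pair,
    larvae_per_trial = as.integer(larvae_per_trial),
    n_females_LF = as.integer(n_females_LF),
    n_females_LP = as.integer(n_females_LP),
    fail_pair_equal_number = isTRUE(fail_pair_equal_number),
    short_trial = isTRUE(short_trial),
    eggs_mean = eggs_mean,
    fert_p_eggs_LF = fert_p_eggs_LF, fert_p_eggs_LP = fert_p_eggs_LP,
    viability_p = viability_p,
    seed = as.integer(seed)
  )
  validate_truth_config(cfg)
  structure(cfg, class = "truth_config")
}

validate_truth_config <- function(cfg) {
  bad <- function(msg) stop("invalid truth_config: ", msg, call. = FALSE)
  if (cfg$n_males_per_ecotype < 1) bad("need at least one male per ecotype")
  conc <- c(cfg$conc_mean_LF, cfg$conc_mean_LP)
  if (any(conc <= 0)) bad("concentrations must be positive")
  if (cfg$conc_cv < 0) bad("conc_cv must be non-negative")
  sp <- c(cfg$vap_mean_LF, cfg$vap_mean_LP, cfg$vcl_mean_LF, cfg$vcl_mean_LP)
  if (any(sp <= 0)) bad("speeds must be positive")
  if (cfg$vcl_mean_LF < cfg$vap_mean_LF || cfg$vcl_mean_LP < cfg$vap_mean_LP) {
    bad("VCL means must be >= VAP means")
  }
  if (cfg$speed_sd < 0) bad("speed_sd must be non-negative")
  if (length(cfg$alpha) != 7 || !is.numeric(cfg$alpha)) bad("alpha must be numeric length 7")
  if (cfg$sd_female < 0 || cfg$sd_pair < 0) bad("random-effect SDs must be non-negative")
  if (cfg$larvae_per_trial < 1) bad("larvae_per_trial must be >= 1")
  if (any(c(cfg$mass_mean_LF, cfg$mass_mean_LP) <= 0)) bad("masses must be positive")
  prob <- c(cfg$fert_p_eggs_LF, cfg$fert_p_eggs_LP, cfg$viability_p)
  if (any(prob <= 0 | prob > 1)) bad("probabilities must lie in (0, 1]")
  invisible(cfg)
}

#' Simulate per-male sperm profiles
#'
#' Draws one row per male: concentration lognormal around the ecotype
#' median (sigma from the configured CV) and true VCL/VAP normal around
#' the ecotype means with SD `speed_sd`, truncated so that speeds stay
#' positive and VCL >= VAP for every male.
#'
#' @param cfg A [truth_config()].
#' @param seed Seed (defaults to `cfg$seed`); pass `NULL` to use the
#'   current RNG state.
#' @return A tibble: `male_id`, `ecotype` ("LF"/"LP"), `body_mass_g`,
#'   `concentration` (sperm/mL), `vcl_true`, `vap_true` (um/s).
#' @export
simulate_males <- function(cfg = truth_config(), seed = cfg$seed) {
  validate_truth_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_males_per_ecotype
  sdlog <- sqrt(log(1 + cfg$conc_cv^2))
  sdlog_m <- sqrt(log(1 + cfg$mass_cv^2))
  one_ecotype <- function(eco, conc_med, mass_med, vcl_mu, vap_mu) {
    conc <- stats::rlnorm(n, meanlog = log(conc_med), sdlog = sdlog)
    mass <- stats::rlnorm(n, meanlog = log(mass_med), sdlog = sdlog_m)
    vap <- truncnorm_pos(n, vap_mu, cfg$speed_sd)
    vcl <- pmax(truncnorm_pos(n, vcl_mu, cfg$speed_sd), vap)
    tibble::tibble(
      male_id = sprintf("%s%02d", eco, seq_len(n)),
      ecotype = eco,
      body_mass_g = mass,
      concentration = conc,
      vcl_true = vcl,
      vap_true = vap
    )
  }
  dplyr::bind_rows(
    one_ecotype("LF", cfg$conc_mean_LF, cfg$mass_mean_LF,
                cfg$vcl_mean_LF, cfg$vap_mean_LF),
    one_ecotype("LP", cfg$conc_mean_LP, cfg$mass_mean_LP,
                cfg$vcl_mean_LP, cfg$vap_mean_LP)
  )
}

truncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Simulate females for the competitive design
#'
#' Females are homozygous at the diagnostic locus: river-lamprey (LF)
#' females are `ff`, brook-lamprey (LP) females `pp`.
#'
#' @inheritParams simulate_males
#' @return A tibble: `female_id`, `ecotype`, `genotype`.
#' @export
simulate_females <- function(cfg = truth_config()) {
  tibble::tibble(
    female_id = c(sprintf("F_LF%01d", seq_len(cfg$n_females_LF)),
                  sprintf("F_LP%01d", seq_len(cfg$n_females_LP))),
    ecotype = rep(c("LF", "LP"), c(cfg$n_females_LF, cfg$n_females_LP)),
    genotype = rep(c("ff", "pp"), c(cfg$n_females_LF, cfg$n_females_LP))
  )
}

#' Simulate tracked sperm-head trajectories for one male
#'
#' Generates a correlated random walk per track: constant step length
#' `vcl_true / fps` (so the measured VCL equals the male's true VCL
#' exactly) and von Mises-free Gaussian turning angles whose SD is tuned by
#' a closed form so that the moving-average-smoothed path speed — the VAP
#' that [vap()] measures with the same `window` — matches the male's true
#' VAP. Starting positions are scattered over a 650 x 480 um field of view
#' and initial headings are uniform.
#'
#' @param male One row of the [simulate_males()] table (needs `vcl_true`
#'   and `vap_true`).
#' @param n_tracks Number of tracks to generate.
#' @param fps Frames per second (default 60).
#' @param duration Track duration in seconds (default 3); each track has
#'   `floor(fps * duration)` points.
#' @param window Smoothing window the downstream VAP measurement will use
#'   (default 5); the turning-angle tuning targets this window.
#' @param seed Optional seed.
#' @return A tibble: `track_id`, `frame` (0-based), `x_um`, `y_um`.
#' @export
simulate_trajectories <- function(male, n_tracks = 116, fps = 60, duration = 3,
                                  window = 5, seed = NULL) {
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vcl_true <- male$vcl_true[1L]
  vap_true <- male$vap_true[1L]
  n_pts <- as.integer(floor(fps * duration))
  step <- vcl_true / fps
  sigma <- turning_sd_for_ratio(vap_true / vcl_true, window)
  purrr::map_dfr(seq_len(n_tracks), function(tr) {
    heading <- stats::runif(1, 0, 2 * pi) +
      cumsum(c(0, stats::rnorm(n_pts - 2L, 0, sigma)))
    dx <- step * cos(heading)
    dy <- step * sin(heading)
    tibble::tibble(
      track_id = tr,
      frame = 0:(n_pts - 1L),
      x_um = stats::runif(1, 0, 650) + c(0, cumsum(dx)),
      y_um = stats::runif(1, 0, 480) + c(0, cumsum(dy))
    )
  })
}

# Turning-angle SD such that a correlated random walk with unit steps,
# smoothed by a centred moving average of `window` points, travels at
# `ratio` times its raw speed. For Gaussian turns of SD s the step
# autocorrelation is rho^k with rho = exp(-s^2/2); the expected squared
# displacement over w steps is w + 2*sum_k (w-k) rho^k, giving the
# smoothed/raw speed ratio in closed form (root-mean-square approximation).
turning_sd_for_ratio <- function(ratio, window) {
  if (ratio >= 1) return(0)
  w <- as.integer(window)
  r_of_rho <- function(rho) {
    k <- seq_len(w - 1L)
    sqrt(w + 2 * sum((w - k) * rho^k)) / w
  }
  lo <- 1e-8
  if (ratio <= r_of_rho(lo)) return(sqrt(-2 * log(lo)))
  rho <- stats::uniroot(function(r) r_of_rho(r) - ratio,
                        lower = lo, upper = 1 - 1e-10, tol = 1e-12)$root
  sqrt(-2 * log(rho))
}

#' Simulate the competitive-fertilization experiment
#'
#' Builds the full paired-male design — each LF x LP male pair crossed in
#' both mixing designs (equal semen volume, equal sperm number) with one
#' female of each ecotype — then draws each trial's LP-sired larva count
#' from the hierarchical binomial siring model: `C ~ Binomial(N, p)` with
#' `logit(p)` the linear predictor built from `cfg$alpha`, the pair's
#' scaled true sperm speeds (z-scores of true VAP within ecotype), and
#' Gaussian female-identity and male-pair random effects. Per-larva
#' genotypes at the diagnostic locus follow Mendel from the mother's
#' genotype and the sire's ecotype.
#'
#' @param males Output of [simulate_males()].
#' @param females Output of [simulate_females()].
#' @param cfg A [truth_config()].
#' @param seed Seed (defaults to `cfg$seed + 1` so male and competition
#'   draws are independent streams under one configuration seed).
#' @return A list with tibbles `trials` (trial_id, pair_id, experiment,
#'   female_id, female_ecotype, male_LF, male_LP, vs_LP, vs_LF, N, C_true,
#'   p_true) and `genotypes` (trial_id, larva_id, genotype). Failed trials
#'   appear with `N = 0` and no larvae.
#' @export
simulate_competition <- function(males, females, cfg = truth_config(),
                                 seed = cfg$seed + 1L) {
  validate_truth_config(cfg)
  if (!all(c("LF", "LP") %in% males$ecotype)) {
    stop("`males` must contain both ecotypes to form pairs", call. = FALSE)
  }
  if (!all(females$genotype %in% c("ff", "pp"))) {
    stop("female genotypes must be homozygous (ff or pp)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  lf <- males[males$ecotype == "LF", ]
  lp <- males[males$ecotype == "LP", ]
  n_pairs <- min(nrow(lf), nrow(lp))
  if (nrow(lf) != nrow(lp)) {
    stop("unpaired males: ", nrow(lf), " LF vs ", nrow(lp), " LP", call. = FALSE)
  }

  pairs <- tibble::tibble(
    pair_id = sprintf("P%02d", seq_len(n_pairs)),
    male_LF = lf$male_id, male_LP = lp$male_id,
    speed_LF = lf$vap_true, speed_LP = lp$vap_true
  )
  pairs$vs_LF <- scale_speeds(pairs$speed_LF)
  pairs$vs_LP <- scale_speeds(pairs$speed_LP)

  f_lf <- females[females$ecotype == "LF", ]
  f_lp <- females[females$ecotype == "LP", ]
  # recycle females across pairs, as in the study (9 females, 13 pairs)
  fem_for <- function(f, i) f$female_id[(i - 1L) %% nrow(f) + 1L]

  grid <- tidyr::expand_grid(
    pair_id = pairs$pair_id,
    experiment = c("equal_volume", "equal_number"),
    female_ecotype = c("LF", "LP")
  ) |>
    dplyr::left_join(pairs, by = "pair_id") |>
    dplyr::mutate(
      female_id = ifelse(
        .data$female_ecotype == "LF",
        fem_for(f_lf, match(.data$pair_id, pairs$pair_id)),
        fem_for(f_lp, match(.data$pair_id, pairs$pair_id))
      )
    )

  b_f <- stats::rnorm(nrow(females), 0, cfg$sd_female)
  names(b_f) <- females$female_id
  b_p <- stats::rnorm(n_pairs, 0, cfg$sd_pair)
  names(b_p) <- pairs$pair_id

  a <- cfg$alpha
  grid <- grid |>
    dplyr::mutate(
      is_LP_female = as.integer(.data$female_ecotype == "LP"),
      is_eq_number = as.integer(.data$experiment == "equal_number"),
      eta = a[1] + a[2] * .data$is_LP_female + a[3] * .data$is_eq_number +
        a[4] * .data$vs_LP + a[5] * .data$vs_LF +
        a[6] * .data$is_eq_number * .data$vs_LP +
        a[7] * .data$is_eq_number * .data$vs_LF +
        b_f[.data$female_id] + b_p[.data$pair_id],
      p_true = stats::plogis(.data$eta)
    )

  grid$N <- rep(cfg$larvae_per_trial, nrow(grid))
  if (cfg$fail_pair_equal_number) {
    failed <- grid$pair_id == pairs$pair_id[n_pairs] &
      grid$experiment == "equal_number"
    grid$N[failed] <- 0L
  }
  if (cfg$short_trial) {
    short <- which(grid$experiment == "equal_number" & grid$N > 0)
    if (length(short)) grid$N[short[1L]] <- min(22L, grid$N[short[1L]])
  }

  grid$C_true <- stats::rbinom(nrow(grid), grid$N, grid$p_true)
  grid$trial_id <- sprintf("T%02d", seq_len(nrow(grid)))

  trials <- grid |>
    dplyr::select(
      "trial_id", "pair_id", "experiment", "female_id", "female_ecotype",
      "male_LF", "male_LP", "vs_LP", "vs_LF", "N", "C_true", "p_true"
    )

  genotypes <- trials |>
    dplyr::filter(.data$N > 0) |>
    dplyr::left_join(females[, c("female_id", "genotype")], by = "female_id") |>
    dplyr::rowwise() |>
    dplyr::reframe(
      trial_id = .data$trial_id,
      larva_id = sprintf("%s_L%02d", .data$trial_id, seq_len(.data$N)),
      genotype = larva_genotypes(.data$genotype, .data$N, .data$C_true)
    )

  list(trials = trials, genotypes = genotypes)
}

# Mendelian genotypes: homozygous mother x homozygous sire.
# LP sire carries p alleles, LF sire f alleles.
larva_genotypes <- function(mother, n, n_lp_sired) {
  sires <- sample(rep(c("LP", "LF"), c(n_lp_sired, n - n_lp_sired)))
  if (mother == "ff") ifelse(sires == "LP", "pf", "ff") else
    ifelse(sires == "LP", "pp", "pf")
}

#' Simulate counting-chamber replicates for each male
#'
#' Emulates the sperm-number quantification: each replicate's cell count is
#' Poisson around the expected number of cells in the counting volume after
#' dilution, `conc[/uL] x volume / dilution`.
#'
#' @param males Output of [simulate_males()].
#' @param replicates Replicate subsamples per male (3 in the study design).
#' @param chamber_volume_ul Counting volume in microlitres.
#' @param dilution_factor Dilution applied before loading.
#' @param seed Optional seed.
#' @return A tibble: `male_id`, `replicate_id`, `cells_counted`,
#'   `chamber_volume_ul`, `dilution_factor`.
#' @export
simulate_chamber_counts <- function(males, replicates = 3,
                                    chamber_volume_ul = 0.1,
                                    dilution_factor = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expected <- males$concentration / 1e3 * chamber_volume_ul / dilution_factor
  tidyr::expand_grid(male_id = males$male_id, replicate_id = seq_len(replicates)) |>
    dplyr::mutate(
      cells_counted = stats::rpois(
        dplyr::n(), rep(expected, each = replicates)
      ),
      chamber_volume_ul = chamber_volume_ul,
      dilution_factor = dilution_factor
    )
}

#' Simulate noncompetitive control fertilizations
#'
#' Each female contributes two egg batches, one fertilized by an LF male
#' and one by an LP male (within- vs between-ecotype crosses). Egg numbers
#' are Poisson around `cfg$eggs_mean`; fertilized counts are binomial with
#' a logit probability combining the egg-ecotype baseline and the female's
#' Gaussian random effect; surviving embryos are a binomial thinning of the
#' fertilized eggs at `cfg$viability_p`.
#'
#' @inheritParams simulate_competition
#' @param seed Seed (defaults to `cfg$seed + 2`).
#' @return A tibble: `cross_id`, `female_id`, `female_ecotype`, `male_id`,
#'   `male_ecotype`, `cross_type` ("within"/"between"), `eggs`,
#'   `fertilized`, `survived`.
#' @export
simulate_noncompetitive <- function(males, females, cfg = truth_config(),
                                    seed = cfg$seed + 2L) {
  validate_truth_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  b_f <- stats::rnorm(nrow(females), 0, cfg$sd_female)
  names(b_f) <- females$female_id
  lf <- males$male_id[males$ecotype == "LF"]
  lp <- males$male_id[males$ecotype == "LP"]
  crosses <- tidyr::expand_grid(
    female_id = females$female_id,
    male_ecotype = c("LF", "LP")
  ) |>
    dplyr::left_join(females[, c("female_id", "ecotype")], by = "female_id") |>
    dplyr::rename(female_ecotype = "ecotype")
  n <- nrow(crosses)
  base_p <- ifelse(crosses$female_ecotype == "LF",
                   cfg$fert_p_eggs_LF, cfg$fert_p_eggs_LP)
  eggs <- stats::rpois(n, cfg$eggs_mean)
  p <- stats::plogis(stats::qlogis(base_p) + b_f[crosses$female_id])
  fert <- stats::rbinom(n, eggs, p)
  crosses |>
    dplyr::mutate(
      cross_id = sprintf("NC%02d", seq_len(n)),
      male_id = ifelse(.data$male_ecotype == "LF",
                       lf[sample.int(length(lf), n, replace = TRUE)],
                       lp[sample.int(length(lp), n, replace = TRUE)]),
      cross_type = ifelse(.data$female_ecotype == .data$male_ecotype,
                          "within", "between"),
      eggs = eggs,
      fertilized = fert,
      survived = stats::rbinom(n, fert, cfg$viability_p)
    ) |>
    dplyr::select(
      "cross_id", "female_id", "female_ecotype", "male_id", "male_ecotype",
      "cross_type", "eggs", "fertilized", "survived"
    )
}
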