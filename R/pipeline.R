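#' Run the full analysis pipeline on a synthetic study
#'
#' One call reproduces the whole analysis end to end under a known truth:
#' simulate males, tracked sperm trajectories and counting-chamber
#' replicates; measure VCL/VAP with the kinematics module and concentration
#' with the chamber-count module; compare traits between ecotypes with
#' rank/t tests; simulate the paired-male competitive fertilizations,
#' genotype the larvae and tally paternity; fit the hierarchical binomial
#' siring model by MCMC with measured (not true) sperm speeds; and fit the
#' same engine to the noncompetitive fertilization and embryo-viability
#' counts. Everything is seeded through `cfg$seed`, so two runs with the
#' same configuration are identical.
#'
#' @param cfg A [truth_config()].
#' @param n_tracks Tracks per subsample fed to the kinematics module
#'   (default 116, the study's mean tracked-cell count).
#' @param n_subsamples Activation subsamples per male (default 3).
#' @param fps,duration,window,min_frames Kinematics settings; see
#'   [track_velocities()].
#' @param chains,n_iter,burnin,thin MCMC settings for every model fit; the
#'   default 4 chains x 20,000 iterations (10,000 burn-in, thin 10)
#'   converges well below R-hat 1.1 at this data size.
#' @param speed_trait Which measured velocity enters the siring model:
#'   `"vap"` (default) or `"vcl"`.
#' @return A list of class `lampetra_report`: `males` (truth),
#'   `traits` (measured per-male traits incl. concentration and GSI-based
#'   total sperm), `trait_tests`, `trials`, `tallies`, `fit`
#'   (the `siring_fit`), `siring_table` (fixed-effect summary in the
#'   study's table layout), `delta` (fair-raffle departures), `bayes_p`,
#'   `noncompetitive` (data + per-egg-ecotype fertilization fits and the
#'   viability fit summaries), and `meta`.
#' @export
run_pipeline <- function(cfg = truth_config(),
                         n_tracks = 116, n_subsamples = 3,
                         fps = 60, duration = 3, window = 5, min_frames = 30,
                         chains = 4, n_iter = 20000, burnin = 10000, thin = 10,
                         speed_trait = c("vap", "vcl")) {
  speed_trait <- match.arg(speed_trait)
  validate_truth_config(cfg)

  males <- simulate_males(cfg)
  females <- simulate_females(cfg)

  # kinematics: simulate and measure each male's subsamples
  tracks <- purrr::map_dfr(seq_len(nrow(males)), function(i) {
    purrr::map_dfr(seq_len(n_subsamples), function(s) {
      simulate_trajectories(
        males[i, ], n_tracks = n_tracks, fps = fps, duration = duration,
        window = window, seed = cfg$seed + 1000L + i * 10L + s
      ) |>
        dplyr::mutate(male_id = males$male_id[i], subsample = s)
    })
  })
  speed <- summarize_male(tracks, fps = fps, window = window,
                          min_frames = min_frames)

  # gamete quantification: measured concentration and GSI-based totals
  counts <- simulate_chamber_counts(males, seed = cfg$seed + 3L)
  conc <- counts |>
    dplyr::group_by(.data$male_id) |>
    dplyr::summarise(
      concentration = sperm_concentration(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
  traits <- males |>
    dplyr::select("male_id", "ecotype", "body_mass_g") |>
    dplyr::left_join(speed, by = "male_id") |>
    dplyr::left_join(conc, by = "male_id") |>
    dplyr::mutate(total_sperm = total_sperm(
      .data$body_mass_g, default_gsi(.data$ecotype), .data$concentration
    ))

  trait_tests <- compare_sperm_traits(traits)

  # competition, genotyping, paternity
  comp <- simulate_competition(males, females, cfg)
  tallies <- tally_paternity(comp$genotypes, comp$trials, females)

  # the model sees measured speeds of each pair's males
  speed_col <- paste0(speed_trait, "_mean")
  measured <- stats::setNames(traits[[speed_col]], traits$male_id)
  model_data <- tallies |>
    dplyr::select(-dplyr::any_of(c("vs_LP", "vs_LF"))) |>
    dplyr::mutate(speed_LP = measured[.data$male_LP],
                  speed_LF = measured[.data$male_LF])

  fit <- fit_siring_model(model_data, chains = chains, n_iter = n_iter,
                          burnin = burnin, thin = thin, seed = cfg$seed)
  delta <- delta_stat(fit)
  bp <- bayes_pvalue(fit, seed = cfg$seed)

  # noncompetitive controls: same engine, simpler designs
  nc <- simulate_noncompetitive(males, females, cfg)
  fit_nc <- function(df, success, size, effect_col, level) {
    X <- cbind(intercept = 1, effect = as.integer(df[[effect_col]] == level))
    colnames(X)[2] <- paste0(effect_col, "_", level)
    fit_bglmm(df[[success]], df[[size]], X, g1 = df$female_id,
              chains = chains, n_iter = n_iter, burnin = burnin,
              thin = thin, seed = cfg$seed)
  }
  nc_fits <- list(
    fert_eggs_LF = fit_nc(nc[nc$female_ecotype == "LF", ],
                          "fertilized", "eggs", "male_ecotype", "LP"),
    fert_eggs_LP = fit_nc(nc[nc$female_ecotype == "LP", ],
                          "fertilized", "eggs", "male_ecotype", "LP"),
    viability = fit_nc(dplyr::filter(nc, .data$fertilized > 0),
                       "survived", "fertilized", "cross_type", "between")
  )

  structure(
    list(
      males = males, females = females, traits = traits,
      trait_tests = trait_tests,
      trials = comp$trials, genotypes = comp$genotypes, tallies = tallies,
      fit = fit, siring_table = siring_table(fit), delta = delta,
      bayes_p = bp,
      noncompetitive = list(data = nc,
                            tests = purrr::map_dfr(nc_fits, nc_summary,
                                                   .id = "model")),
      meta = list(cfg = cfg, n_tracks = n_tracks,
                  n_subsamples = n_subsamples, fps = fps,
                  duration = duration, window = window,
                  chains = chains, n_iter = n_iter, burnin = burnin,
                  thin = thin, speed_trait = speed_trait)
    ),
    class = "lampetra_report"
  )
}

nc_summary <- function(fit) {
  td <- tidy(fit)
  td[2, c("term", "estimate", "std.error", "rhat", "mcmc_p")]
}

#' Fixed-effect summary in the study's table layout
#'
#' Posterior mean and SD, Gelman-Rubin R-hat, and MCMC p-value for each
#' fixed effect of the siring model. Following the study's convention, the
#' two experiment-by-speed interaction p-values are one-tailed (the
#' fraction of positive draws — the directional hypothesis that faster LF
#' sperm raise LF siring success at equal sperm number); all others are
#' two-tailed.
#'
#' @param fit A [fit_siring_model()] object.
#' @return A tibble: `term`, `estimate`, `sd`, `rhat`, `mcmc_p`, `tail`.
#' @export
siring_table <- function(fit) {
  pooled <- pool_draws(fit)
  terms <- colnames(fit$data$X)
  one_tailed <- grepl(":", terms, fixed = TRUE)
  rh <- gelman_rubin(fit, terms)
  tibble::tibble(
    term = terms,
    estimate = colMeans(pooled[, terms, drop = FALSE]),
    sd = apply(pooled[, terms, drop = FALSE], 2, stats::sd),
    rhat = unname(rh),
    mcmc_p = purrr::map2_dbl(terms, one_tailed, function(tm, ot) {
      mcmc_pvalue(pooled[, tm], tail = if (ot) "one_positive" else "two")
    }),
    tail = ifelse(one_tailed, "one_positive", "two")
  )
}

#' @export
print.lampetra_report <- function(x, ...) {
  cat("Synthetic sperm-competition study (seed ", x$meta$cfg$seed, ")\n",
      sep = "")
  cat("  males: ", nrow(x$males), "; trials retained: ", nrow(x$tallies),
      "; larvae genotyped: ", sum(x$tallies$N), "\n", sep = "")
  cat("\nTrait comparisons (LF vs LP):\n")
  print(as.data.frame(x$trait_tests), digits = 4)
  cat("\nSiring model (fixed effects):\n")
  print(as.data.frame(x$siring_table), digits = 3)
  cat("\nFair-raffle departures (Delta = 0.5 - p_LP):\n")
  print(as.data.frame(x$delta), digits = 3)
  cat("\nBayesian (posterior-predictive) p-value: ",
      format(x$bayes_p, digits = 4), "\n", sep = "")
  cat("Max R-hat: ", format(max(gelman_rubin(x$fit)), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic study to disk as plain-text files
#'
#' Writes `males.csv`, `females.csv`, `trials.csv`, `genotypes.csv`,
#' `chamber_counts.csv`, `noncompetitive.csv`, one trajectory CSV per
#' male-subsample under `trajectories/`, and the generating `truth.json`
#' (schema-versioned). All CSVs are RFC-4180 with a header row.
#'
#' @param cfg A [truth_config()].
#' @param dir Output directory (created if needed).
#' @param n_tracks,n_subsamples,fps,duration,window Trajectory settings.
#' @return `dir`, invisibly.
#' @export
write_study <- function(cfg = truth_config(), dir,
                        n_tracks = 116, n_subsamples = 3, fps = 60,
                        duration = 3, window = 5) {
  dir.create(file.path(dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  males <- simulate_males(cfg)
  females <- simulate_females(cfg)
  comp <- simulate_competition(males, females, cfg)
  counts <- simulate_chamber_counts(males, seed = cfg$seed + 3L)
  nc <- simulate_noncompetitive(males, females, cfg)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, quote = FALSE)
  wr(males, "males.csv"); wr(females, "females.csv")
  wr(comp$trials, "trials.csv"); wr(comp$genotypes, "genotypes.csv")
  wr(counts, "chamber_counts.csv"); wr(nc, "noncompetitive.csv")
  for (i in seq_len(nrow(males))) {
    for (s in seq_len(n_subsamples)) {
      tr <- simulate_trajectories(males[i, ], n_tracks = n_tracks, fps = fps,
                                  duration = duration, window = window,
                                  seed = cfg$seed + 1000L + i * 10L + s)
      utils::write.csv(
        tr, file.path(dir, "trajectories",
                      sprintf("%s_%d.csv", males$male_id[i], s)),
        row.names = FALSE, quote = FALSE
      )
    }
  }
  truth <- c(list(schema = "lampetra-truth/1"), unclass(cfg))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trajectory CSV
#'
#' Reads a `track,frame,x_um,y_um` file as written by [write_study()].
#'
#' @param path CSV path.
#' @return A tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "track"] <- "track_id"
  tibble::as_tibble(df)
}
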