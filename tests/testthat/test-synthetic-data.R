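test_that("default configuration yields 13 + 13 males with positive traits", {
  m <- simulate_males(truth_config())
  expect_equal(unname(table(m$ecotype)["LF"]), 13L)
  expect_equal(unname(table(m$ecotype)["LP"]), 13L)
  expect_true(all(m$concentration > 0))
  expect_true(all(m$vcl_true >= m$vap_true))
})

test_that("zero concentration CV collapses concentrations to the median", {
  cfg <- truth_config(conc_cv = 0)
  m <- simulate_males(cfg)
  expect_equal(m$concentration[m$ecotype == "LP"],
               rep(cfg$conc_mean_LP, 13))
  expect_equal(m$concentration[m$ecotype == "LF"],
               rep(cfg$conc_mean_LF, 13))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- truth_config(seed = 99)
  expect_identical(simulate_males(cfg), simulate_males(cfg))
  m <- simulate_males(cfg); f <- simulate_females(cfg)
  c1 <- simulate_competition(m, f, cfg)
  c2 <- simulate_competition(m, f, cfg)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(simulate_trajectories(m[1, ], n_tracks = 3, seed = 5),
                   simulate_trajectories(m[1, ], n_tracks = 3, seed = 5))
})

test_that("invalid configurations are rejected", {
  expect_error(truth_config(conc_mean_LF = -1), "concentration")
  expect_error(truth_config(vcl_mean_LF = 100, vap_mean_LF = 200), "VCL")
  expect_error(truth_config(larvae_per_trial = 0), "larvae")
  expect_error(truth_config(alpha = 1:3), "alpha")
})

test_that("trajectories have floor(fps x duration) points and recover truth", {
  m <- simulate_males(truth_config(seed = 3))
  tr <- simulate_trajectories(m[1, ], n_tracks = 116, fps = 60, duration = 3,
                              seed = 11)
  expect_equal(unique(table(tr$track_id)), 180L)
  tv <- track_velocities(tr, fps = 60, window = 5, min_frames = 30)
  expect_lt(abs(mean(tv$vcl) - m$vcl_true[1]) / m$vcl_true[1], 0.05)
  expect_lt(abs(mean(tv$vap) - m$vap_true[1]) / m$vap_true[1], 0.05)
  expect_error(simulate_trajectories(m[1, ], fps = -1), "fps")
})

test_that("zero turning angle gives straight tracks with vcl = vap = truth", {
  male <- tibble::tibble(male_id = "x", vcl_true = 300, vap_true = 300)
  tr <- simulate_trajectories(male, n_tracks = 4, seed = 2)
  tv <- track_velocities(tr, fps = 60, window = 5, min_frames = 30)
  expect_equal(tv$vcl, rep(300, 4))
  expect_equal(tv$vap, rep(300, 4))
})

test_that("trials respect 0 <= C <= N and the study-scale design", {
  s <- small_study(seed = 21)
  expect_true(all(s$trials$C_true >= 0 & s$trials$C_true <= s$trials$N))
  # 13 pairs x 2 experiments x 2 female ecotypes, one pair failed at equal number
  expect_equal(nrow(s$trials), 52)
  expect_equal(sum(s$trials$N == 0), 2)
  expect_equal(sum(s$trials$N), 50 * 27 - 5) # one short trial of 22
})

test_that("offspring genotypes obey the Mendelian constraint", {
  s <- small_study(seed = 22)
  g <- dplyr::left_join(
    s$genotypes,
    dplyr::left_join(s$trials[, c("trial_id", "female_id")],
                     s$females[, c("female_id", "genotype")],
                     by = "female_id"),
    by = "trial_id", suffix = c("", "_mother")
  )
  ff <- g[g$genotype_mother == "ff", ]
  pp <- g[g$genotype_mother == "pp", ]
  expect_true(all(ff$genotype %in% c("ff", "pf")))
  expect_true(all(pp$genotype %in% c("pp", "pf")))
})

test_that("the fair raffle pools to one half over 10^4+ larvae", {
  cfg <- truth_config(alpha = rep(0, 7), sd_female = 0, sd_pair = 0,
                      larvae_per_trial = 200, fail_pair_equal_number = FALSE,
                      short_trial = FALSE, seed = 2)
  comp <- simulate_competition(simulate_males(cfg), simulate_females(cfg), cfg)
  n_tot <- sum(comp$trials$N)
  expect_gte(n_tot, 1e4)
  frac <- sum(comp$trials$C_true) / n_tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("a strongly positive intercept saturates paternity to the LP male", {
  cfg <- truth_config(alpha = c(20, rep(0, 6)), sd_female = 0, sd_pair = 0,
                      seed = 3)
  comp <- simulate_competition(simulate_males(cfg), simulate_females(cfg), cfg)
  kept <- comp$trials[comp$trials$N > 0, ]
  expect_true(all(kept$C_true == kept$N))
})

test_that("a negative experiment effect lowers the LP share at equal number", {
  cfg <- truth_config(alpha = c(0, 0, -0.7, 0, 0, 0, 0),
                      larvae_per_trial = 100, fail_pair_equal_number = FALSE,
                      short_trial = FALSE, seed = 4)
  m <- simulate_males(cfg); f <- simulate_females(cfg)
  shares <- purrr::map_dfr(1:20, function(i) {
    comp <- simulate_competition(m, f, cfg, seed = 100 + i)
    comp$trials |>
      dplyr::group_by(experiment) |>
      dplyr::summarise(share = sum(C_true) / sum(N), .groups = "drop")
  })
  means <- tapply(shares$share, shares$experiment, mean)
  expect_lt(means[["equal_number"]], means[["equal_volume"]])
})

test_that("unpaired males and non-homozygous females are rejected", {
  cfg <- truth_config()
  m <- simulate_males(cfg); f <- simulate_females(cfg)
  expect_error(simulate_competition(m[-1, ], f, cfg), "unpaired")
  f_bad <- f; f_bad$genotype[1] <- "pf"
  expect_error(simulate_competition(m, f_bad, cfg), "homozygous")
})

test_that("chamber counts scale with concentration and are reproducible", {
  cfg <- truth_config(seed = 6)
  m <- simulate_males(cfg)
  cc <- simulate_chamber_counts(m, seed = 7)
  expect_equal(nrow(cc), 3 * nrow(m))
  expect_identical(cc, simulate_chamber_counts(m, seed = 7))
  est <- cc |>
    dplyr::group_by(male_id) |>
    dplyr::summarise(conc = sperm_concentration(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  r <- dplyr::left_join(est, m[, c("male_id", "concentration")], by = "male_id")
  # Poisson noise on ~50-100 cells: estimates within ~35% of truth
  expect_true(all(abs(r$conc - r$concentration) / r$concentration < 0.35))
})

test_that("noncompetitive crosses nest survived <= fertilized <= eggs", {
  cfg <- truth_config(seed = 8)
  nc <- simulate_noncompetitive(simulate_males(cfg), simulate_females(cfg), cfg)
  expect_true(all(nc$fertilized <= nc$eggs))
  expect_true(all(nc$survived <= nc$fertilized))
  expect_setequal(unique(nc$cross_type), c("within", "between"))
  # two batches per female
  expect_equal(nrow(nc), 2 * (cfg$n_females_LF + cfg$n_females_LP))
})
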