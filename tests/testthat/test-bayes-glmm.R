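test_that("speed scaling centres and scales with the sample-SD convention", {
  expect_equal(scale_speeds(c(1, 2, 3)), c(-1, 0, 1))
  z <- scale_speeds(rnorm(40, 300, 20))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(scale_speeds(z), z) # idempotent on scaled input
  expect_error(scale_speeds(rep(2, 5)), "distinct")
})

test_that("log posterior matches closed forms and the naive evaluator", {
  # single fair-raffle trial: binomial term log C(2,1) + 2 log(0.5) = log(0.5)
  X1 <- cbind(intercept = 1)
  lp <- bglmm_log_posterior(list(beta = 0), C = 1, N = 2, X = X1)
  prior0 <- dt(0, df = 1, log = TRUE) - log(2.5)
  expect_equal(lp - prior0, log(0.5))

  # order invariance of the likelihood
  set.seed(60)
  n <- 12
  X <- cbind(intercept = 1, x = rnorm(n))
  C <- rbinom(n, 20, 0.4); N <- rep(20, n)
  g1 <- sample(1:3, n, TRUE); g2 <- sample(1:4, n, TRUE)
  pars <- list(beta = c(0.3, -0.5), u1 = rnorm(3), sd1 = 0.7,
               u2 = rnorm(4), sd2 = 1.2)
  o <- sample(n)
  expect_equal(
    bglmm_log_posterior(pars, C, N, X, g1, g2),
    bglmm_log_posterior(pars, C[o], N[o], X[o, ], g1[o], g2[o])
  )

  # random parameter draws against the independent direct-formula evaluator
  for (i in 1:10) {
    pars_i <- list(beta = rnorm(2), u1 = rnorm(3), sd1 = runif(1, 0.2, 2),
                   u2 = rnorm(4), sd2 = runif(1, 0.2, 2))
    expect_equal(
      bglmm_log_posterior(pars_i, C, N, X, g1, g2),
      naive_log_posterior(pars_i$beta, pars_i$u1, pars_i$sd1, pars_i$u2,
                          pars_i$sd2, C, N, X, g1, g2)
    )
  }
  expect_equal(bglmm_log_posterior(list(beta = 0, u1 = 0, sd1 = -1),
                                   C = 1, N = 2, X = X1, g1 = 1), -Inf)
})

test_that("the sampler is reproducible and validates its configuration", {
  C <- c(5, 7); N <- c(10, 12); X <- cbind(intercept = c(1, 1))
  f1 <- fit_bglmm(C, N, X, chains = 2, n_iter = 2000, burnin = 1000,
                  thin = 2, seed = 8)
  f2 <- fit_bglmm(C, N, X, chains = 2, n_iter = 2000, burnin = 1000,
                  thin = 2, seed = 8)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), 500)
  expect_error(fit_bglmm(C, N, X, chains = 1), "chains")
  expect_error(fit_bglmm(C, N, X, burnin = 5000, n_iter = 2000), "burnin")
})

test_that("Gelman-Rubin follows the classic formula and flags degeneracy", {
  mk <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "a"))
  # identical chains: B = 0, R = sqrt((n-1)/n)
  r <- gelman_rubin(list(mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(unname(r), sqrt(2 / 3))
  expect_warning(
    r2 <- gelman_rubin(list(mk(c(0, 0, 0)), mk(c(10, 10, 10)))),
    "within-chain"
  )
  expect_true(is.nan(unname(r2)))
})

test_that("MCMC p-values implement the sign-opposite-the-mean convention", {
  expect_equal(mcmc_pvalue(rep(1, 10)), 0)
  expect_equal(mcmc_pvalue(c(-1, 1, 1, 1)), 0.5) # 2 x 1/4
  expect_equal(mcmc_pvalue(c(-1, 1)), 1)          # capped at the mean-zero edge
  # zeros count with the mean's sign, not against it
  expect_equal(mcmc_pvalue(c(0, 1, 1, 1)), 0)
  expect_equal(mcmc_pvalue(c(-2, 1, 1, 1, 1), tail = "one_positive"), 0.8)
  expect_equal(mcmc_pvalue(c(-2, 1, 1, 1, 1), tail = "one_negative"), 0.2)
})

test_that("delta statistics reduce to closed forms on fixed draws", {
  zeros <- matrix(0, nrow = 50, ncol = 7,
                  dimnames = list(NULL, paste0("a", 0:6)))
  d0 <- delta_stat(fake_fit(zeros))
  expect_equal(d0$delta_mean, rep(0, 4))
  expect_equal(d0$mcmc_p, rep(1, 4))
  shifted <- zeros; shifted[, 1] <- qlogis(0.6)
  d1 <- delta_stat(fake_fit(shifted))
  expect_equal(d1$delta_mean, rep(-0.1, 4))
  expect_equal(d1$p_LP_mean, rep(0.6, 4))
})

test_that("posterior matches grid quadrature on a reduced model", {
  set.seed(61)
  C <- c(5, 7, 3); N <- c(10, 12, 9)
  X <- cbind(intercept = rep(1, 3))
  fit <- fit_bglmm(C, N, X, chains = 2, n_iter = 22000, burnin = 2000,
                   thin = 2, seed = 3)
  draws <- do.call(rbind, fit$draws)[, "intercept"]
  grid <- seq(-4, 4, length.out = 2001)
  lp <- vapply(grid, function(a) {
    sum(dbinom(C, N, plogis(a), log = TRUE)) +
      dt(a / 2.5, df = 1, log = TRUE) - log(2.5)
  }, numeric(1))
  w <- exp(lp - max(lp))
  ks <- max(abs(ecdf(draws)(grid) - cumsum(w) / sum(w)))
  expect_lt(ks, 0.03)
})

test_that("label swapping LP <-> LF negates the matching contrasts", {
  s <- small_study(seed = 5)
  fitA <- fit_siring_model(s$tallies, chains = 2, n_iter = 10000,
                           burnin = 5000, thin = 5, seed = 2)
  swapped <- s$tallies |>
    dplyr::mutate(C = N - C,
                  female_ecotype = ifelse(female_ecotype == "LP", "LF", "LP")) |>
    dplyr::rename(vs_LP = vs_LF, vs_LF = vs_LP)
  fitB <- fit_siring_model(swapped, chains = 2, n_iter = 10000,
                           burnin = 5000, thin = 5, seed = 2)
  a <- tidy(fitA)$estimate
  b <- tidy(fitB)$estimate
  tol <- 0.1 # Monte-Carlo error at these chain lengths
  expect_equal(b[3], -a[3], tolerance = tol, ignore_attr = TRUE) # experiment
  expect_equal(b[4], -a[5], tolerance = tol, ignore_attr = TRUE) # speeds swap
  expect_equal(b[5], -a[4], tolerance = tol, ignore_attr = TRUE)
  expect_equal(b[1], -(a[1] + a[2]), tolerance = tol, ignore_attr = TRUE)
})

test_that("the intercept's 95% interval covers zero under the fair raffle", {
  covered <- 0
  for (s in 1:20) {
    cfg <- truth_config(alpha = rep(0, 7), sd_female = 0, sd_pair = 0,
                        seed = 200 + s)
    comp <- simulate_competition(simulate_males(cfg), simulate_females(cfg), cfg)
    tal <- tally_paternity(comp$genotypes, comp$trials, simulate_females(cfg))
    fit <- fit_siring_model(tal, chains = 2, n_iter = 6000, burnin = 3000,
                            thin = 3, seed = s)
    td <- tidy(fit)
    a0 <- td[td$term == "intercept", ]
    covered <- covered + (a0$conf.low <= 0 & 0 <= a0$conf.high)
  }
  expect_gte(covered, 18) # >= 90% of 20 replicates
})

test_that("tidy and glance summarise a fit coherently", {
  s <- small_study(seed = 7)
  fit <- fit_siring_model(s$tallies, chains = 2, n_iter = 4000,
                          burnin = 2000, thin = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, colnames(fit$data$X))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(td$mcmc_p >= 0 & td$mcmc_p <= 1))
  ta <- tidy(fit, effects = "all")
  expect_gt(nrow(ta), nrow(td))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(s$tallies))
  expect_equal(gl$n_chains, 2)
  tab <- siring_table(fit)
  expect_equal(tab$tail, c(rep("two", 5), "one_positive", "one_positive"))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("a grossly misspecified fit is flagged by the Bayesian p-value", {
  set.seed(62)
  # half the trials all-LP, half all-LF: far more dispersed than binomial
  n <- 40
  C <- rep(c(27L, 0L), each = n / 2); N <- rep(27L, n)
  X <- cbind(intercept = rep(1, n))
  fit <- fit_bglmm(C, N, X, chains = 2, n_iter = 6000, burnin = 3000,
                   thin = 3, seed = 4)
  bp <- bayes_pvalue(fit, seed = 1)
  expect_lt(min(bp, 1 - bp), 0.05)
})
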