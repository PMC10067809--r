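#' Scale sperm speeds to z-scores
#'
#' Centres to zero mean and scales to unit *sample* standard deviation
#' (n - 1 denominator), the convention used before entering speeds in the
#' siring model to avoid spurious intercept-slope correlation.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
scale_speeds <- function(x) {
  if (length(x) < 2 || stats::sd(x) == 0) {
    stop("need at least two distinct values to scale", call. = FALSE)
  }
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Log posterior density of the hierarchical binomial siring model
#'
#' Evaluates, up to nothing (all constants included), the joint log density
#' of data and parameters: binomial log-likelihoods with logit link,
#' Student-t priors on the fixed effects, Gaussian priors on the random
#' effects given their SDs, and half-Cauchy hyperpriors on the SDs. This is
#' the density the sampler explores; it is exported so the model can be
#' checked against independent evaluations.
#'
#' @param params List with `beta` (fixed effects, length = ncol(X)) and
#'   optionally `u1`, `sd1`, `u2`, `sd2` for the two random-effect blocks.
#' @param C,N Successes and trials per observation.
#' @param X Design matrix (rows = observations).
#' @param g1,g2 Integer group indices (1-based) for the two random-effect
#'   blocks, or `NULL`.
#' @param prior_scale,prior_df Scale and degrees of freedom of the
#'   Student-t prior on fixed effects (defaults 2.5 and 1, i.e.
#'   Cauchy(0, 2.5)).
#' @param re_scale Scale of the half-Cauchy hyperprior on random-effect
#'   SDs (default 2.5).
#' @return Scalar log posterior density; `-Inf` if an SD is non-positive.
#' @export
bglmm_log_posterior <- function(params, C, N, X, g1 = NULL, g2 = NULL,
                                prior_scale = 2.5, prior_df = 1,
                                re_scale = 2.5) {
  beta <- params$beta
  stopifnot(length(beta) == ncol(X), length(C) == nrow(X), length(N) == nrow(X))
  eta <- drop(X %*% beta)
  lp <- 0
  for (blk in list(list(u = params$u1, sd = params$sd1, g = g1),
                   list(u = params$u2, sd = params$sd2, g = g2))) {
    if (!is.null(blk$u)) {
      if (is.null(blk$sd) || blk$sd <= 0) return(-Inf)
      eta <- eta + blk$u[blk$g]
      lp <- lp + sum(stats::dnorm(blk$u, 0, blk$sd, log = TRUE)) +
        log(2) + stats::dcauchy(blk$sd, 0, re_scale, log = TRUE)
    }
  }
  lp + sum(stats::dbinom(C, N, stats::plogis(eta), log = TRUE)) +
    sum(stats::dt(beta / prior_scale, df = prior_df, log = TRUE) -
          log(prior_scale))
}

#' Fit a hierarchical binomial logit model by MCMC
#'
#' Runs the package's adaptive random-walk Metropolis-within-Gibbs sampler:
#' every scalar parameter (each fixed effect, each random-effect value, and
#' each random-effect SD on the log scale) gets a Gaussian proposal whose
#' step size adapts toward a 44% acceptance rate during burn-in only, so
#' the retained draws come from a fixed transition kernel. Chains are
#' seeded `seed, seed + 1, ...` and are individually reproducible.
#'
#' The default chain specification (4 chains of 200,000 iterations, 100,000
#' burn-in, thinning 10) matches the study's; far shorter chains converge
#' for data of this size and are used throughout the package's own tests.
#'
#' @inheritParams bglmm_log_posterior
#' @param X Design matrix with named columns.
#' @param g1,g2 Factors (or `NULL`) giving the random-effect grouping of
#'   each observation.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter,burnin,thin Iterations per chain, burn-in discarded, and
#'   thinning period.
#' @param seed Integer seed for the first chain.
#' @param init_sd SD of the Gaussian initial values for fixed effects.
#' @return An object of class `bglmm`: list with `draws` (list of
#'   per-chain matrices, one named column per parameter plus `lp__`),
#'   `data` (C, N, X, group factors) and `meta` (chain spec, seed, priors).
#' @seealso [fit_siring_model()] for the competitive-paternity front end;
#'   [tidy.bglmm()], [gelman_rubin()], [bayes_pvalue()].
#' @export
fit_bglmm <- function(C, N, X, g1 = NULL, g2 = NULL,
                      chains = 4, n_iter = 200000, burnin = 100000, thin = 10,
                      seed = 1, prior_scale = 2.5, prior_df = 1,
                      re_scale = 2.5, init_sd = 1) {
  stopifnot(nrow(X) == length(C), length(N) == length(C), all(C >= 0),
            all(C <= N))
  if (chains < 2) stop("need >= 2 chains for convergence diagnostics", call. = FALSE)
  if (burnin >= n_iter) stop("`burnin` must be smaller than `n_iter`", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("beta", seq_len(ncol(X)) - 1)

  f1 <- if (!is.null(g1)) factor(g1) else NULL
  f2 <- if (!is.null(g2)) factor(g2) else NULL
  n_g1 <- if (is.null(f1)) 0L else nlevels(f1)
  n_g2 <- if (is.null(f2)) 0L else nlevels(f2)
  i1 <- if (is.null(f1)) integer(length(C)) else as.integer(f1) - 1L
  i2 <- if (is.null(f2)) integer(length(C)) else as.integer(f2) - 1L

  par_names <- c(
    colnames(X),
    if (n_g1) paste0("u_", levels(f1)),
    if (n_g2) paste0("v_", levels(f2)),
    if (n_g1) "sd_g1",
    if (n_g2) "sd_g2",
    "lp__"
  )

  draws <- lapply(seq_len(chains), function(ch) {
    set.seed(seed + ch - 1L)
    out <- .bglmm_chain(
      as.numeric(C), as.numeric(N), X, i1, i2, n_g1, n_g2,
      as.integer(n_iter), as.integer(burnin), as.integer(thin),
      prior_scale, prior_df, re_scale, init_sd
    )
    m <- out$draws
    colnames(m) <- par_names
    m
  })

  structure(
    list(
      draws = draws,
      data = list(C = C, N = N, X = X, g1 = f1, g2 = f2),
      meta = list(chains = chains, n_iter = n_iter, burnin = burnin,
                  thin = thin, seed = seed, prior_scale = prior_scale,
                  prior_df = prior_df, re_scale = re_scale)
    ),
    class = "bglmm"
  )
}

#' Fit the competitive-paternity siring model
#'
#' Front end to [fit_bglmm()] for paternity tallies: models the number of
#' larvae sired by the brook-lamprey (LP) male, `C`, out of `N` genotyped
#' larvae per trial as binomial with
#' `logit(p) = a0 + a1 femaleLP + a2 equal_number + a3 vsLP + a4 vsLF +
#' a5 equal_number:vsLP + a6 equal_number:vsLF + female + pair`,
#' where `vsLP`/`vsLF` are the pair's sperm speeds scaled to z-scores and
#' the female-identity and male-pair effects are Gaussian. Reference levels
#' are the LF female and the equal-volume experiment (0/1 dummies).
#'
#' @param tallies Tibble with one row per trial: `C`, `N`,
#'   `female_ecotype` ("LF"/"LP"), `experiment`
#'   ("equal_volume"/"equal_number"), `female_id`, `pair_id`, and either
#'   already-scaled `vs_LP`/`vs_LF` or raw `speed_LP`/`speed_LF` (scaled
#'   here, pooled over both experiments).
#' @inheritParams fit_bglmm
#' @param ... Passed on to [fit_bglmm()] (priors, `init_sd`).
#' @return A `siring_fit` (inherits `bglmm`) whose fixed effects are named
#'   `intercept`, `female_LP`, `equal_number`, `vs_LP`, `vs_LF`,
#'   `equal_number:vs_LP`, `equal_number:vs_LF`.
#' @export
fit_siring_model <- function(tallies, chains = 4, n_iter = 20000,
                             burnin = 10000, thin = 10, seed = 1, ...) {
  need <- c("C", "N", "female_ecotype", "experiment", "female_id", "pair_id")
  miss <- setdiff(need, names(tallies))
  if (length(miss)) stop("tallies missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  tallies <- dplyr::filter(tallies, .data$N > 0)
  if (!all(c("vs_LP", "vs_LF") %in% names(tallies))) {
    if (!all(c("speed_LP", "speed_LF") %in% names(tallies))) {
      stop("need scaled speeds (vs_LP, vs_LF) or raw speeds (speed_LP, speed_LF)",
           call. = FALSE)
    }
    tallies$vs_LP <- scale_speeds(tallies$speed_LP)
    tallies$vs_LF <- scale_speeds(tallies$speed_LF)
  }
  fem <- as.integer(tallies$female_ecotype == "LP")
  eqn <- as.integer(tallies$experiment == "equal_number")
  X <- cbind(
    intercept = 1, female_LP = fem, equal_number = eqn,
    vs_LP = tallies$vs_LP, vs_LF = tallies$vs_LF,
    `equal_number:vs_LP` = eqn * tallies$vs_LP,
    `equal_number:vs_LF` = eqn * tallies$vs_LF
  )
  fit <- fit_bglmm(tallies$C, tallies$N, X,
                   g1 = tallies$female_id, g2 = tallies$pair_id,
                   chains = chains, n_iter = n_iter, burnin = burnin,
                   thin = thin, seed = seed, ...)
  fit$data$tallies <- tallies
  class(fit) <- c("siring_fit", class(fit))
  fit
}

# pooled draws across chains as one matrix
pool_draws <- function(fit) do.call(rbind, fit$draws)

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-free R-hat over the retained chains:
#' `R = sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of chain means times `n`.
#' Values below 1.1 are conventionally taken as convergence. If the
#' within-chain variance is zero the statistic is undefined and `NaN` is
#' returned with a warning.
#'
#' @param fit A [fit_bglmm()] object, or a list of per-chain draw matrices
#'   with identical named columns.
#' @param pars Parameter names (default: all columns except `lp__`).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit, pars = NULL) {
  chains <- if (inherits(fit, "bglmm")) fit$draws else fit
  stopifnot(is.list(chains), length(chains) >= 2)
  if (is.null(pars)) pars <- setdiff(colnames(chains[[1]]), "lp__")
  n <- nrow(chains[[1]])
  if (n < 2) stop("need >= 2 retained draws per chain", call. = FALSE)
  vapply(pars, function(p) {
    x <- vapply(chains, function(m) m[, p], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    if (W == 0) {
      warning("zero within-chain variance for ", p, "; R-hat undefined",
              call. = FALSE)
      return(NaN)
    }
    B <- n * stats::var(colMeans(x))
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' MCMC p-value of a posterior sample
#'
#' Two-tailed: twice the fraction of draws whose sign opposes the sign of
#' the posterior mean, capped at 1 (zero draws count with the mean's sign,
#' not against it). One-tailed `"one_positive"`: the fraction of positive
#' draws; `"one_negative"`: the fraction of negative draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param tail `"two"` (default), `"one_positive"`, or `"one_negative"`.
#' @return p-value in \[0, 1\].
#' @export
mcmc_pvalue <- function(draws, tail = c("two", "one_positive", "one_negative")) {
  tail <- match.arg(tail)
  stopifnot(length(draws) >= 1)
  switch(tail,
    two = {
      m <- mean(draws)
      if (m == 0) return(1)
      opposite <- if (m > 0) draws < 0 else draws > 0
      min(1, 2 * mean(opposite))
    },
    one_positive = mean(draws > 0),
    one_negative = mean(draws < 0)
  )
}

# per-draw linear predictors (n obs x S draws) from a fitted model
draw_etas <- function(fit, draws = pool_draws(fit)) {
  X <- fit$data$X
  p <- ncol(X)
  eta <- X %*% t(draws[, seq_len(p), drop = FALSE])
  if (!is.null(fit$data$g1)) {
    u <- draws[, p + seq_len(nlevels(fit$data$g1)), drop = FALSE]
    eta <- eta + t(u)[as.integer(fit$data$g1), , drop = FALSE]
  }
  if (!is.null(fit$data$g2)) {
    off <- p + if (is.null(fit$data$g1)) 0L else nlevels(fit$data$g1)
    v <- draws[, off + seq_len(nlevels(fit$data$g2)), drop = FALSE]
    eta <- eta + t(v)[as.integer(fit$data$g2), , drop = FALSE]
  }
  eta
}

#' Posterior-predictive (Bayesian) p-value
#'
#' For every retained draw, data are re-simulated from the fitted model
#' (`C ~ Binomial(N, p)` at that draw's parameters) and the sum of squared
#' Pearson residuals is computed for both the replicate and the observed
#' data. The Bayesian p-value is the fraction of draws where the replicate
#' discrepancy exceeds the observed one; values near 0.5 indicate the model
#' reproduces its own residual structure.
#'
#' @param fit A [fit_bglmm()] object.
#' @param seed Seed for the replicate simulations.
#' @return p-value in \[0, 1\].
#' @export
bayes_pvalue <- function(fit, seed = 1) {
  set.seed(seed)
  draws <- pool_draws(fit)
  eta <- draw_etas(fit, draws)
  p <- stats::plogis(eta)
  N <- fit$data$N
  C <- fit$data$C
  mu <- N * p
  v <- pmax(N * p * (1 - p), 1e-12)
  d_obs <- colSums((C - mu)^2 / v)
  C_rep <- matrix(stats::rbinom(length(p), rep(N, ncol(p)), p), nrow = nrow(p))
  d_rep <- colSums((C_rep - mu)^2 / v)
  mean(d_rep > d_obs)
}

#' Departure from the fair raffle by design cell
#'
#' For each of the four female-ecotype x experiment cells, computes at
#' every retained draw the model-implied probability that the LP male
#' sires a larva — fixed effects evaluated at scaled speeds 0 (the average
#' pair) and random effects at 0 — and the departure
#' `Delta = 0.5 - p` from random paternity, with a two-tailed
#' [mcmc_pvalue()] per cell.
#'
#' @param fit A [fit_siring_model()] object (or any `bglmm` whose first
#'   three fixed effects are intercept, female ecotype and experiment
#'   type).
#' @return A tibble with one row per cell: `female_ecotype`, `experiment`,
#'   `p_LP_mean`, `delta_mean`, `delta_sd`, `mcmc_p`. The per-draw Delta
#'   matrix is attached as attribute `"draws"`.
#' @export
delta_stat <- function(fit) {
  draws <- pool_draws(fit)
  a0 <- draws[, 1]; a1 <- draws[, 2]; a2 <- draws[, 3]
  cells <- tidyr::expand_grid(
    female_ecotype = c("LF", "LP"),
    experiment = c("equal_volume", "equal_number")
  )
  delta <- purrr::map2(cells$female_ecotype, cells$experiment, function(f, e) {
    0.5 - stats::plogis(a0 + a1 * (f == "LP") + a2 * (e == "equal_number"))
  })
  out <- cells |>
    dplyr::mutate(
      p_LP_mean = purrr::map_dbl(delta, ~ mean(0.5 - .x)),
      delta_mean = purrr::map_dbl(delta, mean),
      delta_sd = purrr::map_dbl(delta, stats::sd),
      mcmc_p = purrr::map_dbl(delta, mcmc_pvalue)
    )
  attr(out, "draws") <- do.call(cbind, delta)
  out
}
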