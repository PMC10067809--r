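# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

# point-by-point loop VCL
naive_vcl <- function(track, fps) {
  d <- 0
  for (i in 2:nrow(track)) {
    d <- d + sqrt((track$x_um[i] - track$x_um[i - 1])^2 +
                    (track$y_um[i] - track$y_um[i - 1])^2)
  }
  d / ((track$frame[nrow(track)] - track$frame[1]) / fps)
}

# reference smoother: explicit mean() over a symmetrically shrinking window
naive_vap <- function(track, fps, window) {
  n <- nrow(track)
  h <- (window - 1) / 2
  sx <- sy <- numeric(n)
  for (i in seq_len(n)) {
    hw <- min(h, i - 1, n - i)
    sx[i] <- mean(track$x_um[(i - hw):(i + hw)])
    sy[i] <- mean(track$y_um[(i - hw):(i + hw)])
  }
  d <- 0
  for (i in 2:n) d <- d + sqrt((sx[i] - sx[i - 1])^2 + (sy[i] - sy[i - 1])^2)
  d / ((track$frame[n] - track$frame[1]) / fps)
}

# full-enumeration Mann-Whitney: W by pair counting, exact two-sided p by
# enumerating every assignment of ranks to the first group (untied data)
enum_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  W_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  r <- rank(c(x, y))
  subsets <- utils::combn(n1 + n2, n1)
  W_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
  list(W = W_obs, p = p)
}

# direct-formula evaluator for the hierarchical binomial log posterior
naive_log_posterior <- function(beta, u1, sd1, u2, sd2, C, N, X, g1, g2,
                                prior_scale = 2.5, prior_df = 1,
                                re_scale = 2.5) {
  lp <- 0
  for (i in seq_along(C)) {
    eta <- sum(X[i, ] * beta)
    if (!is.null(u1)) eta <- eta + u1[g1[i]]
    if (!is.null(u2)) eta <- eta + u2[g2[i]]
    p <- 1 / (1 + exp(-eta))
    lp <- lp + lchoose(N[i], C[i]) + C[i] * log(p) + (N[i] - C[i]) * log(1 - p)
  }
  for (b in beta) {
    lp <- lp + log(gamma((prior_df + 1) / 2) / (gamma(prior_df / 2) *
            sqrt(prior_df * pi) * prior_scale) *
            (1 + (b / prior_scale)^2 / prior_df)^(-(prior_df + 1) / 2))
  }
  hc <- function(s) log(2 / (pi * re_scale * (1 + (s / re_scale)^2)))
  if (!is.null(u1)) {
    lp <- lp + sum(-0.5 * log(2 * pi * sd1^2) - u1^2 / (2 * sd1^2)) + hc(sd1)
  }
  if (!is.null(u2)) {
    lp <- lp + sum(-0.5 * log(2 * pi * sd2^2) - u2^2 / (2 * sd2^2)) + hc(sd2)
  }
  lp
}

# random correlated-walk track for property tests
random_track <- function(n, step_sd = 2) {
  tibble::tibble(
    frame = 0:(n - 1),
    x_um = cumsum(stats::rnorm(n, 0, step_sd)),
    y_um = cumsum(stats::rnorm(n, 0, step_sd))
  )
}

# a minimal bglmm-shaped object carrying fixed draws, for closed-form checks
fake_fit <- function(draw_matrix) {
  structure(list(draws = list(draw_matrix)), class = "bglmm")
}

# small synthetic study shared by several tests
small_study <- function(seed = 1, ...) {
  cfg <- truth_config(seed = seed, ...)
  males <- simulate_males(cfg)
  females <- simulate_females(cfg)
  comp <- simulate_competition(males, females, cfg)
  tallies <- suppressWarnings(tally_paternity(comp$genotypes, comp$trials, females))
  list(cfg = cfg, males = males, females = females,
       trials = comp$trials, genotypes = comp$genotypes, tallies = tallies)
}
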