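#include <Rcpp.h>
using namespace Rcpp;

// Binomial logit log-likelihood contribution of one trial, without the
// constant lchoose(N, C) term (it cancels in all Metropolis ratios).
static inline double ll_term(double C, double N, double eta) {
  // C*eta - N*log(1 + exp(eta)), numerically stable for large |eta|
  double log1pexp = (eta > 0) ? eta + std::log1p(std::exp(-eta))
                              : std::log1p(std::exp(eta));
  return C * eta - N * log1pexp;
}

// log density of Student-t(location 0, scale s, df nu) at x
static inline double lt_prior(double x, double s, double nu) {
  return R::dt(x / s, nu, 1) - std::log(s);
}

// log density of half-Cauchy(0, s) at x > 0
static inline double lhalfcauchy(double x, double s) {
  return std::log(2.0) - std::log(M_PI * s * (1.0 + (x / s) * (x / s)));
}

// One adaptive Metropolis-within-Gibbs chain for the hierarchical
// binomial logit model:
//   C_i ~ Bin(N_i, inv_logit(eta_i)),
//   eta_i = X_i beta + u1[g1_i] + u2[g2_i]
//   beta_j ~ t(0, prior_scale, prior_df)
//   u*     ~ N(0, sd*^2),   sd* ~ half-Cauchy(0, re_scale)
// Random-effect SDs are updated on the log scale (Jacobian included).
// Uses R's RNG, so set.seed() in R makes the chain reproducible.
// [[Rcpp::export(name = ".bglmm_chain")]]
List bglmm_chain(NumericVector C, NumericVector N, NumericMatrix X,
                 IntegerVector g1, IntegerVector g2,
                 int n_g1, int n_g2,
                 int n_iter, int burnin, int thin,
                 double prior_scale, double prior_df, double re_scale,
                 double init_sd) {
  RNGScope scope;
  const int n = C.size();
  const int p = X.ncol();
  const bool has1 = n_g1 > 0, has2 = n_g2 > 0;
  const int n_par = p + n_g1 + n_g2 + (has1 ? 1 : 0) + (has2 ? 1 : 0);

  std::vector<double> beta(p), u1(n_g1, 0.0), u2(n_g2, 0.0);
  for (int j = 0; j < p; ++j) beta[j] = R::rnorm(0.0, init_sd);
  double sd1 = 1.0, sd2 = 1.0;

  // trial indices per random-effect level, for local likelihood updates
  std::vector< std::vector<int> > idx1(n_g1), idx2(n_g2);
  if (has1) for (int i = 0; i < n; ++i) idx1[g1[i]].push_back(i);
  if (has2) for (int i = 0; i < n; ++i) idx2[g2[i]].push_back(i);

  std::vector<double> eta(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    if (has1) e += u1[g1[i]];
    if (has2) e += u2[g2[i]];
    eta[i] = e;
  }

  // adaptive proposal scales, one per scalar parameter
  std::vector<double> prop(n_par, 0.5);
  std::vector<int> acc(n_par, 0), att(n_par, 0);
  const int batch = 50;
  int batch_no = 0;

  const int n_keep = (n_iter - burnin) / thin;
  NumericMatrix draws(n_keep, n_par + 1);  // + log-posterior column
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    int k = 0;  // scalar-parameter index

    // fixed effects
    for (int j = 0; j < p; ++j, ++k) {
      double prop_b = beta[j] + prop[k] * R::norm_rand();
      double d = prop_b - beta[j];
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        dll += ll_term(C[i], N[i], eta[i] + d * X(i, j)) -
               ll_term(C[i], N[i], eta[i]);
      }
      dll += lt_prior(prop_b, prior_scale, prior_df) -
             lt_prior(beta[j], prior_scale, prior_df);
      ++att[k];
      if (std::log(R::unif_rand()) < dll) {
        beta[j] = prop_b;
        for (int i = 0; i < n; ++i) eta[i] += d * X(i, j);
        ++acc[k];
      }
    }

    // random effects, group 1
    for (int g = 0; g < n_g1; ++g, ++k) {
      double prop_u = u1[g] + prop[k] * R::norm_rand();
      double d = prop_u - u1[g];
      double dll = 0.0;
      for (size_t m = 0; m < idx1[g].size(); ++m) {
        int i = idx1[g][m];
        dll += ll_term(C[i], N[i], eta[i] + d) - ll_term(C[i], N[i], eta[i]);
      }
      dll += R::dnorm(prop_u, 0.0, sd1, 1) - R::dnorm(u1[g], 0.0, sd1, 1);
      ++att[k];
      if (std::log(R::unif_rand()) < dll) {
        u1[g] = prop_u;
        for (size_t m = 0; m < idx1[g].size(); ++m) eta[idx1[g][m]] += d;
        ++acc[k];
      }
    }

    // random effects, group 2
    for (int g = 0; g < n_g2; ++g, ++k) {
      double prop_u = u2[g] + prop[k] * R::norm_rand();
      double d = prop_u - u2[g];
      double dll = 0.0;
      for (size_t m = 0; m < idx2[g].size(); ++m) {
        int i = idx2[g][m];
        dll += ll_term(C[i], N[i], eta[i] + d) - ll_term(C[i], N[i], eta[i]);
      }
      dll += R::dnorm(prop_u, 0.0, sd2, 1) - R::dnorm(u2[g], 0.0, sd2, 1);
      ++att[k];
      if (std::log(R::unif_rand()) < dll) {
        u2[g] = prop_u;
        for (size_t m = 0; m < idx2[g].size(); ++m) eta[idx2[g][m]] += d;
        ++acc[k];
      }
    }

    // SDs on the log scale: prior + Jacobian + RE likelihood
    if (has1) {
      double ls = std::log(sd1);
      double prop_ls = ls + prop[k] * R::norm_rand();
      double prop_sd = std::exp(prop_ls);
      double dll = lhalfcauchy(prop_sd, re_scale) - lhalfcauchy(sd1, re_scale) +
                   prop_ls - ls;  // Jacobian
      for (int g = 0; g < n_g1; ++g) {
        dll += R::dnorm(u1[g], 0.0, prop_sd, 1) - R::dnorm(u1[g], 0.0, sd1, 1);
      }
      ++att[k];
      if (std::log(R::unif_rand()) < dll) { sd1 = prop_sd; ++acc[k]; }
      ++k;
    }
    if (has2) {
      double ls = std::log(sd2);
      double prop_ls = ls + prop[k] * R::norm_rand();
      double prop_sd = std::exp(prop_ls);
      double dll = lhalfcauchy(prop_sd, re_scale) - lhalfcauchy(sd2, re_scale) +
                   prop_ls - ls;
      for (int g = 0; g < n_g2; ++g) {
        dll += R::dnorm(u2[g], 0.0, prop_sd, 1) - R::dnorm(u2[g], 0.0, sd2, 1);
      }
      ++att[k];
      if (std::log(R::unif_rand()) < dll) { sd2 = prop_sd; ++acc[k]; }
      ++k;
    }

    // proposal adaptation during burn-in only (keeps the retained chain
    // a valid fixed-kernel Markov chain)
    if (it <= burnin && it % batch == 0) {
      ++batch_no;
      double step = std::min(0.1, 1.0 / std::sqrt((double) batch_no));
      for (int q = 0; q < n_par; ++q) {
        double rate = att[q] ? (double) acc[q] / att[q] : 0.0;
        prop[q] *= std::exp(rate > 0.44 ? step : -step);
        acc[q] = 0; att[q] = 0;
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      double lp = 0.0;
      for (int i = 0; i < n; ++i) lp += ll_term(C[i], N[i], eta[i]);
      for (int j = 0; j < p; ++j) lp += lt_prior(beta[j], prior_scale, prior_df);
      if (has1) {
        for (int g = 0; g < n_g1; ++g) lp += R::dnorm(u1[g], 0.0, sd1, 1);
        lp += lhalfcauchy(sd1, re_scale);
      }
      if (has2) {
        for (int g = 0; g < n_g2; ++g) lp += R::dnorm(u2[g], 0.0, sd2, 1);
        lp += lhalfcauchy(sd2, re_scale);
      }
      int col = 0;
      for (int j = 0; j < p; ++j) draws(kept, col++) = beta[j];
      for (int g = 0; g < n_g1; ++g) draws(kept, col++) = u1[g];
      for (int g = 0; g < n_g2; ++g) draws(kept, col++) = u2[g];
      if (has1) draws(kept, col++) = sd1;
      if (has2) draws(kept, col++) = sd2;
      draws(kept, col) = lp;
      ++kept;
    }
  }

  return List::create(_["draws"] = draws);
}
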