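#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted hierarchical binomial model
#'
#' One row per parameter with posterior mean, SD, central 95% credible
#' interval, Gelman-Rubin R-hat, and the two-tailed MCMC p-value.
#'
#' @param x A [fit_bglmm()] object.
#' @param effects `"fixed"` (default) or `"all"` (adds random effects and
#'   their SDs).
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`, `mcmc_p`.
#' @export
tidy.bglmm <- function(x, effects = c("fixed", "all"), ...) {
  effects <- match.arg(effects)
  pars <- if (effects == "fixed") colnames(x$data$X)
          else setdiff(colnames(x$draws[[1]]), "lp__")
  pooled <- pool_draws(x)[, pars, drop = FALSE]
  rh <- gelman_rubin(x, pars)
  tibble::tibble(
    term = pars,
    estimate = colMeans(pooled),
    std.error = apply(pooled, 2, stats::sd),
    conf.low = apply(pooled, 2, stats::quantile, 0.025),
    conf.high = apply(pooled, 2, stats::quantile, 0.975),
    rhat = unname(rh[pars]),
    mcmc_p = apply(pooled, 2, mcmc_pvalue)
  )
}

#' Glance at a fitted hierarchical binomial model
#'
#' @param x A [fit_bglmm()] object.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n_chains`, `n_draws` (retained, all
#'   chains), `max_rhat`, `mean_lp`.
#' @export
glance.bglmm <- function(x, ...) {
  pooled <- pool_draws(x)
  tibble::tibble(
    nobs = length(x$data$C),
    n_chains = x$meta$chains,
    n_draws = nrow(pooled),
    max_rhat = max(gelman_rubin(x)),
    mean_lp = mean(pooled[, "lp__"])
  )
}

#' Trace plot of a fitted model's chains
#'
#' @param object A [fit_bglmm()] object.
#' @param pars Parameters to plot (default: the fixed effects).
#' @param ... Unused.
#' @return A ggplot: one facet per parameter, one colour per chain.
#' @export
autoplot.bglmm <- function(object, pars = colnames(object$data$X), ...) {
  df <- purrr::imap_dfr(object$draws, function(m, ch) {
    tibble::as_tibble(m[, pars, drop = FALSE]) |>
      dplyr::mutate(.iteration = dplyr::row_number(), .chain = factor(ch))
  }) |>
    tidyr::pivot_longer(dplyr::all_of(pars),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$.iteration, .data$value,
                                   colour = .data$.chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}

#' Paternity shares by design cell
#'
#' Mean and standard error of the observed LP-sired fraction per
#' female-ecotype x experiment cell, with per-trial points.
#'
#' @param tallies Tibble with `C`, `N`, `female_ecotype`, `experiment`.
#' @return A ggplot.
#' @export
plot_paternity_shares <- function(tallies) {
  df <- tallies |>
    dplyr::filter(.data$N > 0) |>
    dplyr::mutate(share = .data$C / .data$N)
  summ <- df |>
    dplyr::group_by(.data$female_ecotype, .data$experiment) |>
    dplyr::summarise(mean = mean(.data$share),
                     se = stats::sd(.data$share) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$experiment, .data$mean)) +
    ggplot2::geom_jitter(data = df,
                         ggplot2::aes(.data$experiment, .data$share),
                         width = 0.08, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~female_ecotype,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "LP-sired fraction") +
    ggplot2::theme_minimal()
}

#' Sperm traits by ecotype
#'
#' Mean and standard error of a per-male trait (VAP or concentration) in
#' each ecotype, with per-male points.
#'
#' @param males Tibble with `ecotype` and the trait column.
#' @param trait Name of the trait column (default `"vap_mean"`).
#' @return A ggplot.
#' @export
plot_sperm_traits <- function(males, trait = "vap_mean") {
  summ <- males |>
    dplyr::group_by(.data$ecotype) |>
    dplyr::summarise(mean = mean(.data[[trait]]),
                     se = stats::sd(.data[[trait]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$ecotype, .data$mean)) +
    ggplot2::geom_jitter(data = males,
                         ggplot2::aes(.data$ecotype, .data[[trait]]),
                         width = 0.05, alpha = 0.5, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = NULL, y = trait) +
    ggplot2::theme_minimal()
}
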