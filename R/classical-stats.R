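#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum comparison of two groups, returned broom-style. The
#' statistic `W` counts the pairs where a first-group value exceeds a
#' second-group value (plus half the ties) — so group order matters and is
#' fixed by the caller; putting the river-lamprey (LF) group first
#' reproduces the convention of the study's printed statistics. The p-value
#' is exact (full enumeration of rank assignments) when both groups have
#' fewer than 50 values and no ties occur, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors (first and second group).
#' @return One-row tibble: `statistic` (W), `p.value`, `n1`, `n2`,
#'   `method`, `alternative`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  tibble::tibble(
    statistic = unname(wt$statistic),
    p.value = wt$p.value,
    n1 = length(x), n2 = length(y),
    method = "Mann-Whitney",
    alternative = "two.sided"
  )
}

#' Two-sample t test
#'
#' Pooled-variance Student's t (default; degrees of freedom
#' `n1 + n2 - 2`, the convention matching the study's df = 24 with 13 + 13
#' males) or Welch's unequal-variance variant, returned broom-style.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return One-row tibble: `statistic` (t), `df`, `p.value`, `n1`, `n2`,
#'   `method`, `alternative`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two values per group", call. = FALSE)
  }
  if (variant == "student" && stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = variant == "student")
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    n1 = length(x), n2 = length(y),
    method = paste0(variant, " t-test"),
    alternative = "two.sided"
  )
}

#' Ecotype comparison of per-male sperm traits
#'
#' Reproduces the study's trait-comparison table: Mann-Whitney tests for
#' sperm concentration and GSI-derived total sperm (count-derived,
#' non-normal residuals), Student's t tests for the velocity traits VCL and
#' VAP. The LF group enters each test first.
#'
#' @param males Tibble with `ecotype` and per-male columns among
#'   `concentration`, `total_sperm`, `vcl_mean`, `vap_mean` (missing
#'   columns are skipped).
#' @return A tibble with one row per trait: `trait`, `mean_LF`, `mean_LP`,
#'   `statistic`, `df` (`NA` for rank tests), `p.value`, `method`.
#' @export
compare_sperm_traits <- function(males) {
  stopifnot("ecotype" %in% names(males))
  lf <- males[males$ecotype == "LF", ]
  lp <- males[males$ecotype == "LP", ]
  spec <- list(
    concentration = "mw", total_sperm = "mw",
    vcl_mean = "t", vap_mean = "t"
  )
  purrr::imap_dfr(spec, function(kind, trait) {
    if (!trait %in% names(males)) return(NULL)
    x <- lf[[trait]]; y <- lp[[trait]]
    res <- if (kind == "mw") {
      dplyr::mutate(mann_whitney(x, y), df = NA_real_)
    } else {
      two_sample_t(x, y)
    }
    tibble::tibble(
      trait = trait, mean_LF = mean(x), mean_LP = mean(y),
      statistic = res$statistic, df = res$df,
      p.value = res$p.value, method = res$method
    )
  })
}
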