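---
title: "Methods: the siring model and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the siring model and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the measurement conventions, the hierarchical model and its priors, the
sampler, the synthetic-data generator that makes everything testable, and
the places where a genuine design choice had to be made.

## The experimental system

Two lamprey ecotypes with partial reproductive isolation — the
anadromous, parasitic river lamprey (LF) and the freshwater-resident,
nonparasitic brook lamprey (LP) — spawn communally and can hybridize.
Whether postmating, prezygotic processes (sperm competition, cryptic
female choice) restrict gene flow is tested with paired-male in vitro
fertilizations: one male of each ecotype competes for a female's eggs,
either at *equal semen volume* (6 µL split 3 + 3) or at *equal sperm
number* (volumes set from measured concentrations so each male
contributes the same cell count in 6 µL). Because females are homozygous
at a diagnostic biallelic locus (LF *ff*, LP *pp*, hybrids *pf*), every
larva's sire ecotype is identified by a single genotype call.

## Kinematics: VCL and VAP

A track is an ordered set of positions `(frame, x, y)` in µm at a fixed
frame rate (60 fps, 3 s clips → 180 points in the emulated design).

* **VCL** (curvilinear velocity) is the summed point-to-point Euclidean
  distance divided by elapsed time. Elapsed time is
  `(last frame − first frame) / fps`, so dropped frames extend time
  rather than inflate speed.
* **VAP** (average-path velocity) is the length of the smoothed path over
  the same elapsed time. Smoothing is a centred moving average whose
  half-width shrinks symmetrically near the ends
  (`min(h, i−1, n−i)` with `h = (window−1)/2`), so the smoothed track
  keeps its endpoints and no positions are invented. With this edge rule
  every smoothed step is a convex-weighted mixture of raw steps whose
  per-step weights sum to one, which *guarantees* VAP ≤ VCL for every
  window — the property the tests exercise on 10,000 random tracks. The
  one-sided-truncation alternative ("average whatever falls in the
  window") loses that guarantee, which is why it was not chosen.

Tunables: `fps` (frames/s, default 60), `window` (points, odd, default 5
— a common CASA smoothing span at 60 fps; the original analysis software
setting is not public), `min_frames` (default 30; shorter fragments carry
little information and are dropped, mirroring CASA track filters).
Male-level traits are means of subsample means (three activation
subsamples per male), *not* pooled track means — pooling would weight
subsamples by how many cells happened to be tracked.

## Gamete quantification

Concentration is `cells / chamber volume × dilution`, averaged over
replicates, per mL. The chamber volume is an explicit argument — Thoma
chambers vary, so no grid constants are hard-coded. Total sperm per male
is `GSI × body mass × concentration` with semen density taken as
1 g/mL; GSI defaults are the literature values 4.64% (LF) and 11.9%
(LP). The GSI formulation requires body mass even though it is sometimes
left implicit: GSI is mass-relative, so mass is what converts it to a
semen volume. Equal-number mixing solves
`v_LF·c_LF = v_LP·c_LP, v_LF + v_LP = total`.

## The hierarchical siring model

Per trial, the count of LP-sired larvae is

$$C_i \sim \mathrm{Binomial}(N_i, p_i)$$
$$\operatorname{logit}(p_i) = \alpha_0 + \alpha_1\,\text{femaleLP}_i +
\alpha_2\,\text{eqnum}_i + \alpha_3\,vs^{LP}_i + \alpha_4\,vs^{LF}_i +
\alpha_5\,\text{eqnum}_i\,vs^{LP}_i + \alpha_6\,\text{eqnum}_i\,vs^{LF}_i +
\beta_{1,\text{female}(i)} + \beta_{2,\text{pair}(i)}$$

Design coding is 0/1 with the LF female and the equal-volume experiment
as reference levels — chosen so that a drop in LP paternity at equal
sperm number appears as a negative $\alpha_2$. Speeds are the pair
males' VAP (configurable to VCL) scaled to zero mean and unit *sample*
SD within the analysis dataset, each ecotype's variable separately;
scaling decorrelates intercept and slopes.

**Priors.** Fixed effects: Student-t with location 0, scale 2.5, df 1 —
i.e. Cauchy(0, 2.5), the standard weakly-informative logistic-regression
prior; the df is configurable because the original specification of the
t prior is ambiguous. Random effects: Gaussian with SDs given
half-Cauchy(0, 2.5) hyperpriors (unstated in the source analysis;
half-Cauchy is the conventional weakly-informative choice for a handful
of groups — 9 females, 13 pairs).

**Sampler.** An adaptive random-walk Metropolis-within-Gibbs, written in
C++: each scalar parameter (7 fixed effects, each random effect, each
log-SD with its Jacobian) takes a Gaussian proposal whose step size
adapts toward 44% acceptance in batches of 50 iterations *during burn-in
only*, so the retained draws come from a fixed kernel. Likelihood
updates are incremental in the linear predictor, making study-scale
chains (50 trials, 31 parameters) run at millions of updates per second.
Chains are seeded consecutively and byte-reproducible. Any correct
sampler would do; this one is validated against deterministic grid
quadrature on a reduced (intercept-only) model, where the
Kolmogorov-Smirnov distance between 10^5 MCMC draws and the quadrature
CDF must stay below 0.02.

**Default chain specification** is 4 chains × 200,000 iterations,
100,000 burn-in, thinning 10 — the original analysis scale. The
package's own tests, pipeline default and acceptance script use 4 ×
20,000 (10,000 burn-in, thin 10): at 50 binomial observations this
leaves every R-hat far below the 1.1 convergence convention while
keeping a full pipeline run around twenty seconds; the chain spec is an
argument everywhere.

**Derived statistics.**

* *MCMC p-value*: twice the posterior fraction whose sign opposes the
  posterior mean's sign, capped at 1; zero draws count with the mean
  (they do not oppose it), and a mean of exactly zero gives p = 1.
  One-tailed variants report the fraction of positive (or negative)
  draws; the two experiment-by-speed interactions are reported
  one-tailed (fraction positive), following the directional hypothesis
  that faster LF sperm raise LF siring success at equal sperm number.
* *Bayesian (posterior-predictive) p-value*: per retained draw, a
  replicate dataset is simulated from that draw's binomial
  probabilities; the discrepancy is the sum of squared Pearson
  residuals, and p is the fraction of draws whose replicate discrepancy
  exceeds the observed one. A caution from our replicate simulations:
  with this discrepancy — essentially a pivotal chi-square — the
  p-value's sampling distribution under a correctly specified model is
  considerably more spread out than the "always near 0.5" intuition,
  so single values in the 0.2–0.8 range should not be over-interpreted
  in either direction.
* *Fair-raffle departure* Δ: for each female-ecotype × experiment cell,
  per draw, `Δ = 0.5 − plogis(fixed effects at scaled speeds 0, random
  effects 0)`. Setting speeds to 0 (the average pair) and random effects
  to 0 (the typical female and pair) makes Δ a population-level cell
  summary rather than a prediction for any observed dish; that reading
  of "posterior probability of LP paternity per cell" is a choice, made
  once and flagged here.

The same engine fits the noncompetitive controls: fertilization success
(male ecotype fixed effect, female random effect, per egg ecotype) and
embryo viability (cross type fixed effect, female random effect). The
original frequentist quasibinomial/likelihood-ratio versions of those
comparisons are deliberately not reproduced; the binomial Bayesian fit
answers the same question with one engine.

## Classical tests

Sperm numbers (concentration, GSI-derived totals) are compared with
Mann-Whitney tests — count-derived traits deviate from normality — and
velocities with pooled Student t tests (df = n₁+n₂−2 = 24 at 13+13,
matching the published degrees of freedom). The rank statistic counts
first-group wins, so the LF-first convention is fixed by the caller; the
implementation defers to `wilcox.test()`/`t.test()` (exact rank p for
groups under 50 without ties, normal approximation with tie and
continuity corrections otherwise), and the test suite checks it against
a full-enumeration oracle for all group sizes up to 8.

## The synthetic-data generator

The generator's defaults *are* the emulated study conditions, fixed once:

| quantity | default | basis |
|---|---|---|
| males per ecotype | 13 | study design |
| concentration | lognormal; medians 0.5×10⁹ (LF), 1.0×10⁹ (LP) sperm/mL, CV 0.5 | ~2× LP/LF ordering; lognormal for positive, right-skewed support |
| body mass | lognormal; medians 38 g (LF), 6.5 g (LP), CV 0.2 | with the GSI defaults, reproduces the published total-sperm scale (~8–9×10⁸) |
| VCL means | 353.2 / 321.56 µm/s (LF/LP) | published values |
| VAP means | 270 / 230 µm/s; between-male SD 35 µm/s | published ordering and t-statistic scale; exact means unpublished |
| α (logit) | (0.25, −0.04, −0.7, −0.18, 0.13, 0.21, −0.83) | published posterior means; intercept = logit of the observed equal-volume LP share |
| RE SDs | 0.3 (female), 0.3 (pair) | unpublished; moderate heterogeneity |
| larvae/trial | 27 (one trial 22; one pair fails at equal number) | study design |
| females | 3 LF + 6 LP, recycled across pairs | study design |

Trajectories are correlated random walks: constant step `VCL_true/fps`
(so measured VCL is exact by construction) and Gaussian turning angles
whose SD comes from a closed form — for turning SD *s* the step
autocorrelation is `ρ^k` with `ρ = exp(−s²/2)`, and the expected squared
displacement over a `w`-point smoothing window gives the smoothed/raw
speed ratio `sqrt(w + 2Σ(w−k)ρ^k)/w`, solved for ρ at the target
`VAP/VCL`. The root-mean-square approximation and edge windows bias the
measured VAP slightly low (a few percent); the recovery tests allow 5%.

What the generator deliberately does **not** emulate: video segmentation
and tracking errors (tracks are clean by construction), cell-to-cell
speed heterogeneity within a male, motility fractions, temporal decline
of motility after activation, genotyping dropout (violations can only be
injected manually), overdispersion of paternity counts beyond what the
female/pair random effects induce, and egg development beyond a binomial
survival thinning. Passing tests therefore demonstrate correctness of
the *computations* under the model's assumptions, not robustness of the
science to measurement artefacts real data would add.

One bookkeeping note: the emulated design (13 pairs × 2 experiments × 2
female ecotypes, one pair failed at equal number, one 22-larva trial)
gives 50 informative trials and 1,345 genotyped larvae by arithmetic;
the published total of 1,342 presumably reflects a few larvae that
failed genotyping, which the generator does not emulate.

## Numerical choices and degenerate inputs

* Binomial log-likelihoods use the stable `log1p(exp(·))` form; the
  `lchoose` constant is dropped inside the sampler (it cancels in every
  Metropolis ratio) but included in the exported log-posterior.
* Random-effect SDs are sampled on the log scale with the Jacobian term.
* R-hat is the classic `sqrt(((n−1)/n·W + B/n)/W)`; zero within-chain
  variance returns NaN with a warning rather than an error.
* Pearson-residual variances are floored at 1e−12 before division.
* Degenerate kinematics inputs (single-point tracks, even or oversized
  smoothing windows, non-increasing frames, non-positive fps) raise
  errors; zero cell counts are valid (zero concentration), a zero
  chamber volume is not.
* Trials with no assignable larvae (failed fertilizations, all-violation
  genotypes) are excluded from tallies, mirroring the exclusion of the
  failed male pair.
* `mcmc_pvalue` tie-break: draws exactly at zero never count as opposing
  the mean.

## Problem sizes used by the test suite

Unit tests run the sampler at 2 chains × a few thousand iterations;
property tests use 10,000 random tracks, full enumeration up to 8 + 8
group sizes, and 20-replicate parameter-recovery loops at the full study
design (50 trials) with 4 × 20,000-iteration chains. These sizes were
chosen so the entire suite exercises study-scale behaviour in a few
minutes on one core; every size is an argument, so heavier runs are one
call away.

## Known limitations

* The sampler is single-site Metropolis: adequate here (a few dozen
  weakly correlated parameters), but it would mix poorly for strongly
  correlated high-dimensional posteriors; no gradient-based alternative
  is provided.
* Δ uses the cell-level covariate convention above; per-trial posterior
  paternity probabilities are available from the draws but are not the
  reported statistic.
* The equal-number design trusts the measured concentrations; pipetting
  error in the mixing volumes is not modelled.
* Only the diagnostic single-locus paternity logic is implemented;
  multi-locus parentage inference is out of scope.
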