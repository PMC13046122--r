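---
title: "Multi-trait drought selection: models, indices and the ideotype distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait drought selection: models, indices and the ideotype distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideoselect)
library(dplyr)
```

`ideoselect` implements the complete analysis chain used to screen crop
accessions for drought tolerance in staged multi-environment trials run under
contrasting water regimes: a well-watered (WW) control and a managed
water-stress (WS) treatment, each repeated over years. The chain has four
stages — mixed-model adjusted means and heritability, yield-based drought
tolerance indices with rank-sum screening, the multi-trait
genotype-ideotype distance index (MGIDI), and association/selection-set
comparison — plus a simulator that generates trials with known ground truth
so that every stage is testable without field data.

## The plot-level model

Each trait in each regime is modelled additively on the plot level:

$$y = \mu + g_i + e_j + (ge)_{ij} + r_{k(j)} + b_{l(kj)} + \varepsilon$$

with genotype, environment (regime crossed with year), genotype-by-environment
interaction, replicate within environment, incomplete block within replicate,
and residual, all random except when genotype is switched to fixed for
adjusted means. Two fits are used:

* **Variance components** (`fit_variance_components()`): all terms random,
  REML via `lme4`, followed by two damped Newton steps on the profiled
  deviance so that on balanced data the solution agrees with the analytical
  expected-mean-squares (Henderson III) estimator — exposed independently as
  `ems_variance_components()` — to better than `1e-6` relative whenever the
  moment solution is interior. Negative components are reported as zero.
* **BLUEs** (`blues()`): genotype fixed, nuisance terms random; generalized
  least squares genotype means per regime across that regime's environments.
  On balanced noise-free data these are exactly the arithmetic genotype
  means.

Broad-sense heritability on an entry-mean basis is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/n_{env} +
\sigma^2_\varepsilon/(n_{env}\,n_{rep})}$$

classified low below 30%, moderate to 60%, high above 60%; the residual CV is
$100\sqrt{\sigma^2_\varepsilon}/\bar{y}$. The combined ANOVA
(`trial_anova()`) uses sequential sums of squares with F denominators from
expected-mean-squares logic: genotype over the interaction mean square,
environment over replicate-within-environment, the rest over the residual.
On unbalanced data the sequential decomposition is order-dependent and a
warning is issued; the package targets (near-)balanced designed trials.

## Drought tolerance indices and rank-sum screening

From per-genotype yield BLUEs under stress ($Y_s$) and irrigation ($Y_p$),
`compute_indices()` returns STI, GMP, MP, HM, TOL, SSI, YSI and YI in their
standard forms (e.g. $STI = Y_sY_p/\bar{y}_p^2$, $GMP = \sqrt{Y_sY_p}$),
together with the stress intensity $SI = 1-\bar{y}_s/\bar{y}_p$. Yield and
productivity indices rank descending (largest = rank 1); TOL and SSI measure
susceptibility and rank ascending. Ties get average ranks. The screening
statistic is $RS = \bar{R} + SDR$, the genotype's mean rank plus the sample
standard deviation (n−1) of its ranks; low RS means consistently tolerant.
Selection keeps `round(g * intensity)` genotypes, half-up rounding, with ties
broken by rank mean then label. The aggregation reproduces, to printed
precision, the published rank table shipped as `soy_rank_matrix()`.

## MGIDI

`mgidi()` chains four steps on a genotype-by-trait table of BLUEs:

1. **Rescaling** to 0–100 toward the desired direction per trait
   (`rescale_traits()`); the ideotype scores 100 everywhere. The map is
   linear and invariant to positive affine transforms of the input.
2. **Factor analysis** of the trait correlation matrix: factors with
   eigenvalue strictly greater than 1 are retained (at least one always),
   initial loadings are eigenvectors scaled by root-eigenvalues, varimax
   rotation is applied, and regression scores $F = Z R^{-1} A$ are computed
   for genotypes and ideotype. The ideotype is standardized with the
   genotype column statistics — it is a reference point, not data. A `1e-8`
   ridge stabilizes $R^{-1}$ for (near-)singular correlation matrices, e.g.
   duplicated traits.
3. **Distance**: $MGIDI_i = \left[\sum_j (F_{ij}-F_j^{ideo})^2\right]^{1/2}$.
   Distances are invariant to the rotation (any orthogonal transform of
   scores and ideotype together), which is why the test suite can check them
   against an unrotated literal transcription of the recipe to `1e-10`.
4. **Selection, gains and contributions**: smallest distances are kept
   (half-up rounding, label tie-break); per-trait selection differentials
   $SD\% = 100(\bar{x}_{sel}-\bar{x})/\bar{x}$ are flagged desirable when
   their sign matches the trait's sense and are additionally reported
   heritability-weighted ($SD\%\times H^2$) when $H^2$ is supplied, since
   "predicted genetic gain" conventions differ between programs; and
   $\omega_{ij} = D^2_{ij}/\sum_j D^2_{ij}$ decomposes each genotype's
   squared distance by factor (small shares = strengths). A genotype at
   distance exactly zero has undefined shares and is reported uniform with a
   flag.

Design choices worth stating: eigenvalue retention is strictly `> 1`
(boundary equality excluded); factor signs are oriented so each factor's
dominant loading is positive (the sign is otherwise arbitrary and only
affects reporting, not distances); varimax follows the method's usual
practice even though retention alone would suffice for the distances.

## Association tools

`correlate()` gives Pearson correlations with two-sided t-based p-values
(g−2 df). `index_biplot()` column-standardizes the genotype-by-index matrix
and takes its SVD; axis variance shares are squared singular values over
their total, and symmetric scaling ($U\sqrt{d}$, $V\sqrt{d}$) gives genotype
and index coordinates. Standardization (rather than centring only) is used
because the indices live on wildly different scales; on such data the cosine
between index vectors approximates their correlation. Polygon
("which-won-where") sector assignment is out of scope — only the SVD layer
is provided. `compare_selections()` enumerates all $2^k-1$ Venn regions of
the selection sets and the consensus.

## The simulator and what it does (not) emulate

`simulate_trials()` draws the additive model above with Gaussian effects.
Genotype and interaction effects are drawn once per genotype (per
environment) and reused across replicates; blocks follow a cyclic
incomplete-block layout (block composition shifts between replicates), which
gives statistical balance rather than an optimal field plan. Bounded traits
(lodging score in 1–5) are truncated after assembly. A genotype's genetic
effects in the two regimes share a latent component with correlation
`genetic_cor`, so stress performance tracks irrigated performance
imperfectly, as in real screens.

`soy_trial_config()` calibrates the generator to a published 150-accession
soybean screen (2 regimes × 2 years, 3 replicates, 10 incomplete blocks,
9 traits): regime means are taken directly from the published trial
summaries (`soy_trait_targets()`), residual variance is backed out of the
published CV, and $\sigma^2_g$ is solved in closed form from the published
$H^2$ with $\sigma^2_{ge} = 0.25\,\sigma^2_g$ — interaction present but
smaller than the genotypic signal, matching the published significance
pattern. Environment, replicate and block variances are set to 5% of the
residual variance each (nuisance structure; the source does not report
them). The default `genetic_cor = 0.5` is a deliberate compromise: the
published $r(Y_s, Y_p) = 0.38$ is unattainable under the published grain
yield heritabilities (the implied genetic correlation would exceed 1), so no
value can reproduce it; 0.5 gives a screen where regimes agree partially, and
the implied BLUE-level correlation is about 0.15.

What the generator does **not** emulate: correlations among different
traits (traits are drawn independently, so the factor structure found on
synthetic data reflects sampling noise around an identity correlation
matrix, not biology); spatial field trend; non-Gaussian residuals; weather.
Consequently, passing tests demonstrate the correctness of the machinery
(estimators recover known components, the distance algebra is exact, the
pipeline is deterministic), not that any particular published factor
composition or gain figure is recovered — those depend on unpublished plot
data.

## Numerical choices and problem sizes

* REML: `lme4` fit plus 2 Newton steps (central differences, step `1e-4`)
  on the profiled deviance; components truncated at zero.
* Ridge `1e-8` on correlation inversion; eigen/SVD from base R.
* Half-up rounding for selection sizes; average ranks for ties; selection
  tie-breaks by statistic then label, so results are fully deterministic.
* The test suite exercises recovery at 300 genotypes × 2 environments × 3
  replicates (single trait) and full-structure pipelines at 30–60 genotypes
  with 3–5 traits; the acceptance script runs the full 150 × 9 × 4-environment
  screen. These sizes were chosen so the whole suite runs comfortably on a
  laptop while keeping the recovery checks statistically meaningful.

## Limitations

* The ANOVA falls back to order-dependent sequential sums of squares on
  unbalanced data rather than a true type-III decomposition.
* Single-environment data cannot separate interaction variance; it is
  reported as zero with a warning.
* The rank-sum and MGIDI methods are selection heuristics: no standard
  errors are attached to RS or MGIDI values, matching field practice.
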