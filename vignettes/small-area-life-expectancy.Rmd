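---
title: "Small-area life expectancy: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area life expectancy: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saele)
```

## The problem

Death counts in small census geographies (a few thousand households each)
are too sparse to support direct life tables: a typical area contributes
100-200 deaths per sex over a pooled three-year period, spread over a
hundred single-year ages. `saele` implements the estimation chain that makes
area-level life expectancy (LE) workable at that scale:

1. **Denominators** — single-year-age populations per area do not exist for
   the analysis period, so they are reconstructed from (a) census
   single-age counts per area and (b) projections by 5-year band at a
   coarser administrative unit, via penalized composite link model (PCLM)
   graduation and proportional allocation.
2. **Rates** — a Bayesian spatial TOPALS Poisson model borrows strength
   across ages (a smooth city standard plus a 6-knot linear-spline offset)
   and across space (neighboring areas have similar offsets).
3. **Life tables** — every retained posterior draw of the rate schedule
   becomes a single-age life table; LE at birth, 20, 40 and 60 is
   summarized by the posterior median and the 2.5th/97.5th percentiles.
4. **Inequities** — percentile gaps across areas, decile scoring of
   socioeconomic variables, the slope index of inequality (SII) fitted once
   per posterior draw and pooled with Rubin's rules, and a composite
   socioeconomic Z-score.

## The mortality model

For area $a$, sex-specific single age $x$, deaths $D_{ax}$ and person-year
exposure $N_{ax}$:

$$D_{ax} \sim \text{Poisson}(N_{ax}\, m_a(x)), \qquad
\log m_a(x) = \log m^{std}(x) + B(x)^\top \alpha_a .$$

$B$ is a linear B-spline ("tent") basis with knots at ages 0, 1, 10, 20, 40
and 70 — the canonical TOPALS layout: one knot per broad mortality regime
(infant, child, young adult, adult, old). Each area is summarized by a
6-vector $\alpha_a$ of log-rate offsets from the city standard; ages past
the last knot carry the last offset unchanged. Strata with zero estimated
exposure are excluded from the likelihood (and any deaths recorded there
are reported and dropped, mirroring how registries report non-linkable
deaths).

The prior is a product of two improper Gaussian kernels:

$$-\frac{\tau_{sp}}{2}\sum_{a \sim a'} \lVert \alpha_a - \alpha_{a'}\rVert^2
  \;-\; \frac{\tau_{sh}}{2}\sum_a \sum_k (\alpha_{a,k+1}-\alpha_{a,k})^2 .$$

The first term is an intrinsic-CAR-style pairwise-difference penalty over
the adjacency graph (spatial smoothing of whole offset vectors); the second
is a first-difference shape penalty within each area's offset vector,
discouraging implausibly jagged deviations from the standard. Defaults are
$\tau_{sp} = 5$ and $\tau_{sh} = 2$ — weak enough that an area with ~300
deaths is dominated by its own likelihood, strong enough that a
zero-exposure area shrinks to its neighbors. Both can instead be given
Gamma(2, 0.5) hyperpriors updated by Gibbs steps (`sample_tau = TRUE`).
These prior settings are this package's own construction, following the
established Bayesian-TOPALS small-area literature; they are deliberately
configurable rather than asserted as canonical. No global intercept is
added beyond the standard schedule, and offsets are not sum-constrained:
every area's likelihood is informative, so the improper penalties' free
level is absorbed.

The sexes are fitted as independent models with sex-specific standards.

### The standard schedule

The city-level schedule is a LOESS (local quadratic) regression of the
empirical log rates $\log((D_x + 0.5)/N_x)$, with two non-default choices:

* the regression runs on the $\log(1+x)$ age scale. Log mortality falls
  near-exponentially through infancy; on the linear age scale a local
  quadratic centred in the 5-12 trough is dragged upward by the infant
  ages in its window (a bias of several tenths of a log unit that no
  amount of data removes). The log-age transform stretches infancy and
  compresses old age, where log mortality is nearly linear anyway.
* observations are precision-weighted by `deaths + 0.5`, the sampling
  variance of an empirical log rate being roughly `1/deaths`.

The default span is 0.3. `age_scale = "linear"` and uniform weights
recover the plain local quadratic, which reproduces exactly any input that
is polynomial in age of degree two or less.

### The sampler

An adaptive blockwise random-walk Metropolis, written in C++: one block per
area (6 components), spherical Gaussian proposals, with each area's scale
adapted toward an acceptance rate of 0.3 by Robbins-Monro on the log scale
during burn-in (batches of 50, step $1/\sqrt{b}$) and frozen afterwards.
This is deliberately a boring, owned sampler rather than a probabilistic
programming back end: the posterior is log-concave per block and mixes well
(per-area acceptance 0.26-0.34 at the default schedule; split-half R-hat
below 1.1 on the toy models in the test suite).

The analysis-scale schedule is 100,000 iterations, 80,000 discarded as
burn-in, thinning by 10 — exactly 2000 retained draws. The package default
is the scaled-down 10,000 / 8,000 / 1 (also 2000 draws), which the
parameter-recovery results below show is adequate for 100-area problems
while keeping a full pipeline run around half a minute on one core.
Chains are reproducible: the C++ core consumes R's RNG stream, so the
`seed` argument fully determines the draws.

## Denominators

PCLM graduation treats band totals $y$ as Poisson with mean $C\mu$,
$\mu = e^\eta$, and penalizes $\lVert \Delta^2 \eta \rVert^2$ — a smooth
latent single-age series whose band sums reproduce the observed bands. Two
implementation choices:

* the penalty weight is `lambda * sum(y)`. Scaling the penalty with the
  total count makes graduation exactly equivariant under uniform scaling
  (graduating $c\,y$ gives $c$ times the graduation of $y$) and makes one
  lambda comparable across units of different size. Lambda is selected on
  a $10^{-2}\ldots10^6$ grid by AIC (deviance + 2 × trace of the hat
  matrix).
* after fitting, single-age counts are rescaled within each band so band
  totals match the projections exactly; the allocation arithmetic
  downstream assumes conserved unit totals.

Census shares then distribute each unit's graduated single-age projection
across its areas, stratum by stratum: the two-stage correction (allocate
the census year, re-derive proportions, allocate the analysis years) is
kept explicit even though the proportions coincide when unit scaling is
uniform. Strata whose census unit total is zero get zero population —
they are excluded from the likelihood rather than imputed, avoiding 0/0
rates at the price of a sub-0.5% leak in end-to-end conservation at the
oldest ages. Fractional populations are retained; denominators feed rates,
not counts. Exposure for a pooled period defaults to the sum of the annual
mid-year populations (a mid-period population × 3 is available via
`method = "midyear"`, since sources differ on this convention); the
open-ended ages default to 103 (women) and 100 (men).

## Life tables

Standard single-age columns with $a_x = 0.5$ for $x \ge 1$ and the infant
separation factor $a_0 = 0.07 + 1.7\,m_0$ capped to $[0.01, 0.5]$ (a flat
$a_0$, e.g. 0.1, can be passed instead). The open interval is closed with
$L_\omega = l_\omega / m_\omega$. Posterior tails can propose rates extreme
enough that $q_x > 1$; such values are clipped to 1 with a warning rather
than rejected, since discarding those draws would bias the posterior
summaries. Against a continuous piecewise-exponential survivorship oracle,
$e_0$ agrees within 0.002 years on realistic schedules (the 0.1-year test
bound is conservative); moving the open age between 100 and 103 moves
$e_0$ by well under 0.2 years whenever $m(100) > 0.3$.

## Inequity statistics

Deciles are formed from sample quantiles with linear interpolation between
order statistics (R type 7), ties going to the lower decile; decile $d$
scores $(d-1)/9$, so an SII regression slope reads directly as the modeled
LE difference between the top and bottom decile. The SII is an unweighted
OLS of per-area LE on the decile score, fitted once per posterior draw and
pooled with Rubin's rules ($\bar U$ within, $B$ between,
$T = \bar U + (1+1/m)B$); the deliberate omission of any spatial term in
this second stage follows the spatial-statistics guidance against spatial
random effects when the estimand is an association. Confidence intervals
use the normal quantile by default (with 2000 draws the Barnard-Rubin
degrees of freedom are effectively infinite; the t-based adjustment is
available behind `df_adjust = TRUE`). Percentile gaps (P90-P10, max-min)
use the same type-7 quantiles. The composite Z-score standardizes each of
the five census variables to mean 0 / SD 1 (denominator $n-1$), negates
unemployment and overcrowding so that higher always means better
conditions, and averages. Decile cut points are computed once on the
pooled area set, since the census variables do not vary by sex.

## The synthetic-city generator

The generator exists so every stage has a ground truth. It emulates:

* 100 areas (a 10×10 rook-adjacency lattice) nested in 15 contiguous
  higher-level units; single ages to 103 (women) / 100 (men);
* sex-specific Gompertz-Makeham + infant-bump standard schedules
  calibrated to $e_0 \approx 81.9$ (women) and 76.7 (men), typical of a
  large, unequal Latin American city;
* a spatially autocorrelated latent socioeconomic field (SAR smoothing,
  $\rho = 0.9$) driving both the true offsets
  ($\alpha_{a} = -0.15\, z_a +$ spatially correlated noise, SD 0.05 —
  higher SES, lower mortality at all ages, a true LE spread of roughly
  7-9 years across areas) and five noisy monotone census variables with
  marginals in realistic ranges (unemployment ~3-6%, overcrowding ~0-3%,
  high-school completion ~50-90%, school attendance ~85-99%, water access
  ~93-100%), with unemployment and overcrowding oriented so higher raw
  values mean worse conditions;
* ~12,000 residents per area (stable-population age structure, growth
  0.01, ±25% lognormal area size), giving on the order of 150 deaths per
  sex per area over the pooled three years;
* deaths drawn Poisson from true rates × true person-years, and grouped
  unit projections derived by exact aggregation of the true populations.

What it does **not** emulate: migration, temporal mortality trends,
cause-of-death structure, census undercount, the geocoding failures of
real registries, or disagreement between census and projections beyond
rounding. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and well calibrated under the model's own
assumptions — not that those assumptions hold in any particular city.

## Problem sizes and observed accuracy

The test suite and the acceptance script run, on one core in well under a
minute each:

* parameter recovery on the default 100-area city with the scaled-down
  MCMC schedule: per-area posterior-median $e_0$ mean absolute error
  ≈ 0.5-0.7 years against ground truth, 95% credible-interval coverage
  ≈ 0.92-0.99, per sex;
* pooled SII coverage of a known slope ≈ 0.99 over 200 replicates
  (Rubin's total variance is mildly conservative in this design, as
  expected);
* PCLM recovery of a known smooth age structure from 5-year bands:
  mean absolute relative error ≈ 0.6%;
* standard-schedule smoothing within 0.1 log units of the true schedule
  at ages 5-90 for a metropolis-scale pooled exposure (5×10⁷
  person-years); at small-city exposures (~2×10⁶) the childhood ages are
  noise-limited to ~0.3-0.4 — which is precisely why the spatial model
  offsets from a smoothed standard instead of using raw rates.

## Known limitations

* Adjacency from GeoJSON polygons matches shared boundary *segments* via
  canonicalized vertex pairs: exact for tilings that reuse vertex chains
  (lattices, clean census geographies), but borders digitized with
  non-matching vertices are not detected. Supply an explicit edge list in
  that case.
* The improper priors' precisions are fixed by default; the Gibbs
  hyperprior option trades a little extra posterior width for robustness
  when the spatial signal is much rougher or smoother than the default
  assumes.
* The PCLM open band is weakly identified when the open interval spans
  several latent ages with near-zero counts; the exact rescaling step
  keeps totals right, but the within-band age shape there is prior-driven.
* Second-stage SII regressions use classical OLS standard errors inside
  Rubin's within-variance; heteroskedasticity-robust errors were left out
  deliberately to keep the estimator definition standard.
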