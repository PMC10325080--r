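---
title: "Continuous-time ASCA for longitudinal multivariate data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time ASCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascatime)
```

## The problem

Frequently sampled intervention studies -- a meal challenge with plasma
drawn eleven times over a morning, say -- produce data that are
simultaneously multivariate (tens of correlated metabolite
concentrations), longitudinal (smooth, non-linear time courses), and
structured by design (each subject measured under every treatment in a
cross-over). Univariate summaries such as areas under the curve discard
the temporal shape and the correlation between outcomes; classical ASCA
with time as a qualitative factor discards the ordering of the time
points. `ascatime` combines the two missing pieces: each response is
modelled over *numeric* time by a linear mixed model with a basis
expansion, and the multivariate structure is recovered by decomposing the
response matrix into design-driven effect matrices, each summarised by
PCA.

## The univariate model

For subject $i$, treatment occasion $h$ and time $t_k$, a response is
modelled as

$$y_{ihk} = (\beta_0 + \gamma_{i0})
  + \sum_m (\beta_m + \gamma_{im})\, f_m(t_k)
  + \sum_m (\beta_{m'} + \gamma_{im'})\, f_m(t_k)\, g_h
  + \varepsilon_{ihk}$$

where $f_1, \dots, f_b$ are the time-basis functions (raw polynomials
$t, t^2, \dots$ or an anchored natural cubic spline), $g_h$ is the
sum-coded treatment contrast ($\pm 1$ for two arms), the random effects
$\gamma_i \sim N_q(0, D)$ have an **unstructured** covariance $D$, and
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$ iid. The fixed design row
is $[1 \mid f(t) \mid f(t)\,g]$; there is deliberately **no treatment
main-effect column**. In a cross-over with a pre-treatment baseline
sample the arms are exchangeable at $t = 0$, so any treatment effect must
enter through the interaction with time; the design encodes this
assumption structurally rather than testing it.

Random effects mirror the fixed structure by default
(`random_structure = "mirror_fixed"`, $q = p$), so heterogeneity is
allowed not only in level but in the *dynamics* -- each subject carries
their own perturbation of every temporal coefficient, and the
off-diagonal elements of $D$ let level and shape covary.

Estimation is by REML through `lme4::lmer`, one response at a time.
Two numerical choices matter:

* **Column rescaling.** Raw polynomial columns on a $0..10$ grid span
  three orders of magnitude ($t^2$ reaches 100), which makes the
  covariance-parameter optimisation badly conditioned. `fit_univariate`
  rescales each design column to unit maximum absolute value, fits, and
  transforms $\hat\beta$, $\hat\gamma$ and $\hat D$ back. Because the
  unstructured-$D$ family is closed under diagonal rescaling of the
  random design, this is an exact reparameterisation, not an
  approximation.
* **Optimizer tolerance.** Reference fits use lme4's default tolerances.
  Bootstrap replicate fits use a relaxed absolute tolerance of `1e-4`
  (`fast = TRUE`) and warm starts from the reference fit's covariance
  parameters: percentile confidence bounds are order statistics over
  replicates and are insensitive to the fifth decimal of a variance
  component, while the ~6-fold speedup keeps 100 replicates x 25
  responses tractable on one CPU.

Fits that do not converge are returned with `converged = FALSE` and a
warning -- never silently dropped; boundary (singular) $\hat D$ estimates
are flagged but kept, since with moderate $I$ an unstructured $5 \times 5$
$D$ frequently touches the boundary without harming the fixed-effect
estimates that drive the downstream decomposition.

## Time bases

Two bases are provided. Raw polynomials (`time_basis("polynomial", d)`)
reproduce the textbook quadratic model and are used throughout the
simulation machinery. For real data, natural cubic splines
(`time_basis("natural_spline", df)`) are preferred: piecewise cubics,
$C^2$ at the knots, constrained to be linear beyond the boundary knots,
so they do not oscillate at the ends the way high-order polynomials do.
Knots default to the range of the observed times (boundary) and
equally spaced quantiles (interior, $df - 1$ of them).

One decision was genuinely open: `splines::ns` basis columns are not zero
at the earliest time, which would leak a spurious treatment contrast into
the baseline rows through the interaction columns. We therefore **anchor**
the spline basis by subtracting its row at $t = \min(t)$ from every row.
This keeps the intercept interpretable as the baseline value and makes
interaction columns vanish exactly at baseline, so the no-difference-at-
baseline constraint holds for splines exactly as it does for polynomials.
Anchoring subtracts a constant per column and changes neither the spanned
model space (with the intercept present) nor the fitted values.

## Effect-matrix decomposition

With $J$ responses, the per-response coefficient vectors are collected
column-wise into $B$ ($p \times J$) and the BLUPs into $\Gamma$
($Iq \times J$), and the $IHK \times J$ response matrix decomposes as

$$Y = M_0^f + M_T^f + M_{TG}^f + M_0^r + M_T^r + M_{TG}^r + E$$

where each effect matrix is the product of one group of design columns
(intercept / time / time-treatment) with the matching coefficient rows,
fixed and random parts separately. The identity holds to machine
precision on observed cells by construction; cells that were missing in
$Y$ receive model predictions in the effect matrices and a missing
residual, keeping every matrix rectangular for PCA.

Each (possibly summed, e.g. $M_T^f + M_{TG}^f$) effect matrix is
column-centered and decomposed by SVD, $M_c = USV'$, with standardized
scores $T = \sqrt{n-1}\,U_A$ and loadings $P = V_A S_A / \sqrt{n-1}$, so
that $TP'$ reproduces the rank-$A$ truncation and every score column has
unit sample variance. Two geometries are supported: *trajectory*
(rows are $(i,h,k)$ cells; fixed-effect scores trace the population
temporal patterns per treatment) and *individual* (the matrix is reshaped
to $I \times HKJ$ first; one score point per subject). The reshape
concatenates, per subject, treatments then times with the $J$ responses
fastest; the convention is arbitrary but fixed and documented, since any
fixed convention merely permutes loading entries.

Numerical conventions worth stating: centering is per analysed matrix
(combined matrices are centered jointly, after summing); the SVD sign
ambiguity is resolved by making the largest-magnitude loading entry of
each component positive; `A` defaults to 3 and is capped at the numerical
rank (a quadratic time term spans rank 2 -- asking for PC3 of $M_T^f$ is
then meaningless and the cap avoids a hard error in routine use); an
identically zero matrix yields an empty result with a warning rather than
undefined explained-variance fractions.

## Bootstrap validation

Approximate 95% confidence intervals for scores and loadings come from a
non-parametric bootstrap. The resampling unit is the **subject**: a drawn
subject carries its complete cross-over series into the replicate, and
duplicated draws are relabelled with fresh ids so the mixed model treats
them as distinct grouping units (without relabelling, a subject drawn
twice would be pooled into a single random-effect level and the replicate
model would be mis-specified). Each replicate is refitted end to end,
its loading matrix is rotated onto the reference loadings by orthogonal
Procrustes analysis ($R$ minimising $\|P_b R - P_\text{ref}\|_F$, closed
form via the SVD of $P_b' P_\text{ref}$), the same rotation is applied to
the scores, and entrywise percentile bounds are taken across aligned
replicates at the 2.5th and 97.5th percentiles.

Percentiles are inverse-ECDF order statistics (R's `type = 1`), so two
replicates give min/max bounds rather than interpolated values. Failed or
non-converged replicates are dropped and counted; more than 50% failures
aborts, since bounds from a minority of convergent replicates would be
misleading. Replicate substreams are derived deterministically from
`(seed, r)`, so any single replicate can be reproduced in isolation.

## The synthetic-data generator

`simulation_spec()` / `simulate_dataset()` generate cross-over datasets
from the same model family the estimator assumes: population polynomial
curves from per-response fixed effects, per-(subject, response) random
effects drawn from a common $D$ with non-zero off-diagonals, one draw per
subject shared across both treatment occasions (the subject is the same
person on both days), plus iid Gaussian noise.
`encode_ground_truth()` returns the noise-free effect matrices computed
from the drawn coefficients through the very same design products used on
the estimation side, so estimator output can be compared with encoded
truth component by component.

`crossover_scenario()` freezes a documented reference scenario: $I = 40$
subjects, $H = 2$ treatments, $K = 11$ times on $0..10$, $J = 25$
responses -- the scale of a typical nutritional cross-over. Its
constants, chosen once:

* baseline level 10 for every response;
* two orthogonal temporal profiles, a slow linear increase $f_1(t) = t$
  and a parabolic excursion $f_2(t) = t(10 - t)$, used for **both** the
  time effect and the time-treatment interaction, with weights varying
  smoothly across the 25 responses (amplitudes up to ~8, ~3, ~2.5 and ~2
  response units respectively) -- effects deliberately *notable*, i.e.
  clearly above the noise, so that recovery failures indicate estimator
  defects rather than an underpowered scenario;
* random-effect standard deviations $(0.8, 0.08, 0.015, 0.05, 0.008)$
  for (intercept, $t$, $t^2$, $tg$, $t^2g$) with exchangeable correlation
  $0.3$, giving subject-level trajectory spreads comparable to the fixed
  effects;
* measurement noise $\sigma_\varepsilon = 0.5$, visible against a
  baseline random-effect SD of 0.8 but not dominant.

What the generator does *not* emulate: skewed or heteroscedastic
measurement error, responses whose true curves lie outside the
polynomial family (delayed or piecewise responses), missingness
mechanisms, and between-response residual correlation beyond what the
shared design induces. A green recovery test therefore establishes that
the pipeline estimates what it models -- it does not establish that the
quadratic model suits any particular real dataset; model adequacy remains
the analyst's responsibility, and per-response model selection is out of
scope by design.

## Preprocessing for real data

Below-detection-limit cells are set to missing (rows are never deleted;
the continuous-time model handles missing cells natively), and each
response is divided by the sample SD (n-1 denominator) of its baseline
observations, pooled across subjects *and* treatment arms -- pooling is
consistent with the baseline-exchangeability assumption built into the
design, though per-arm baseline SDs could differ in an imperfectly
randomised study; this is flagged as a known limitation. After scaling,
every response has baseline SD exactly 1, preventing high-variance
responses from dominating the PCA.

## Known limitations

* $H > 2$ designs are supported structurally ($H - 1$ sum-coded
  contrasts) but exercised far less than the two-arm case.
* Only iid residuals are offered; no AR(1) or heteroscedastic residual
  structures.
* Percentile bootstrap only -- no BCa or studentized variants.
* The relaxed replicate tolerance trades a negligible bias in replicate
  variance components for a large constant-factor speedup; users who want
  full-precision replicates can pass `fast_replicates = FALSE`.
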