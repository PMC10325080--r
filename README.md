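# ascatime

ANOVA simultaneous component analysis (ASCA) for **frequently sampled
longitudinal multivariate data**, built on linear mixed models with
*continuous* time.

## Who this is for

Metabolomics and nutrition researchers analysing designed longitudinal
studies — typically a cross-over meal challenge where `I` subjects are
sampled at `K` time points under each of `H` treatments, with `J`
correlated responses (e.g. lipoprotein subclass concentrations) per
sample. Classic ASCA treats time as a qualitative factor and throws away
the temporal ordering; univariate summaries (AUC, per-metabolite mixed
models) throw away the correlation between responses. `ascatime` keeps
both.

## The model

Each response is fitted by REML (via lme4) with a basis expansion of
numeric time and sum-coded treatment interactions:

```
y_ihk = (b0 + g_i0) + sum_m (b_m + g_im) f_m(t_k)
                    + sum_m (b_m' + g_im') f_m(t_k) g_h + e_ihk
```

with `f` a polynomial or natural-cubic-spline basis, `g_h ∈ {+1, −1}`
the sum-coded treatment, random effects `g_i ~ N_q(0, D)` (unstructured
`D`, mirroring the fixed structure), and iid residuals. There is no
treatment main effect: arms are exchangeable at baseline, so treatment
acts only through its interaction with time.

Collecting coefficients over all `J` responses (`B`: p×J, BLUPs `Γ`:
Iq×J), the response matrix decomposes additively into effect matrices

```
Y = M0f + MTf + MTGf + M0r + MTr + MTGr + E
```

(baseline / time / time-treatment, fixed `f` and random `r` parts). Each
effect matrix — or a sum such as `MTf + MTGf` — is column-centered and
analysed by SVD-PCA with standardized scores `T = sqrt(n−1) U` and
loadings `P = V S / sqrt(n−1)`, either per (treatment, time) cell
("trajectory" plots) or per subject after reshaping to I×HKJ
("individual" plots). Subject-level non-parametric bootstrapping with
orthogonal Procrustes alignment of each replicate's loadings yields
percentile confidence intervals for scores and loadings.

## Worked example

Simulate the package's documented reference scenario (40 subjects, 2
treatments, 11 time points, 25 responses, correlated random effects),
fit, decompose, and summarise the overall treatment-period effect:

```r
library(ascatime)

sim    <- simulate_dataset(crossover_scenario(), seed = 1)
sim$data
#> long_dataset: 880 rows, I=40 subjects x H=2 treatments x K=11 times, J=25 responses

design <- build_design(sim$data, time_basis("polynomial", 2))
#> design_bundle: 880 rows, p=5 fixed, q=5 random (mirror_fixed), basis=polynomial(2)

fit <- fit_all(sim$data, design)
fit
#> multivariate_fit: J=25 responses, p=5, q=5, I=40 subjects
#>   non-converged: 0, singular: 6

dec <- decompose_effects(fit)
res <- analyse_effect(combine_effects(dec, c("MTf", "MTGf")),
                      "trajectory", A = 3, dims = fit$dims,
                      labels = dec$labels)
res
#> sca_result (trajectory): 880 x 25, A=3
#> explained variance: PC1 84.2%, PC2 10.4%, PC3 5.4%

head(res$loadings, 3)
#>             PC1       PC2       PC3
#> met01 -2.759946 1.0790286 1.2194411
#> met02 -2.675491 1.0026392 0.5015609
#> met03 -2.691030 0.8789614 0.1624102
```

Reading the output: PC1 (84% of the combined time + interaction effect)
carries the dominant population-level temporal pattern; each score row is
one (subject, treatment, time) cell, so plotting PC1 scores against time,
one line per treatment (`plot(res)`), shows the population trajectories
and how the two arms diverge. Loadings link each response to the
patterns: responses with large same-sign loadings follow the pattern
together. The six `singular` flags mark responses whose unstructured
random-effect covariance was estimated at the boundary — common at I=40
and harmless for the fixed-effect summaries.

Bootstrap confidence bands (95%, 100 subject-level replicates):

```r
bp <- bootstrap_pipeline(sim$data, time_basis("polynomial", 2),
                         effects = c("MTf", "MTGf"), A = 2,
                         n_boot = 100, seed = 1)
sca_plot_data(bp$reference, bp$ci)   # long table: value, lower, upper
```

For real data, read a concentration table and preprocess first:

```r
ld <- read_long_csv("concentrations.csv",
                    list(subject = "id", treatment = "drink", time = "minutes"))
ld <- drop_below_lod(ld)            # flagged cells -> missing, grid kept
ld <- baseline_sd_scale(ld, 0)      # per-response baseline SD = 1
design <- build_design(ld, time_basis("natural_spline", 2))
```

There is also a config-driven command line
(`Rscript -e 'ascatime::asca_cli()' simulate|fit|validate --config run.json`)
that writes labelled CSVs plus a provenance record; see `?read_run_config`.

## Documentation

The methods vignette (`vignettes/continuous-time-asca.Rmd`) documents the
model and its assumptions, the basis and knot choices, the spline
anchoring that preserves the baseline-equality constraint, the bootstrap
and Procrustes details, what the synthetic-data generator does and does
not emulate, and known limitations.
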