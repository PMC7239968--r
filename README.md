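# pollenflow

Zero-inflated count models for pollen-mediated gene flow between adjacent
*Brassica napus* (pollen donor) and *Brassica rapa* (recipient) plots, and
the isolation distances they imply for regulatory cross-pollination
thresholds.

## Who this is for

Researchers and regulators assessing GM/non-GM coexistence on a small
field scale. The data such studies produce are progeny assays -- hybrid
counts among 384 screened seedlings per sample, taken at fixed distances
(0.35-12.95 m in 0.7-m steps) from the donor plot -- and they are
dominated by excess zeros (most far samples contain no hybrids) and
overdispersion (variance > mean). Ordinary Poisson regression fails on
both counts; this package implements the analysis that works.

## The model

A hybrid count `y` at distance `d` follows a zero-inflated Poisson (ZIP)
or negative-binomial (ZINB) mixture:

```
P(Y = 0) = pi(d) + (1 - pi(d)) g(0)
P(Y = y) = (1 - pi(d)) g(y),          y > 0
```

where `g` is Poisson(`mu`) or NB(`mu`, dispersion `alpha`). The mean
decays with distance through one of eleven named pollen dispersal
kernels `r(d)` (negative-exponential, Gaussian, exponential-power,
power-law, logistic, 2Dt, gamma, WALD, Weibull, log-normal, log-sech):

```
mu(d) = exp(Q r(d)),        pi(d) = 1 / (1 + mu(d))
```

(the shared logit link for `pi`; see the vignette for the two link
orientations). Models are fitted by multi-start maximum likelihood,
compared by RMSE / adjusted R^2 / AIC / BIC on a stratified 70/30
training split and by MSPR on the held-out 30%, and the winning curve is
inverted to find the smallest distance at which the predicted CP rate
`100 (1 - pi) mu / 384` stays below a threshold (3%, 1%, 0.9%), with a
stratified-bootstrap 95th-percentile conservative estimate.

Because the raw per-sample field data of the motivating trial are not
public, the package includes a first-class generator that simulates the
full study design (8 experiments x 2 plots x 19 distances x 10 samples),
calibrated to the published distance -> mean-CP profile (2.78% at 0.35 m
down to 0.028% at 12.95 m) with a ~75% pooled zero fraction.

## Worked example

```r
library(pollenflow)

cfg <- simulation_config(seed = 42)      # the study design, one seed
samples <- simulate_dataset(cfg)         # 3,040 progeny assays

diag <- diagnose_experiments(samples)
head(diag[, c("experiment_id", "observed_zero_fraction",
              "expected_zero_fraction", "deviance_ratio")], 3)
#>   experiment_id observed_zero_fraction expected_zero_fraction deviance_ratio
#> 1        2013-1                  0.729                  0.229           6.31
#> 2        2013-2                  0.734                  0.352           3.72
#> 3        2014-1                  0.747                  0.355           4.02
```

Every experiment shows far more zeros than a Poisson at its mean would
give (0.73 observed vs 0.23 expected) and deviance/d.f. well above 1:
zero inflation and overdispersion, so the ZINB family is appropriate.

```r
fit <- fit_zi_model(samples, family = "ZINB",
                    kernel = "exponential-power", seed = 42)
fit
#> ZINB-exponential-power fit (reconciled link): loglik -3045.0572 on 3040 samples
#>   Q = 2.9209, a = 1.5858, b = 1.1427, alpha = 1.3311
#>   converged: TRUE (|grad| = 9.26e-05, 20 starts)

isolation_table(fit)
#>   threshold                  model point_distance_m
#> 1       3.0 ZINB-exponential-power        0.2963363
#> 2       1.0 ZINB-exponential-power        1.0736903
#> 3       0.9 ZINB-exponential-power        1.1600260
```

Reading the fit: `Q = 2.92` sets the short-distance mean
(`mu(0.35) ≈ 11` hybrids per 384 seeds, a CP rate of ~2.8%),
`a`/`b` shape the exponential-power decay, and `alpha = 1.33` absorbs
the overdispersion. The isolation table says: under the strict 0.9%
labeling threshold the two crops need ~1.2 m of separation; under
Taiwan's 3% threshold, ~0.3 m. `bootstrap_isolation()` adds the
conservative (95th-percentile) counterpart, and `run_pipeline()` runs
the whole workflow -- diagnostics, exclusion filter, the 22-model grid,
selection, observed-vs-predicted table, isolation distances -- as one
seeded, reproducible call (see also the thin CLI wrapper in
`inst/scripts/pollenflow.R`).

## Package layout

| Where | What |
|---|---|
| `R/core_data.R` | sample table, CP-rate arithmetic, plant distance, CSV I/O |
| `R/field_profile.R` | published distance profile, two-site field geometry |
| `R/simulate.R` | design-conformant synthetic datasets (empirical / model mode) |
| `R/diagnostics.R` | excess-zero, overdispersion, wind z-test and ANOVA |
| `R/kernels.R` | the eleven dispersal kernels |
| `R/zi_models.R` | ZIP/ZINB pmfs, likelihood, multi-start ML fitting |
| `R/selection.R` | split, fit/prediction criteria, model ranking |
| `R/isolation.R` | threshold inversion, bootstrap conservative distance |
| `R/pipeline.R` | end-to-end orchestration and report bundle |
| `vignettes/isolation-distances.Rmd` | the methods write-up |
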