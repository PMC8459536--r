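# isomite

Reproductive-isolation barriers versus genetic distance in haplodiploid
spider mite crosses.

In arrhenotokous (haplodiploid) mites, unfertilized eggs develop into
sons and fertilized eggs into daughters, so offspring counts alone
measure where a cross fails: fertilization failure shows up as a
male-biased brood, hybrid inviability as dead diploid offspring, and
hybrid female sterility as dead offspring in backcrosses of F1 hybrid
females. `isomite` turns cross-experiment count tables from a
seven-population Palaearctic design (hawthorn spider mite populations F,
T, I, CIM, CN, K, J) into four barrier indices, regresses each on the
mitochondrial (COI) Kimura 2-parameter distance with overdispersed
logistic models, and inverts the fitted models to the genetic distance
at which each barrier is nearly complete.

For whom: evolutionary biologists analysing crossing experiments in
haplodiploid arthropods, and anyone needing a tested quasibinomial
GLM / barrier-threshold workflow on proportion-type count data.

## The model

Each cross combination contributes `k` "failures" out of `n` trials for
a barrier (e.g. sons out of eggs for the prezygotic stage). Barrier
strength follows a logistic curve in genetic distance `d`:

    logit(p) = β₀ + β₁·d,   Var(k) = φ·n·p(1−p)   (quasibinomial)

fitted by IRLS with the Pearson-based dispersion φ scaling all standard
errors and sequential (type-I) quasi-F tests. A significant
distance-by-population interaction routes the analysis to per-population
fits; otherwise the interaction is dropped (the published decision
rule). The distance at which a barrier reaches completeness `p*` is the
analytic inversion

    d* = (logit(p*) − β₀) / β₁,   p* ∈ {0.99, 0.999}.

The four indices per combination: prezygotic `sons/eggs`, inviability
`(unhatched + dead_juv)/(eggs − sons)`, total `1 − daughters/eggs`
(= prezygotic + (1−prezygotic)·inviability exactly), and backcross
sterility `(unhatched + dead_juv)/eggs`.

## Worked example

Simulate the full study design (42 interpopulation crosses, 7 controls,
16 backcross dam types) at the published barrier parameters, fit the
distance-only inviability model, and invert it:

```r
library(isomite)
library(dplyr)

crosses <- simulate_study(sim_config(seed = 2024))
obs     <- barrier_observations(crosses)
fit     <- gd_only_fit(filter(obs, barrier == "inviability"))
fit
#> Quasibinomial logit fit (1 + gd)
#> # A tibble: 2 × 5
#>   term        estimate std.error statistic  p.value
#>   <chr>          <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)    -1.35    0.0611     -22.0 2.06e-26
#> 2 gd             39.6     1.24        32.0 1.50e-33
#> dispersion 5.867 on 47 residual df; deviance 279.4

invert_threshold(fit)
#> # A tibble: 2 × 3
#>       p gd_star extrapolated
#>   <dbl>   <dbl> <lgl>
#> 1 0.99    0.150 TRUE
#> 2 0.999   0.209 TRUE
```

The simulated data were generated with true coefficients (−1.337,
39.450); the fit recovers them (−1.35, 39.6) and the inverted thresholds
say hybrid female inviability is 99% complete at a K2P distance of about
0.150 and 99.9% complete at about 0.209 — beyond the largest observed
distance (0.075), hence the extrapolation flag. The dispersion of ~5.9
is the overdispersion the beta-binomial generator builds in (mites
sharing a mother are not independent trials).

The same table for all four barriers, from the published coefficient
estimates:

```r
threshold_table(avien_barrier_coefs())
#> # A tibble: 4 × 5
#>   barrier     intercept slope gd_star_99 gd_star_99.9
#>   <chr>           <dbl> <dbl>      <dbl>        <dbl>
#> 1 prezygotic     -1.45   12.7      0.475        0.657
#> 2 inviability    -1.34   39.4      0.15         0.209
#> 3 total          -0.594  35.8      0.145        0.21
#> 4 sterility      -1.31   54.6      0.108        0.151
```

Sterility completes earliest, the prezygotic barrier last. `run_pipeline()`
(or `Rscript inst/scripts/isomite.R run --crosses crosses.csv --outdir out`)
runs the whole chain — distances, indices, model simplification,
thresholds — and writes CSV/JSON/text artifacts.

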