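---
title: "Reproductive barriers versus mitochondrial distance in haplodiploid mite crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproductive barriers versus mitochondrial distance in haplodiploid mite crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomite)
library(dplyr)
```

## The question and the measurement trick

How much mitochondrial divergence does it take before two populations can
no longer produce viable, fertile offspring? In arrhenotokous
(haplodiploid) arthropods such as spider mites this question can be asked
barrier by barrier with nothing more than offspring counts, because the
reproductive system itself reports fertilization: unfertilized (haploid)
eggs develop into sons and fertilized (diploid) eggs into daughters. A
cross that fails at fertilization therefore produces a male-biased brood;
a cross that fails after fertilization kills female-destined offspring
before adulthood.

`isomite` implements this analysis for a seven-population crossing design
(France F, Turkey T, Iran I, Inner Mongolia CIM, Eastern China CN, Korea
K, Japan J; the hawthorn spider mite). Every record is one cross
combination with the counts of eggs, viable sons, viable daughters,
unhatched eggs and dead juveniles, bound by the accounting identity

    eggs = sons + daughters + unhatched + dead_juv

which the reader enforces row by row.

## The four barrier indices

For parental crosses (interpopulation plus intra-population controls):

* **prezygotic** (post-mating fertilization failure): `sons / eggs`;
* **inviability** (hybrid female inviability — mortality among diploid
  offspring): `(unhatched + dead_juv) / (eggs − sons)`; undefined for
  all-male broods and then excluded with a warning rather than imputed,
  the only choice that never fabricates a denominator;
* **total**: `1 − daughters / eggs`. Under the accounting identity this
  equals `prezygotic + (1 − prezygotic) × inviability` exactly, so the
  "total" measure is the exact composition of the two stages. (Male
  mortality is folded into `dead_juv` in the identity even though it is
  negligibly low in practice.)

For backcrosses — F1 hybrid females crossed to a parental-population male
— **sterility** is scored as dead offspring per egg,
`(unhatched + dead_juv) / eggs`, with intra-population controls included
at distance zero. This slightly overestimates sterility by the background
mortality (typically below 5% in controls); we deliberately apply no
correction, matching the original analysis, but
`barrier_observations(correct_background =)` offers one as a clearly
non-standard extension.

Each observation carries the Kimura 2-parameter COI distance between the
two populations crossed; for a backcross, between the hybrid dam's two
parental populations, so control dams sit at distance 0.

## Genetic distances

Distances come either from the packaged published matrix
(`avien_distances()`, range 0–0.075, with the CIM/CN/K triplet sharing a
haplotype) or from an aligned FASTA via `k2p_matrix()`. The K2P distance
is computed from the per-pair site partition: gaps and any non-ACGT
symbol (N and all IUPAC ambiguity codes) are treated as missing and the
site is dropped for that pair only (pairwise deletion, the default of the
standard distance software; ambiguity codes are excluded rather than
fractionally matched — the simplest defensible convention). Among usable
sites, transitions (A↔G, C↔T) give the proportion P and transversions Q,
and

    d = −(1/2) · ln[(1 − 2P − Q) · sqrt(1 − 2Q)]

with an explicit, pair-named saturation error when the correction leaves
its domain. No gamma-rate correction is applied. Outputs are written at 3
decimals (the conventional reporting precision); full precision is kept
internally.

## The overdispersed logistic model

Brood fates of mites sharing a mother are not independent, so
combination-level counts are overdispersed relative to binomial sampling.
Each barrier is therefore modelled as a quasibinomial logistic
regression: `fit_barrier_glm()` maximises the binomial likelihood of `k`
successes in `n` trials per combination by IRLS (logit link), then
estimates the dispersion φ from the Pearson statistic,
φ = X²/df_residual. φ scales the covariance (φ·(XᵀWX)⁻¹), the t values
and the quasi-F tests, but never the coefficients.

Terms are added sequentially (distance, female population, interaction),
and each addition is tested with F = (Δdeviance/Δdf)/φ of the largest
model — the type-I analysis-of-deviance convention, which is the only one
consistent with the reported degrees-of-freedom pattern of the original
study (1 and 47 for distance, then 6 and 41 for population, on 49
combinations). `simplify_barrier_model()` applies the published decision
rule at α = 0.05: a significant interaction routes to separate
distance-only fits per female population; a non-significant one is
dropped and the main-effects model refitted. The sterility model is
distance-only from the start: each hybrid-dam type contributes a single
aggregated observation, so a dam factor is not estimable.

Numerical choices: starting values are the Haldane-corrected empirical
logits `logit((k+0.5)/(n+1))`; convergence is a relative deviance change
below 1e-10 with a 50-iteration cap (non-convergence is flagged, never
silent); rank deficiency is detected by QR and reported with the aliased
column names; |linear predictor| > 30 triggers a separation warning with
the fit still returned. The analysis unit is the aggregated combination
(replicate rows are summed first): coefficients are invariant to the
aggregation, the dispersion estimate is not, and the combination level is
the one the published residual degrees of freedom imply.

## Completeness thresholds

The headline quantity inverts each distance-only fit analytically:

    gd* = (logit(p) − β0) / β1,   p ∈ {0.99, 0.999}

(`invert_threshold()`; no root-finding, so the inversion is exact and the
round-trip `predict(fit, gd*) = p` holds to machine precision). A
non-positive slope is an error — the barrier then never completes. The
`extrapolated` flag marks thresholds beyond the observed distance range;
with the published coefficients the prezygotic thresholds (0.475–0.657)
lie far above the data's maximum of 0.075, and the flag is raised rather
than the estimate suppressed, as in the original analysis. No confidence
intervals are attached to gd* (none were published); a delta-method
interval would be straightforward but is deliberately not part of the
standard output.

```{r thresholds}
threshold_table(avien_barrier_coefs())
```

With the published coefficients, sterility completes earliest
(gd* 0.108–0.151), then inviability (0.150–0.209) and total isolation
(0.145–0.210), with the prezygotic barrier last (0.475–0.657): hybrid
dysfunction evolves well before post-mating fertilization barriers in
this allopatric system.

## What the simulator emulates — and what it does not

`simulate_study()` regenerates the full design: 42 ordered
interpopulation combinations, 7 controls and 16 backcross dam types (the
published list), with 20 replicate pairs per combination (the study used
12–30) and Poisson fecundity of mean 40 eggs per female over the five-day
oviposition window (~8 eggs/day, a realistic tetranychid rate that puts
combination totals in the hundreds of eggs). Per female, eggs stay
unfertilized with probability `logit⁻¹(a_pre + b_pre·gd)` and become
sons; fertilized eggs die with probability `logit⁻¹(a_inv + b_inv·gd)`,
the deaths split 70:30 between "unhatched" and "dead juvenile" — an
arbitrary bookkeeping split with no counterpart in the published
analysis, since only the sum enters any index. Backcross eggs die with
the sterility probability; surviving unfertilized eggs yield sons only
for dams whose parental populations are genetically identical (hybrid
males are otherwise inviable, as observed; `son_viability` tunes this).
Each dam type is crossed to a male of her maternal population — the
original study used several sires per dam type, but the sterility model
only ever sees the dam's parental-population distance, so the sire label
carries no information. Within-female probabilities are beta-distributed
with correlation ρ = 0.1, making counts beta-binomial with variance
inflation 1 + (m−1)ρ ≈ 5 at m ≈ 40 — enough real overdispersion that the
Pearson dispersion estimator has something to estimate.

The default barrier parameters are the published distance-only
coefficients themselves, so the generator's conditions are the study's
own fitted ones. What the generator does *not* reproduce: directional
asymmetries between reciprocal crosses (a real and interpreted feature of
the data), population-specific slopes (unless configured), between-female
heterogeneity beyond the single ρ, and any within-population sequence
variation (one haplotype per population, as in the study). Passing tests
on simulated data therefore demonstrate correctness of the estimators
under the stated mechanism, not that the mechanism captures every feature
of real rearing data; in particular the simulated dispersion is milder
than the residual scatter the published standard errors imply, part of
which stems from exactly those unmodelled asymmetries.

`evolve_k2p_pair()` complements this with a sequence-pair generator under
the K2P substitution process (closed-form transition probabilities at
total divergence t, expected distance (α + 2β)·t), used to validate the
distance estimator against its own generating model.

## Validation problem sizes

The test suite checks, among other things: exact reproduction of the
eight published completeness thresholds from the published coefficients
(±0.001); the total-isolation decomposition identity on 10,000 random
records; coefficient, standard-error, dispersion and sequential-F
agreement with `stats::glm(quasibinomial)`/`anova(test = "F")` to 1e-6
relative on 50 random data sets; recovery of the inviability threshold
(mean over 500 simulated studies of 49 combinations each, against the
generating value 0.1504); size (300 null replicates) and power (100
replicates) of the distance quasi-F test; and unbiasedness of the K2P
estimator at divergence 0.075 over 100 sequence pairs of 100,000 sites.
These sizes keep the full suite to a few minutes on one core while
leaving Monte-Carlo intervals tight enough to be informative.

## Known limitations

* The distance axis is a single mitochondrial locus; thresholds inherit
  every caveat of COI as a divergence proxy, and nothing here corrects
  for phylogenetic non-independence of cross combinations (the original
  analysis deliberately did not either, to keep reciprocal asymmetries
  visible).
* Prezygotic thresholds are extreme extrapolations (flagged, not
  suppressed).
* The quasibinomial dispersion is assumed common across combinations
  within a model; strongly asymmetric reciprocal pairs violate this
  quietly.
* `sequential_f_tests()` is order-dependent by construction; reorder the
  terms if a different marginality logic is wanted.
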