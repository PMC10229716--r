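# riverbaci

Analysis toolkit for multi-river **detritus-supplementation field
experiments** in a Before–After-Control-Impact (BACI) design, written for
stream ecologists and restoration practitioners who manipulate channel
retentiveness (e.g. by staking the stream bed to trap drifting coarse
particulate organic matter) and need the full inferential chain: from
line-intercept retentiveness surveys to community ordination.

The design the package assumes: several rivers, each with one upstream
**reference** site in intact vegetation plus equal numbers of **control**
and **manipulation** sites allocated at random in stratified pairs along
the channel, every site sampled **before** and **after** the
manipulation, invertebrates pooled over 15 Surber samples (0.30 × 0.33 m,
1.485 m² per site).

## What it computes

* **Synthetic experiments** (`simulation_config()`,
  `simulate_experiment()`, `null_dataset()`): negative-binomial taxon
  counts with river/site/seasonal effects, taxon response classes
  (increasers, new colonists, decreasers, lost taxa, non-responders),
  lognormal detritus stocks and gamma line-intercept transects, all
  reproducible from one seed.
* **Retentiveness indices** (`retentiveness_summary()`): Linear Coverage
  Index (m of element per m of transect), per-element Trapping
  Efficiency (m detritus per m element), effective retentiveness
  (TE-weighted LCI), detritus standing stock (g·m⁻²).
* **Repeated-measures BACI ANOVA** (`fit_baci_anova()`): Treatment ×
  River × Time with Site nested in Treatment × River; between-subject
  terms tested over the Between-sites MS, within-subject terms over the
  Residual MS. The planned treatment contrast

  L = (x̄_BC + x̄_BM + x̄_AC) − 3·x̄_AM

  is tested pooled and per river (`apriori_contrast()`,
  `per_river_contrasts()`, with the smallest-|ES| river excluded to keep
  contrasts independent), with effect sizes
  ES = (x̄_AM − Y)/Y × 100, Y = (x̄_BC + x̄_BM + x̄_AC)/3.
  Plus Tukey-HSD letter displays (`one_way_anova_tukey()`) and per-taxon
  responder classification (`classify_responders()`).
* **Bio-equivalence** (`equivalence_test()`): ratio R of
  manipulation-site mean to the reference target, Fieller 90% interval,
  one-tailed test of R ≤ R_l (margin 0.8), and a similarity-ratio test of
  compositional convergence on the reference
  (`composition_equivalence()`).
* **Community analyses**: fourth-root transform, Bray–Curtis (0–100
  scale), repeated-measures **PERMANOVA** with design-appropriate
  permutation (treatment terms by exact re-randomisation of the
  stratified allocation; other terms by reduced-model residual
  permutation), pairwise t-tests by period, seeded best-of-restarts
  **NMDS** with centroid trajectories, and **SIMPER** taxon
  contributions.
* **Pipeline** (`run_full_analysis()`, `write_report()`): everything end
  to end with a reproducibility manifest and CSV outputs.

## Worked example

```r
library(riverbaci)

cfg <- simulation_config(seed = 42, treatment_multiplier = 3)
sim <- simulate_experiment(cfg)

det <- derive_responses(sim$abundance)$detritus
an  <- fit_baci_anova(response_table(det))
an[, c("source", "df", "MS", "F", "P")]
#>                                     source df      MS      F        P
#> 1                                Treatment  1 0.65981 14.672 8.08e-04
#> 2                                    River  5 0.32281  7.178 3.11e-04
#> 3                        Treatment x River  5 0.02383  0.530 7.51e-01
#> 4 Between sites (within Treatment x River) 24 0.04497     NA       NA
#> 5                                     Time  1 1.17042 71.372 1.19e-08
#> 6                         Time x Treatment  1 0.77384 47.189 4.19e-07
#> 7                             Time x River  5 0.00586  0.357 8.73e-01
#> 8                 Time x Treatment x River  5 0.01806  1.101 3.86e-01
#> 9                                 Residual 24 0.01640     NA       NA

apriori_contrast(an)
#>    scope mean_BC mean_BM mean_AC mean_AM estimate   F        P direction
#> 1 pooled    1.51    1.49    1.56    1.95    -1.31 156 5.29e-12  increase
#>      Y effect_size_pct
#> 1 32.1             178
```

The simulated threefold boost in detritus is detected: the Time ×
Treatment interaction (F = 47.2) and the pooled contrast (negative
estimate = increase at manipulation sites, P ≈ 5e-12) are significant,
and manipulation-after stocks sit 178% above the baseline mean Y on the
raw g·m⁻² scale (the response was log10(x+1)-analysed, effect sizes are
back-transformed).

```r
after <- det[det$period == "after", ]
ref   <- tapply(after$value[after$treatment == "reference"],
                after$river[after$treatment == "reference"], mean)
equivalence_test(after$value[after$treatment == "manipulation"],
                 as.numeric(ref))
#>      R ci_low ci_high R_l   decision includes_full_equivalence
#> 1 2.61   1.69    4.47 0.8 equivalent                     FALSE
```

Manipulation sites exceed the reference condition: R = 2.61 with the 90%
Fieller interval entirely above the 0.8 margin (and above 1, so the
sites overshoot rather than merely match the reference).

```r
dm <- bray_curtis_matrix(transform_abundance(abundance_matrix(sim$abundance)))
permanova(dm, sim$design, n_perm = 999, seed = 1)[, c("source", "df",
  "pseudo_F", "P_perm")]
#>                                     source df pseudo_F P_perm
#> 1                                    River  5    3.602  0.001
#> 2                                Treatment  1    6.138  0.001
#> 3                        River x Treatment  5    0.825  0.875
#> 4 Between sites within (River x Treatment) 24       NA     NA
#> 5                                     Time  1   12.212  0.001
#> 6                         Time x Treatment  1   10.712  0.001
#> 7                             Time x River  5    1.140  0.146
#> 8                 Time x River x Treatment  5    0.911  0.605
#> 9                                 Residual 24       NA     NA
```

Community composition shifts at manipulation sites after treatment
(Time × Treatment pseudo-F = 10.7, P(perm) = 0.001 — the smallest value
attainable at 999 permutations).

See `vignettes/riverbaci-methods.Rmd` for the models, their assumptions,
parameter defaults and known limitations.

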