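---
title: "Statistical methods in riverbaci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in riverbaci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverbaci)
```

## The experiment this package analyses

`riverbaci` implements the analysis of a multi-river field experiment in
which channel retentiveness is increased — for example by staking the
stream bed so that drifting coarse particulate organic matter (CPOM) is
trapped — and the responses of benthic detritus, macroinvertebrate
richness, density and community composition are assessed. The design is
Before–After–Control–Impact (BACI): each of six rivers holds one upstream
*reference* site in intact riparian vegetation, plus six treatment sites
(three *control*, three *manipulation*) spaced about 1 km apart through
cleared agricultural land, with treatments allocated at random within
consecutive site pairs so both arms span the channel. Every site is
sampled once before and once after the manipulation; invertebrates are
pooled over 15 Surber samples (0.30 × 0.33 m frame, 1.485 m² per site)
so that sites, not samples, are the replicates.

The treatment effect is the Time × Treatment interaction: manipulation
sites after treatment should depart from all other treatment–period
combinations.

## The synthetic-data generator

Because the package must be testable end-to-end without field data,
`simulation_config()` / `simulate_experiment()` generate complete
experiments with the statistical structure the analysis assumes.

**Count model.** Pooled Surber counts for taxon *t* at site *s* in period
*p* are negative binomial (gamma-mixed Poisson) with log mean

\[
\log \mu_{tsp} = \log b_t + \rho_{tr} + \gamma_s + \delta_{rp}
  + \log(m)\,[\text{manipulation} \wedge \text{after} \wedge t \in \text{responders}] ,
\]

where \(b_t\) is a lognormal per-taxon baseline around
`baseline_abundance`, \(\rho_{tr}\) a taxon-by-river effect (sd
`river_sd`), \(\gamma_s\) a site effect (sd `site_sd`), \(\delta_{rp}\) a
river-by-period (seasonal) effect (sd `period_sd`) and *m* the
`treatment_multiplier`. The negative-binomial `dispersion` is the size
parameter; `Inf` recovers Poisson counts. Pooled counts of benthic
invertebrates are overdispersed in practice, which motivates the
gamma-Poisson choice.

**Responder classes.** Each taxon is pre-assigned to one of five classes
(`responder_fractions`): *increasers* gain the multiplier in
manipulation-after cells, *decreasers* lose it, *new colonists* are
structurally absent at manipulation sites before treatment, *lost* taxa
are structurally absent after, and *non-responders* ignore the treatment.
The structural presence/absence switches make the colonist/lost classes
exactly recoverable by the classifier and are inert at multiplier 1, so a
unit multiplier yields a dataset that is null in distribution for every
treatment term. Default fractions (0.25 / 0.075 / 0.05 / 0.025 / 0.6)
reflect the common observation that roughly a third to a half of common
taxa respond to detritus supplementation, mostly positively.

**Detritus and transects.** Detritus standing stock is lognormal around
`mean_gm2` with the same river/site/period effect structure and the same
multiplier. Reference sites carry a configurable uplift
(`reference_uplift`, default 1.5) on detritus and taxon densities, so
equivalence tests have a meaningful target. Line-intercept surveys
generate, per transect, a gamma-distributed intercepted length for each
of ten retentive-element types (truncated at the transect length,
zero-inflated so patchy elements are absent from some transects) and a
detritus length whose expectation is the intercepted length times that
element type's trapping efficiency; the generating efficiencies are gamma
draws around `te_mean`.

**Defaults.** 6 rivers × (1 reference + 3 + 3) sites × 2 periods, 80
taxa, 8 transects of 8 m per site, baseline abundance 15, dispersion 5,
`river_sd` 0.3, `site_sd` 0.2, `period_sd` 0.15 (natural-log scale),
detritus 30 g m⁻². These are declared modelling choices — values a stream
ecologist would call realistic for agricultural streams — not estimates
from any particular dataset. All randomness flows from one root seed via
named substreams (design, abundance, transects), so identical
configurations reproduce byte-identical tables.

**What the generator does not emulate.** No spatial autocorrelation
between sites (1 km spacing is treated as giving independence), no
hydrological dynamics or detritus transport, no between-taxon abundance
correlations beyond the shared site/period effects, and no
observation-level taxonomic error. Tests that pass on these data
demonstrate the correctness of the statistical machinery under the
model's assumptions, not robustness to every feature of real survey
data.

## Retentiveness indices

The Linear Coverage Index (LCI) of an element type at a site is the mean
over transects of intercepted metres per metre of transect (m/m); the
detritus LCI is computed identically from detritus lengths. Trapping
Efficiency (TE) of an element type is a ratio of sums within each site —
summed detritus length over summed intercepted length, so transects
without the element are harmless — averaged across the sites where the
element occurs. Whether that average runs within rivers (default) or over
all sites is exposed as a `scope` switch, since either pooling is
defensible. Element types intercepted nowhere get `NA` (undefined), never
0, and `effective_retentiveness()` refuses to drop silently an element
that is present but has no TE. Effective retentiveness is
\(\sum_e \mathrm{LCI}_e \times \mathrm{TE}_e\), the expected metres of
detritus retained per metre of transect. Standing stocks divide pooled
dried mass by the pooled Surber area (1.485 m²); the mass-based and
length-based detritus measures are kept as two separate responses.

## The univariate BACI ANOVA

`fit_baci_anova()` fits the three-factor repeated-measures decomposition:
Treatment (fixed, 2 levels) × River (fixed) × Time (before/after), with
Site nested in Treatment × River. On the default design the degrees of
freedom are (1, 5, 5, 24, 1, 1, 5, 5, 24) for Treatment, River, T×R,
Between-sites, Time, Time×T, Time×R, Time×T×R and Residual. The
denominator mapping follows the error strata of the design: the
between-subject terms (Treatment, River, T×R) are tested over the
Between-sites mean square, the within-subject terms (Time and its
interactions) over the Residual (Site × Time) mean square.
`apply_denominator_mapping()` exposes this mapping so F ratios can be
reconstructed from any table of mean squares. Sums of squares are exact
for balanced data and additive to the total corrected SS; unbalanced
inputs are refused rather than approximated.

**Transform rule.** Field practice log-transforms "where necessary".
This is operationalised as log10(x + 1), applied automatically when the
ratio of the largest to the smallest variance among the four
Time × Treatment cells (pooled over rivers and sites, so each variance is
well supported) exceeds 4, with `"none"`/`"log"` overrides.

**The a priori contrast.** The planned treatment contrast is

\[
L = \bar x_{BC} + \bar x_{BM} + \bar x_{AC} - 3\,\bar x_{AM},
\]

tested as a single-df F, \(F = L^2 / (\mathrm{MS}_{res}\,\Sigma c_i^2 /
n_{cell})\), against the Residual df; the sign of *L* carries the
direction (negative = increase at manipulation sites). Effect sizes are
\(ES = (\bar x_{AM} - Y)/Y \times 100\) with
\(Y = (\bar x_{BC} + \bar x_{BM} + \bar x_{AC})/3\); when the analysis
ran on the log scale, cell means are back-transformed first so ES remains
a percentage of raw densities. Per-river contrasts are computed within
the Time × Treatment × River stratum against the pooled Residual MS; to
preserve independence of the contrasts, the river with the smallest |ES|
is excluded (ties broken towards the alphabetically first river, with a
message).

**A calibration caveat.** The contrast is not orthogonal to the Time main
effect (a common seasonal shift enters *L* with weight −2) nor to
site-level random effects (which contribute \(8\sigma^2_{site}/n\) to
var *L* while the Residual-MS error term assumes \(12\sigma^2_e/n\)).
The F test is therefore exact when within-site errors are the only
random component beyond the modelled means, and becomes anticonservative
under strong site heterogeneity or seasonal shifts. The package's
calibration tests accordingly simulate the model-matched null
(`site_sd = 0`, `period_sd = 0`), where the empirical type-I error sits
at the nominal 0.05; users analysing systems with large common seasonal
swings should interpret marginal contrast P values cautiously. This is a
property of the published contrast form, preserved here deliberately.

**Responder classification.** Per river, taxa are filtered to "common"
(total pooled count ≥ 20 and nonzero counts in ≥ 4 site-period cells —
configurable, since any operational definition of "sufficiently abundant"
is a judgement call), analysed on log10(x + 1) counts, and classified
from the per-river contrast: *increased*, *new* (absent at
manipulation-before), *decreased*, *lost* (absent at
manipulation-after), or *no response*. Residual mean squares for all taxa
are computed in one pass through the balanced-design projections.

## Bio-equivalence

Demonstrating that manipulation sites have *attained* reference condition
is a null result under classical testing, so the package uses
bio-equivalence: the ratio \(R\) of the manipulation-site mean to the
reference target is tested one-tailed against a pre-set margin
\(R_l = 0.8\); rejecting \(R \le R_l\) demonstrates equivalence. The
target is the arithmetic mean of the per-river reference values; because
reference sites are unreplicated within rivers, the target's sampling
variance is taken across the six rivers. The confidence interval for
\(R\) is Fieller's interval for a ratio of two independent means (exact
under normality), with \(t\) on \(n_1 + n_2 - 2\) df; the two-sided 90%
interval corresponds to the one-tailed test at α = 0.05, and the interval
also reports whether full equivalence (\(R = 1\)) is covered. When the
reference mean is not significantly positive the interval is unbounded
and the decision is `not_shown`, flagged explicitly. A seeded percentile
bootstrap (`equivalence_bootstrap_ci()`) is built in as a cross-check;
the two agree to within 0.05 on small-sample fixtures.

**Compositional equivalence.** The mean Bray–Curtis similarity of each
manipulation site to its river's reference site (after treatment) is
divided by the mean pairwise similarity among control sites. The
inference method for this ratio is not fixed by any standard, so the
package uses a stratified bootstrap over sites (resampling both
similarity sets, P = proportion of bootstrap ratios ≤ 1) — an
implementation choice, documented as such; rejection means manipulation
sites are significantly more similar to the reference than controls are
to each other.

## Community analyses

Abundances are fourth-root transformed and converted to Bray–Curtis
dissimilarities on the PRIMER-style 0–100 scale (`vegan::vegdist`
internally). Pairs of entirely empty samples have no defined
dissimilarity and are returned `NA` with a warning rather than imputed.

**PERMANOVA.** The same three-factor repeated-measures model partitions
the Gower-centred inner-product matrix; on the default design the df
column is (5, 1, 5, 24, 1, 1, 5, 5, 24) and the pseudo-F denominators
mirror the univariate mapping. On Euclidean distances of a univariate
response, every pseudo-F equals the classical ANOVA F exactly — the
module's primary correctness anchor, asserted to 1e-6 in the tests.
Permutation strategies are chosen per term and reported per source row:

* Terms involving Treatment (Treatment, River×Treatment,
  Time×Treatment, three-way) are tested by **re-randomising the
  treatment allocation**: whole-site blocks (both periods together) are
  permuted among the treatment sites within each river, exactly
  mirroring the design's stratified randomisation. Under the
  no-treatment null this test is exact by the randomisation argument,
  regardless of the distribution of the dissimilarities. (A
  reduced-model residual scheme was evaluated for these terms and showed
  small but detectable miscalibration of the null P distribution at 500
  replicates; the re-randomisation scheme was adopted for its
  exactness. Its trade-off: when a strong Treatment main effect is
  present but the tested interaction is null, it errs conservative.)
* River, Time and Time×River cannot be re-randomised, so they use
  permutation of residuals under the reduced model, with exchangeable
  units from the term's error stratum: whole-site blocks across rivers
  for River; site blocks plus random before/after swaps within sites for
  the within-subject terms (after removing site means, the two residuals
  of a site are exact negatives, so freely permuting site-period samples
  would be badly conservative).

P values are (number of permuted statistics ≥ observed + 1)/(n_perm + 1);
the number of unique sampled permutations is reported. Pairwise
control-vs-manipulation tests within a period report
\(t = \sqrt{\text{pseudo-}F}\) with labels permuted within river strata.

**NMDS.** Two-dimensional non-metric MDS minimising Kruskal's stress-1
via `vegan::monoMDS`, wrapped in a seeded best-of-restarts search
(default 20 starts: one metric-scaling start plus random
configurations; maximum 500 iterations, stress-ratio tolerance 1e-6).
The best solution is centred and rotated to principal axes; a
non-converged best solution is returned with a warning and flag.
`centroid_trajectories()` summarises community change as
before-to-after centroid arrows per river and treatment.

**SIMPER.** For every between-group sample pair, taxon *k* contributes
\(100\,|x_k - y_k| / \sum_j (x_j + y_j)\); contributions are averaged
over pairs so they sum exactly to the average between-group
dissimilarity, with the mean/SD ratio flagging consistent
discriminators. All-zero pairs are skipped with a warning. The
implementation is cross-checked against `vegan::simper` in the tests.

## The pipeline

`run_full_analysis()` chains the stages — validation, retentiveness,
univariate BACI with contrasts and effect sizes for detritus standing
stock, taxon richness (count of taxa with nonzero pooled abundance) and
total density (individuals m⁻²), bio-equivalence (pooled and per river),
and the community analyses — and returns a report bundle whose manifest
records seed, settings and a configuration fingerprint; identical
configurations reproduce identical tables. `write_report()` emits
everything as plain CSV. The spec-level command-line surface maps onto
the exported functions one-to-one (`simulate_experiment`,
`retentiveness_summary`, `fit_baci_anova`, `equivalence_test`,
`permanova`, `nmds`, `simper`, `run_full_analysis`).

## Problem sizes used in the checks

The packaged tests and `scripts/acceptance.R` size their simulations as
follows (package choices balancing Monte-Carlo precision against a quick
default run): 1000 replicates for the contrast's null rejection rate
(with 2 simulated taxa, since the detritus response alone is analysed);
500 replicates at 199 permutations for the PERMANOVA null-uniformity KS
check (20 taxa); 500 replicates for effect-size recovery at multiplier 2
(the central 95% Monte-Carlo interval of the replicate ES distribution is
required to cover +100%); 100 replicates at 40 taxa for responder-class
recovery at multiplier 5; 9999 bootstrap resamples for the
Fieller-vs-bootstrap comparison.

## Known limitations

* The a priori contrast's anticonservativeness under site heterogeneity
  and seasonal shifts, described above.
* Only balanced designs are supported; there is no Type-II/III machinery
  and no REML variance-component estimation.
* Bray–Curtis, two NMDS dimensions and the lower equivalence margin only
  (no upper-margin TOST); no beta-dispersion (PERMDISP) test.
* Fieller's interval assumes approximately normal means; with n = 3
  manipulation sites the bootstrap cross-check is coarse, and both
  should be read as indicative for such small samples.
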