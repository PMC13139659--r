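---
title: "Methods: stability indices, phenology and source-sink partitioning for multi-environment wheat trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability indices, phenology and source-sink partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements,
the choices made where the methodology was genuinely open, and what the
simulation-based tests do and do not establish about real field data.

## The data model

All analyses start from a tidy plot-level table: one row per year, block,
nitrogen level (220 or 176 kg N ha⁻¹), application time (split/combined),
sowing date (early/late), genotype and trait. The experimental layout is a
split–split–split-plot design: nitrogen randomized on main plots within
blocks, application time on split plots, sowing date on split–split plots,
genotype on split–split–split plots, with three blocks as replicates. The
2 × 2 × 2 treatment grid defines eight managements; two years × eight
managements give sixteen "environments" for stability analysis.

Stability indices are computed on block-averaged means, not raw plot
values: both indices are defined on a single value per entity and
environment, and the block average is the natural plot-free estimate of
that value. Missing cells are an error, never imputed — ecovalence's
double-centering silently misbehaves on incomplete tables, so
`env_means()` refuses them and `validate_design()` locates the holes.

## Dual-perspective stability

For an entity × environment matrix $X$ with $n$ environments:

$$P_i = \frac{\sum_j (X_{ij} - M_j)^2}{2n}, \qquad
  W_i = \sum_j (X_{ij} - \bar X_{i\cdot} - \bar X_{\cdot j} + \bar X)^2$$

where $M_j$ is the environment maximum. $P_i$ (superiority) mixes mean
performance and stability: the entity that wins everywhere scores zero.
$W_i$ (ecovalence) is the entity's share of the interaction sum of squares
and is blind to mean level. Reporting both separates "good and dependable"
from "merely consistent".

The *genotype perspective* treats genotypes as entities and year ×
management combinations as environments; the *management perspective*
swaps the roles (entities = managements, environments = year × genotype).
The two matrices are built by the same aggregation with the grouping
exchanged, which keeps the perspectives exactly symmetric.

Rank agreement between traits uses Spearman correlations on the index
values across entities. With eight entities the usual $t$ approximation on
$n-2$ degrees of freedom is coarse, so an exact permutation p-value
(enumeration of all $8! = 40\,320$ rank permutations, cached per $n$) is
offered alongside it; ties fall back to the $t$ form. Ties in stability
ranks themselves receive average ranks, the conventional Spearman
treatment.

## Thermal time, senescence, green canopy duration

Thermal time accumulates $\max(0, (T_{min}+T_{max})/2 - T_{base})$ with
$T_{base} = 0\,^\circ$C. The daily contribution is clipped at zero: with a
zero base temperature, winter days would otherwise subtract degree days,
which the standard growing-degree-day convention does not allow. BBCH
stages scouted on a weekly grid are dated by linear interpolation on the
BBCH-versus-date line, and the thermal sum is interpolated inside the
fractional final day.

Canopy decline after anthesis is summarized by
$GCA(TT) = GCA_{max} / (1 + \exp(k\,(TT - TT_{50})))$, fit by
Levenberg–Marquardt least squares. Initialization: $GCA_{max}$ at the
observed maximum, $TT_{50}$ at the point nearest half-maximum,
$k = 4/\mathrm{range}(TT)$, with $k$ box-constrained to $(0, 1]$ per °Cd —
senescence rates above 1 per °Cd are physiologically meaningless and only
arise when a fit chases noise. A series that rises monotonically is
rejected before fitting. Green canopy duration is
$GCD = TT_{50} - TT_{anthesis}$, using 50% of the *fitted asymptote*
rather than of the first observation: the first scouting visit often
happens after decline has begun, and the asymptote definition makes GCD
invariant to vertical scaling of the series (verified as a test
invariant).

## Source–sink partition

Spike content at maturity decomposes as

$$\text{pool}_{87,\text{spike}} = \text{pool}_{61,\text{spike}}
  + \Delta_{61\text{–}87,\text{straw}} + \Delta_{87\text{–}61,\text{all}}$$

with straw remobilization $\Delta_{61\text{–}87,\text{straw}} =
\max(0, \text{straw}_{61} - \text{straw}_{87})$ — clipped at zero when the
straw gains mass, in which case the straw acted as a sink. The
post-anthesis term is the residual and *may* be negative under measurement
noise; it is flagged rather than clipped, because clipping both terms
would break the identity. The identity holds to one unit in the last place
for every input (asserted over $10^5$ random quartets).

Contribution percentages are means of per-observation fractions, not
ratios of pooled means. Averaging observations is the reading most
consistent with summaries "across years, cultivars and managements", and
it weights every plot equally; with the package's generator defaults the
two conventions differ by well under a percentage point.

## Split–split–split-plot ANOVA

On balanced data the saturated block × treatment linear model gives exact
sequential sums of squares (all terms orthogonal, verified by
row-shuffling invariance). F ratios follow the expected mean squares of
the mixed model with random blocks: each fixed source is tested against
the pooled block-interaction terms of the deepest stratum it touches —
nitrogen against block × nitrogen; application time (and nitrogen ×
application) against the pooled block × application stratum; the sowing
stratum likewise; genotype and every genotype interaction against the
pooled block × genotype terms, which form the residual, since the design
has one observation per plot. This matches the error strata produced by
`aov(… Error(block/nitrogen/application/sowing))`, which the tests use as
an independent oracle. The ANOVA is fit per year; years differ in weather
so a pooled across-year model would need year as a random environment,
which is out of scope.

Compact letter displays use unadjusted LSD comparisons at $\alpha = 0.05$
with the factor's EMS denominator (Bonferroni available): letters at
$P = 0.05$ without a named adjustment are the field's default reporting
convention. Letters come from the insert-and-absorb algorithm, whose
defining property — two levels share a letter iff their pairwise test is
non-significant — is asserted directly in the tests.

## Phenotypic space

`pca_scaled()` centers and unit-scales every trait before
eigen-decomposition, so traits with different units contribute equally.
Eigenvector signs are arbitrary; the package fixes each loading vector so
its largest-magnitude element is positive, making scores reproducible
across platforms. Quadrant labels follow the Cartesian counterclockwise
convention (I = +,+; IV = +,−). Trait–trait slope screening regresses
group-level management means (eight equally weighted points per genotype ×
year with the full design) and flags slopes at $\alpha = 0.05$; equal
weighting is used because the managements are design points, not random
samples of differing precision.

## The simulator and what it does (not) establish

The generator reproduces the reference design — 8 genotypes × 2 years × 8
managements × 3 blocks — with the plot model

$$y = \mu + g_i + b_i e_j + \eta_{ij} + \text{block} + \varepsilon,
  \qquad \eta_{ij} \sim N(0, \sigma^2_{GE,i}).$$

G×E enters in two ways a stability index can see: slope heterogeneity
$b_i$ on the additive environment index (a Finlay–Wilkinson structure)
and genotype-specific interaction noise $\sigma_{GE,i}$. This is the
simplest structure whose ground truth maps onto both indices — $W_i$
responds to $\sigma^2_{GE,i}$ (and to $b_i$ spread), $P_i$ to mean and
slope. Defaults, chosen once for realism at the scale of intensive German
winter wheat production: grand mean 6.95 t ha⁻¹ with year effects
±0.73 t ha⁻¹ (a wet and a dry year), nitrogen ±0.2, sowing ±0.1,
application ±0.05 t ha⁻¹, genotype means within ±0.25 t ha⁻¹ (elite
material of similar yield level), slopes 0.85–1.15, $\sigma_{GE} = 0.15$
t ha⁻¹, block SD 0.1, plot residual SD 0.3 t ha⁻¹ (a ~4% CV, typical of
well-run yield trials). Seven yield-component traits share one latent per
plot plus correlated residuals (correlation applied via the Cholesky
factor of the trait correlation matrix, then per-trait SDs, so zero-noise
configurations stay exact).

Weather is statistical, not meteorological: a seasonal cosine with
Gaussian noise, constructed so `tmax >= tmin` holds by construction. The
default profile accumulates ≈2550 °Cd over an October–July season, placing
the 50%-GCA window in the realistic 2100–2300 °Cd range. Canopy series are
the logistic itself plus observation noise — so the senescence round-trip
test establishes *estimator correctness*, not that real canopies are
logistic. Source–sink draws build the partition identity in by
construction; straw WSC at maturity is the anthesis pool times a lognormal
factor centred above 1 for the stay-green archetype (PS1) and below 1 for
the remobilizing archetype (PS2), with the SD set so the probability of a
PS1 straw-WSC gain equals the configured 0.8.

One root seed drives everything; each stage derives its own stream
(`stage_seed()`), so adding draws in one stage never shifts another, and
fixed-seed runs are byte-identical (hash-asserted on the pipeline
manifest).

What passing tests show: the estimators compute their definitions exactly,
the F tests hold their nominal size under the null (empirical rejection
rates within [0.040, 0.060] over 2000 simulated trials per stratum), and
configured interaction-variance orderings are recovered. What they do not
show: that field data satisfy the generator's assumptions — additive
environment indices, Gaussian noise, logistic senescence, or any
particular trait correlation structure.

## Numerical and test-design notes

- Problem sizes: the type-I calibration uses 2000 simulated 192-plot
  trials; invariance suites use 250–1000 randomized matrices; the
  partition identity is checked on $10^5$ quartets; senescence bias on
  200 seeded fits of 12 points. These sizes keep the full suite under a
  minute while leaving Monte-Carlo margins of several binomial standard
  errors.
- Ecovalence recovery is assessed by ranking genotypes on the mean
  ecovalence across 20 replicate trials (seeds fixed a priori). A single
  trial with 16 environments estimates each $W_i$ with ~14 df, i.e. a
  ~38% coefficient of variation, so adjacent ranks in a 4× spread swap
  often regardless of implementation quality; the replicate mean isolates
  the estimator's consistency from that sampling noise. The per-trial
  behaviour is asserted separately with a correspondingly weaker bound.
- Thermal-time additivity is exact in exact arithmetic; tests assert it
  bitwise on quarter-degree temperature grids (where floating-point sums
  are exact) and at 1e-9 otherwise.
- The partition's fraction denominators are undefined when the maturity
  spike pool is zero; fractions are reported missing rather than forced.

## Limitations

- No imputation or REML machinery for unbalanced trials: the package
  targets designed experiments and says so early (`validate_design()`).
- Only the two implemented stability indices; no AMMI/GGE or
  Finlay–Wilkinson slope index, though the simulator's ground truth would
  support testing them.
- The pipeline's command-line wrapper is intentionally thin; the R
  functions are the interface.
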