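---
title: "Nearest-neighbour spatial adjustment and genomic prediction in semi-field trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nearest-neighbour spatial adjustment and genomic prediction in semi-field trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnagp)
```

# The experimental setting

`nnagp` targets semi-field row experiments: long beds divided into
independent half-bed units, each unit a sequence of single-line rows at
25 cm spacing, with a sub-surface water gradient splitting every row into a
wet and a dry half. Above-ground traits (grain yield in t/ha, protein
content in %, nitrogen removal in kg/ha, thousand-kernel weight in g) are
measured per half-row; root growth is imaged through one minirhizotron tube
per row at a grid of soil depths, repeatedly over the season.

Rows this close are not independent: soil compaction, moisture and other
micro-environmental trends vary smoothly along a bed. The package's central
contribution is a pair of nearest-neighbour adjustments that model this
trend as a random spatial effect with a structured covariance over rows,
inside a full genomic-prediction mixed model.

# Spatial covariance structures

Both structures start from a loading matrix `X` relating every real target
row to the row sites in its neighbourhood — including *virtual rows* that
pad each unit edge so edge rows have complete windows — and define the
correlation structure as the trace-normalised Gram matrix

$$S = \frac{XX'}{\mathrm{tr}(XX')/n},$$

where `n` is the number of target rows. Normalisation makes the mean (here:
every) diagonal equal to 1, so the companion variance parameter is
interpretable as the spatial variance on the trait scale.

* **Indicator window (`build_s_knn`)** — unit loadings on the target row and
  its `k = 5` neighbours per side. Interior correlations have the closed
  form `(2k + 1 − d)/(2k + 1)` for rows `d ≤ 2k` apart and 0 beyond; the
  tests assert this exactly against a brute-force Gram computation.
* **Distance weighting (`build_s_euc`)** — the same 5-per-side
  neighbourhood, with loadings `w = 1 − d_ij/d_max` and `d_max = 2.75` m
  (the span of 11 rows at 25 cm). Relative to the indicator window this
  concentrates correlation on close neighbours: above the indicator values
  for rows 1–4 apart, below them from 5 apart, with the ratio of the two
  falling with distance. A configuration switch (`window_k = NULL`) gives
  the alternative reading in which *every* row within 2.75 m per side
  contributes; it produces a wider, flatter correlation profile and is kept
  for comparison. Note that no Gram-based construction can make the
  euc/knn ratio fall monotonically from distance zero: both diagonals are
  normalised to 1, so the ratio starts at 1 and peaks around two rows
  before declining.

Distances are one-dimensional (along the row axis); beds and units never
share neighbours. The virtual padding width is the largest requirement of
the structures the layout will carry, `max(k, ceil(d_max/spacing))`.
Dropping the virtual columns would deflate the raw Gram diagonal at unit
edges — the tests construct both variants to demonstrate the effect.

# The mixed models

The above-ground model (AM) for one trait is

$$y = Xb + Z_g g + Z_l l + Z_{ng} n_g + Z_{nl} n_l + Z_r r + Z_{tg} t_g +
Z_{tl} t_l + Z_{s1} s_1 + Z_{s2} s_2 + e,$$

with a combined unit-bed-treatment fixed factor and, in order: additive
genomic effects (`G` kernel), non-additive line effects (identity),
genomic and non-genomic neighbour-line effects, row effects,
genomic-by-treatment (block-diagonal `[G 0; 0 G]`) and line-by-treatment
interactions, a spatial effect per treatment, and the residual. Each
observation loads the neighbour terms on the lines sown in its two flanking
rows with coefficient 1 — the factor 2 multiplying the neighbour variances
in the phenotypic-variance formula below follows from exactly this
two-flank loading. The root model (RM) drops the neighbour and interaction
terms (the repeated-records data cannot support them), uses a
bed-camera-time fixed factor (collapsing to bed-time when no camera column
exists), shares row effects across time points, and carries one spatial
variance per time point.

## Genomic relationship matrix

`compute_grm` implements the first VanRaden method,
`G = MM′/2Σp_j(1−p_j)`, centring dosages by twice the *counted*-allele
frequency of the analysed sample. The printed formula's `p_j` is described
as a minor-allele frequency; for the denominator the two conventions agree
exactly, and for centring the counted-allele convention is the standard
one — the choice is documented here rather than guessed. QC applies the
10% missingness cap to SNPs and lines simultaneously (judged on the
original matrix) and then a 3% MAF floor on the retained set; residual
missingness is mean-imputed (`2p_j`). The average diagonal `d(G)` is
reported alongside; for (near-)inbred material it approaches 2.

## AI-REML engine

`reml_fit` maximises the restricted likelihood of
`y = Xb + Σ Z_i u_i + e`, `u_i ~ N(0, K_i σ²_i)`, with dense linear algebra
— at the problem sizes this design produces (≤ ~1500 observations, ≤ ~700
effect levels) sparse methods buy nothing. Each iteration proposes an
average-information update; if the proposal leaves the parameter space or
would lower the likelihood it is step-halved (1, 1/2, 1/4, 1/10 of the AI
direction) and, failing that, replaced by an EM-REML step, which is
monotone by construction. Numerical choices:

* starting values: `var(y)` split equally across components (configurable);
* convergence: largest relative variance change `< 1e-8` or log-likelihood
  change `< 1e-9`; maximum 200 iterations, non-convergence is flagged,
  never silent;
* variance floor `1e-8 × var(y)`: near-zero components are held and
  *reported* at the floor rather than dropped, matching how essentially-zero
  interaction variances are tabulated rather than removed;
* components whose design loads no observation (e.g. the time-2 spatial
  variance when only time-1 data are supplied) are structurally
  unidentified: pinned to the floor and excluded from updates;
* standard errors come from the inverse of the full AI matrix at
  convergence, including floored components (falling back to the free block
  if singular);
* the fixed-effect design uses cell-means coding with dependent columns
  dropped in first-occurrence order;
* a constant response degenerates gracefully: every component lands on the
  floor.

On balanced one-way designs the engine agrees with the closed-form
mean-square estimators to 1e-6, and on unbalanced identity-kernel models
with `lme4::lmer` to the same precision — including the restricted
log-likelihood constant.

## Genetic parameters

The half-row phenotypic variance per context sums the components,

$$\sigma^2_{P_i} = d\,\sigma^2_g + \sigma^2_l + 2d\,\sigma^2_{ng} +
2\sigma^2_{nl} + \sigma^2_r + d\,\sigma^2_{tg} + \sigma^2_{tl} +
\sigma^2_{s_i} + \sigma^2_e,$$

where the scaling `d` is either the GRM average diagonal `d(G)` (the
stated heritability formulas) or 1. Both variants are implemented side by
side because tabulated heritability summaries in this literature are
frequently consistent with the *unscaled* arithmetic — e.g. variance
components 0.23/0.11/…/0.48 for a yield-like trait give
`h̄² = 0.217, H̄² = 0.321` unscaled but `0.33/0.41` scaled against the same
printed `0.22/0.32` — so the unscaled variant is the default and the
`scale_by_avg_diag` flag exposes the formula-faithful one. The genetic
coefficient of variation is `GCV = 100·σ_g/x̄` with no `d(G)` factor in
either variant.

# Cross-validation and prediction quality

Leave-one-line-out CV estimates variance components and fixed effects
*once*, on the full data; each fold only re-solves the mixed-model
equations with the line's records removed and predicts its genomic effect
through the GRM. Corrected phenotypes are `y_c = y − Xb̂` from the
full-data fit. Predictive ability is the correlation between `y_c` and the
line GEBVs, paired at observation level by default (a line-mean option
exists); the maximum potential PA is `√(nh²/(1+(n−1)h²))` with `n` the
average records per line, and accuracy is their ratio. The dispersion
slope `b_w,p = cov(ĝ_w, ĝ_p)/var(ĝ_p)` reads 1 under no inflation.
Standard errors use the ordinary non-parametric bootstrap — records
resampled with replacement at full sample size, 10 000 replicates by
default, deterministic given a seed; a line-block variant is available via
resampling at the report level. Competing models' predictive abilities are
compared with the Hotelling-Williams t-test for dependent correlations
(`n − 3` degrees of freedom), with `n` the number of shared observations.

Note a genetic ceiling worth keeping in mind when reading PA against its
formula maximum: `PA/maxPA` estimates the GEBV accuracy, which is limited
by the relatedness between each left-out line and the remainder of the
population — not by the trait's heritability. Even at `h² ≈ 0.8` a
founder-derived population plateaus well below `maxPA`.

# The synthetic-data generator

`simulate_experiment` generates everything the pipeline consumes, as the
generative mirror of the models above. It emulates: ~70 inbred lines
descended from biparental crosses of 8 founders (giving the GRM the family
structure of breeding material — with *unrelated* lines, `G ≈ d(G)·I` and
the genomic and line variances are nearly unidentifiable); a MAF spectrum
on [0.03, 0.5]; per-SNP full homozygosity with probability 0.86, putting
`d(G)` near 1.86; the 2-bed × 2-unit × 150-row layout with wet/dry
half-rows (1200 records); and minirhizotron tubes in one unit per bed
imaged every 5 cm from 40 to 270 cm at three time points. Generating
variances default to the magnitudes of the tabulated yield (above-ground)
and total-root-length (root) analyses; fixed treatment means default to
the tabulated wet/dry means.

Root images are allocated from the tube × time latent trait by a scaled
Gaussian depth profile whose centre deepens across time points (80/110/140
cm, SD 25/30/35 cm) — chosen so the deep-window fraction grows over the
season; only the summation contract matters, and image lengths sum exactly
to the non-negative part of the latent total. Time-point means (24/34/43
cm) average to the tabulated overall mean; because the latent trait is
Gaussian with a large environmental variance, a few percent of latents are
negative and truncate to empty tubes — a visible but minor departure from
real (right-skewed) root data.

Every draw sits behind a named substream of the master seed, so adding one
model term never shifts the draws of another and identical configurations
are byte-identical. What the generator does *not* emulate: linkage
disequilibrium decay along chromosomes, skewed/heteroscedastic trait
distributions, missing-at-random phenotypes, or mechanistic root growth.
Passing tests on this generator therefore demonstrates correctness of the
estimation machinery under the assumed model, not robustness to real-data
pathologies.

# Data editing

`edit_records` applies the ±3 SD rule per trait in a single pass, with mean
and SD taken from the unedited column — a value outside the post-removal
spread but inside the original one is retained, and a zero SD disables the
rule. Editing defaults to global (not per treatment or time point) with a
`group` option, since the grouping convention is a free choice in this
design. Records of lines without genotypes are dropped. For Gaussian
records the rule removes ~0.27% of values.

# Problem sizes and test design

The test suite exercises the full study scale where the property demands
it: parameter recovery runs 20 seeded replicates of the complete
nine-component above-ground model at 1200 records × 70 lines, requiring
every non-zero generating variance inside 3 AI standard errors in ≥ 90% of
replicates and the zero-generated interaction/neighbour variances at the
floor. Cross-validation properties (null band at zero heritability,
monotonicity of PA in h², dispersion in [0.8, 1.2]) use 40-line or
full-scale configurations as each check requires. Worked-example checks
recompute genetic parameters from the shipped reference tables by plain
arithmetic.

# Known limitations

* One-dimensional spatial modelling only; no row × column structures,
  autoregressive products or splines.
* Single-trait models; no genetic-correlation (multi-trait) machinery.
* Dense algebra bounds practical problem sizes at a few thousand records.
* Heterogeneous residual variances are not supported; heterogeneity enters
  only through the per-treatment / per-time spatial variances.
* REML convergence tolerances differ from those of external AI-REML
  programs, so last-digit variance-component differences against other
  software are expected.
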