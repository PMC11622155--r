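---
title: "Methods: genotype-environment association scans and climate-adjusted provenancing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-environment association scans and climate-adjusted provenancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`seagrassGEA` takes reduced-representation SNP genotypes of estuarine
seagrass meadows from raw calls to a climate-projection donor registry.
This vignette records the models behind each stage, the parameters that
matter, the numerical choices that were genuinely open, and what the
synthetic-data validation does and does not demonstrate.

## Data model

Genotypes are biallelic SNP calls coded 0/1/2 against a designated
reference allele, with `NA` the single missing sentinel everywhere in
memory (`"NA"` in CSV, `./.` in VCF). Individuals carry a site (meadow)
label and optional technical-replicate / clone links; loci carry a
DArT-style id (`<cloneid>-<pos>-<ref>/<alt>`), a call rate that is always
recomputed from the matrix, an assay reproducibility in [0, 1] and a mean
read depth. Environmental data are site-by-variable summary tables; the
shipped 13-meadow NSW table (average and maximum summer temperature,
temperature range in °C; pH range and minimum pH in pH units; average and
maximum salinity in PSU; turbidity range and minimum turbidity in NTU) is
the canonical instance and the default gradient set in examples and
tests. Because one meadow was sampled per estuary, environmental
variables vary at the site level only; individual-level analyses expand
each individual to its site's values.

## Synthetic data: what it emulates

The generator draws deme allele frequencies with the Balding–Nichols
parameterisation `p_i ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` around ancestral
frequencies drawn Uniform(0.05, 0.95) — wide enough that MAF filters have
real work to do — and genotypes as independent `Binomial(2, p_i)` draws.
A single `fst` knob therefore controls differentiation; the test suite
verifies recovery against an independently coded Weir–Cockerham
variance-components estimator (±0.02 at 5000 loci). Defaults mirror the
survey design this package targets: 13 demes of 26 individuals, 3000
loci, F_ST = 0.10, ~20% missing data, six technical-replicate pairs with
a 0.2% per-call error rate.

Environmental effects are planted by shifting deme frequencies on the
logit scale, `p' = plogis(qlogis(p) + beta * z(env))`, with the covariate
standardised by its population SD (so two demes at ±e map to z = ±1
exactly, keeping the closed-form examples exact). Every locus column is
drawn from its own seed derived from the generator seed, which makes
planting with `beta = 0` reproduce the original matrix bit for bit — a
cheap but sharp regression test.

What the generator does *not* emulate: linkage (loci are independent),
somatic variation within clones (clonal copies are exact), read-level
sequencing error models (depth and reproducibility are drawn, not
simulated from reads), isolation-by-distance (demes are exchangeable),
and temporal environmental variability (a site is one number per
variable). Passing tests therefore demonstrate that the algorithms
recover planted structure under an idealised generative model, not that
real data meet that model.

## SNP quality control

Technical-replicate error is the bitwise distance: differing genotype
calls over jointly non-missing loci, flagged above 0.9%. Genotype-state
counting is the default; "proportion of allelic differences" is
ambiguous between state and allele counting, so a `per_allele` switch
(heterozygote-vs-homozygote = half a difference) is provided.

Filters run sequentially — locus call rate ≥ 0.67, individual call rate
≥ 0.25, locus call rate re-applied over the retained individuals,
reproducibility ≥ 0.99, mean depth in [2, 50], MAF ≥ 0.01 computed over
non-missing calls of the retained individuals — because only sentence
order documents the original pipeline and the filtering toolkits in this
field do not enforce one. Whether call rates were originally recomputed
between steps is unknowable; recomputing is the self-consistent reading
and is what the report records (one row per step, counts non-increasing,
an explicit error naming the first step that would empty the matrix).
Clonal resamples are *kept* for outlier scans: in largely clonal
organisms somatic variation carries much of the standing adaptive
variation, so a clone-dedup utility exists but is off by default.

Nearest-neighbour imputation replaces each missing call with the call of
the bitwise-nearest individual that has one, falling through to the
next-nearest; ties break on the lower individual index, the search is
global rather than within-meadow (nothing in the workflow restricts it),
and non-missing calls are never altered.

## Environmental compilation

Raw series are restricted to the warm season (October–April) and to
daylight, defined as 06:00–18:00 local clock time — the sources behind
such compilations sample in daylight but publish no cutoff, so the window
is a configurable convention. Daily averages feed mean/min/max/range;
per-year rates are the slopes of Gaussian identity-link fits of monthly
means on time in years. Collinearity pruning computes all pairwise
Pearson correlations over sites (the |r| > 0.7 rule of thumb is
Pearson-based) and greedily resolves the strongest offending pair by
dropping the member with the larger mean absolute correlation to the
remaining variables — deterministic, with lexicographic tie-breaks.
Variance inflation factors use the textbook `1/(1-R²)` regression
definition with the conventional threshold of 10 (none is stated in this
literature's sources); a single surviving variable is returned unchanged
since its VIF is undefined.

## Ancestry and the number of populations

The ancestry model factorises `G/2 ≈ QF` with `Q` rows on the probability
simplex and `F` in [0, 1], fitted by alternating least squares: `F` by a
ridge-penalised solve (`alpha`, default 10 — the regularisation regime of
the established sparse-NMF tools), `Q` by simplex-constrained row-wise
least squares. The `Q` step warm-starts from the projected unconstrained
solution and then applies three projected-gradient iterations with step
`1/L` (L the largest eigenvalue of `FF'`); projection alone is not the
constrained optimum and fails outright on degenerate loci (a deme fixed
for the reference allele makes the unconstrained solution collapse to the
origin, which projects to the uninformative simplex centre). Convergence
is declared at a relative loss change below 1e-6 or 200 iterations.

Model choice holds out a random 5% of observed entries; held-out calls
are scored by the binomial cross-entropy `-log dbinom(g, 2, (QF))` with
frequencies clipped to [1e-6, 1-1e-6]. Held-out and missing entries are
soft-imputed from the current fit during the ALS, so they never
constrain it. `choose_K` runs repeated seeded fits per K and picks the K
with the lowest minimum cross-entropy (the median is available as an
option); with one repetition and a fixed seed the choice is exactly
reproducible. PCA uses the binomial scaling `(g - 2p)/sqrt(2p(1-p))`
with monomorphic loci excluded.

## The three genome scans

**RDA.** The constrained ordination of centred genotypes on standardised
predictors is delegated to `vegan::rda`; the tests verify its per-locus
constrained-axis loadings against an explicit projection-plus-SVD oracle
to 1e-8. Outliers are loci whose loading on any constrained axis lies
beyond mean ± 2.5 SD of that axis's loadings (a two-tailed normal
p ≈ 0.0005); the rule is applied per axis and unioned, with a
`pool_axes` flag for the pooled-distribution alternative since either
reading is defensible. Overall model significance comes from
permutations of the environmental rows (pseudo-F), per-axis tests
optionally by sequential permutation. Each outlier locus is attributed
to the predictor it correlates with most strongly, giving
per-variable outlier counts. A per-axis genomic inflation factor
(median squared standardised loading over the χ²₁ median) is reported
as calibration metadata.

**PC-Mahalanobis.** Per locus, the binomially scaled genotype is
regressed on the top-K principal component scores; the K-vector of
z-scores gets a robust Mahalanobis distance (MASS `cov.rob`, MCD), which
is divided by the genomic inflation factor (median distance / χ²_K
median) and converted to χ²_K p-values. K = 5 is the default for data
of this structure. The Methods-style Bonferroni mode (adjusted p < 0.05)
and the Results-style q-value mode are both implemented; the default is
the q-value mode at 0.1, which matches how such candidate sets are
reported downstream.

**Latent-factor ridge.** Per environmental variable: latent factors are
the top-K left singular vectors of the genotype matrix after the
variable is regressed out; per-locus effects come from least squares of
genotypes on [variable, factors] with a ridge penalty on the factor
block (scale 1e-4 of the mean design cross-product diagonal — never
stated in the source literature, so exposed as a parameter); z-scores
are calibrated by the genomic inflation factor. K = 8 by default, fed
from `choose_K`. The outlier rule is a *conjunction* — BH-adjusted
p < 0.05 **and** raw p < 0.001 — because both thresholds are part of the
documented workflow and the conjunction is the only reading that uses
both; each arm can be switched off. With K = 0 the estimator reduces
exactly to per-locus OLS, which the tests verify to 1e-8. The scan is
run per variable (per-variable outlier counts are the reported shape);
a locus counts once toward the method-level set no matter how many
variables flag it.

**Consensus.** Loci flagged by ≥ 2 of the 3 methods. Monotone in the
threshold; with `min_methods = 1` it is the union.

## Allelic turnover

Each candidate locus gets a regression random forest (default 500 trees,
bootstrap rows, `mtry = ceiling(p/3)` predictors per split, minimum leaf
5, variance-reduction splitting) implemented in C++ because the
construction needs every split's impurity reduction, which the
off-the-shelf forest packages do not expose. Out-of-bag R² decides
contribution: only loci with R² > 0 enter the model, each contributing
total importance R². That total is partitioned across predictors by the
forest's out-of-bag permutation importance (clipped at zero; in-bag
split gains partition it only when permutation importance is degenerate)
— impurity gains alone give every predictor a chance-share floor of
roughly 1/p, whereas permutation importance of an uninformative
predictor is centred on zero, which is what makes a permuted gradient's
importance collapse. Within a predictor, the partitioned mass is
distributed along the threshold axis proportionally to split gains,
standardised by the density of observed split opportunities (200
equal-width bins over the predictor's observed range; the published
construction standardises equivalently but does not fix a bin count) and
rescaled so the standardisation redistributes without creating or
destroying mass. Cumulative curves are right-continuous non-decreasing
step functions whose endpoint equals the predictor's total aggregated
importance to 1e-9.

Responses are individual-level genotypes by default, with a site-level
allele-frequency mode (`response = "frequency"`). The choice matters for
one property: permuting a predictor's site values destroys its
importance at the site scale, but at the individual scale any injective
relabelling of 13 site values still identifies the sites, so deep trees
can recover site means regardless of ordering. The permutation-collapse
property is therefore a site-level statement, and the test suite asserts
it in frequency mode with shallow trees (min leaf 2 on 13 rows).

## Zygosity mapping and the donor registry

Zygosity profiles are per-meadow × locus proportions of 0/1/2 calls over
non-missing calls (cells with no calls are flagged, not fabricated);
"reference" is a labelling convention, not an ancestral-state inference.
Ordering along a gradient sorts meadows by the variable's value with
stable alphabetical tie-breaks.

The registry projects `current + rate × (target - base)` — defaults
+0.2 °C yr⁻¹ from base year 2024 for average and maximum summer
temperature over horizons 2030/2040/2050; both are parameters, never
constants, and no projections are made for turbidity or pH range.
Display rounding is half-up to 2 decimals; matching uses unrounded
values with a 0.005 tolerance so values that agree at printed precision
satisfy `≥`. The default matching rule, `min_above`, returns the meadow
with the *smallest* current value that still meets the projection
(alphabetical tie-break, self-matching disallowed) — the reading that
reproduces the large majority of published donor grids of this form; a
`nearest` rule is provided because a minority of published cells are
only explicable as nearest matches. `compare_registry` classifies every
cell against a reference grid as agreeing, valid-but-not-minimal, or
violating the `≥` rule outright — published grids do contain cells no
rule choice can reproduce, and the comparison surfaces them rather than
silently matching.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` choose sizes that make the
statistical properties measurable while keeping a full run in minutes on
one core: null calibration on a panmictic 299-individual × 5000-locus
panel; planted-effect recovery on 13 demes × 26 individuals × 2000 loci
with 40 planted loci at `beta = 2` (the package's study conditions, with
the locus count below the generator default to afford multiple seeds);
cross-entropy K-recovery on 3 demes × 50 × 800 loci with 10 repetitions
per K over K = 1..6; turnover forests at the default 500 trees. The
empirical false-discovery rate of the latent-factor scan under the
global null is estimated as the mean of V/max(R, 1) over replicate ×
variable families, the quantity the BH procedure controls; a
single-family V/R is 0/1-valued and not a rate.

## Known limitations

* The ancestry factorisation is a least-squares surrogate with the
  masked-binomial cross-entropy, not a reimplementation of any specific
  published solver; its role here is K selection and feeding K to the
  latent-factor scan, and its K-recovery is validated by simulation.
* Scan p-values rely on genomic-inflation calibration, which corrects
  the median, not the tails; with strong unmodelled structure the
  extreme tail remains approximate (this is a property of the method
  family, not of this implementation).
* Turnover curves interpolate nothing between observed split
  thresholds and say nothing outside the observed predictor range; no
  geographic extrapolation ("genomic offset") is attempted.
* Registry projections are deliberately naive constant-rate
  extrapolations with no confounding or mitigating factors; they are a
  planning heuristic, not a climate model.
* Published environmental summaries are point estimates at single
  monitoring locations; the pipeline treats them as exact.
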