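---
title: "Methods: models, defaults and design choices in altifun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in altifun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`altifun` implements the analysis chain of an altitudinal-gradient study of
rhizosphere soil microbiomes and soil multifunctionality: diversity and
ordination, signed co-occurrence networks, null-model partitioning of
community assembly, ecosystem function and multifunctionality indices,
enzyme stoichiometry vectors, and the group-comparison / ordination / path
models that tie them together. This vignette records the models, the
defaults and why they were chosen, and what the synthetic-data module does
and does not emulate.

## Data model and validation

The central container is the `otu_table`: a non-negative integer count
matrix (taxa x samples) with a ranked taxonomy and per-sample metadata
carrying a free-string group label. Readers validate and refuse rather than
repair: duplicated ids, negative or non-integer counts, and samples missing
from the metadata are errors with distinct condition classes
(`altifun_format_error`, `altifun_metadata_error`, ...). Group labels are
arbitrary strings; the HB1–HB4 altitude naming is a convention of the study
design, not hard-coded, so the same machinery serves other gradients. The
OTU table is treated as given input: clustering identity, denoising and
rarefaction are upstream decisions the package deliberately does not make.

All stochastic operations take an explicit seed; pipeline stages derive
theirs from the run seed with `substream(seed, tag)`, a small
multiplicative hash. Two runs with the same inputs and config are therefore
bit-identical, which the test suite asserts end-to-end.

## Diversity

Alpha diversity uses the bias-corrected Chao1,
`S_obs + F1(F1-1) / (2(F2+1))`, so tables without doubletons stay finite,
and ACE with the conventional rare-abundance cutoff of 10 (the source
studies rarely state the cutoff; 10 is the de facto standard). Both come
from vegan's estimators and need integer counts; Shannon (natural log) and
Simpson (`1 - Σ p²`) remain available for non-integer abundances. Beta
diversity is Bray–Curtis. Ordination is PCoA (classical metric scaling):
negative eigenvalues are retained in the report but excluded from
coordinates, and proportions explained are taken over the positive
eigenvalues only. Gradient studies sometimes label a Bray–Curtis ordination
"PCA"; on a distance matrix only PCoA is defined, and that is what is
implemented.

ANOSIM follows Clarke: midranks of all pairwise distances,
`R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`, and
`p = (1 + #{R_perm >= R_obs}) / (1 + n_permutations)` under label
permutation. The `n(n-1)/4` denominator is what bounds R in [-1, 1] and
makes perfectly separated groups reach exactly R = 1. The permutation loop
is vectorized enough that the test suite calibrates the test's type-I error
over 1000 null datasets (4 x 3 design, 199 permutations each) in seconds;
rejection at alpha = 0.05 must land in [0.03, 0.07].

## Co-occurrence networks

Construction details are rarely printed in field studies, so they are
explicit parameters here with the dominant soil-literature convention as
default: Spearman correlation on relative abundances at the genus rank,
|rho| >= 0.6, Benjamini–Hochberg adjusted p <= 0.05, taxa present in at
least one third of samples, at least 4 samples. Edge sign is the sign of
rho; edge weight is |rho|. Isolated nodes are dropped; the pre-filter taxon
count is kept for reporting.

The topology report contains closed-form descriptors — average degree
`2L/N`, density `2L/(N(N-1))`, weighted degree `2 Σw / N`, signed-edge
percentages summing to exactly 100 — plus modularity, computed as the best
of 10 seeded Louvain restarts on the absolute-correlation weights (signs are
ignored for community detection, matching the default behavior of the usual
visualization tools). The best-of-restarts value is deterministic under a
fixed seed, and on small graphs it is verified in tests against exhaustive
search over all node partitions. Published topology tables sometimes
conflate weighted and unweighted degree; the report always carries both.

## Community assembly

The five-process partition uses the standard two-step null-model framework,
the only published scheme matching the heterogeneous/homogeneous selection,
dispersal limitation, homogenizing dispersal and drift vocabulary.

βMNTD between samples i and j is the abundance-weighted mean, over each
sample's taxa, of the phylogenetic distance to the nearest taxon present in
the other sample, averaged over both directions (a shared taxon contributes
zero). The unweighted variant pools both samples' nearest-taxon distances
into one mean, matching picante's convention, against which the
implementation is tested exactly. βNTI standardizes observed βMNTD against
`n_nulls` draws in which taxon labels are shuffled across the tree tips.
Pairs whose null distribution has zero variance (e.g. star phylogenies, or
identical presence sets) are flagged NA, excluded from fractions, and
warned about. Because observation and null scale together, βNTI is
invariant to rescaling all branch lengths — asserted on a 16-tip tree.

Raup–Crick nulls preserve each sample's richness and total abundance: taxa
are drawn without replacement with probability proportional to occurrence
frequency, seeded with one individual, and remaining reads assigned
multinomially by regional relative abundance. RC is the doubled, centered
null quantile of Bray–Curtis, in [-1, 1] by construction.

Classification: βNTI > 2 heterogeneous selection; < -2 homogeneous
selection; otherwise RC > 0.95 dispersal limitation, RC < -0.95
homogenizing dispersal, else "drift and others" (the residual category). A
group is deterministic-dominated when its two selection fractions sum above
0.5. Defaults `n_nulls = 999`, cutoffs 2 and 0.95 — all configurable.

Caveat: fungal (ITS) phylogenies are unreliable, and studies differ on
whether a fungal tree should feed βNTI at all. The package requires a tree
for the phylogenetic step; without one the pipeline marks the assembly
stage as skipped rather than substituting a taxonomic surrogate.

## Multifunctionality and enzyme stoichiometry

Indicators are min–max standardized per indicator across plots,
`f = (x - min)/(max - min)`; a constant indicator is set to 0.5 with a
warning rather than dropped, keeping panel dimensions stable. The default
17-indicator panel groups into EF-C (soil/stem/leaf total C, sucrase), EF-N
(soil/stem/leaf total N, urease), EF-P (soil/stem/leaf total P, alkaline +
acid phosphatase) and EF-Prod (plant height, stem biomass, leaf biomass,
crown width); the map is fully configurable, and EMF is the plain mean of
all standardized indicators (the averaging approach; threshold-based
variants are out of scope). EF and EMF inherit min–max invariance to
positive affine transforms of any indicator, and EMF equals the
`n_g/N`-weighted mean of the group indices — both properties are asserted
over 1000 random panels.

Enzyme vectors use x = C:P and y = C:N activity ratios (C = sucrase,
N = urease, P = alkaline + acid phosphatase): `VL = sqrt(x² + y²)`, and
`VA = degrees(atan2(y, x))`. The defining formula is written
spreadsheet-style, whose ATAN2 takes (x, y) — the opposite argument order
from most math libraries. The package defaults to the spreadsheet reading
and exposes `convention = "math"` and `"both"`; the two angles are
complementary (sum to 90°), and the 45° nitrogen/phosphorus boundary is the
same under either. At exactly 45° the plot is labeled "balanced". Ratios
default to raw activities; log-transform, if wanted, is the caller's
preprocessing.

## Group inference, RDA, PLS-PM

`anova_lsd` is one-way ANOVA plus Fisher's LSD with the pooled mean squared
error, df = N - k, and a compact letter display built by greedy insertion
over groups sorted by decreasing mean (maximal mutually non-significant
runs, contained runs absorbed). The letter-sharing relation is tested
against the pairwise p matrix, and the ANOVA's type-I error is calibrated
like ANOSIM's. All-zero within-group variance raises a degenerate-input
error instead of an infinite F.

RDA Hellinger-transforms the community matrix by default (standard for
abundance data; disable with `hellinger = FALSE`) and checks the
explanatory matrix for collinearity explicitly, naming the aliased columns,
before delegating to vegan.

PLS-PM is implemented in-package: mode-A outer estimation, centroid inner
scheme, outer weights iterated to `tol = 1e-6` (max 300 iterations,
non-convergence is an error carrying the last weight change), scores
standardized, path coefficients by per-block least squares, GoF =
sqrt(mean communality x mean R²), and seeded bootstrap resampling for
two-sided normal-approximation path p-values. Latent score signs are
anchored to each block's first manifest, which makes estimates invariant to
row order and reproducible. Every block must be connected in the inner
model; a disconnected block has no defined inner estimate and raises a
usage error. The default block layout mirrors the altitude cascade:
altitude and pH as single indicators, bacterial and fungal community
structure as two ordination axes each (the usual choice when a study does
not state its manifest variables — this is exposed as configuration), EF-C,
EF-N, EF-P and EMF as single indicators.

## The synthetic-data module

Generators are pure functions of (parameters, seed) and default to the
supported study design: 4 altitude groups x 5 replicate plots, 300 taxa,
sequencing depth 10,000 — small enough that 999-draw nulls run on a laptop
in minutes, large enough that presence/absence structure exists for the
phylogenetic nulls.

* **Phylogeny**: pure-birth (Yule) trees, ultrametric with positive branch
  lengths.
* **Selection regimes**: a Brownian-motion trait on the tree (so niche
  conservatism — the assumption βNTI needs for power — holds by
  construction) filtered by Gaussian fitness
  `exp(-(trait - env)² / (2 σ²))` with niche width σ = 0.3 trait SD;
  heterogeneous selection spreads sample environments over the 5%–95% trait
  quantiles, homogeneous selection uses the common median.
* **Drift**: neutral multinomial resampling from a shared lognormal
  (sdlog = 2) metacommunity. The heavy lognormal tail is what creates
  per-sample absences; with a near-uniform pool every taxon occurs in every
  sample and βNTI's null degenerates (the package flags this rather than
  hiding it).
* **Dispersal limitation**: disjoint regional pools per sample cluster (2
  pools by default); **homogenizing dispersal**: 90% migration toward the
  common pool.
* **Planted network modules**: taxa sharing a latent log-abundance factor
  inside a 50-taxon table whose background is ~e³ more abundant and stable.
  The background share matters: when module taxa dominate total abundance,
  compositional closure of relative abundances creates real cross-module
  correlation, and no threshold recovers clean modules. The default places
  modules at a small fraction of community mass — the realistic regime.
* **Function panel**: latent block scores generated in topological order
  with unit variance (structural residual sized so the specified path
  coefficients ARE the standardized coefficients), altitude fixed to the
  standardized group altitudes, manifests = score + N(0, noise_sd).
  `noise_sd = 0` reproduces the linear structure exactly.

What the generator does **not** emulate: sequencing artifacts (chimeras,
contamination, compositional bias of primers), overdispersion beyond the
multinomial, phylogenetic signal in the metacommunity abundances, spatial
autocorrelation among plots, and real covariance between the community
tables and the function panel (they are linked only through the group
design). Passing recovery tests therefore demonstrates that the estimators
recover the stated generative structure at the design scale — not that
field data meet these assumptions.

Two behaviors of the drift regime deserve note. First, because drift
samples are exchangeable draws from one metacommunity, their observed
Bray–Curtis is often *smaller* than the Raup–Crick null expects, so
drift-generated pairs frequently classify as homogenizing dispersal rather
than the drift residual; the deterministic-vs-stochastic dominance call is
unaffected, which is why the recovery tests assert dominance, not the
residual fraction. Second, homogeneous selection on a Brownian trait yields
only weak phylogenetic clustering (similar trait values occur in many
clades), so βNTI < -2 recovery is not asserted; heterogeneous selection,
which pushes samples into different deep clades, is.

## Problem sizes and numerical choices

The test suite runs the assembly recovery at the full design scale (10
seeds x 20 samples x 300 taxa x 999 nulls for both nulls, ~90 s total),
type-I calibrations at 1000 simulated datasets each, PLS-PM recovery at
n = 200 plots x 10 seeds, and the EMF invariants over 1000 random panels.
Ties in ANOSIM use midranks; Raup–Crick equality uses a 1e-12 tolerance and
splits ties half to each side; βNTI null variance below 1e-12 is treated as
undefined; PCoA eigenvalues within 1e-12 of zero are neither retained as
positive nor reported as negative. PLS-PM recovery is judged against the
estimator's own sampling noise: at n = 200 and manifest noise 0.3 a single
path estimate has sd ≈ 0.06, so recovery is asserted on the mean across
seeds (±0.12) with a per-seed band met in at least 8 of 10 seeds.

## Known limitations

* Spearman-threshold networks inherit compositionality; no log-ratio or
  conditional-independence correction is applied (by design, to match the
  field convention the defaults document).
* βNTI requires a tree; there is no taxonomic fallback for the selection
  step.
* PLS-PM supports mode A + centroid scheme only — the configuration used by
  the targeted class of studies.
* The LSD letter display assumes the usual interval structure of pairwise
  non-significance after sorting by mean; pathological unequal-n cases are
  handled by a full clique check but can produce more letters than the
  minimal display.
* Raup–Crick on very uneven designs (samples with fewer than 2 taxa) flags
  pairs NA rather than attempting a degenerate null.
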