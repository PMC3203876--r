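---
title: "Methods: comparative analysis of niche evolution on a chronogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of niche evolution on a chronogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichephylo)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the underlying methods
leave room.

## The question and the pipeline

For a clade of species with occurrence localities, climate-like raster
layers, and a time-calibrated phylogeny, the pipeline asks two linked
questions: do sister species occupy distinguishable climatic niches, and do
niche variables carry phylogenetic signal? Strong niche conservatism with
largely allopatric sister ranges is the signature of geographic speciation;
repeated niche divergence between sisters is the signature of ecological
speciation. The pipeline chains six analyses: buffer-union range overlap,
per-pair PCA with Mann-Whitney score tests, maximum-entropy suitability
modeling, niche overlap (D, I) with identity and background randomization
tests, phylogenetic signal (QVI, Blomberg's K), and age-range correlation.

## Geographic ranges

A species' range is the union of discs of radius `radius_km` around its
deduplicated localities. The default radius is 20 km, the value best suited
to patchy tropical-tree distributions at continental scale; 2 and 10 km are
conventional sensitivity settings. Overlap is reported relative to the
smaller range, so a narrow endemic nested inside a widespread sister scores
near 100% even though the pair never grows in strict sympatry — a known
reading caveat of this statistic.

Areas are computed exactly from the circular-arc boundary of the disc union
(Green's theorem over the exposed arcs of every circle), not from a
polygonal approximation: for each circle the angular intervals covered by
neighbouring discs are merged and the complement arcs are integrated. The
method handles disjoint components and interior holes, and closed-form two-
and three-disc checks agree to machine precision, so the package's area
tolerance is set by floating point, not by vertex count. Intersection areas
use inclusion–exclusion on union areas, which is exact for equal radii.
Coordinates are planar kilometres throughout; projecting geographic data to
an equal-area CRS is an input-preparation step outside the package.

## Climatic niches at localities

Layer values are read at the cell containing each locality; localities on
nodata cells are dropped and counted. Each sister pair gets one PCA on the
pooled, standardized localities of both species — a correlation-matrix PCA,
because climate layers carry heterogeneous units (temperature in tenths of
a degree, precipitation in mm), and a pooled analysis so both species'
scores live in a single component space. Score differences on PC1–PC3 are
tested with a two-sided Mann-Whitney U test: an exact permutation null when
the pooled sample is at most 20, otherwise the tie-corrected normal
approximation. A rank test is used deliberately — locality-level climate
values routinely violate the normality and variance-homogeneity assumptions
of ANOVA-family tests, so those are not offered. Significance is coded
`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `NS` otherwise, everywhere in
the package.

Per-species trait values for the signal analyses are the mean over
localities (median selectable); the choice matters little for ranked
statistics but the mean is the field convention.

## The maximum-entropy model

The suitability model is the exponential-family (Maxent-style) distribution
over study-area cells closest to uniform subject to matching the presence
data, fitted by minimizing the convex objective

$$-\frac1m\sum_{i \in \text{pres}} \lambda^\top f_i
  + \log\sum_{\text{cells}} e^{\lambda^\top f}
  + \sum_j \beta_j |\lambda_j|,
  \qquad \beta_j = \text{reg} \cdot s_j/\sqrt{m},$$

with `s_j` the background SD of feature `j` and `m` the presence count.
Design choices:

- **Features are linear + quadratic only**, min-max scaled to [0, 1] on the
  background. This keeps the objective small, convex, and testable while
  still expressing unimodal response curves; hinge/threshold/product
  features trade auditability for flexibility the synthetic studies do not
  need.
- **Optimizer**: monotone proximal-gradient descent (soft-thresholding for
  the L1 term) with backtracking line search, step growth 1.25 per accepted
  iteration, tolerance `1e-6` on the step max-norm, default cap 500
  iterations. Monotonicity is structural, and fits agree with a generic
  BFGS run on the same objective to better than `1e-4` in objective value
  (often beating it).
- **Background** is a seeded uniform sample of up to 10,000 unmasked cells;
  on the package's synthetic grids that is the whole study area. The raw
  surface is normalized over unmasked cells and all overlap statistics use
  it directly; the `logistic` slot is a plain monotone rescaling to [0, 1]
  for display, since any monotone transform is irrelevant to D and I after
  renormalization.
- **Replication** mirrors the standard protocol: 100 replicates, each
  holding out a random 25% of presence cells for AUC and fitting on a
  bootstrap resample of the remaining 75%; the averaged surface is
  renormalized. A per-cell SD surface is produced only for species with at
  least 8 presences — below that the replicate spread is not meaningful.
- **Rare species**: with fewer than `fallback_min_points = 5` distinct
  presence cells no model is fitted; the species' surface in every overlap
  computation is instead uniform over its buffer-union range. Five is
  chosen because real studies have modeled species down to 6 localities but
  not 4.

Training gain is `mean log p(presence) − log(1/N_cells)`; it is exactly 0
for constant layers or crushing regularization, both of which return the
uniform surface.

## Niche overlap and the two randomization tests

D and I are computed on surfaces normalized to sum to 1:
`D = 1 − ½Σ|p−q|`, `I = 1 − ½Σ(√p−√q)²`. The total-variation/Hellinger
inequality guarantees `0 ≤ D ≤ I ≤ 1`, which the tests fuzz-check.

The **identity test** pools both species' presence cells, re-partitions
them at random into the original sample sizes (without replacement),
refits both models, and records null D/I. It is one-tailed low: only
observed overlap *smaller* than the null argues the niches are not
equivalent. The pseudo-p is `(1 + #{null ≤ obs})/(n_reps + 1)`, so 100
pseudoreplicates bound p below at 1/101 ≈ 0.0099. The pooled set is put in
canonical coordinate order and the smaller group drawn first, making the
null invariant to which species is called A — a property the suite asserts.
Observed and null surfaces are produced by the same single-fit routine so
the comparison is exchangeable.

The **background test** compares the focal model against models fitted on
cells drawn uniformly from the *sister's* range (its buffer union — "what
the sister could occupy"), with the pseudoreplicate sample size equal to
the sister's occurrence count, following the source method's convention.
It is two-tailed at the null's 2.5th/97.5th percentiles: `more` above,
`less` below, `NS` between, with stars from the doubled one-sided pseudo-p.
Because CI position and pseudo-p resolution are distinct criteria at 100
replicates, a direction can carry an `NS` star string in borderline cases;
both pieces are reported rather than collapsed. The full design runs the
test in both directions per pair — 2 metrics × 2 directions × pairs
results. 100 pseudoreplicates are used for both tests.

Calibration, checked in the acceptance suite under the generator's own
conditions (30 occurrences per species, 100 pseudoreplicates, 50 trials):
the identity test rejects a true null in ≈4–8% of trials at α = 0.05 and
separates strongly distinct niches at α ≤ 0.01 in ≥ 90%; the background
test is NS in ≥ 80% of trials when sister occurrences really are a uniform
draw from their own background.

## Phylogenetic signal

**QVI.** The observed cost is exact linear (Wagner) parsimony: the minimum
of `Σ|child − parent|` over internal states, computed by bottom-up interval
propagation — each node keeps the interval of optimal states; for a node
with k children the interval is the k-th/(k+1)-th order statistics of the
2k child endpoints, which handles polytomies exactly (slope-clipping
argument; verified against brute-force grid minimization on small trees).
Then `QVI = (Obs − Min)/(Max − Min)` with `Min = range(x)` (the cost on a
perfectly conforming tree) and `Max = Σ|x − median(x)|` (the star-tree
cost). Linear rather than squared-change parsimony is essential: the range
is the linear-parsimony minimum, so the index stays in [0, 1]. Branch
lengths are ignored (retention-index analogues are length-free); constant
traits, and trees too small for Max to exceed Min (n ≤ 3), return 0 by
convention. QVI is invariant to positive affine transforms of the trait.

The posterior test averages QVI over up to 1000 trees (subsampled without
replacement if more are supplied) and builds the null from tip shuffles —
independently per tree within each randomization, since a shared shuffle
would understate the null spread across topologies. Signal is called when
the observed mean falls below the 1st percentile of the randomized means;
the direction (low QVI = signal) is fixed, the percentile is a parameter
because published phrasings of this cutoff are ambiguous.

**Blomberg's K** follows the ratio-of-mean-squares definition with the
Brownian covariance `V` from the tree: the phylogenetic mean
`â = (1ᵀV⁻¹x)/(1ᵀV⁻¹1)`, `MSE0/MSE` observed, scaled by its Brownian
expectation `(tr(V) − n/(1ᵀV⁻¹1))/(n − 1)`. K is exactly 1 on an
equal-branch star tree for any non-constant trait, averages ≈1 over
Brownian simulations (the suite checks [0.85, 1.15] over 200 sims on 32
tips), is invariant to affine trait transforms, and agrees with the
independent `picante` implementation to 1e-8. Significance comes from 999
tip shuffles, `p = (1 + #{K_null ≥ K_obs})/1000`; power is limited on
14–16-tip trees, which is why the calibration checks use 32 tips.

## Age-range correlation

For every internal node the mean overlap between its child clades' tips is
plotted against node age and fitted by OLS. The default between-clade
summary is the unweighted mean over tip pairs; the source method's nested
weighting (`0.5` per extra internal node on the path to each tip) is
available behind `weighting = "nested"` since published applications do not
always state which was used. The Monte-Carlo null jointly permutes the
species identities of the overlap matrix and refits; `f(greater)` is the
proportion of null coefficients *strictly* greater than observed — ties are
excluded, which makes a constant matrix report 0 rather than an arbitrary
split, and explains possible ±1/n_sims differences from tie-splitting
implementations. The frequency is reported as such, never converted to a
two-sided p.

## The synthetic-data generator

The generator defines the study conditions for every calibration result:

- **Layers** are Gaussian random fields: white noise convolved (circularly,
  via FFT) with a Gaussian kernel of SD `corr_length_km`, standardized,
  with inter-layer correlation induced by mixing one shared field into
  every layer at weight `√ρ`. Defaults (5 layers, 30×30 cells of 2 km,
  correlation length 8 km, inter-layer correlation 0.3) give the smooth,
  mutually correlated structure of real bioclim stacks at a size every test
  can afford. Negative ρ enters alternate layers with opposite sign.
- **Occurrences** are cell centres drawn with probability proportional to a
  product-Gaussian suitability in layer space, then deduplicated — repeated
  draws of one locality count once, as with herbarium specimens. Default 30
  draws per species matches the typical per-species sample of the motivating
  study system (most species over ten localities, a few rare ones below).
- **Niche evolution** is Brownian motion of per-layer optima along the
  chronogram (exact multivariate-normal simulation from the tree
  covariance), rate `sigma2 = 0.05` per Ma and shared breadth 1.2 by
  default — drift slow enough that congeners stay on the landscape, wide
  enough breadth that ranges overlap, mirroring the weak-divergence regime
  the analyses are meant to detect.
- **The study fixture** transcribes the published two-genus system: 27
  sampled species, root at 14.9 Ma, the three Madagascar species as a
  monophyletic excluded clade, the unresolved three-species group as a hard
  polytomy, and the 11 sister-pair comparisons with their published mean
  MRCA ages, 95% intervals, and range-overlap percentages. Internal node
  ages that were never published numerically are fixed at plausible values
  consistent with the topology and root age; only cherry/polytomy MRCA ages
  are data. The published table lists the three pairwise comparisons of the
  unresolved trio (its accompanying prose mentions four; the fixture
  records the three actually tabulated). A posterior sample is emulated by
  multiplicative lognormal jitter of node ages (σ = 0.1) with parent-child
  ordering restored — it models dating uncertainty only, not topological
  uncertainty.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: spatial sampling bias along roads and rivers,
georeferencing error, non-Gaussian (e.g. skewed or multimodal) suitability,
environmental change over the tree's timespan, and range movement
decoupled from niche evolution.

## Problem sizes and determinism

Every stochastic routine takes a seed, and `run_study()` derives all stage
seeds from one master seed, so a rerun reproduces every table exactly (the
suite asserts byte-identical tables across two runs). The package's own
report-scale defaults — 100 identity/background pseudoreplicates, 199–999
signal randomizations, 1000 ARC permutations, 50-tree jittered posterior —
are chosen so a full synthetic study completes in a few minutes on one
core; the calibration experiments in the acceptance suite use 50 trials per
condition, enough to bound rates at the precision the criteria state.

## Known limitations

- The maximum-entropy model omits hinge features and clamping, so it is not
  bit-compatible with Maxent 3.x outputs; comparisons to published AUCs are
  qualitative.
- Equal buffer radii are assumed when intersecting ranges (the
  inclusion–exclusion shortcut requires it).
- The identity/background tests fit one model per pseudoreplicate rather
  than a replicate-averaged ensemble; this matches the observed-side
  computation here, but ensemble-averaged observed surfaces from other
  software will differ slightly.
- ARC intercepts are not interpreted as sympatry fractions; only the
  niche-similarity adaptation is implemented.
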