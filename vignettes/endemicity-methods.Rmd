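---
title: "Methods: parsimony analysis of endemicity, constraint envelopes, and richness regression"
author: "endemicity package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony analysis of endemicity, constraint envelopes, and richness regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endemicity)
```

# The problem

Continental-scale occurrence compilations for poorly known freshwater taxa
— the motivating case is calanoid copepods recorded across the freshwater
ecoregions of a continent — typically arrive as a binary table: which
species has been recorded in which ecoregion. Three questions follow
naturally and this package implements the full chain that answers them:

1. **Which groups of areas share restricted-range species?** Parsimony
   Analysis of Endemicity (PAE) treats areas as "taxa" and species
   presences as binary characters, searches for the most-parsimonious area
   tree, and reads supported clades as areas of endemism.
2. **Does any environmental variable cap species richness without
   predicting it?** The Boundary Sum of Squares (BSS) test asks whether
   richness–environment scatterplots concentrate under a triangular upper
   boundary more than a randomization null allows.
3. **What correlates with richness linearly?** An eight-predictor multiple
   regression of per-area richness on log(area), altitude and six
   bioclimatic summaries.

Every stage can be exercised against synthetic data with planted, known
structure, so the package tests are recovery tests rather than snapshot
tests.

# PAE: model and search

## Characters, polarity and the hypothetical outgroup

The incidence matrix (species × areas) is transposed for tree search:
areas are terminals, species are unordered binary characters. Presence
must be polarized as the derived state for nested clades to be readable as
areas of endemism; following the standard PAE convention we root with a
hypothetical area in which every species is absent (tip label
`ROOT_ALL_ABSENT`). Without that outgroup the character polarity — and
hence the interpretation of any grouping — would be undefined.

Tree length is Fitch parsimony: per species, the minimum number of
0↔1 changes on the tree, summed. The implementation (compiled code, as is
usual for parsimony kernels) passes state-set bitmasks up a leaf-rooted
traversal; its unit tests compare every value against brute-force
enumeration of all internal-state assignments, which is exact for the tree
sizes a test can afford (≤ 8 leaves, 2^6 assignments per character).

## Heuristic search protocol

The search follows the conventional parsimony protocol: random addition
sequences refined by tree-bisection-reconnection (TBR). Defaults are 1000
addition-sequence replicates with up to 100 trees retained per replicate;
package tests and examples use far smaller settings (5–10 replicates)
because the matrices involved are small and the exhaustive optimum is
known for comparison.

Design choices that the protocol's usual prose leaves open were fixed as
follows:

* **Stepwise addition** starts from the star of the outgroup and the first
  two areas of the sequence; each later area is inserted on the edge
  minimizing total length, ties broken uniformly at random from the
  run-level RNG. This makes a replicate a pure function of (matrix, seed).
* **TBR neighborhood**: every edge is bisected (pendant edges included —
  bisecting a pendant edge is the leaf-SPR special case) and the two
  fragments are reconnected across all pairs of their edges. Enumeration
  order is deterministic; only tie choices consume randomness.
* **Acceptance** is strict improvement; the climb stops when no neighbor
  is shorter. Equal-length neighbors of the final tree are retained.
* **Retention** keeps, per replicate, up to `keep` topologically distinct
  trees *tied at the replicate's best length* — the tree-buffer semantics
  of the classic parsimony programs. Retaining strictly worse trees to
  fill the buffer would contaminate the consensus: on noise-free data the
  pooled consensus must show every true clade at 100%, which is exactly
  what the recovery tests assert.
* **Consensus** is majority-rule (> 50%) over the pooled, deduplicated
  retained trees of all replicates, with clade frequencies reported as
  percentages on the outgroup-rooted view. Clades above 50% are always
  mutually compatible, so the consensus tree is well defined.

An exhaustive enumerator (all (2n−5)!! unrooted topologies, refused above
9 areas) provides the ground truth that the heuristic is tested against:
on random 7-area × 30-species matrices the 5-replicate heuristic matches
the exhaustive minimum in well over 95% of trials and can never undercut
it.

## What drops out, and what does not

Species present in fewer than two areas (autapomorphies of one area, or
absent everywhere) are parsimony-uninformative given the all-absent
outgroup: they add a constant to every topology's length. The filter
`dropUninformative()` is therefore optional and off by default — retaining
such species changes no topology, which the property tests verify
directly.

# The BSS constraint-envelope test

## Geometry

For points $(x_i, y_i)$ (environment, richness), the observed ranges
delimit a rectangle. The `lower_right` triangle has vertices
$(\min x, \min y)$, $(\max x, \max y)$, $(\max x, \min y)$, hypotenuse
from $(\min x, \min y)$ to $(\max x, \max y)$: the pattern in which warm
areas *may* be rich but cold areas cannot be. The `lower_left` triangle
(used for variables like altitude that cap richness at high values) has
hypotenuse from $(\min x, \max y)$ to $(\max x, \min y)$. A published
verbal description of the lower-left vertex list that coincides, as a set,
with the lower-right one is treated as a typo; the geometrically
meaningful mirror image is implemented.

The statistic is the mean distance (or mean squared distance, when
`distancePower = 2` — the "sum of squares" reading of the test's name) of
the points strictly outside the triangle to the *hypotenuse segment*.
Points on the hypotenuse count as inside. Distances are measured after
both axes are affinely mapped to $[0,1]$ (`standardize = TRUE`): the axes
carry incommensurate units (°C, mm, km², species counts), so unscaled
distances would be meaningless and the test would not be invariant to
unit changes. With standardization the decision is provably invariant to
positive affine transforms of either axis, and the property tests check
this to numerical precision.

## Null model and p-value

The default null permutes the $y$ values over the points, preserving both
marginals and breaking only the association; since ranges are
permutation-invariant the triangle needs no recomputation. A
`uniform_rectangle` null (points drawn uniformly in the observed
rectangle, the EcoSim-style model) is available for comparison. With $N$
randomizations (default 1000) the one-sided p-value uses the add-one
rule,

$$p = \frac{1 + \#\{S_{null} \le S_{obs}\}}{1 + N},$$

so $p$ is never exactly zero and lies on the grid $k/(N+1)$. Small $p$
means the points hug the boundary. Calibration is verified by simulation:
under an independence null the rejection rate at $\alpha = 0.05$ sits in
[0.03, 0.07] over 500 datasets, and the p-value distribution is within
Kolmogorov–Smirnov distance 0.1 of uniform; against a hard planted
envelope ($y \sim U(0, x)$ plus jitter of sd 0.05 at $n = 60$) power
exceeds 80%.

# Richness regression

`buildDesign()` joins per-area richness to the covariate table, logs area
(natural log by default; base 10 via `logBase` since the published
convention is rarely stated and the log-area coefficient scales with the
base), and leaves the seven remaining predictors untransformed. The
response is the raw species count by default, with `log` and `log1p`
options. `fitOls()` is ordinary least squares via `stats::lm`, reporting
the coefficient table, $F$, $R^2$ and adjusted $R^2$; rank deficiency is
an error naming the collinear columns, never a silent drop. Its outputs
are tested against explicit normal-equations algebra on a small worked
dataset.

# Synthetic-data generators

The generators define the study conditions of every recovery test:

* `simulateAreaCladogram(n)` draws a uniform random unrooted binary
  topology (sequential insertion on a uniformly chosen edge).
* `simulateIncidence(truth, nSpecies)`: each species is an endemic of one
  uniformly chosen nontrivial clade (uniform over clades, not
  size-weighted, so every clade has equal expected support and recovery
  tests are sharp); a fraction `w` is instead widespread-random
  (Bernoulli(0.5) per area); cell-wise i.i.d. flips at rates `eps01`
  (false presence) and `eps10` (false absence) follow. Noise is
  deliberately free of spatial autocorrelation so binomial bounds on flip
  counts are exact.
* `simulateEnvelope(n, slope, intercept, noiseSd, constrained)` plants
  $y \sim U(0,\ slope\cdot x + intercept)$ plus truncated Gaussian jitter,
  or an independent uniform under the null.
* `simulateSpeciesArea(nAreas, c, z, noiseSd)` draws areas log-uniformly
  over 10–10^5 km² (four orders of magnitude, a continental ecoregion
  span) and richness as $c + z\log(\text{area})$ plus Gaussian noise,
  floored at zero and rounded to whole species; the other seven
  covariates are drawn independently of richness within physically
  consistent ranges (warmest-month maximum above coldest-month minimum,
  nonnegative precipitation). Defaults $c = 2$, $z = 0.45$, sd 1 keep
  expected richness safely above the zero floor so the rounding and
  flooring perturb the planted slope negligibly.

All generators are pure functions of (parameters, seed).

What the synthetic data do *not* emulate: spatially autocorrelated
sampling effort, correlated climate covariates, widespread species with
contiguous (rather than random) ranges, and clade-dependent detection.
Passing recovery tests therefore demonstrate correctness of the
algorithms under the stated generative model, not robustness of PAE or
BSS to the sampling pathologies of real occurrence compilations.

# Numerical and degenerate-input choices

* Zero range in either envelope axis is an error, not a silent zero
  statistic.
* Fewer than 5 envelope points warns (the permutation null is coarse).
* Exhaustive search refuses beyond 9 areas, naming the 2,027,025-topology
  bound.
* Incidence cells outside {0, 1} are rejected with their coordinates;
  missing values are not imputed.
* The reserved outgroup label `ROOT_ALL_ABSENT` may not collide with a
  real area label.
* All reported clade supports are percentages rounded to one decimal.

# Problem sizes used in tests

The test suite and the acceptance script run, by design, at the sizes the
recovery properties call for: 100 random 7-area matrices against the
exhaustive oracle, 50 trees for the Fitch brute-force comparison, a
12-area cladogram with 150 species for clade recovery, 500 null datasets
(1000 permutations each) for BSS calibration, 200 replicates each for BSS
power and species–area slope recovery, and a 98 × 72 round-trip at the
dimensions of a full continental compilation. The complete suite runs in
about a minute on a single CPU.

# Known limitations

* PAE itself is a first-approximation method: it cannot separate
  vicariance from dispersal and inherits the area delimitation it is
  given. The package implements the method; it does not arbitrate that
  debate.
* Consensus supports are majority-rule frequencies over retained trees,
  not bootstrap or Bremer support.
* The regression applies no spatial autocorrelation correction and no
  multiple-testing adjustment across BSS variables, matching the standard
  usage it reproduces.
* The BSS test's power depends on the triangle orientation being chosen
  a priori per variable; orientation is a user decision (`lower_right`
  for temperature-like variables, `lower_left` for altitude) and is not
  selected from the data.
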