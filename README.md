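# endemicity

Biogeographical inference from species-by-area incidence data, for
researchers working with occurrence compilations over natural area
schemes (e.g. freshwater ecoregions): which groups of areas share
restricted-range species, whether climate caps species richness, and
what richness correlates with linearly.

The package implements three linked analyses plus the synthetic-data
generators needed to test them against known truth:

* **Parsimony Analysis of Endemicity (PAE).** Areas are treated as taxa
  and species presences as unordered binary characters, polarized by a
  hypothetical all-absent outgroup area. Tree length is Fitch parsimony
  $L(T) = \sum_s \min \#\{0 \leftrightarrow 1 \text{ changes of } s
  \text{ on } T\}$; search is the standard protocol of random addition
  sequences followed by TBR branch swapping, with an exhaustive
  enumerator (all $(2n-5)!!$ topologies, $n \le 10$ leaves) as testing
  oracle, and a majority-rule consensus with percentage clade supports.
* **Boundary Sum of Squares (BSS) constraint-envelope test.** For a
  richness-vs-environment scatter, a triangular envelope is drawn inside
  the bounding rectangle (lower-right for variables whose high values
  permit but do not guarantee richness; lower-left for variables like
  altitude that cap richness at high values). The statistic is the mean
  distance of points outside the triangle to its hypotenuse, on axes
  standardized to the unit square; significance comes from a permutation
  null with the add-one rule $p = (1 + \#\{S_{null} \le
  S_{obs}\})/(1 + N)$. Small $p$: points concentrate under an upper
  boundary.
* **Richness regression.** OLS of per-area species richness on
  log(area), altitude and six bioclimatic summaries, reported as a
  coefficient table with model-level $F$, $p$ and adjusted $R^2$.

## Worked example

Plant an 8-area cladogram, generate a noisy incidence matrix from it, and
run the chain:

```r
library(endemicity)

tr    <- simulateAreaCladogram(8, seed = 11)
truth <- syntheticTruth(tr, eps01 = 0.02, eps10 = 0.05, w = 0.1, seed = 12)
m     <- simulateIncidence(truth, 80)
m
#> IncidenceMatrix: 80 species x 8 areas, 328 presences

res <- heuristicSearch(m, replicates = 20, keep = 50, seed = 13)
res
#> SearchResult: best length 113, 1 distinct tree(s), 20 replicate(s)

cons <- majorityRuleConsensus(res)
writeNewick(cons)
#> (((((A01,A04)100,((A03,A08)100,A07)100)100,A02)100,A05)100,A06);
```

The best tree needs 113 character changes; every clade of the consensus
appears in 100% of the retained trees, and (by construction of the
simulation) the recovered clades are exactly the clades of the planted
cladogram. On real data the tip labels would be ecoregion names and the
supported clades are read as candidate areas of endemism.

Climate envelope and regression on a simulated species-area dataset:

```r
sa  <- simulateSpeciesArea(nAreas = 40, seed = 14)
pts <- envelopePoints(sa$covariates$annual_mean_temp, sa$richness,
                      sa$covariates$area_id)
bssTest(pts, orientation = "lower_right", seed = 15)
#> BSS test (lower_right, power 1, permute_y null): stat = 0.22161,
#>   19 point(s) outside, p = 0.4875

fit <- fitOls(buildDesign(sa$covariates, sa$richness))
fit
#> Richness regression: n = 40, F = 6.10, p = 9.92e-05, adj R2 = 0.51
#>                     term  estimate std_error t_value  p_value
#> 1            (Intercept)  2.22e+00  1.105155   2.005 5.38e-02
#> 2               log_area  4.76e-01  0.076593   6.214 6.69e-07
#> 3               altitude -1.33e-04  0.000146  -0.911 3.69e-01
#> ...
```

Here temperature shows no envelope (p = 0.49, as it should: the generator
gave it no signal), while the planted species-area slope z = 0.45 is
recovered as 0.476 ± 0.077 on log(area) — the only significant predictor,
with every climatic covariate correctly flat.

File-based workflows use `readIncidence()` / `readCovariates()` for
CSV/TSV input, `writeNexus()` for a PAUP*-compatible DATA block (areas as
taxa, outgroup row included), `writeNewick()` for trees, and `runFull()`
to drive the whole chain from a YAML/JSON config, writing a consensus
tree, richness table, BSS report, regression table and an md5 manifest.

## Package layout

* `R/`, `src/` — S4 classes (`IncidenceMatrix`, `SearchResult`,
  `ConsensusTree`, `EnvelopePoints`, `BssResult`, `RichnessFit`,
  `SyntheticTruth`) with accessors, plus the compiled parsimony kernel
  (Fitch scoring, stepwise addition, TBR, exhaustive enumeration).
* `tests/testthat/` — unit, property and end-to-end recovery tests; all
  expected values come from independent oracles (brute-force enumeration,
  normal equations, `ape`/`phangorn` cross-checks) or closed forms.
* `vignettes/endemicity-methods.Rmd` — the methods vignette: model
  assumptions, design decisions, null-model calibration, limitations.
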