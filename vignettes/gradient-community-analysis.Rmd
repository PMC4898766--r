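---
title: "Methods: incidence-based diversity and ecotone structure along short elevation gradients"
author: "betagrad maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incidence-based diversity and ecotone structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betagrad)
```

# Scope and data model

`betagrad` analyses georeferenced specimen surveys along short elevation
gradients. The atomic input is a *specimen table*: one row per collected
individual with a path (transect) code, a locality point, coordinates,
elevation, and one or more species-hypothesis label columns (e.g. a
morphospecies sorting and a DNA-based delimitation such as bPTP). Every
statistic in the package is *incidence-based*: the table is first collapsed
to a species-by-unit presence/absence matrix, where the sample-unit can be
the locality point (the default, because specimens are assigned to a single
representative locality), the path, a fixed-width elevation bin, or a biome
compartment at a threshold elevation *t*. The biome convention is half-open:
elevations in [0, *t*) are "dry", [*t*, ∞) "moist"; the motivating survey
never states which side the 300-m threshold itself belongs to, so the
convention is fixed here once and used everywhere.

Geographic distances use the haversine formula on a sphere of radius
6371.0088 km (the IUGG mean radius). Any standard spherical model reproduces
the survey's "about 5.6 km" maximum sampling distance; on the bundled
locality set the maximum over non-DH points is 5.651 km, between AH10 and
MN15.

# Richness estimation

All estimators consume the incidence frequency counts
(S~obs~, m, Q~1~, Q~2~, ...), where Q~k~ is the number of species found in
exactly *k* of the *m* sample-units.

* **Chao2.** Classic form S~obs~ + ((m−1)/m) Q~1~²/(2Q~2~); bias-corrected
  form S~obs~ + ((m−1)/m) Q~1~(Q~1~−1)/(2(Q~2~+1)). The automatic mode uses
  the bias-corrected form unless the coefficient of variation of the
  incidence distribution exceeds 0.5, in which case the classic form is
  used. The CV is defined here as sd/mean of the per-species unit counts —
  the switching rule in the EstimateS tradition names a CV "for abundance
  and/or incidence distributions" without a formula, and this pipeline is
  incidence-only, so the incidence CV is the defensible reading. When
  Q~2~ = 0 the classic form is undefined and the bias-corrected form is
  substituted (standard practice). Standard deviations follow Chao's
  incidence variance formulas.
* **ICE.** Species are split at a frequency cutoff (default 10 units) into
  frequent and infrequent groups; coverage C~ice~ = 1 − Q~1~/N~inf~ and the
  Lee–Chao squared-CV correction follow the usual definitions. If every
  infrequent incidence is a unique (C~ice~ = 0) the estimator is undefined
  and the bias-corrected Chao2 is returned with an explanatory note.
* **Jackknife.** Jack1 = S~obs~ + Q~1~(m−1)/m and
  Jack2 = S~obs~ + Q~1~(2m−3)/m − Q~2~(m−2)²/(m(m−1)).
* **Rarefaction/extrapolation.** Interpolation uses the exact
  hypergeometric expectation
  E[S(t)] = S~obs~ − Σ~s~ C(m−m~s~, t)/C(m, t) (computed on the log scale
  for stability); extrapolation to t = m + m\* uses the Chao2
  unseen-species estimate Q̂~0~ in
  S~obs~ + Q̂~0~[1 − (1 − Q~1~/(Q~1~ + mQ̂~0~))^m\*^]. The default target is
  3× the observed effort. SDs come from a bootstrap over sample-units
  (default 100 replicates, seeded) rather than an analytic variance; the
  reference workflow reports "100 sample order randomisations" without
  stating the SD method, so the bootstrap is a documented choice, not a
  claimed equivalence.

Reports round estimates to 1 decimal and SDs to 2, the precision of the
published richness tables this design mirrors.

# Similarity and reconstruction of shared counts

Sørensen 2a/(2a+b+c) and Jaccard a/(a+b+c) are linked by J = S/(2−S); the
package exposes this identity directly because published tables often print
both indices but not the shared-species count *a*. Given per-community
richness S₁, S₂ and a printed Sørensen value, the integer shared count is
recovered as a = round(S·(S₁+S₂)/2) (ties round half-up, result clamped to
[0, min(S₁, S₂)]). On the bundled path-pair table this reconstruction lands
within 0.03 of an integer for all ten pairs and reproduces the printed
Jaccard entries exactly at three decimals for nine of ten; the remaining
entry (NO–ST) prints 0.298 where the reconstruction gives 26/87 = 0.2989,
i.e. the printed value appears truncated rather than rounded. The package
reports rounded values and documents the discrepancy instead of matching
truncation.

# Beta-diversity partitions

Two additive decompositions of pairwise dissimilarity are implemented:

* Baselga: β~sor~ = (b+c)/(2a+b+c) split into turnover
  β~sim~ = min(b,c)/(a+min(b,c)) and nestedness β~sne~ = β~sor~ − β~sim~;
* Carvalho: β~cc~ = (b+c)/(a+b+c) split into replacement
  β~repl~ = 2·min(b,c)/(a+b+c) and richness difference
  β~rich~ = |b−c|/(a+b+c) (a Sørensen-denominator family is available too).

In both families the stored total is *computed as* turnover + remainder, so
the additivity identity holds bit-exactly by construction; the total agrees
with its closed form to one ulp. Multiple-site Baselga values use the
Σmin/Σmax formulation over all site pairs. For the Carvalho family the
multi-site generalisation is taken as the arithmetic mean of the pairwise
components — the package ecosystem offers several variants and the source
design does not say which was used, so the simplest additive one is used and
flagged in the output metadata.

Community clustering uses UPGMA on 1 − Sørensen dissimilarity by default
(the source design shows dendrograms without naming a linkage; average
linkage is the conventional choice for compositional data and single and
complete linkage are provided as alternates). The implementation is
in-package with a deterministic tie-break by member labels, is
`hclust`-compatible, and exports Newick with ultrametric leaf depths equal
to half the merge heights. Distance decay fits similarity against
great-circle distance by OLS plus a moving-window least-squares smooth with
a window of 25% of the pairs — the reference analysis says only
"least-squares smoothing", so the window fraction is an explicit, tunable
default.

# Sliding-window ecotone detection

The sample is sliced into contiguous half-open elevation bins of width 40 m
anchored at 0 m (the width is a user parameter with a sensitivity-scan
helper, `ecotone_width_scan()`; 40 m was the motivating survey's "good
compromise" and no automatic selection is attempted). For each shared edge
*t* between adjacent bins the profile records the Sørensen–Dice index of
the two bins' species sets, plus exclusivity counts in one of two modes:
*global* (species whose every record lies below, or at/above, *t* —
the default, reading "exclusively found below or above the corresponding
elevation threshold" as whole-dataset compartments) and *pairwise* (species
present in only one bin of the pair, matching a per-pair reading). Both are
available because the source wording is ambiguous; neither is asserted as
the original series. Singleton exclusion (species with exactly one
*individual* in the whole table, not one incidence) is applied before all
computations when requested; it provably never lowers the shared index nor
raises exclusivity counts.

The ecotone call proceeds in two steps:

1. **Transition interval** — the maximal contiguous run of comparisons whose
   shared index is at or below the profile's `low_quantile` quantile
   (default 0.25) while strictly below the profile maximum. The
   at-or-below rule makes the run robust to ties at the minimum in sparse
   profiles, while a perfectly flat profile still yields "no ecotone". A
   profile-relative threshold replaces the survey's absolute 0.16, which is
   dataset-specific; an absolute override is provided.
2. **Boundary** — where the exclusivity balance (below-exclusive minus
   above-exclusive) changes sign: at a comparison edge if the balance is
   exactly zero there, otherwise at the midpoint of the bin separating the
   last negative and first positive comparisons; among several candidates
   the one nearest the transition interval's centre wins. Note that with
   40-m bins anchored at 0, an elevation like 300 m is a *bin midpoint*
   (of [280, 320)), not a bin edge — this is why the boundary convention
   admits midpoints; snapping to edges only would make a 300-m boundary
   unexpressible. If no sign change exists the boundary falls back to the
   minimum-shared-index edge with a low-confidence note.

# The synthetic gradient community

The generator provides the package's ground-truth world: two species pools,
one adapted to drier, lower elevations and one to moister, higher
elevations, overlapping in an ecotone band. Its defaults state a
Núi-Chúa-like survey:

* the 60 bundled non-DH locality points with their real elevations
  (38–486 m);
* visits per path as in the survey design: 4 for the two low paths (AH,
  DD), 10 for the three high ones (MN, NO, ST);
* 155 species split 80 dry / 75 moist — the total is the survey's observed
  species count and the mild dry-side excess mirrors its 103 vs 90
  per-biome richness;
* rectangular elevational ranges with centres N(170, 60) m (dry) and
  N(430, 60) m (moist) and widths N(260, 60) m floored at 40 m, so the
  upper edges of dry ranges and lower edges of moist ranges both centre on
  300 m — the stated true boundary — inside the stated 160–320 m band
  (a Gaussian-occupancy mode gives smoother ecotones when wanted);
* detection as a per-visit Bernoulli with a species-specific log-normal
  abundance multiplier (mean 1, sdlog 1.2) and a baseline rate *calibrated
  by root-finding* so the expected individual-based singleton fraction
  equals the configured target of 0.497, the survey's reported value. The
  calibration integrates the exact probability of observing a species
  exactly once over its realized exposures, so it is deterministic given
  the seed's species draws.

Draw order is canonical (species-major, locality-minor, visit-innermost)
under one integer seed, so a config and seed reproduce byte-identical
tables.

What the generator does *not* emulate: within-locality spatial structure,
temporal (seasonal) turnover across visits, abundance counts beyond
presence (each detection emits one specimen), haplotype structure (the
haplotype column holds per-individual unique tokens), and observational
biases such as varying collector effort. A green parameter-recovery test
therefore establishes that the sliding-window procedure recovers a known
compositional boundary under realistic sampling sparseness and singleton
load — not that it would do so under, say, strong seasonal turnover.

One tension is worth stating: with the pool fixed at 155 species and the
singleton fraction calibrated to 0.497, the realized surveys are sparser
than the motivating one (≈170 specimens and ≈65–70 observed species per
replicate rather than ≈494 and 155). A single baseline-rate knob cannot
match specimen count and singleton fraction simultaneously; the singleton
target was kept because rare-species load is what stresses every estimator
and filter in the pipeline. Richness estimators are accordingly exercised
both on these sparse worlds and on saturating-detection configurations
where the truth is exactly recoverable.

# Delimitation agreement

Two species partitions of the same specimens are compared by classifying
each reference species' specimen set against the test partition: **agree**
(equal to exactly one test species), **split** (union of ≥2 test species,
all inside it), **merge** (wholly absorbed, with at least one other complete
reference species, into one test species — every absorbed reference species
counts), and **complex** (any many-to-many overlap). The four classes are
mutually exclusive and exhaustive, so they always sum to the reference
species count; published agree/split/merge tables that sum exactly to their
reference count imply no complex cases in those data, and the explicit
fourth class here surfaces them rather than folding them silently. A
haplotype-collapsed mode compares on haplotypes (first record's labels per
haplotype) and mirrors a-posteriori reassignment workflows. The headline
statistic is the match percentage, 100·agree/n~ref~.

# Numerical choices and degenerate inputs

* Rounding of reconstructed shared counts: half-up (`floor(x + 0.5)`).
* Chao2 with Q~1~ = 0 returns S~obs~ in every mode (no unseen-species
  signal); rarefaction's extrapolated segment is flat when Q̂~0~ = 0.
* Similarity and beta of two empty communities, turnover fraction of a zero
  total, clustering of asymmetric matrices, profiles with fewer than two
  non-empty bins, and distance-decay fits with all-equal distances are
  errors, not NaNs.
* UPGMA ties (equal merge distances) break by lexicographic member labels,
  within a 1e-12 tolerance band.
* All randomness (generator, bootstraps) flows from explicit integer seeds;
  the pipeline derives per-stage seeds from one root seed so stage order
  cannot change results.

# Known limitations

* Multi-site Carvalho values are means over pairs; other published
  generalisations will differ.
* The ecotone caller implements the described heuristics only — no
  changepoint statistics, no 2-D boundary estimation, no smoothing.
* Abundance-based estimators (Chao1, ACE) and abundance-weighted
  similarity (Bray–Curtis, Morisita–Horn) are out of scope: the pipeline is
  incidence-only by design.
* No significance testing of beta-diversity is provided.
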