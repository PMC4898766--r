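# betagrad

Incidence-based community diversity and ecotone structure along short
elevation gradients.

`betagrad` is aimed at community ecologists working with georeferenced
specimen surveys — typically hyperdiverse arthropod samples whose species
hypotheses come from morphology and/or DNA-based delimitation (GMYC, bPTP).
It was built around the analysis design of a leaf-beetle (Chrysomelidae)
survey of Núi Chúa National Park (South Vietnam), where ~500 specimens from
~10 km² of forest paths spanning a 40–500 m elevation gradient cross the
ecotone between lowland dry deciduous forest and moister evergreen forest.
Everything the package does starts from a specimen table (one row per
collected individual, with coordinates, elevation and one or more
species-hypothesis label columns) and proceeds through presence/absence
(incidence) matrices — no abundance-based statistics.

## What it computes

* **Incidence matrices** over configurable sample-units: locality points,
  forest paths, fixed-width elevation bins, or biome compartments split at an
  elevation threshold t (half-open: [0, t) dry, [t, ∞) moist).
* **Species-richness estimation** from incidence frequency counts
  (S_obs, m, Q₁, Q₂, …):
  - Chao2, classic `S_obs + ((m−1)/m) Q₁²/(2Q₂)` and bias-corrected
    `S_obs + ((m−1)/m) Q₁(Q₁−1)/(2(Q₂+1))`, with the EstimateS-style rule
    that switches to the classic form when the CV of the incidence
    distribution exceeds 0.5;
  - ICE (Lee–Chao coverage estimator), first- and second-order jackknife;
  - sample-based rarefaction (exact hypergeometric) and Chao2-anchored
    extrapolation to a 3× sampling effort, with bootstrap SDs.
* **Compositional similarity**: Sørensen `2a/(2a+b+c)` and Jaccard
  `a/(a+b+c)`, the identity `J = S/(2−S)`, and reconstruction of the integer
  shared-species count `a = round(S·(S₁+S₂)/2)` from published richness +
  similarity summaries.
* **Beta-diversity partitions**, pairwise and multiple-site:
  - Baselga: `β_sor = β_sim + β_sne` (turnover + nestedness);
  - Carvalho: `β_cc = β_repl + β_rich` (replacement + richness difference).
* **UPGMA clustering** of communities (deterministic tie-breaks, Newick
  export) and **distance decay** of similarity with OLS and moving-window
  least-squares fits.
* **Sliding-window ecotone detection**: slice the sample into 40-m elevation
  bins, profile the Sørensen–Dice index and species exclusivity between
  adjacent bins, and call the transition interval and boundary.
* **Species-delimitation agreement**: agree / split / merge / complex
  accounting of one partition against another, with the percentage of
  reference species perfectly recovered.
* **Synthetic gradient communities** with known ground truth: two
  elevationally offset species pools overlapping in an ecotone band, per-visit
  Bernoulli detection with log-normal abundance heterogeneity, calibrated to a
  target singleton fraction.

## Worked example

```r
library(betagrad)

sim <- generate_gradient_community(nui_chua_default_config(seed = 1))
tab <- sim$table
tab
#> <specimen_table> 142 specimens, 53 localities, hypotheses: true

X <- build_incidence(tab, "true", "path")
richness_table(X, n_boot = 100, seed = 1)
#>       estimator value    sd                                      notes
#> 1 Rarefaction3x  94.8 18.36 m=5, target t=15, 100 bootstrap replicates
#> 2           ICE 123.3    NA     cutoff=10, C_ice=0.6346, gamma2=0.3753
#> 3 Chao2-classic 100.1 15.96           auto: CV=0.564 > 0.50 -> classic
#> 4         Jack1  94.4  8.06
#> 5         Jack2 110.0    NA

baselga_multisite(X)
#> baselga_sorensen [multisite(5 sites)]: total 0.788 = turnover 0.714 + nestedness 0.074

prof <- sliding_profile(slice_elevation(tab, 40), "true")
detect_ecotone(prof)
#> <ecotone_call> boundary 300 m, transition 40-300 m (boundary at exclusivity-balance sign change)

summarize_singletons(tab, "true")$fraction
#> [1] 0.4838710
```

Reading: the simulated survey observed 64 species in 142 specimens across
five paths; the nonparametric estimators put true richness at roughly
95–125 species (the generator's truth is 155, about half of which are
reachable and detectable at this effort, so the estimators correctly signal
substantial unseen diversity). Multisite dissimilarity among paths is high
(0.79) and dominated by turnover rather than nestedness, and the
sliding-window procedure recovers the generator's true 300-m boundary
between the dry- and moist-adapted pools. About half the observed species
are singletons, matching the configured target (0.497).

The full pipeline (incidence → richness → similarity → beta/UPGMA →
ecotone → comparison → logs) runs from one config:

```r
run_pipeline(pipeline_config(output_dir = "out", seed = 1))
```

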