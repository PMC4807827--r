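# seasondiv

Seasonal change in species richness (SR), functional diversity (FD) and
phylogenetic diversity (PD) of two-season assemblage data, tested
against a turnover-preserving null model.

## The problem

Communities sampled at the same sites in a wet and a dry season usually
lose species in the harsher season.  The interesting question is not
*whether* but *how*: is the loss random with respect to what species do
and how they are related?  Comparing three diversity currencies answers
it —

* **SR**: the species count;
* **FD** (Petchey–Gaston, dendrogram-based): Gower distance on a mixed
  categorical/continuous trait table → UPGMA dendrogram over the full
  species pool → per assemblage, the total branch length needed to
  connect its species;
* **PD** (Faith-style): the branch-length sum of the phylogeny's
  subtree connecting the assemblage, on a time-calibrated tree.

Each observed assemblage pair is compared against **null assemblages**
that preserve the whole observed design except composition.  Per site,
the pool is wet ∪ dry; each replicate shuffles the pool, takes the
first *x* species as the wet null (*x* = observed wet SR), forces the
*y* remaining species (the observed dry-only turnover count) into the
dry null, and restocks the dry null from that replicate's wet null up
to the observed dry SR.  Null richness equals observed richness
exactly, so FD/PD deviations isolate compositional non-randomness.

Seasonal change is measured as `-1 * (1 - dry/wet)` (0 = no change,
−1 = total loss, positive = increase), and observed values or changes
are paired with per-site null means in two-sided paired *t* tests.
Redundancy — a saturating diversity–richness relationship — is detected
by AICc stepwise simplification of `FD ~ SR + SR²` (and `PD ~ SR +
SR²`); Moran's I checks spatial autocorrelation.  A scenario-based
synthetic-data generator (Yule tree, traits with tunable phylogenetic
signal, neutral / filtering / limiting-similarity / clustered-loss
assembly) makes the whole pipeline testable end to end and its error
rates measurable.

The intended users are community ecologists with site × species ×
season presence/absence data, a species × trait table, and a phylogeny
of (most of) the species pool.

## Worked example

Simulate a dataset in which dry-season survival is concentrated in one
clade *and* spares functionally distinct species (scenario `"C+D"`),
then run the full analysis:

```r
library(seasondiv)

ds  <- simulate_dataset(scenario_config("C+D"), seed = 42)
rep <- run_seasonal_analysis(ds$occ, ds$traits, ds$tree,
                             coords = ds$coords,
                             replicates = 1000, seed = 7)
rep
```

```
Seasonal diversity report (12 sites, 1000 null replicates, seed 7)

Global tests:
                  test  n mean_diff      t df         p
         SR_wet_vs_dry 12   3.91667  6.869 11 2.696e-05
 change_FD_obs_vs_null 12   0.05517  8.111 11 5.730e-06
 change_PD_obs_vs_null 12  -0.11322 -2.870 11 1.525e-02
    FD_wet_obs_vs_null 12  -0.01248 -1.671 11 1.229e-01
    FD_dry_obs_vs_null 12   0.08279  7.364 11 1.423e-05
    PD_wet_obs_vs_null 12   0.03101  1.004 11 3.371e-01
    PD_dry_obs_vs_null 12  -0.47079 -2.793 11 1.750e-02
...
```

Reading the output: richness drops from wet to dry
(`SR_wet_vs_dry`, t = 6.9).  FD *declines less than the null model
predicts* (`change_FD_obs_vs_null`: mean difference +0.055, p ≈ 6e-6)
while PD *declines more* (`change_PD_obs_vs_null`: −0.113, p = 0.015).
Season by season, the wet assemblages are indistinguishable from null,
but dry assemblages show high FD (t = 7.4) together with low PD —
phylogenetic clustering (t = −2.8).  That joint signature (functionally
over-dispersed yet phylogenetically clustered dry-season survivors) is
exactly what the generator built in, and the per-site table
`rep$per_site` carries the corresponding standardised effect sizes and
null rank quantiles.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes example datasets (plain CSV +
Newick), `02_observed_diversity.R` computes observed SR/FD/PD through
the file readers, `03_null_model.R` builds and summarises the null
ensemble, `04_inference.R` produces full report bundles, and
`05_power.R` tabulates operating characteristics across scenarios.
Outputs land under `results/`.

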