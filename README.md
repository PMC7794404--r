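# meltpot

Why are hotspots of intraspecific genetic diversity so "hot"? Two
mechanisms compete. Populations may have persisted through glacial cycles
inside bioclimatically stable **refugia**, accumulating and retaining
variation in place; or divergent lineages that diverged in separate
refugia may have met again at secondary contact zones, where admixture
inflates diversity — hotspots as **melting pots**. `meltpot` implements
the comparative workflow that quantifies the two contributions for a
spatially structured species, and ships a synthetic-world generator with
known drivers so every stage of the workflow is verifiable without any
external download.

The core quantities:

- **Diversity statistics** per population: haplotype diversity
  *h* = n/(n−1) · (1 − Σpᵢ²), nucleotide diversity π (mean per-site
  pairwise difference, pairwise deletion), observed and Nei-unbiased
  expected heterozygosity Ho/He, and rarefaction allelic richness
  Ar = Σₐ [1 − C(N−Nₐ, g)/C(N, g)] at a common gene-copy size g.
- **Admixture**: the Simpson index D = 1 − Σₖ qₖ² of a population's mean
  cluster proportions (from external Bayesian clustering), 0 for a pure
  population and approaching 1 − 1/K under even admixture; cluster number
  K is selected at the plateau of the DIC-versus-K curve.
- **Refugia and stability**: an AUC-weighted ensemble of species
  distribution models (cleaned and spatially thinned occurrences,
  VIF-pruned climate variables, target-group background) is calibrated on
  current climate, projected onto palaeoclimate scenarios, binarised at
  the maxTSS threshold; glacial refugia are cells suitable under at least
  two GCMs, stability areas the overlap of current suitability, refugia,
  and phylogeographically inferred ancestral areas.
- **Attribution**: Gaussian GLMs of He and Ar on the Simpson index and
  the distances to the nearest refugium and stability area, with
  sequential ANOVA and AIC model comparison over a fixed six-model set.

## Worked example

Simulate a study system whose diversity is driven by admixture, compute
the diversity table and predictors, and ask the model comparison which
driver explains heterozygosity:

```r
library(meltpot)

w   <- generate_world(world_config(driver_mode = "admixture", seed = 42))
gt  <- filter_populations(w$genotypes)$genotypes       # n >= 4 rule
div <- diversity_table(w$sequences[unique(gt$population)], gt)
head(div, 3)
#>   population n_mt   h     pi n_nuc    Ho    He   Ar
#> 1        P01    5 0.9 0.0147    10 0.842 0.791 5.58
#> 2        P02    5 0.8 0.0133    10 0.810 0.832 6.93
#> 3        P03    5 0.7 0.0113    10 0.784 0.849 7.72

pops <- w$populations; names(pops)[1] <- "population"
pops <- pops[pops$population %in% div$population, ]
pred <- build_predictor_table(pops, population_mean_q(w$q_matrix),
                              w$truth$refugia_mask, w$truth$stability_mask)
head(pred, 3)
#>   population simpson dist_refugium dist_stability
#> 1        P01   0.034           200          346.6
#> 2        P02   0.345            50           98.5
#> 3        P03   0.355           151          151.3

mc <- run_model_set(div, pred)
mc$responses$He$aic
#>                                          model      aic
#>                                   He ~ simpson -254.845
#>                   He ~ dist_refugium + simpson -253.467
#>                  He ~ dist_stability + simpson -253.342
#>  He ~ dist_stability + dist_refugium + simpson -251.480
#>                            He ~ dist_stability -181.416
#>                             He ~ dist_refugium -179.861
```

The AIC-best model for He is `He ~ simpson`, with a strongly significant
Simpson coefficient (0.213, p ≈ 3e-17): admixed populations are the
diverse ones, and the distance predictors add nothing — exactly the
driver this world was built with. With
`driver_mode = "stability"` the comparison flips to a distance model with
a negative coefficient. `run_pipeline(list(seed = 1), out_dir = "out")`
chains everything — simulation, filters, admixture summaries, the
ensemble SDM, refugia/stability maps, attribution — and writes every
intermediate artifact (FASTA, GenePop, CSV, ESRI ASCII grids, GeoJSON,
JSON reports) plus a run report sufficient to reproduce the run bit for
bit from its seed.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/meltpot.R simulate --seed 1 --out out
Rscript inst/cli/meltpot.R divstats --seed 1 --out out
Rscript inst/cli/meltpot.R all      --seed 1 --out out
```

See `vignettes/hotspot-attribution.Rmd` for the models, their
assumptions, the synthetic-world design, and the pre-registered rules the
recovery experiments use.

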