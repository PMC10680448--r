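# reefguest

Analysis of sponge host–guest interaction networks on tropical coral
reefs.

Reef sponges act as living habitat for a wide range of guest species —
snapping shrimps, brittle stars, polychaetes, gobies, molluscs — and
the resulting associations form a bipartite host–guest network. For
community ecologists working with such networks, `reefguest` provides
the complete analysis chain in one tested package:

* build a binary hosts × guests incidence matrix from species-level
  interaction records, with validation, duplicate collapsing and
  per-ecoregion dataset summaries;
* quantify network architecture: **NODF nestedness** and **Barber
  bipartite modularity**

  *Q* = (1/*m*) Σᵢⱼ (*A*ᵢⱼ − *k*ᵢ*d*ⱼ/*m*) δ(*g*ᵢ, *g*ⱼ),

  the latter optimized by simulated annealing with a hill-climb
  finish, both tested against null ensembles (fill-preserving by
  default, marginal-preserving curveball as the alternative) with
  one-sided (*r*+1)/(*n*+1) p-values;
* score every host sponge with **seven structural descriptors** —
  degree, betweenness, closeness, Katz centrality, among-module
  connectivity *c*ᵢ, within-module standardized degree *z*ᵢ, and
  per-species nestedness contribution *cn*ᵢ — and collapse them into a
  single importance index via principal coordinate ordination:
  importance = √(PCO1 − min PCO1);
* compute each host's **accumulated geographic area**: 10 m² circular
  buffers around occurrence records, cropped by reef polygons, in km²;
* relate importance to traits: Poisson GLM on accumulated area,
  one-way ANOVAs across functional morphologies (Crust-like, Massive,
  Cup-like, Erect) and taxonomic orders, and a publication-bias
  meta-analysis of per-ecoregion publication proportions
  (ML τ², Cochran's Q, Thompson–Sharp asymmetry test);
* generate **synthetic input bundles** with planted nested and modular
  structure, trait effects and degree-coupled occurrences, so every
  stage is testable and calibratable without any download.

See the vignette (`vignettes/reef-sponge-networks.Rmd`) for the models,
parameter choices and known limitations.

## Worked example

```r
library(reefguest)

cfg <- network_config(n_hosts = 30, n_guests = 60, connectance = 0.1,
                      seed = 42)
bundle <- generate_bundle(cfg)
res <- run_pipeline(bundle$interactions, traits = bundle$traits,
                    occurrences = bundle$occurrences,
                    reefs = bundle$reefs,
                    n_null = 200, n_null_modularity = 100,
                    steps = 10000, null_steps = 2000, n_rand = 200,
                    seed = 43)
res
```

```
Host-guest network pipeline result
Interaction dataset: 141 unique host-guest pairs (30 hosts, 60 guests)
...
NODF = 9.973 (p = 0.00995); Q = 0.5872 (p = 0.0099), 14 modules
PCO axis 1 explains 92.65% of descriptor variation
GLM importance ~ area: intercept = 0.6199, z = 3.49
Morphology ANOVA F = 2.987 (p = 0.0494); order ANOVA F = 0.2689 (p = 0.926)
```

The generated network is significantly nested (NODF above all 200 null
matrices) *and* significantly modular (Q above all 100 optimized
nulls) — the planted double structure is recovered. The GLM confirms
the planted positive coupling between importance and reef area, the
morphology ANOVA detects the planted growth-form effect, and the order
ANOVA is null, as orders were assigned at random.

The per-species table joins everything:

```r
head(res$species_table[order(-res$species_table$importance),
     c("species", "degree", "importance", "accumulated_area",
       "morphology")], 5)
```

```
             species degree importance accumulated_area morphology
19 Hostia species019     10   4.502849          0.00023    Massive
21 Hostia species021      8   4.157967          0.00017   Cup-like
20 Hostia species020      7   3.960953          0.00002      Erect
8  Hostia species008      9   3.849285          0.00020   Cup-like
25 Hostia species025      8   3.794490          0.00003 Crust-like
```

High-degree hosts top the importance ranking — axis 1 of the
ordination is dominated by connectivity, which is the index's intended
reading. `write_results(res, "out/")` saves `summary.json` plus the
species, module and ecoregion tables as CSV.

To analyse an empirical dataset, point `run_pipeline()` at your own
files: an interaction CSV (`host_species`, `guest_species`,
`ecoregion`, `latitude`, `longitude`, `reference`; other layouts via
the `columns` map of `read_interactions()`), a trait CSV (`species`,
`morphology`, `order`), an occurrence CSV (`species`, `latitude`,
`longitude`) and reef polygons as GeoJSON.

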