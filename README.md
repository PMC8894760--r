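# bittertea

Quantitative ethnobotany of herbal-tea formulation surveys.

Surveys of herbal-tea traditions — the motivating case is the Taiwanese
bitter tea (kǔ-chá) trade — record which plant materials each store combines
into a recipe (*formulation*), together with per-material attributes: botanical
family, part used, cultivated/wild source, and the traditional property,
flavor and function assigned by compendia. This package is for
ethnobotanists and ethnopharmacologists who want the standard quantitative
treatment of such data:

* **Use value** of material *i*: `UV_i = U_i / N`, where `U_i` is the number
  of formulations containing the material and `N` the number of formulations
  surveyed (binary per store).
* **Shannon diversity** of the inventory: `H = -Σ P_i log2 P_i`, where
  `P_i = U_i / Σ_j U_j` is the material's share of all material occurrences —
  computed overall and per regional stratum.
* **Attribute distributions**: family (by species and by formulation), plant
  part, source, property/flavor (with the unannotated materials excluded
  from the denominator), and function-tag prevalence.
* **Inventory comparison**: k-way set-partition (Venn) counts over 2–5
  inventories matched on normalised scientific names, including top-k
  use-value comparisons between two traditions.
* **Drug-pair co-occurrence network**: every unordered pair of materials
  sharing a formulation is counted; pairs with count *strictly above* a
  threshold (default 4) form the core network, whose nodes carry use values
  and whose weighted-degree ranking identifies the core medicinal materials.
* **Synthetic-survey generator**: a seeded generator reproducing the summary
  structure of such surveys (long-tailed Zipf material popularity,
  zero-truncated-Poisson formulation sizes, attribute marginals), so the
  full pipeline is testable when raw survey tables are unavailable.

## Worked example

```r
library(bittertea)

# a synthetic 32-store survey with the default marginals
ds <- generate_survey(generator_config(), seed = 1)
ds
#> Formulation survey: 32 formulations, 73 plant materials
#> Regions: north=19, central=8, south=5

freq <- material_frequencies(ds)
print(freq, n = 5)
#> Frequency table: 73 materials, N = 32 formulations, 174 occurrences
#>  material frequency    UV
#>      m001         9 0.281
#>      m002         9 0.281
#>      m004         9 0.281
#>      m007         6 0.188
#>      m039         6 0.188

round(shannon_diversity(freq), 2)     # inventory diversity, bits
#> [1] 5.67
round(mean_formulation_size(ds), 1)   # mean materials per recipe
#> [1] 5.4
```

The most frequent material appears in 9 of 32 formulations, a use value of
9/32 = 0.28125, displayed at the conventional 3 decimals as 0.281. Diversity
of 5.67 bits approaches the `log2(73) ≈ 6.19` maximum, reflecting the long
popularity tail.

Core-network analysis, here on a survey with a drug pair planted at
co-occurrence 5 (the kind of structure the thresholded network is built to
find):

```r
ds <- plant_core_structure(ds, c("m005", "m012"), 5L, seed = 1)
net <- build_core_network(count_pairs(ds),
                          use_values(material_frequencies(ds)),
                          threshold = 4)
net
#> Core co-occurrence network: 2 materials, 1 drug pairs with count > 4
#>     a    b count
#>  m005 m012     5
rank_core_materials(net)
#>  material score      uv
#>      m005     5 0.28125
#>      m012     5 0.18750
```

Only the planted pair exceeds the strict threshold; its two members are the
network's core materials, ranked by weighted degree (sum of incident pair
counts) with use values attached.

Comparing inventories — 73 survey materials against an external list that
shares 38 of them:

```r
vp <- venn_partition(list(bitter_tea = paste0("tw", 1:73),
                          mainland = c(paste0("tw", 36:73), paste0("cn", 1:30))))
vp
#> Venn partition of 2 inventories ( bitter_tea, mainland ), union size 103
#>  signature count
#>         01    30
#>         10    35
#>         11    38
#> Exclusive: bitter_tea=35 (47.9%), mainland=30 (44.1%)
```

35 of the 73 survey materials (48% under integer display) occur nowhere in
the comparison inventory.

The whole pipeline — frequency/UV table, regional Shannon indices, attribute
tables, Venn JSONs, pair counts, core network in GraphML/TSV/JSON, ranking
and run log — is emitted as a report bundle by `run_full_analysis()`, or
from a shell via the thin wrapper `inst/scripts/bittertea-cli.R`
(subcommands `validate`, `indices`, `compare`, `network`, `simulate`,
`all`).

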