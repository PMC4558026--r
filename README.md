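# slavstrata

Joint population-genetic and lexicostatistical analysis of structured
population surveys, built around the toolkit used to study Balto-Slavic
speaking populations: how much of the genetic landscape of a language
family's speakers reflects the languages' history, and how much reflects
geography and the substrata the speakers absorbed.

The package is for population geneticists and quantitative linguists who
have (a) haplogroup frequency tables with population metadata, (b) pairwise
IBD-segment lists from a detector such as fastIBD/BEAGLE, and/or (c)
multistate cognate wordlists, and who want the standard battery computed
reproducibly from plain text files:

* **Nei's standard genetic distance** between haplogroup frequency vectors,
  `D = -ln(Jxy / sqrt(Jx * Jy))`, with group-mean summaries and great-circle
  geographic distances (6371 km sphere);
* **Non-metric MDS** with Kruskal stress-1 (isotonic regression, Torgerson +
  random restarts);
* **Hierarchical AMOVA** on haplogroup counts (0/1 mismatch distance,
  Excoffier–Smouse–Quattro sums of squares, unequal-size EMS coefficients)
  with Phi-statistics (`phi_ST`, `phi_SC`, `phi_CT`) and the matching
  permutation tests, over any linguistic hierarchy (branch → ethnic group →
  local population);
* **Mantel and partial Mantel tests** among genetic, geographic and
  linguistic distance matrices, with exact enumeration for small n;
* the **ibd-statistic** — average number of IBD segments per cross-group
  pair of individuals, in ten configurable cM length classes — with
  permutation comparisons of sharing between group pairs;
* **lexicostatistics**: cognate shares with the synonym rule, Starostin-law
  glottochronological dating, neighbor-joining dated trees, and the
  ≤300-year consensus collapse into multifurcations;
* **synthetic-data generators** with known ground truth (hierarchical
  Dirichlet haplogroup surveys with optional spatially autocorrelated drift,
  a recombination-clock IBD simulator with closed-form expectations, a
  Poisson replacement-clock wordlist simulator), so the full pipeline is
  testable without any external data.

## Worked example

Simulate a Balto-Slavic-sized survey (4 branches × 3 ethnic groups × 3
local populations, 12 haplogroups, 100 men per population), then run the
genetic half of the pipeline:

```r
library(slavstrata)

survey <- simulate_haplogroups(haplo_sim_config(seed = 7))
survey
#> <haplogroup_table> 36 populations x 12 haplogroups, with counts, with metadata

D <- nei_distance_matrix(survey)
round(D[1:3, 1:3], 3)
#>        B1G1P1 B1G1P2 B1G1P3
#> B1G1P1  0.000  0.154  0.075
#> B1G1P2  0.154  0.000  0.317
#> B1G1P3  0.075  0.317  0.000

mean_group_distance(D, survey$meta$population[survey$meta$branch == "B1"],
                    name_a = "branch B1")
#> # A tibble: 1 × 4
#>   group_a   group_b mean_d n_pairs
#> 1 branch B1 <NA>     0.343      36

mds_embed(D, k = 2, restarts = 8, seed = 1)
#> <mds_result> k = 2, stress-1 = 0.1384 (8 restarts)

amova(survey, groups = "branch", permutations = 199, seed = 1)
#> <amova_result>
#>                            level   df     sum_sq   variance ...
#>                     among_groups    3  116.21972 0.04085599
#>  among_populations_within_groups   32   63.02444 0.01568498
#>               within_populations 3564 1429.22000 0.40101571
#>                            total 3599 1608.46417 0.45755669
#>   phi_st = 0.1236 (p = 0.005, 199 permutations)
#>   phi_sc = 0.0376 (p = 0.005, 199 permutations)
#>   phi_ct = 0.0893 (p = 0.005, 199 permutations)

mantel_test(D, haversine_matrix(survey$meta), permutations = 999, seed = 1)
#> <Mantel> r = 0.1652, p = 0.006 (greater, 999 permutations)
```

Reading the output: within this simulated family, 8.9% of haplogroup
variance lies among linguistic branches (`phi_ct = 0.089`) and 3.8% of the
within-branch variance among ethnic groups (`phi_sc = 0.038`) — the ordering
a hierarchical survey of a real language family shows. The MDS stress of
0.14 says the 36 populations flatten into two dimensions about as well as
real NRY surveys do, and the Mantel test finds the geography signal
(r = 0.17, p < 0.01) that the contiguous placement of branches creates.

Every result type has `tidy()`/`glance()` methods returning tibbles, and
`autoplot()` methods for the MDS configuration and IBD sharing profiles.
`run_study()` drives all six stages (distances, MDS, AMOVA, Mantel, IBD,
lexicostatistics) from one YAML file and writes TSVs plus a JSON manifest.

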