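---
title: "Methods: joint population-genetic and lexicostatistical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint population-genetic and lexicostatistical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slavstrata)
```

slavstrata implements the quantitative core of a multi-system survey of
population structure in the Balto-Slavic area: haplogroup-frequency genetic
distances and ordination, hierarchical AMOVA over a linguistic hierarchy,
matrix correlation tests among genetic, geographic and linguistic distances,
a group-level IBD-segment-sharing statistic with resampling comparisons, and
cognate-matrix lexicostatistics with dated trees. This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Genetic distances from haplogroup frequencies

Populations are summarised by relative frequencies of Y-chromosomal (or
mitochondrial) haplogroups. For two frequency vectors $p, q$ the package uses
Nei's standard genetic distance

$$D = -\ln \frac{J_{xy}}{\sqrt{J_x J_y}}, \qquad
  J_{xy} = \sum_i p_i q_i,\; J_x = \sum_i p_i^2,\; J_y = \sum_i q_i^2,$$

as the plain plug-in estimator. No small-sample bias correction is applied:
haplogroup surveys conventionally report the uncorrected statistic, and the
correction would change within-group means by far less than the sampling
noise of typical per-population sample sizes (tens to low hundreds).

Two vectors with disjoint haplogroup support have $J_{xy} = 0$ and an
infinite distance. Real survey tables occasionally produce this for small
samples, and an infinite entry would poison every downstream step (MDS,
Mantel), so `nei_distance()` caps the distance at a configurable finite value
(default 10, far above any realistic $D$) and warns; `strict = TRUE` turns
the condition into an error.

Geographic distances are great-circle (haversine) distances on a sphere of
radius 6371 km, computed from decimal-degree coordinates.

## Non-metric MDS and Kruskal stress-1

`mds_embed()` performs non-metric multidimensional scaling: the first start
is classical (Torgerson) scaling, subsequent restarts are random Gaussian
configurations, isotonic-regression MDS iterations run to convergence, and
the lowest-stress solution wins. Stress is Kruskal stress-1,

$$\sigma_1 = \sqrt{\frac{\sum_{i<j} (\hat d_{ij} - \delta_{ij})^2}
                        {\sum_{i<j} \delta_{ij}^2}},$$

with $\delta$ the configuration distances and $\hat d$ the
monotone-regression disparities (pool-adjacent-violators over the
dissimilarity order, primary treatment of ties: configuration distances may
order freely within tied dissimilarities). `stress1()` is a pure evaluator
implemented directly on `stats::isoreg`, and `mds_embed()` reports the
stress of its final configuration through `stress1()`, so optimiser and
evaluator agree by construction; the test suite additionally checks both
against the optimiser's internal accounting. Convergence uses a relative
stress-improvement threshold of $10^{-9}$ with at most 500 iterations per
start, tight enough that perfectly embeddable distance matrices reach stress
below $10^{-6}$.

## Hierarchical AMOVA with Phi-statistics

Individuals carry a single haplogroup, and the molecular distance between
two individuals is the 0/1 haplogroup mismatch, which makes $\Phi_{ST}$ the
haplogroup-frequency analogue of $F_{ST}$. Sums of squared deviations are
partitioned by the Excoffier–Smouse–Quattro scheme (among groups, among
populations within groups, within populations), and variance components are
solved from the standard expected-mean-square coefficients for unequal
sample sizes. With 0/1 distances the within-set sum of squares reduces to
$(n - \sum_h c_h^2/n)/2$ for haplogroup counts $c_h$, so the whole analysis
— including every permutation replicate — runs on count tables.

Permutation schemes follow the component being tested: $\Phi_{ST}$ permutes
individuals among all populations, $\Phi_{SC}$ permutes individuals among
populations within their group, $\Phi_{CT}$ permutes whole populations among
groups. p-values use $(b+1)/(m+1)$, which cannot return zero.

Numerical conventions:

* Negative variance components are reported as estimated (the
  method-of-moments estimator is unbiased but unbounded below, and
  Arlequin-style software reports raw values); a clamped-to-zero copy is
  provided alongside. Note that truly identical populations give *slightly
  negative* raw among-level components, not zero — the among-population mean
  square is exactly zero while the within mean square is positive — so the
  "no differentiation" reading belongs to the clamped estimates.
* A level with a single unit is reported as `NA` (not testable), never as
  zero.
* When both the among-populations-within-groups and within-population
  components are exactly zero, $\Phi_{SC}$ is reported as 0 rather than 0/0.

`amova_per_group()` runs one two-level AMOVA per unit of a chosen stratum
(e.g. $\Phi_{ST}$ among the local populations of each ethnic group) and
averages across units — the two-level and three-level readings of a
hierarchical survey are both available because published tables rarely say
which produced their per-level figures.

## Mantel and partial Mantel tests

`mantel_test()` correlates the $n(n-1)/2$ upper-triangle entries of two
label-aligned distance matrices and builds the null by simultaneous
row/column permutation of the second matrix. For $n \le 7$ the full
permutation distribution can be enumerated, giving exact p-values. Tests are
one-sided ("greater") by default, since distance–distance associations of
interest here are positive; two-sided is available.

`partial_mantel_test()` uses the first-order partial correlation
$r_{AB \cdot C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}$
with the raw permutation method (permute $B$, recompute the partial each
time), the most common implementation lineage; residual permutation is
available behind `method = "residual"`. A control matrix perfectly collinear
with either argument is refused rather than divided by zero.

## The ibd-statistic and sharing comparisons

For two disjoint groups of individuals, the ibd-statistic is the average
number of IBD segments per cross-group pair, tabulated by segment-length
class; pairs sharing nothing still count in the denominator. The default ten
length classes are $[1,1.5), [1.5,2), [2,2.5), [2.5,3), [3,4), [4,5),
[5,6), [6,8), [8,10), [10,\infty)$ cM — half-cM boundaries at the short end,
where such analyses cite classes like "1.5–3 cM" and "2–3 cM", with an
open-ended last class; the edges are fully configurable because published
figures do not print them.

`compare_sharing()` tests whether a focal group shares more with comparator
1 than with comparator 2: $\Delta$ is the difference of the two totals over
a selectable subset of classes, and the null reassigns the individuals of
the two comparators to pseudo-groups of the original sizes. Individuals, not
populations, are the exchangeable units, because the statistic is defined
per pair of individuals. The p-value is two-sided, $(b+1)/(m+1)$.

Segment input is fastIBD-style marker intervals plus a genetic map with cM
positions; coordinates are half-open $[start, end)$ in map units, physical
positions are not modelled, and segments below a 1 cM detection minimum are
dropped on read (configurable) — matching the resolution floor of
fastIBD-class detectors.

## Lexicostatistics and dated trees

A wordlist matrix holds, per Swadesh concept and lect, a set of cognate-class
ids (synonyms allowed). For a pair of lects the compared items are those
scored in both; an item matches when the class sets intersect; the cognate
share is the weight-sum of matches over the weight-sum of comparisons
(per-item stability weights default to 1), and distance is one minus share.

`glotto_date()` converts a share $c$ into years before present. Three decay
laws are provided:

* `"starostin"` (default): $t = \sqrt{-\ln c / (2\lambda c)}$ millennia with
  $\lambda = 0.05$ per squared millennium — the root-corrected law of the
  Starostin school, whose division by $c$ compensates for the stability bias
  of the items that survive comparison;
* `"sqrt"`: $t = \sqrt{-\ln c / (2\lambda)}$, the uncorrected square-root
  law;
* `"constant"`: $t = -\ln c / (2\lambda)$ with $\lambda$ a per-millennium
  replacement rate — the exact inverse of a homogeneous-Poisson replacement
  clock.

The third law exists because the package's wordlist simulator *is* a
homogeneous-Poisson clock: simulation-recovery experiments must date with
the generative model's inverse, otherwise the comparison confounds
estimation error with a deliberate model mismatch (the square-root laws
applied to constant-rate data misdate shallow nodes by design, by tens of
percent). For real lexical data the Starostin default stands.

`starling_nj()` builds the topology by neighbor joining on the lexical
distances, roots it (midpoint by default, or on a designated outgroup),
dates each internal node by the mean cognate share between the leaf sets of
its child clades, and monotonises dates root-ward with a running maximum so
no parent is younger than a child. Lects can be excluded up front — the
analysis this package descends from excluded Slovenian, whose vocabulary
mixes West and South Slavic strata.

`collapse_consensus()` contracts every internal edge whose parent–child date
gap is at most 300 years (configurable), producing the multifurcations of a
consensus tree; the merged node keeps the parent's date. A single
simultaneous pass is a fixed point: a contraction can only *widen* the gaps
to the surviving children, so the operation is idempotent (tested). Dated
trees are ultrametric `ape::phylo` objects with branch lengths in years, so
Newick round-trips preserve both topology and node dates.

## Synthetic data: what it emulates, and what it does not

Every input class has a generator that is a pure function of a config and a
seed.

**Haplogroup surveys** (`simulate_haplogroups()`): branch base frequencies
are symmetric-Dirichlet draws; group frequencies are
Dirichlet($\tau_{group} \times$ branch frequencies), population frequencies
Dirichlet($\tau_{pop} \times$ group frequencies); counts are multinomial.
Level-wise differentiation is approximately $1/(1+\tau)$, so the defaults
($\tau_{branch}=1$, $\tau_{group}=30$, $\tau_{pop}=100$, 4 branches × 3
groups × 3 populations, 12 haplogroups, 100 samples per population) give
branch/group/population differentiation of order 0.06/0.03/0.01 — the
magnitudes continental haplogroup surveys report at those levels. Branch
territories are geographically contiguous (branch centers far apart, groups
and populations jittered around them). An optional spatially autocorrelated
field multiplies log-frequencies by a Gaussian-kernel-correlated
($K = e^{-(d/\rho)^2}$, $d$ in km) Gaussian draw, producing a tunable
geography–genetics correlation without any hierarchy.

For the component-ordering recovery experiment the concentrations must be
*graded* ($\tau_{branch} < \tau_{group} < \tau_{pop}$): since
$\sigma^2_b/\sigma^2_c \approx 1/\tau_{group}$, an among-group component
exceeding the within-population one requires $\tau_{group} < 1$, and a
dominant among-branch component then requires branches drawn near fixation.
The experiment uses $\tau = (0.02, 0.2, 1000)$ over 5 branches × 5 groups ×
2 populations.

**IBD segments** (`simulate_ibd()`): a recombination-clock model. A pair of
individuals whose groups coalesce $g$ generations back carries
Poisson($\mu$) detectable segments with cM lengths exponential of mean
$100/(2g)$, left-truncated at the detection minimum (the truncation uses
the exponential's memorylessness — a shift by the minimum — which is
distribution-identical to rejection sampling). $\mu$ is the post-threshold
mean, so the binning-free total of the ibd-statistic equals $\mu$ at every
depth and depth moves mass between short and long classes; the closed-form
per-class expectation `ibd_expected_profile()` makes the generator testable
to Monte-Carlo accuracy, and it also dictates *which* classes separate two
depths (for 30 vs 60 generations: the classes from 2 cM upward).

**Wordlists** (`simulate_wordlists()`): per item, Poisson replacements along
each branch at a per-millennium rate, each replacement drawing a globally
novel cognate class (optionally added as a synonym instead of replacing).
With no synonyms, two lects separated by total path time $T$ share an item
with probability $e^{-\lambda T}$. The default rate, 0.2 per millennium, is
a typical basic-vocabulary turnover. Recovery experiments use an 8-lect
reference tree with splits between 500 and 3400 YBP; at 200 items the
binomial noise of a share estimate alone propagates to roughly 15% date
error at the shallowest (500 YBP) nodes, so recovery is assessed as exact
topology plus *mean* relative node-date error under 15%.

What the generators do **not** emulate: linkage between haplogroups and
geography beyond the smooth kernel field (no rivers, barriers or clines with
direction), IBD detector artefacts (miscalled boundaries, power loss near
the threshold, phasing errors), borrowing or semantic drift in wordlists,
and any form of population growth or admixture dynamics. Passing tests
therefore demonstrate that the estimators recover the parameters of these
idealised processes, not that real surveys satisfy the processes.

## Pipeline and reproducibility

`run_study()` executes the six stages — distances, MDS, AMOVA, Mantel, IBD,
lexicostatistics — from a single YAML configuration, writing one TSV (or
Newick) per result and a JSON manifest with the package version, seed and
parameters. Stages communicate only through declared files; deterministic
stages are bit-identical on rerun. Out of scope by design: raw-genotype
analyses (PCA, ADMIXTURE-style ancestry models, autosomal $F_{ST}$) and IBD
segment *detection* — the pipeline consumes detector output.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (36–50
population surveys, 75 individuals in IBD designs, 110–200-item wordlists,
50–60 seed replicates, 499–999 permutations) were chosen so the whole suite
runs in well under a minute per file on one CPU while keeping every
stochastic margin at three or more standard errors.
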