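---
title: "Dynamic protein-complex detection by genetic-algorithm biclustering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic protein-complex detection by genetic-algorithm biclustering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynbic)
```

## The problem

Protein complexes assemble and dissolve as a cell moves through conditions
and cell-cycle phases, but the protein–protein interaction (PPI) networks we
can measure are static snapshots. A static network mixes interactions that
are always present (the *stable* backbone) with interactions that only exist
in particular expression states (*transient* interactions), and complex
detectors run on the full static graph inherit that confusion.

`dynbic` recovers dynamic structure by integrating the static network with a
time-series gene expression matrix. Rather than slicing the network once per
time-point — which assumes every gene's activity is meaningful at every
time-point — it finds *biclusters*: subsets of genes co-regulated over
subsets of time-points. Each bicluster induces one *dynamic subnetwork* (the
induced subgraph of the static network on the bicluster's genes), a
pluggable complex detector runs on every subnetwork, and the aggregated,
deduplicated predictions are scored against a gold-standard complex set by
Jaccard matching.

## The bicluster fitness

Expression values are first discretized into regulation symbols
(`D` = down, `N` = none, `U` = up; see below). A bicluster $B(I, J)$ —
genes $I$, time-points $J$ — is scored by a discretized column-based
measure:

$$\mathrm{DCM}_B(I,J) \;=\; \sum_{j \in J}\Bigl(1 - (1+\alpha)\,\frac{f_j}{|I|}\Bigr),$$

where $0 < \alpha < 1$ is a penalty factor (default $0.1$) and $f_j$ counts
dissent in column $j$: if one symbol holds a strict majority
($> |I|/2$ occurrences), $f_j$ is the number of genes disagreeing with it —
except that a majority of `N` carries no regulation signal and is only
half-rewarded, $f_j = |I|/2$; with no strict majority, $f_j = |I|$. A
bicluster whose columns are unanimously `D` or `U` attains the maximum
$|J|$; one with no majority anywhere attains the minimum $-\alpha\,|J|$
(the bound is attained, so it is an inclusive lower bound). Because symbols
are computed per gene relative to that gene's own mean and spread, the
measure is insensitive to per-gene shifting and scaling of the shared
profile — exactly the coherence families co-regulated complexes produce —
and the majority rule makes it robust to sporadic noise-induced symbol
flips.

## Preprocessing and discretization

Rows (genes) are normalized to mean 0 and standard deviation 1. The
population standard deviation (divisor $n$) is used throughout: the package
treats rows as complete profiles, not samples, and it makes degenerate-case
arithmetic exact. Constant rows cannot be scaled; they become all-zeros
with a warning, because flat probes are a fact of real microarray matrices.

Four discretization techniques are provided; ties always resolve to the
non-`U` symbol because all thresholds are strict:

* **Simple threshold** (`{D, U}`): `U` where the raw value strictly exceeds
  a global threshold `t`.
* **Mean/sd bands** (`{D, N, U}`, the pipeline default with
  `alpha_disc = 1`): per gene, `D` below $\mu_i - \alpha_d \sigma_i$, `U`
  above $\mu_i + \alpha_d \sigma_i$, `N` inside the band. The default is
  the three-letter technique because the fitness's special `N`-majority
  rule presumes an `N` symbol. `alpha_disc` is deliberately named apart
  from the fitness penalty `alpha_penalty`; they are independent
  parameters.
* **Transitional state** (`{D, U}`): `U` where the z-score is strictly
  positive. The classical description of this technique compares a value
  against its own normalization, which is not computable as stated; the
  sign-of-z reading is this package's declared interpretation.
* **Variation between time-points** (`{D, U}` or `{D, N, U}`): codes the
  difference from the previous time-point against a threshold $\beta$ —
  derived from the first time-point's cross-gene sd in the binary case,
  user-supplied in the three-letter case. The first time-point has no
  predecessor and is assigned the neutral symbol (`D` binary, `N`
  three-letter) so the matrix stays rectangular, which the fixed-length
  chromosome encoding requires.

## The genetic algorithm

A bicluster is encoded as a fixed-length binary chromosome: one bit per
gene and one per time-point. The search uses binary tournament selection,
dual two-point crossover (segments exchanged independently in the gene part
and the time-point part), per-bit flip mutation, and generational
replacement with elitism; a repair step guarantees at least `min_genes`
genes and `min_conditions` time-points per chromosome. Elitism makes the
per-run best fitness monotone, which is also what makes the stall rule
(stop after `stall_generations` without improvement) and the tests simple.

Defaults (chosen as standard GA practice for matrices of a few thousand
genes by a dozen time-points; all overridable in `ga_config()`):
population 200, up to 100 generations, crossover probability 0.85,
mutation probability $1/(m+n)$ per bit, elitism 2, stall 20, 10 restarts,
`min_genes = 3` (mirroring the 3-protein minimum used for complexes),
`min_conditions = 2`. Gene bits initialize sparsely (probability 0.05)
because genuine co-regulation modules are small relative to the matrix,
while condition bits initialize at 0.5. All randomness flows from a single
seed; restart $r$ reseeds deterministically with `seed + r - 1`, so equal
configurations reproduce equal outputs bit for bit.

### Harvesting many biclusters from one optimizer

A GA run optimizes one chromosome, but the pipeline needs a *set* of
biclusters. `dynbic` pools, from each restart's final population, every
distinct chromosome scoring at least `harvest_fraction` (0.9) of the run
best. The raw harvest has a structural redundancy: the fitness is invariant
to adding genes that agree with every selected column's majority (unanimous
columns stay unanimous, `N`-majority columns contribute a constant), so a
population drifts among many partial versions of the same underlying
bicluster. Harvesting therefore ends with a deterministic
*signature completion* (`consolidate_bicluster()`): compute each selected
column's strict majority symbol over the chromosome's genes, keep the
columns with a non-`N` majority as the bicluster's regulation signature,
and redefine the gene set as all matrix genes agreeing with the signature
at more than half of the signature columns — the fitness's own majority
logic applied across columns, which tolerates sporadic noise flips. Partial
discoveries of one coherent bicluster complete to the same maximal gene set
and collapse during exact deduplication. Chromosomes with no non-`N`
signature are left unchanged; they score below `min_dcm_fraction` and fall
to the significance filter.

Harvested biclusters then pass two post-filters: a size/coherence filter
(`filter_biclusters()`: at least 3 genes, 2 time-points, and
$\mathrm{DCM} \ge 0.5\,|J|$ — a coherence proxy for "biologically
significant", since half the maximum attainable score demands a clear
majority in most columns) and greedy redundancy removal
(`remove_redundant()`: descending fitness, drop a bicluster whose gene-set
Jaccard with a kept one reaches 0.75; gene sets only, because subnetworks
are induced by genes alone).

## Dynamic subnetworks and interaction classes

Each retained bicluster induces a subnetwork: its nodes are the bicluster's
genes present in the (pruned) static network — isolated nodes are retained,
so detectors decide their fate — and its edges are exactly the network
edges internal to that set. An interaction present in every subnetwork is
classified *stable*; present in some but not all, *transient*. Gene and
protein identifiers are matched by exact, case-sensitive string equality;
unmatched identifiers are logged rather than raised, since expression and
interaction resources routinely cover different gene universes. Edges are
unweighted; confidence scores in input files are ignored.

## Detection and aggregation

Complex detection is a plug-in seam (`register_detector()`): any function
from subnetwork to protein sets, including adapters that read an external
tool's output files (`read_complexes()`). The built-in baseline,
`greedy_density_detect()`, is intentionally simple — seed at each unvisited
highest-degree node, greedily add the neighbour maximizing edge density
while density stays at or above `min_density` (default 0.6, with
`min_size = 3`), ties broken lexicographically — and is *not* a
reimplementation of any published detector. Predictions from all
subnetworks are pooled; only exactly equal protein sets are collapsed
(fuzzy merging would silently change precision and recall), and complexes
below 3 proteins are dropped, mirroring the convention of curated
references. The 3-protein filter is applied to predictions and benchmarks
alike, for symmetric treatment.

## Evaluation

A predicted complex $D_j$ matches a benchmark complex $B_i$ when their
Jaccard index $|B_i \cap D_j| / |B_i \cup D_j|$ reaches the threshold
$\delta$ (default 0.25). Matching is existence-based in both directions —
no one-to-one assignment — giving precision (matched fraction of
predictions), recall (matched fraction of the benchmark) and their harmonic
mean F1. Threshold comparisons are evaluated as
`intersection >= delta * union` on integer counts, so ties at dyadic
$\delta$ values are exact without an epsilon. Benchmarks are pruned before
scoring: each complex is intersected with the analysed network's proteins
(the wording of the standard pruning recipe supports intersection over
whole-complex removal), and complexes left with fewer than 3 members are
dropped.

## The synthetic study and what it can show

Real inputs at publication scale (thousands of genes, tens of thousands of
interactions, curated complex references) are external resources; the
package instead ships a generator with known ground truth so every stage is
testable offline. `gen_expression()` plants co-regulation blocks in a
standard-normal background: each block's columns get shared offsets of a
single per-block magnitude drawn from $[4, 5]$ with balanced, randomly
ordered signs. Balance keeps row means near zero; the single magnitude
keeps every block column equally far outside the mean ± sd band (a weak
column beside strong ones would inherit their inflated row sd and fall
inside the band); and the random sign order gives each block a distinct
temporal signature. Contiguous condition ranges are placed at evenly spaced
phase offsets — distinct expression phases, disjoint when they fit —
because overlapping plants with partially agreeing signs are genuinely
unidentifiable as separate biclusters. The `shifting` and `scaling`
patterns add per-gene offsets $b_i \sim U(-2, 2)$ or factors
$a_i \sim U(0.5, 2)$, large enough to dominate unit background noise after
row normalization. Gaussian noise (default sd 0.25) is added everywhere.
`gen_ppi()` plants one complex per bicluster (a subset of its genes, sizes
5–10 by default) with within-complex edge probability 0.9 against
background 0.01.

The reference study conditions — a 100 × 12 matrix with two planted 20 × 6
constant-column blocks at noise 0.25, and the planted-complex network
above — are the generator defaults and the sizes used by the test suite and
the acceptance script; they keep a full five-replicate run within a couple
of minutes on one CPU. What passing these tests shows: the fitness, its
optimizer, the induced-subgraph machinery and the scoring are correct and
the whole chain recovers planted structure under Gaussian noise. What they
do not show: performance on real data, where co-regulation is weaker and
graded, expression noise is heteroskedastic and non-Gaussian, interaction
screens have their own false positive/negative structure, and gold
standards are incomplete. The generator also does not simulate periodic
multi-cycle structure or cross-cycle averaging; callers of the real
pipeline pre-average their cycles.

## Numerical and degenerate-case choices

* Population sd everywhere; constant rows normalize to zeros with a
  warning; a zero-sd gene discretizes to all `N` (the band has zero width
  but the inequalities are strict).
* Strict inequalities at every threshold; ties go to the non-`U` symbol.
* The DCM lower bound $-\alpha|J|$ is attained by majority-free columns and
  treated as inclusive.
* Stall comparisons use an absolute tolerance of $10^{-12}$ on fitness
  improvements; harvest thresholds subtract the same tolerance so
  floating-point summation order cannot drop exact-threshold chromosomes.
* Jaccard and DCM arithmetic is exact on integer counts; no epsilons enter
  any matching decision.
* When a run's best fitness is non-positive (possible only on degenerate
  inputs), the harvest keeps only chromosomes at the best value itself,
  since a fractional threshold would then be below the best.
* `sample()`-based operators draw through R's RNG only, so a single
  `set.seed` per restart reproduces the full run; derived seeds stay below
  $2^{31}$.

## Known limitations

* The fitness is size-neutral in $|I|$ by construction; maximality comes
  from the harvest-completion step, not from selection pressure. A
  bicluster whose true member set disagrees with the majority signature in
  more than half of its columns will not be completed correctly.
* Exact-duplicate aggregation means two detectors' near-identical
  predictions both survive; this is intentional but inflates prediction
  counts when plugging in overlapping external detectors.
* Redundancy removal is greedy and order-dependent on ties (descending
  fitness, stable order); a globally optimal diverse subset is not
  attempted.
* The pipeline holds the expression matrix and all subnetworks in memory;
  it targets matrices of a few thousand genes, not single-cell scale.
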