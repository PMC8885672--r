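---
title: "Clustering, mining and classifying complex SV patterns with svcycles"
author: "svcycles maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering, mining and classifying complex SV patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcycles)
```

# The problem

A structural variant is recorded as an *adjacency*: a junction tying together
two oriented breakends. In tumor genomes adjacencies are not independent —
mechanisms such as chromoplexy and chromothripsis produce *chains* of
junctions that close into cycles over a small set of breakpoint clusters.
`svcycles` turns per-sample breakend call sets into per-sample rearrangement
graphs, mines the closed cycles of size 3–6, measures which cycle sizes are
over-represented relative to a degree-preserving null, and subtypes the
triangles (size-3 cycles) by junction orientation and copy-number context.

This vignette explains the model behind each stage, the tunable parameters
and their defaults, the numerical choices, what the synthetic-data generator
does and does not emulate, and the known limitations. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

# Mode-hunting KDE clustering

## Model

The breakpoints of one sample on one chromosome are treated as draws of a
random position variable. Their density is estimated with a Gaussian kernel,

$$\hat f(x) = \frac{1}{n\,h\,\sqrt{2\pi}} \sum_{i=1}^{n}
  \exp\!\left(-\frac{(x - x_i)^2}{2h^2}\right),$$

and each breakpoint is assigned to the nearest local maximum (mode) of
$\hat f$ — a modal ("mode hunting") clustering in which every breakpoint
belongs to exactly one cluster and the mode is the cluster center. The only
hyperparameter is the bandwidth $h$ (bp): larger $h$ merges clusters, smaller
$h$ splits them. For two equal-weight points the modes merge exactly when the
separation drops below $2h$.

Clustering proceeds in two rounds:

1. **Round 1, $h_1 = 1000$.** Coarse clusters. Any adjacency with *both*
   breakends in one round-1 cluster is a local loop (the signature of
   already-described localized events such as chromothripsis) and is
   discarded so it cannot add noise downstream.
2. **Round 2, $h_2 = 400$.** Each surviving round-1 cluster is re-clustered
   independently at the finer bandwidth. Round-1 clusters are then discarded;
   only round-2 clusters remain.

The bandwidths are *global*: one value for every sample and chromosome, so
that the cluster scale is comparable across the cohort. The package provides
`bandwidthSweep()`, which totals the two diagnostics used to justify the
defaults — the intra-cluster distance (largest gap inside a cluster, to be
kept small) and the inter-cluster distance (smallest gap between adjacent
clusters, to be kept large) — over a grid of $h_2$ candidates.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `h1` | 1000 | bp | round-1 bandwidth; resolution of the loop filter |
| `h2` | 400 | bp | round-2 bandwidth; final cluster scale |
| `grid_step_factor` | 0.1 | fraction of `h` | density grid spacing |
| `grid_pad` | 4 | multiples of `h` | evaluation window half-width |

## Numerical choices

* The density is evaluated on a grid of step $0.1h$ restricted to the union
  of windows `data ± 4h`. Beyond $4h$ the kernel mass is below
  $10^{-4}$ of the total, so padding wider changes nothing at the reported
  precision while full-chromosome 1-bp grids would be wasteful. Positions
  further apart than the full window width ($8h$) cannot interact through the
  kernel, so the position vector is cut at such gaps and each block is
  scanned separately; peak assignment stays global.
* Peaks are grid argmaxes; there is no sub-grid refinement. Cluster centers
  feed a graph, so sub-base-pair precision is irrelevant.
* Plateaus of the discrete profile collapse to their leftmost grid point;
  equidistant breakpoints tie-break to the lower-coordinate peak. Both rules
  exist purely for determinism.
* "Adjacent clusters" means consecutive by peak coordinate within one sample
  and chromosome.

# Permutation validation

To check that clusters are not artifacts of chance co-location, simulated
datasets are built by pooling every breakend of the cohort (chromosome and
position preserved — SV hotspots are real and should survive the null),
re-dealing them to samples uniformly while preserving each sample's breakend
count, and re-pairing them uniformly at random within each sample. Two
statistics are compared observed-vs-simulated with one-sample Z-tests:

* **Dispersion** — for every sample chromosome with ≥ 3 breakpoints, the
  population standard deviation (divisor $n$) of the gaps between adjacent
  sorted breakpoints, averaged (unweighted) over those groups. Within-sample
  co-location creates near-zero gaps next to huge ones and inflates this SD.
* **Cluster density** — breakpoints per final cluster, which requires running
  the full two-step clustering on every simulated dataset.

The Z-test uses the sample SD (divisor $n-1$) of the simulated values; the
dispersion statistic uses the population SD internally. Both conventions are
fixed so results are bit-reproducible. With the default 100 simulations the
normal approximation is what makes p-values below $10^{-2}$ (or $10^{-5}$)
expressible at all; an empirical permutation p could never fall below 1/101.

# Graph mining

Each sample's graph has its cluster centers as vertices (identified by the
locus key `chrom:peak`) and one edge per distinct cluster pair connected by
at least one junction — parallel junctions are deduplicated, with provenance
retained. Cycles are enumerated by depth-first path extension from every
start vertex in deterministic (chromosome, position) order; a path closes
when its last vertex neighbors its first. Only simple closed cycles of 3–6
distinct vertices are kept, and every vertex of a reported cycle has degree
exactly 2 within the cycle's edge set.

An occurrence is identified by its *edge set*: the canonical key is the
sorted edge-key list, invariant to rotation and reflection. A dense subgraph
on $k$ vertices may therefore contribute several distinct cycles, all
counted. Since the per-start searches only constrain vertices to be larger
than the start, the start-vertex decomposition is independently processable
and merging + deduplication reproduces the serial result — the property that
makes the search parallelizable. Intermediate DFS paths are never reported.

The cohort table reports, per size: **confidence** (samples with at least one
occurrence), **frequency** (total occurrences) and **average**
(frequency/confidence). Averages are truncated toward zero at two decimals
for table reporting, the convention `patternAverage()` implements.

# Abundance and the switching null

Pattern significance is measured on the pooled cross-sample edge list by the
Abundance

$$\Delta = \frac{f_{\text{input}} - \bar f_{\text{random}}}
                {f_{\text{input}} + \bar f_{\text{random}} + \varepsilon},$$

where $f_{\text{input}}$ is the pattern frequency in the real data,
$\bar f_{\text{random}}$ its mean frequency over $N$ randomized datasets, and
$\varepsilon \ge 0$ a pseudo-count (Laplace smoothing) that keeps the ratio
defined for rare patterns. $\Delta \in [-1, 1]$; 0 means equal
representation.

Randomized datasets are built by edge switching: repeatedly pick two random
edges A–B and C–D of the pooled list and rewire them to A–D and C–B. Every
edge keeps its sample tag, so per-sample edge counts are conserved; vertex
degrees are conserved by construction. A move that would create a self-loop
or duplicate an existing edge within an affected sample's graph is rejected,
and rejected moves still count toward the move budget — with the default
budget of $100 \times E$ attempts ($E$ = total edges) the acceptance loss is
immaterial. Because edge counts are conserved exactly, the single-edge
control pattern always has $\Delta = 0$ — an exact internal control the
acceptance suite asserts.

Design choices made here, with the reasoning:

* **Global switching with sample tags** (rather than switching each sample's
  graph in isolation) realizes both requirements at once — randomization of
  the pooled edge set and per-sample edge-count conservation — and lets
  cluster loci be reused across samples, as recurrent loci are.
* The rewiring is the deterministic A–D, C–B on canonically stored edges;
  the third possible pairing of four endpoints is reachable in two moves, so
  the chain explores the whole space.
* $\varepsilon = 1$ by default (the usual Laplace convention).
* Frequencies, not confidences, feed $\Delta$.
* Per-cancer-type reports restrict the real and randomized frequencies to the
  type's samples; the ensemble itself is not re-randomized within type.

# Triangle classification

For each size-3 cycle the three junctions get an inversion flag (inverted
iff both breakends have the same orientation — head-to-head or tail-to-tail)
and the three clusters get a copy-number state: the total copy number of the
segment containing the peak is compared with the median of the other
segments within ±1 Mb; a difference of at least +1 copy is a gain, at most
−1 a loss, otherwise neutral. An uncovered peak is neutral with a flag.

States *oscillate* when exactly two distinct states alternate maximally
around the cycle (for odd sizes one equal-adjacent pair is unavoidable and
is exempt) and, when one of the two states is neutral, the altered state
carries at least half the positions — copy number 3–2–3 oscillates, 3–2–2 is
a lone gain. With $I$ = number of inverted junctions, the rules are applied
in order:

1. $I \ge 2$ and oscillating → **non-canonical chromothripsis**
2. $I \ge 2$ and any gain → **templated-insertion cycle**
3. $I \ge 2$ and all neutral → **chromotrikona**
4. $I \le 1$ and no gain (loss allowed) → **chromoplexy**
5. otherwise → unclassified

Oscillation is tested before gain because oscillating profiles generally
*contain* gain states; a gain-first order would make the chromothripsis-like
class unreachable whenever the oscillation peaks are gains. The class
descriptions in the literature are qualitative ("frequently inverted", "no
significant gain"); the thresholds here ($I \ge 2$, ±1 copy, 1 Mb flank) are
one crisp codification and are exposed as arguments so users can tighten or
loosen them. Without copy-number data the labels collapse to the orientation
dichotomy (chromoplexy for $I \le 1$, chromotrikona for $I \ge 2$), flagged
`no_cn`.

Shared-cluster structure between types is summarized by
`triangleOverlapMatrix()` (clusters participating in triangles of both types
of a pair), and per-cancer-type means with normal-approximation 95% CIs
($\bar x \pm 1.96\,s/\sqrt{n}$) by `triangleTypeCancerSummary()`, which
excludes cancer types with fewer than 10 triangle-bearing samples.

# The synthetic-data generator

`generateDataset()` emulates the features the pipeline is built to detect:

* **Recurrent loci.** Each chromosome carries `centers_per_chrom = 12` loci,
  one drawn uniformly inside the middle 60% of each of 12 equal bins, so any
  two loci are several Mb apart — far enough that clusters and their ±1 Mb
  copy-number flanks never interfere.
* **Planted cycles.** A cycle of size $k$ chains $k$ loci spanning two
  chromosomes; each breakend is jittered $N(0, 50^2)$ bp around its locus
  (well under $h_2 = 400$, so planted structure survives round 2). Triangle
  archetypes fix orientations and copy-number profiles: chromoplexy $I=0$
  all-neutral; templated-insertion $I=2$ all-gain; non-canonical
  chromothripsis $I=2$ gain–neutral–gain; chromotrikona $I=3$ all-neutral.
  Copy-number segments realize the profile as ±50 kb windows over a diploid
  baseline.
* **Background with within-sample dependency.** Half of each sample's
  background breakends fall (jittered) at 3 sample-specific active loci, the
  rest uniformly. Tumor breakpoints both concentrate at recurrent loci *and*
  co-occur within a sample; a fully uniform background would present the
  validation tests with data in which their alternative hypothesis is barely
  true.
* **Scale.** The default miniature cohort is 30 samples, 20 planted
  triangles (5 per archetype), 200 background adjacencies on a two-chromosome
  80 + 70 Mb genome. The compact genome keeps per-sample-chromosome
  breakpoint occupancy (~8) in the range where complex rearrangements live
  in real cohorts; spreading the same junctions over many chromosomes would
  leave most sample chromosomes below the three breakpoints the dispersion
  statistic needs.

Every dataset ships with a ground-truth manifest (planted cycle loci,
orientations, states, per-sample counts) checkable by `verifyManifest()` and
matchable against mined cycles by `recoverPlantedCycles()`.

What the generator does **not** emulate: mutational-signature or replication
biology, read-level artifacts, clustered *non-cyclic* complex events,
sample-to-sample heterogeneity in SV burden, sub-clonal copy number, or
realistic chromosome counts. Passing tests therefore show that the
implementation recovers the structures it defines under calibrated noise —
not that the biological claims transfer to any particular cohort.

# Problem sizes used by the tests

The test-suite runs use the generator defaults above (30 samples, ~260
adjacencies), 100 pooled-breakpoint simulations for the validation tests, 50
edge-switched datasets for the Abundance checks, 100 random graphs of up to
10 vertices for the mining oracle, and 40 repetitions of a 10-sample
null-calibrated dataset for the Z-test calibration check. These sizes were
chosen as the smallest at which each property is statistically unambiguous.

# Known limitations

* Positions are treated per chromosome; inter-chromosomal distance has no
  meaning, which is correct for clustering but means the dispersion
  statistic ignores samples whose breakpoints are spread one-per-chromosome.
* The switching chain has no convergence diagnostic beyond the fixed
  $100 \times E$ budget.
* The classification thresholds are conventions, not fitted quantities; on
  real data they should be stress-tested with the exposed arguments.
* Cycle mining is exponential in the worst case; the size cap at 6 and the
  sparsity of deduplicated SV graphs keep it fast in practice, but extremely
  dense graphs (hundreds of edges in one sample) would be slow.
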