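# svcycles

Detection and classification of complex structural-variant (SV) patterns in
tumor genomes from breakend call sets.

Cancer genomes carry chains of rearrangements — chromoplexy, chromothripsis,
templated-insertion cycles — whose junctions tie together recurrent breakpoint
loci. `svcycles` is for researchers who have per-sample SV calls (VCF breakend
records or BEDPE junctions, optionally with total copy-number segments) and
want to find and classify the closed cycles those junctions form, with
statistical backing for every step.

## Method

1. **Two-step KDE clustering.** Per sample and chromosome, breakpoint
   positions x_i are smoothed with a Gaussian kernel density estimate,
   f̂(x) = (1 / n h √(2π)) Σ_i exp(−(x − x_i)² / 2h²), and every breakpoint is
   assigned to its nearest density mode (mode hunting). A first round at
   bandwidth h₁ = 1000 bp removes junctions looping inside a single cluster;
   a second round at h₂ = 400 bp re-clusters each surviving cluster at higher
   resolution. Intra-/inter-cluster distance diagnostics (`bandwidthSweep`)
   support the bandwidth choice.
2. **Permutation validation.** Simulated datasets pool all breakpoints
   (positions preserved), re-deal them to samples preserving per-sample
   counts, and re-pair them at random. One-sample Z-tests compare the
   observed average gap dispersion and average cluster density (breakpoints
   per cluster) against the simulated distribution.
3. **Cycle mining.** Each sample becomes a graph: cluster centers are
   vertices, deduplicated junctions are edges. Depth-first search enumerates
   every simple closed cycle of size 3–6 (each vertex of degree 2 in the
   cycle), deduplicated by canonical edge-set keys. Per size, the cohort
   table reports confidence (samples with ≥ 1 occurrence), frequency (total
   occurrences) and average (frequency / confidence).
4. **Abundance against an edge-switching null.** Degree-preserving
   randomization repeatedly replaces edges A–B, C–D with A–D, C–B (rejecting
   self-loops and duplicates) for 100 × E attempted moves, E the total edge
   count. For each pattern, Δ = (f_input − f̄_random) / (f_input + f̄_random + ε)
   with pseudo-count ε = 1; Δ ranges from −1 (depleted) to +1 (enriched), and
   the single-edge control sits at exactly 0 because edge counts are
   conserved.
5. **Triangle classification.** Size-3 cycles are subtyped from junction
   orientation (I = number of inverted junctions) and per-cluster copy-number
   states (local segment vs. ±1 Mb flank median): oscillating states with
   I ≥ 2 → non-canonical chromothripsis; a gain with I ≥ 2 →
   templated-insertion cycle; all neutral with I ≥ 2 → chromotrikona; no gain
   with I ≤ 1 → chromoplexy.

A synthetic-data generator (`generateDataset`) plants cycles of known
archetypes over recurrent loci with step-wise copy-number profiles and emits
a ground-truth manifest, so the whole pipeline is testable without any
external data.

## Worked example

```r
library(svcycles)
gen <- generateDataset(simulationConfig(seed = 1))   # 30 samples, 20 planted
dataset <- gen$dataset                               # triangles, background
dataset
#> SVDataset: 260 adjacencies in 30 sample(s); 2 chromosome(s)
#>   copy-number segments: 110
#>   cancer types: 2 label(s)

svc <- twoStepClustering(dataset)
svc
#> SVClusters: 315 final cluster(s), 480 assigned breakend(s), 20 loop adjacency(ies) discarded

graphs   <- buildSampleGraphs(svc)
cycleSet <- enumerateCycles(graphs)
patternStatistics(cycleSet)
#>   pattern size confidence average frequency no_occurrence
#> 1 cycle_3    3         20     1.1        22         FALSE
#> 2 cycle_4    4          0     0.0         0          TRUE
#> ...

clusterPermutationTest(dataset, n_datasets = 100, seed = 2)
#>         statistic  observed  sim_mean      z p_two_sided
#> 1      dispersion 8.704e+06 7.176e+06  4.876   1.080e-06
#> 2 cluster_density 1.524e+00 1.143e+00 26.798  3.443e-158

ens <- randomizedEnsemble(graphs, switchingConfig(n_datasets = 50, seed = 3))
motifAbundanceReport(cycleSet, graphs, ens)
#>   pattern f_input f_random_mean delta n_datasets epsilon
#> 1    edge     235           235 0.000         50       1
#> 2 cycle_3      22             0 0.957         50       1
#> ...

calls <- classifyTriangles(cycleSet, graphs, adjacencies(svc),
                           cnSegments(dataset))
table(calls$label)
#>                 chromoplexy               chromotrikona
#>                           6                           6
#> noncanonical_chromothripsis   templated_insertion_cycle
#>                           5                           5
```

Reading: the 20 planted triangles (plus two formed by background junctions at
shared loci) are all mined; both validation tests reject random clustering
(p ≪ 0.01); triangles are strongly enriched over the switching null
(Δ = 0.96) while the single-edge control is exactly 0; and the four planted
archetypes are labeled correctly.

The same pipeline runs from the shell via the thin CLI:

```sh
Rscript inst/cli/svcycles.R run-all --config config.yaml --out results/
```

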