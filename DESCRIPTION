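Package: svcycles
Title: Breakpoint Clustering and Cycle-Motif Mining for Complex
    Structural Variant Patterns in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies complex structural-variant (SV)
    patterns from breakend call sets. Breakpoints are clustered per
    sample and chromosome with a recursive two-step Gaussian kernel
    density mode-hunting scheme, validated against pooled-breakpoint
    permutation nulls with one-sample Z-tests. Per-sample rearrangement
    graphs (cluster centers as vertices, deduplicated junctions as
    edges) are mined for simple closed cycles of size 3 to 6 by
    depth-first search with canonical deduplication. Pattern
    significance is measured by the Abundance statistic against a
    degree-preserving edge-switching null, and size-3 cycles are
    subclassified into chromoplexy, templated-insertion cycles,
    non-canonical chromothripsis and chromotrikona using junction
    orientation and copy-number states. Includes a synthetic-data
    generator with ground-truth manifests, readers/writers for VCF
    breakend, BEDPE and copy-number segment formats, and a pipeline
    driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
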