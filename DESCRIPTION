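Package: cenwalk
Title: Chromosome Walking Assembly and CENP-A ChIP-Seq Domain Mapping for
    Satellite-Free Centromeres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for resolving misassembled satellite-free
    centromeric loci and mapping CENP-A binding domains. Provides a seeded
    synthetic-data generator (corrupted draft references with false tandem
    duplications, N-gaps and unplaced duplicate contigs; paired-end ChIP/input
    and WGS reads; long reads), an iterative chromosome-walking assembler that
    closes gaps by exact query retrieval and consensus extension, reference
    patching with a coordinate liftover map and N-content QC, a minimal
    unique-best read placer with RPKM-subtractive ChIP-minus-input profiling,
    a window/gap Poisson island caller with Benjamini-Hochberg FDR filtering,
    and a cross-tissue domain comparator that classifies centromere position
    conservation versus sliding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
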