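Package: poolscape
Title: Pool-Seq Population Genomics and Transposable-Element Dynamics
Version: 0.1.0
Authors@R: person("poolscape", "maintainers", email = "poolscape@example.org",
    role = c("aut", "cre"))
Description: Pooling-corrected estimators of nucleotide diversity, Watterson's
    theta and Tajima's D from pooled short-read sequencing (pool-seq), the
    bottleneck statistic delta-theta = 1 - pi/theta, windowed pairwise FST and
    major-allele absolute divergence (dXY), signature-based transposable-element
    (TE) insertion frequency estimation, read-versus-library TE divergence
    landscapes, genome-architecture window composition, telomeric-motif scans,
    and a coalescent-backed synthetic pool-seq generator with complete ground
    truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
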