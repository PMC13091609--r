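Package: nanotrace
Title: Reference-Guided Visualization and Comparison of Nanopore Ionic Current Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts nanopore ionic current segments at reference positions
    using basecaller move tables together with conventional BAM alignments,
    and compares experimental conditions through per-position summary
    statistics, kernel density estimates, UMAP embeddings, Gaussian mixture
    clustering, Kolmogorov-Smirnov tests and Jensen-Shannon divergence.
    Includes a ground-truthed synthetic fixture generator (signal store +
    tagged BAM) so every stage is testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    arrow,
    mclust,
    MASS,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
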