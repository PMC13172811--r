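Package: issm
Title: In Silico Sequence Mining of Probe Panels in Raw Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probe-based screening of raw FASTQ/FASTA sequencing data
    without alignment. Short user-defined nucleotide probes, including
    degenerate IUPAC primers, are matched approximately against reads on
    both strands using an insertion/deletion similarity score (partial
    ratio), with uniform read subsampling, batched parallel screening,
    tabular and graphical reporting, and downsampling reliability
    statistics (extraction-fraction regression, back-calculation of
    full-data matched-read counts, and relative-error decay models).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    grid,
    parallel,
    Rcpp,
    Biostrings,
    jsonlite,
    pheatmap,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
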