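# issm — in silico sequence mining of probe panels in raw sequencing reads

`issm` screens raw FASTQ/FASTA sequencing data for short user-defined
nucleotide probes — published PCR primers, hybridization probes, or custom
sequences, including degenerate IUPAC primers — without alignment, reference
genomes, or database construction. It is aimed at rapid pre-alignment
triage: panel sanity checks, pathogen screening of public datasets,
contamination flags, and candidate prioritisation ahead of confirmatory
alignment-based analysis.

## The method

A read `r` matches a probe `p` when their **partial ratio** reaches a
user-chosen threshold. The partial ratio is the maximum, over every
contiguous substring `w` of the read, of the indel similarity

```
sim(p, w) = 100 · 2 · LCS(p, w) / (|p| + |w|)
```

where `LCS` is the longest-common-subsequence length. Equivalently,
`sim = 100 · (1 − d/(|p|+|w|))` with `d` the insertion/deletion edit
distance (a substitution costs one deletion plus one insertion). A score of
100 means some expansion of the probe occurs exactly in the read. Each read
is compared on both strands (its reverse complement is screened too) and
against every unambiguous expansion of a degenerate probe; the decision is
inclusive (`score ≥ threshold`). Reads shorter than a probe are excluded
from that probe's matching. For a 20-mer probe, one interior substitution
in an embedded copy scores exactly 95, which anchors the recommended
95–100% threshold band.

Files can be uniformly subsampled before screening (integer 1–100%
extraction, with a 5,000-read floor for FASTQ, double-pass so files never
need to fit in memory). Reads are screened in batches (default 500) across
parallel workers; results are independent of worker count and batch size.

For reduced-extraction screening, the package also implements the
downsampling reliability analysis: a linear regression of detected
proportion on extraction fraction, back-calculation of 100%-equivalent
matched counts (`ĉ₁₀₀ = 100 · c_obs / (a·x + b)`), relative error, an
error-decay model `err(m) = A·e^(−B·log₁₀ m)` fitted per extraction
fraction, and its inversion to matched-read thresholds for a tolerated
error.

## Worked example

Plant known probe copies into a synthetic, certified probe-free background
and screen it back:

```r
library(issm)
td <- tempfile(); dir.create(td)

panel <- parseProbeFasta(
  ">FcovF\nGATTTGATTTGGCAATGCTAGATTT\n>Chu-RdRp-N1-F\nGGKTGGGAYTAYCCKAARTG\n")
panel
#> ProbePanel with 2 probes
#>   FcovF  GATTTGATTTGGCAATGCTAGATTT (25 bp, 1 expansion)
#>   Chu-RdRp-N1-F  GGKTGGGAYTAYCCKAARTG (20 bp, 32 expansions)

generateFixture(nReads = 500, readLen = 100,
    plants = list(list(probe = "FcovF", copies = 12),
                  list(probe = "Chu-RdRp-N1-F", copies = 5, strand = "-")),
    panel = panel, threshold = 95, format = "fastq", seed = 42,
    outPath = file.path(td, "sample.fastq.gz"))

res <- runScreen(file.path(td, "sample.fastq.gz"), panel,
    ScreenConfig(threshold = 100, jobs = 2, seed = 1))
matchCounts(res)
#>              file         probe matched total percent
#> 1 sample.fastq.gz         FcovF      12   500     2.4
#> 2 sample.fastq.gz Chu-RdRp-N1-F       5   500     1.0
```

All 12 planted `FcovF` copies and all 5 reverse-strand degenerate
`Chu-RdRp-N1-F` copies are recovered; the percentages are matched reads
over selected reads. `writeOutputs(res, outdir)` writes the per-file
results, the timestamped run summary, `total_results.txt` and the
matched-read FASTA; `renderPlots(res, outdir)` adds 300-dpi bar charts and
the probes × files percentage heatmap.

Published probe panels used throughout the tests ship under
`inst/extdata/` (`hiv_probes.fasta`, `coronavirus_probes.fasta`,
`kras_probes.fasta`, and the 105-bp ladder anchor).

A command-line wrapper is installed with the package:

```sh
issm=$(Rscript -e 'cat(system.file("scripts", "issm", package = "issm"))')
$issm screen --probes panel.fasta --input data/ --format fastq \
    --threshold 100 --extract 100 --jobs 4 --seed 1 --out results/
$issm ladder --anchor anchor.fasta --min 5 --max 105 --out ladder.fasta
$issm fixture --config fixture.json --out fixtures/
$issm downsample-stats --counts counts.tsv --out stats/
```

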