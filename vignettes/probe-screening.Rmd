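---
title: "Probe screening of raw reads: model, parameters, and design notes"
author: "issm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe screening of raw reads: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issm)
```

## The screening model

`issm` decides whether a sequencing read contains a copy of a short
nucleotide probe by approximate substring matching. The similarity between
a probe $p$ and a read window $w$ is the indel ratio

$$\mathrm{sim}(p, w) = 100 \cdot \frac{2\,\mathrm{LCS}(p, w)}{|p| + |w|},$$

where $\mathrm{LCS}$ is the longest-common-subsequence length. This equals
$100\,(1 - d/(|p|+|w|))$ with $d$ the insertion/deletion edit distance: a
substitution is charged as one deletion plus one insertion, which is the
metric behind the partial-ratio family of fuzzy string scores. The
**partial ratio** is the maximum of $\mathrm{sim}$ over *every* contiguous
substring of the read; that exhaustive maximum is the contract of
`partialRatio()`, and the pruned production scorer is required (and
tested) to agree with a deliberately naive exhaustive scorer exactly, not
approximately.

Three modelling consequences are worth knowing:

* a score of 100 is attained exactly when some unambiguous expansion of
  the probe occurs verbatim in the read (given the read is long enough);
* for a 20-mer probe, a single **interior** substitution in an embedded
  copy scores exactly $200 \cdot 19/40 = 95$ and a double interior
  substitution $90$. A substitution at the first or last base scores
  $200 \cdot 19/39 \approx 97.4$ instead, because the best window simply
  drops the mutated edge base — the same value as a single deletion. This
  asymmetry is inherent to window-maximising indel scores and is why the
  practical threshold band is 95–100 rather than a single cutoff;
* `N` in a read is treated as a literal character that matches no probe
  base, so uncalled positions can only lower a score.

Each read is screened on both strands: probe expansions are compared
against the read and against its reverse complement, the final score is
the maximum, and ties between strands report `+`. The match decision is
inclusive (`score >= threshold`). Reads shorter than a probe are excluded
from that probe's matching but remain in the per-file denominator, since
one selected-read total is reported per file.

Scores are kept as doubles and never rounded before the threshold
comparison; whether upstream tools round at this point is unknowable from
their outputs, and not rounding is the conservative choice for an
inclusive comparison.

## Degenerate probes

Probes may use the full IUPAC ambiguity alphabet (plus `U`, normalised to
`T` on ingest, since many published panels are RNA-virus primers written
as RNA). A degenerate probe denotes the set of all its unambiguous
expansions; its score against a read is the maximum over expansions.
Expansions are computed once at panel construction and cached, in a fixed
deterministic order (per-position alternatives sorted A<C<G<T, rightmost
position varying fastest) so caches and outputs are reproducible. The
expansion count is the product of per-position degeneracies; a cap
(default 4,096 per probe, configurable) turns combinatorial blow-ups into
a refusal reporting the count rather than a silent memory problem.
Lowercase input is accepted and uppercased, because FASTA dialects vary.
Probe names are the full whitespace-trimmed header line; published panels
use names with internal spaces, so taking only the first token would
create collisions.

## Sampling

Subsampling before screening trades sensitivity for speed. The plan for a
file of $N$ records at ratio $r$ (an integer percent, 1–100) targets
$n = \min(N, \max(\lceil N r / 100\rceil, f))$ records, with a floor of
$f = 5000$ for FASTQ and $f = 1$ for FASTA. Two orderings were open:
we apply the floor first and then cap at $N$, so a 4,000-read file yields
all 4,000 reads at any ratio — the floor exists to protect small samples,
and truncating it at the file size is the only interpretation that never
discards data the floor was meant to keep. `ceiling` (rather than
rounding) guarantees at least one record at tiny $N$. Indices are drawn
uniformly without replacement and kept sorted, so extraction preserves
file order and copies records byte-identically; FASTQ uses two streaming
passes (count, then extract) with gzip temporaries, FASTA is subsampled in
memory. The seed is surfaced in the API and CLI; paired-end mates are
sampled independently per file.

## Orchestration

Sampled reads are screened in batches (default 500 records) across a
worker pool (`parallel::mclapply`; default worker count is the available
cores, capped at the number of pending batches). Because per-read scoring
is deterministic and counts are merged by elementwise summation —
associative and order-invariant — results are identical for any worker
count or batch size, and the tests assert byte-identical output tables
across those settings. Failed files are recorded in the run summary and do
not abort a run. A per-file excluded-short-read count is reported as an
extension of the summary.

## Outputs

Per-file results, a timestamped cross-file summary
(`summary_result_<YYYYMMDD_HHMMSS>.txt`; the timestamp is injectable so
output sets can be byte-stable), an aggregated `total_results.txt`
(tab-delimited: file, probe, matched, total, percent), and a per-file
matched-read FASTA with one entry per (read, probe) pair — a read matched
by two probes appears twice, keeping every hit traceable to downstream
validation. Percentages print with four decimals because real detections
go below 0.01%. Plots (per-file and per-probe bar charts, and a
probes × files percentage heatmap on a diverging blue–red palette) are
rendered straight into 300-dpi PNG file devices, so they work headless;
every plotted number is recomputable from `total_results.txt`. Within the
per-file results the per-read column order is (read_id, probe, score,
strand).

## Downsampling reliability

Screening at reduced extraction raises the question of what the
full-extraction matched count would have been. The analysis pools all
(probe, file) observations with a non-zero 100%-extraction reference
count (zero references leave the detected proportion undefined) and fits
ordinary least squares of the detected proportion
$y = 100\,c_x / c_{100}$ on the extraction fraction $x$, both in percent,
unweighted — pooling raw points rather than per-probe means, which is the
straightforward reading of a pooled scatter fit. Back-calculation inverts
the fit, $\hat c_{100} = 100\,c_x/(ax+b)$, and the relative error
$100\,|\hat c_{100} - c_{100}|/c_{100}$ is then modelled against the
full-data abundance $m = c_{100}$ as

$$\mathrm{err}(m) = A\,e^{-B \log_{10} m},$$

fitted by linearisation (least squares of $\ln \mathrm{err}$ on
$\log_{10} m$), matching the exponential form in which such trends are
reported. Inverting a fitted model at a tolerated error
$\varepsilon \le A$ gives the matched-read threshold
$m^\ast = 10^{\ln(A/\varepsilon)/B}$, rounded to the nearest integer
(thresholds are read counts). These thresholds are dataset-dependent
empirical guides, not universal cutoffs; full extraction remains the
recommended default when target abundance is unknown.

## Synthetic fixtures

`generateFixture()` builds the ground truth every pipeline stage is tested
against: background reads drawn from a configurable alphabet are
rejection-sampled until **no** background read reaches the certification
threshold against any panel probe on either strand — certification is an
exhaustive scan, not a probabilistic argument, so zero-match assertions
are exact. Planted probe copies (optionally mutated with exact
substitution/insertion/deletion loads, optionally reverse-complemented)
are inserted at random positions in dedicated host reads; each planted
read is additionally required to score exactly its copy's isolated score
for its own probe (no window spanning copy and background may inflate it)
and to stay below threshold for every other probe. The manifest records
per-plant copy numbers, mutation loads, strands and host read ids, and
serialises losslessly to JSON.

What the generator does **not** emulate: platform error profiles and
quality-score structure (FASTQ fixtures carry constant quality, which the
matcher ignores), coverage biases, duplicated reads, and real genomic
context around probe sites. Passing tests therefore demonstrate the
*screening logic* — exact recovery of planted material, strand symmetry,
threshold banding, sampling behaviour — on reads whose only structure is
the planted copies; they do not quantify sensitivity or specificity on
real libraries, where target-site representation and sequencing error
dominate.

## Numerical and design notes

* The scoring kernel is compiled (Rcpp). The production partial ratio
  extends an LCS dynamic-programming row per window start and stops
  scanning longer windows once even a perfect subsequence could not beat
  the running maximum — a bound that discards only provably suboptimal
  windows, so equality with the naive exhaustive scorer is exact. An
  exact-substring shortcut handles the common threshold-100 case first.
* Equality of the production and naive scorers is tested on a complete
  cross product of all probes up to 4 bp by all reads up to 7 bp over a
  three-letter alphabet, a seeded random draw from the larger
  6 bp × 10 bp corpus, and 1,000 random probe/read pairs at realistic
  lengths (probes to 25 bp, reads to 150 bp); the naive route is itself
  cross-checked against a base-R edit-distance oracle. These corpus sizes
  keep the complete-enumeration part exhaustive while the whole suite
  stays quick to run.
* Test problem sizes elsewhere follow the same principle: spike-in runs
  use a few hundred 70-bp reads, the sampling-floor check generates a
  200,000-read FASTQ on the fly, and the downsampling round trip uses
  hypergeometric draws (exact sampling without replacement) at five
  abundances in triplicate.
* Ladder panels anchor at the 5′ end with a growing 3′ extension, the
  construction used for published probe-length series, and name probes by
  length (`5bp`, `6bp`, ...).
* Degenerate inputs: empty panels, empty sampled files, all-zero runs and
  single-point regressions are either handled (zero-count summaries,
  all-zero heatmaps) or rejected with specific errors (degenerate
  designs, non-positive predicted proportions, thresholds above the decay
  amplitude).

## Known limitations

* No mapping coordinates, CIGARs, or quality-aware scoring: a match says
  a probe-like subsequence occurs in a read, not where it maps in a
  genome. Positive findings are preliminary and need alignment-based
  confirmation.
* The indel-ratio metric charges substitutions double; error-rich
  platforms with many true substitutions will see lower scores than a
  unit-cost edit distance would give.
* Degenerate probes with very high expansion counts multiply scoring cost
  linearly; the expansion cap guards memory, not time.
* The downsampling regression assumes detected proportion is linear in
  extraction fraction; at very low abundance the hypergeometric noise
  dominates and back-calculated estimates are unreliable — which is
  exactly what the error-decay thresholds quantify.
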