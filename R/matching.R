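# Similarity scoring: indel ratio, partial ratio, and per-read match
# decisions over both strands and all probe expansions.

#' Indel similarity ratio between two sequences
#'
#' Returns 100 * 2 * LCS(a, b) / (|a| + |b|), where LCS is the longest
#' common subsequence length. This equals 100 * (1 - d / (|a| + |b|)) with d
#' the insertion/deletion edit distance (a substitution costs one deletion
#' plus one insertion), the metric behind partial-ratio fuzzy matching.
#'
#' @param a,b non-empty sequences.
#' @return similarity in [0, 100]; 100 iff a == b.
#' @examples
#' indelRatio("ACGT", "ACGT")  # 100
#' indelRatio("AAAA", "CCCC")  # 0
#' @export
indelRatio <- function(a, b) {
    if (!nzchar(a) || !nzchar(b))
        stop("indel ratio requires non-empty sequences", call. = FALSE)
    .indel_ratio_cpp(toupper(a), toupper(b))
}

#' Partial ratio: best indel ratio over all read substrings
#'
#' The maximum of [indelRatio()] between the probe and every contiguous
#' substring of the read. 100 iff the probe occurs exactly as a substring.
#' The implementation prunes candidate windows only when they provably
#' cannot beat the running maximum, so it returns exactly the
#' exhaustive-substring value.
#'
#' @param probe unambiguous probe sequence.
#' @param read read sequence, at least as long as the probe (shorter reads
#'   must be excluded by the caller).
#' @return similarity in [0, 100].
#' @examples
#' partialRatio("ACGT", "TTACGTTT")  # 100
#' partialRatio("ACGT", "TTTT")      # 40: best window is a single T
#' @export
partialRatio <- function(probe, read) {
    if (!nzchar(probe) || !nzchar(read))
        stop("partial ratio requires non-empty sequences", call. = FALSE)
    if (nchar(read) < nchar(probe))
        stop("read is shorter than the probe; excluded from matching",
            call. = FALSE)
    .partial_ratio_cpp(toupper(probe), toupper(read))
}

# naive exhaustive reference scorer (every substring, fresh DP); used as an
# independent route in tests -- not the production path
.partialRatioNaive <- function(probe, read) {
    .partial_ratio_naive_cpp(toupper(probe), toupper(read))
}

#' Score one read against one probe and decide the match
#'
#' The read is compared on both strands: the plus strand scores each probe
#' expansion against the read, the minus strand against the read's reverse
#' complement. The probe score is the maximum over expansions and strands;
#' a read is a match when that score is greater than or equal to the
#' (inclusive) threshold. Reads shorter than the probe are excluded and get
#' no score. N (or any non-ACGT character) in a read matches nothing.
#'
#' @param read read sequence (character) or a list with `id` and `sequence`.
#' @param probe a [ProbePanel-class] of length 1, or an IUPAC sequence.
#' @param threshold inclusive match threshold in [0, 100].
#' @return a list with `status` ("match", "no_match" or "excluded"),
#'   `score` (NA when excluded) and `strand` ("+" or "-", "+" on ties).
#' @examples
#' scoreRead("GGACGG", "AY", threshold = 100)   # match via expansion "AC"
#' scoreRead("TTGGTT", "AACC", threshold = 100) # match on the minus strand
#' @export
scoreRead <- function(read, probe, threshold = 100) {
    if (is.list(read)) read <- read$sequence
    stopifnot(is.character(read), length(read) == 1L)
    if (is.character(probe)) probe <- ProbePanel("probe", probe)
    stopifnot(is(probe, "ProbePanel"), length(probe) == 1L)
    if (threshold < 0 || threshold > 100)
        stop("threshold must be in [0, 100]", call. = FALSE)
    res <- .score_batch_cpp(read, probe@expansions,
        as.integer(nchar(probe@sequences)))
    score <- res$score[1L, 1L]
    if (is.na(score))
        return(list(status = "excluded", score = NA_real_, strand = NA_character_))
    list(
        status = if (score >= threshold) "match" else "no_match",
        score  = score,
        strand = res$strand[1L, 1L]
    )
}

# Score a character vector of reads against a full panel.
# Returns list(score = reads x probes numeric matrix (NA = excluded),
#              strand = reads x probes character matrix).
.scoreReadsPanel <- function(reads, panel) {
    res <- .score_batch_cpp(reads, panel@expansions,
        as.integer(nchar(panel@sequences)))
    colnames(res$score) <- panel@names
    colnames(res$strand) <- panel@names
    res
}
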