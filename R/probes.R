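# Probe panels: FASTA ingestion, validation, IUPAC expansion, reverse
# complement, and anchored length-ladder construction.

.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

# code -> sorted base alternatives (A<C<G<T); built from Biostrings' map so
# the degeneracy table is the community-standard one
.iupac_alternatives <- local({
    m <- Biostrings::IUPAC_CODE_MAP
    lapply(stats::setNames(as.list(m), names(m)), function(s)
        sort(strsplit(s, "")[[1]]))
})

.IUPAC_COMPLEMENT <- c(
    A = "T", C = "G", G = "C", T = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", V = "B", D = "H", H = "D", N = "N"
)

.validate_probe_sequence <- function(seq, name = "<probe>") {
    chars <- strsplit(seq, "")[[1]]
    bad <- which(!chars %in% strsplit(.IUPAC_CHARS, "")[[1]])
    if (length(bad))
        stop(sprintf(
            "probe '%s': invalid character '%s' at position %d",
            name, chars[bad[1]], bad[1]), call. = FALSE)
    invisible(TRUE)
}

.normalize_probe_sequence <- function(seq) {
    seq <- toupper(seq)
    gsub("U", "T", seq, fixed = TRUE)
}

#' Construct a probe panel from names and sequences
#'
#' Sequences are uppercased, U is normalised to T, the IUPAC alphabet is
#' enforced, and all unambiguous expansions are computed and cached.
#'
#' @param names character vector of unique, non-empty probe names.
#' @param sequences parallel character vector of IUPAC nucleotide sequences.
#' @param maxExpansions refusal cap on expansions per probe (see
#'   [expandIUPAC()]).
#' @return a [ProbePanel-class].
#' @examples
#' ProbePanel(c("fwd", "deg"), c("ACGTACGT", "ACYGT"))
#' @export
ProbePanel <- function(names, sequences, maxExpansions = 4096L) {
    if (length(names) == 0L)
        stop("panel is empty", call. = FALSE)
    if (length(names) != length(sequences))
        stop("names and sequences must have equal length", call. = FALSE)
    names <- trimws(as.character(names))
    if (any(!nzchar(names)))
        stop("empty probe name", call. = FALSE)
    dup <- unique(names[duplicated(names)])
    if (length(dup))
        stop(sprintf("duplicate probe name(s): %s", paste(dup, collapse = ", ")),
            call. = FALSE)
    sequences <- .normalize_probe_sequence(as.character(sequences))
    if (any(!nzchar(sequences)))
        stop(sprintf("empty sequence for probe '%s'",
            names[!nzchar(sequences)][1]), call. = FALSE)
    for (i in seq_along(sequences))
        .validate_probe_sequence(sequences[i], names[i])
    expansions <- lapply(sequences, expandIUPAC, maxExpansions = maxExpansions)
    new("ProbePanel", names = names, sequences = sequences,
        expansions = expansions)
}

#' @rdname ProbePanel-class
#' @export
setMethod("probeNames", "ProbePanel", function(x) x@names)

#' @rdname ProbePanel-class
#' @export
setMethod("probeSequences", "ProbePanel",
    function(x) stats::setNames(x@sequences, x@names))

#' @rdname ProbePanel-class
#' @export
setMethod("probeExpansions", "ProbePanel",
    function(x) stats::setNames(x@expansions, x@names))

#' @rdname ProbePanel-class
#' @export
setMethod("probeLengths", "ProbePanel",
    function(x) stats::setNames(nchar(x@sequences), x@names))

#' @rdname ProbePanel-class
#' @export
setMethod("length", "ProbePanel", function(x) length(x@names))

#' @rdname ProbePanel-class
#' @param i index (numeric, logical or probe names)
#' @export
setMethod("[", "ProbePanel", function(x, i) {
    if (is.character(i)) i <- match(i, x@names)
    new("ProbePanel", names = x@names[i], sequences = x@sequences[i],
        expansions = x@expansions[i])
})

setMethod("show", "ProbePanel", function(object) {
    n <- length(object@names)
    cat(sprintf("ProbePanel with %d probe%s\n", n, if (n == 1L) "" else "s"))
    deg <- lengths(object@expansions)
    head_n <- min(n, 6L)
    for (i in seq_len(head_n))
        cat(sprintf("  %s  %s (%d bp, %d expansion%s)\n",
            object@names[i], object@sequences[i], nchar(object@sequences[i]),
            deg[i], if (deg[i] == 1L) "" else "s"))
    if (n > head_n) cat(sprintf("  ... and %d more\n", n - head_n))
})

#' Parse a probe panel from FASTA text or file
#'
#' Validates FASTA structure (leading ">" header), non-empty names and
#' sequences, unique names (the full whitespace-trimmed header line is the
#' name), and the IUPAC nucleotide alphabet. Multi-line sequences are
#' concatenated; lowercase is accepted and uppercased; U is normalised to T.
#'
#' @param text FASTA-formatted string (possibly multi-line).
#' @param path alternatively, path to a FASTA file (used when `text` is NULL).
#' @param maxExpansions per-probe expansion cap passed to [expandIUPAC()].
#' @return a [ProbePanel-class] with one probe per record, in file order.
#' @examples
#' parseProbeFasta(">p1\nACGT\n>p2\nAYGGT\n")
#' @export
parseProbeFasta <- function(text = NULL, path = NULL, maxExpansions = 4096L) {
    if (is.null(text)) {
        if (is.null(path)) stop("either text or path must be given", call. = FALSE)
        lines <- readLines(path, warn = FALSE)
    } else {
        lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
    }
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L)
        stop("empty probe input", call. = FALSE)
    if (!startsWith(trimws(lines[1]), ">"))
        stop("not FASTA: first non-blank line must start with '>'", call. = FALSE)
    is_header <- startsWith(trimws(lines), ">")
    rec <- cumsum(is_header)
    headers <- trimws(sub("^>", "", trimws(lines[is_header])))
    seqs <- vapply(seq_along(headers), function(k) {
        paste(trimws(lines[!is_header & rec == k]), collapse = "")
    }, character(1))
    if (any(!nzchar(headers)))
        stop("empty probe name in FASTA header", call. = FALSE)
    if (any(!nzchar(seqs)))
        stop(sprintf("empty sequence for probe '%s'", headers[!nzchar(seqs)][1]),
            call. = FALSE)
    ProbePanel(headers, seqs, maxExpansions = maxExpansions)
}

#' Write a probe panel as FASTA
#'
#' @param panel a [ProbePanel-class].
#' @param path output path; when NULL the FASTA text is returned invisibly.
#' @return the FASTA text, invisibly.
#' @export
writeProbeFasta <- function(panel, path = NULL) {
    stopifnot(is(panel, "ProbePanel"))
    txt <- paste0(">", panel@names, "\n", panel@sequences, collapse = "\n")
    if (!is.null(path)) writeLines(txt, path)
    invisible(txt)
}

#' Expand a degenerate IUPAC sequence into all unambiguous sequences
#'
#' Each ambiguity code is replaced by its base alternatives; the result
#' enumerates every combination in a fixed deterministic order: alternatives
#' at each position are sorted A<C<G<T and the rightmost position varies
#' fastest. The expansion count equals the product of per-position
#' degeneracies (1 for A/C/G/T, 2 for R/Y/S/W/K/M, 3 for B/D/H/V, 4 for N).
#'
#' @param sequence IUPAC nucleotide string (U accepted, normalised to T).
#' @param maxExpansions refusal cap: degenerate probes whose expansion count
#'   exceeds this are rejected with an error reporting the count, rather than
#'   silently consuming memory. Raise it to override.
#' @return character vector of unambiguous sequences over \{A,C,G,T\}.
#' @examples
#' expandIUPAC("AY")    # "AC" "AT"
#' expandIUPAC("ACGT")  # "ACGT"
#' @export
expandIUPAC <- function(sequence, maxExpansions = 4096L) {
    sequence <- .normalize_probe_sequence(sequence)
    .validate_probe_sequence(sequence)
    chars <- strsplit(sequence, "")[[1]]
    alts <- .iupac_alternatives[chars]
    count <- prod(lengths(alts))
    if (count > maxExpansions)
        stop(sprintf(
            "sequence expands to %.0f combinations, exceeding the cap of %d",
            count, maxExpansions), call. = FALSE)
    if (count == 1)
        return(sequence)
    # rightmost position varying fastest
    grid <- expand.grid(rev(alts), KEEP.OUT.ATTRS = FALSE,
        stringsAsFactors = FALSE)[, rev(seq_along(alts)), drop = FALSE]
    apply(as.matrix(grid), 1L, paste, collapse = "")
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Complements with the full IUPAC table (A<->T, C<->G, R<->Y, K<->M, B<->V,
#' D<->H; S, W, N self-complementary), then reverses. Applying it twice
#' returns the input.
#'
#' @param sequence IUPAC nucleotide string.
#' @return the reverse-complemented string.
#' @examples
#' reverseComplement("GGTCT")  # "AGACC"
#' reverseComplement("ARN")    # "NYT"
#' @export
reverseComplement <- function(sequence) {
    sequence <- .normalize_probe_sequence(sequence)
    .validate_probe_sequence(sequence)
    chars <- strsplit(sequence, "")[[1]]
    paste(rev(.IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Build an anchored probe length ladder
#'
#' Generates probes as 5' prefixes of an anchor sequence at lengths
#' `minLen`, `minLen + step`, ... up to `maxLen`, so each probe is a prefix
#' of the next. Names encode the probe length (e.g. "5bp"). Used to study
#' the effect of probe length on matched read counts.
#'
#' @param anchor unambiguous nucleotide sequence supplying the prefixes.
#' @param minLen,maxLen,step base counts; 1 <= minLen <= maxLen <=
#'   nchar(anchor), step >= 1.
#' @return a [ProbePanel-class] with floor((maxLen - minLen) / step) + 1 probes.
#' @examples
#' buildLengthLadder("GGTCTGAGGG", minLen = 5, maxLen = 10)
#' @export
buildLengthLadder <- function(anchor, minLen = 5L, maxLen = nchar(anchor),
                              step = 1L) {
    anchor <- .normalize_probe_sequence(anchor)
    .validate_probe_sequence(anchor, "<anchor>")
    minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
    step <- as.integer(step)
    if (minLen < 1L || minLen > maxLen)
        stop("need 1 <= minLen <= maxLen", call. = FALSE)
    if (maxLen > nchar(anchor))
        stop(sprintf("maxLen (%d) exceeds anchor length (%d)",
            maxLen, nchar(anchor)), call. = FALSE)
    if (step < 1L) stop("step must be >= 1", call. = FALSE)
    lens <- seq.int(minLen, maxLen, by = step)
    ProbePanel(sprintf("%dbp", lens), substring(anchor, 1L, lens))
}
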