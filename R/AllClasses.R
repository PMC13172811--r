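#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib issm, .registration = TRUE
NULL

#' ProbePanel: an ordered panel of (possibly degenerate) nucleotide probes
#'
#' A panel holds named IUPAC nucleotide probe sequences together with their
#' cached unambiguous expansions over \{A,C,G,T\}. Probes are stored in input
#' order; names are unique and non-empty. U is normalised to T on ingest and
#' sequences are uppercased.
#'
#' @slot names character vector of unique probe identifiers.
#' @slot sequences uppercase IUPAC nucleotide strings, parallel to names.
#' @slot expansions list of character vectors: all unambiguous expansions of
#'   each probe, in deterministic order (per-position alternatives sorted
#'   A<C<G<T, rightmost position varying fastest).
#'
#' @seealso [parseProbeFasta()], [expandIUPAC()], [buildLengthLadder()]
#' @export
setClass("ProbePanel",
    representation(
        names      = "character",
        sequences  = "character",
        expansions = "list"
    )
)

setValidity("ProbePanel", function(object) {
    msg <- character()
    if (length(object@names) == 0L)
        msg <- c(msg, "panel is empty")
    if (length(object@names) != length(object@sequences) ||
        length(object@names) != length(object@expansions))
        msg <- c(msg, "names, sequences and expansions must be parallel")
    if (anyDuplicated(object@names))
        msg <- c(msg, sprintf("duplicate probe name(s): %s",
            paste(unique(object@names[duplicated(object@names)]), collapse = ", ")))
    if (any(!nzchar(object@names)))
        msg <- c(msg, "empty probe name")
    if (any(!nzchar(object@sequences)))
        msg <- c(msg, "empty probe sequence")
    bad <- grepl(sprintf("[^%s]", .IUPAC_CHARS), object@sequences)
    if (any(bad))
        msg <- c(msg, sprintf("invalid characters in probe(s): %s",
            paste(object@names[bad], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ScreenConfig: parameters of a screening run
#'
#' @slot threshold inclusive match threshold, percent in [0, 100]; a read is
#'   a match for a probe when its best score over both strands and all
#'   expansions is greater than or equal to this value.
#' @slot extractRatio integer percent in [1, 100] of records to subsample
#'   from each input file before screening.
#' @slot batchSize records per scoring batch (default 500).
#' @slot jobs worker count for parallel batch scoring.
#' @slot seed integer seed driving subsampling; NA means entropy-seeded.
#'
#' @export
setClass("ScreenConfig",
    representation(
        threshold    = "numeric",
        extractRatio = "numeric",
        batchSize    = "integer",
        jobs         = "integer",
        seed         = "integer"
    ),
    prototype(
        threshold    = 100,
        extractRatio = 100,
        batchSize    = 500L,
        jobs         = 1L,
        seed         = NA_integer_
    )
)

setValidity("ScreenConfig", function(object) {
    msg <- character()
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold < 0 || object@threshold > 100)
        msg <- c(msg, "threshold must be a single value in [0, 100]")
    if (length(object@extractRatio) != 1L || is.na(object@extractRatio) ||
        object@extractRatio < 1 || object@extractRatio > 100 ||
        object@extractRatio != as.integer(object@extractRatio))
        msg <- c(msg, "extractRatio must be an integer percent in [1, 100]")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@jobs < 1L) msg <- c(msg, "jobs must be >= 1")
    if (length(msg)) msg else TRUE
})

#' ScreenResult: per-file, per-probe screening summaries plus match detail
#'
#' @slot counts data.frame with one row per (file, probe): columns `file`,
#'   `probe`, `matched`, `total`, `percent` (percent = 100 * matched / total,
#'   0 when total is 0).
#' @slot matches data.frame of per-read hits: `file`, `read_id`, `probe`,
#'   `score`, `strand`, and the matched read `sequence` (for FASTA export).
#' @slot files data.frame with one row per input file: `file`, `path`,
#'   `total_selected`, `excluded_short` (reads shorter than every probe they
#'   were excluded from, summed over probes), `status`, `message`.
#' @slot panel the [ProbePanel-class] screened.
#' @slot config the [ScreenConfig-class] used.
#' @slot elapsed elapsed wall-clock seconds.
#'
#' @export
setClass("ScreenResult",
    representation(
        counts  = "data.frame",
        matches = "data.frame",
        files   = "data.frame",
        panel   = "ProbePanel",
        config  = "ScreenConfig",
        elapsed = "numeric"
    )
)

#' ExtractionModel: linear regression of detected proportion on extraction fraction
#'
#' Models y = slope * x + intercept where x is the extraction fraction
#' (percent) and y the matched-count proportion relative to full extraction
#' (percent). Used to back-calculate 100%-equivalent matched read counts.
#'
#' @slot slope,intercept fitted coefficients (percent units).
#' @slot n number of observations fitted.
#' @export
setClass("ExtractionModel",
    representation(slope = "numeric", intercept = "numeric", n = "integer"))

setValidity("ExtractionModel", function(object) {
    if (!is.finite(object@slope) || !is.finite(object@intercept))
        "coefficients must be finite" else TRUE
})

#' ErrorDecayModel: relative error as a function of matched-read abundance
#'
#' Models err(m) = A * exp(-B * log10(m)), where m is the matched read count
#' at full (100%) extraction and err the relative error (percent) of the
#' back-calculated estimate.
#'
#' @slot A amplitude (percent): the predicted error at m = 1.
#' @slot B decay rate per decade of matched reads.
#' @slot n number of points fitted (0 for models built from known coefficients).
#' @export
setClass("ErrorDecayModel",
    representation(A = "numeric", B = "numeric", n = "integer"),
    prototype(n = 0L))

setValidity("ErrorDecayModel", function(object) {
    msg <- character()
    if (!is.finite(object@A) || object@A <= 0) msg <- c(msg, "A must be positive")
    if (!is.finite(object@B)) msg <- c(msg, "B must be finite")
    if (length(msg)) msg else TRUE
})
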