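# FASTQ/FASTA streaming, subsampling plans, and double-pass extraction.
#
# FASTQ is parsed as strict 4-line records with line-number diagnostics and
# sampled in two passes (count, then extract by index) so files never need
# to fit in memory; sampled FASTQ is written gzip-compressed. FASTA is
# handled in memory through Biostrings.

.SEQ_EXTENSIONS <- c(
    fastq = "\\.(fastq|fq)(\\.gz)?$",
    fasta = "\\.(fasta|fa|fna)(\\.gz)?$"
)

# evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream; seed NULL/NA means use the current stream
.with_seed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed))
        return(expr)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

.is_gzip <- function(path) {
    magic <- tryCatch(readBin(path, "raw", n = 2L), error = function(e) raw(0))
    if (length(magic) == 2L)
        return(magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    grepl("\\.gz$", path, ignore.case = TRUE)
}

.open_text <- function(path) {
    if (.is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
}

#' Detect sequence file format from a path
#'
#' @param path file path; extensions .fastq/.fq/.fasta/.fa/.fna with optional
#'   .gz are recognised.
#' @return "fastq" or "fasta".
#' @export
detectSeqFormat <- function(path) {
    for (fmt in names(.SEQ_EXTENSIONS))
        if (grepl(.SEQ_EXTENSIONS[[fmt]], path, ignore.case = TRUE))
            return(fmt)
    stop(sprintf("unsupported file extension: %s", basename(path)),
        call. = FALSE)
}

# stream a FASTQ file, calling handler(record_index, four_lines) for every
# record; validates 4-line structure and returns the record count
.stream_fastq <- function(path, handler = NULL, chunkLines = 40000L) {
    con <- .open_text(path)
    on.exit(close(con))
    buffer <- character(0)
    lineOffset <- 0L # global line number of the last consumed line
    nrec <- 0L
    repeat {
        chunk <- readLines(con, n = chunkLines, warn = FALSE)
        eof <- length(chunk) < chunkLines
        buffer <- c(buffer, chunk)
        ncomplete <- length(buffer) %/% 4L
        if (ncomplete > 0L) {
            use <- buffer[seq_len(ncomplete * 4L)]
            buffer <- buffer[-seq_len(ncomplete * 4L)]
            heads <- use[seq(1L, by = 4L, length.out = ncomplete)]
            seps <- use[seq(3L, by = 4L, length.out = ncomplete)]
            badh <- which(!startsWith(heads, "@"))
            if (length(badh))
                stop(sprintf(
                    "FASTQ parse error at line %d: record header must start with '@'",
                    lineOffset + (badh[1] - 1L) * 4L + 1L), call. = FALSE)
            bads <- which(!startsWith(seps, "+"))
            if (length(bads))
                stop(sprintf(
                    "FASTQ parse error at line %d: '+' separator expected",
                    lineOffset + (bads[1] - 1L) * 4L + 3L), call. = FALSE)
            seqs <- use[seq(2L, by = 4L, length.out = ncomplete)]
            quals <- use[seq(4L, by = 4L, length.out = ncomplete)]
            badq <- which(nchar(quals) != nchar(seqs))
            if (length(badq))
                stop(sprintf(
                    "FASTQ parse error at line %d: quality length differs from sequence length",
                    lineOffset + (badq[1] - 1L) * 4L + 4L), call. = FALSE)
            if (!is.null(handler))
                handler(nrec + seq_len(ncomplete), heads, seqs, quals, seps)
            nrec <- nrec + ncomplete
            lineOffset <- lineOffset + ncomplete * 4L
        }
        if (eof) break
    }
    if (length(buffer))
        stop(sprintf(
            "truncated FASTQ record at line %d: file has %d trailing line(s), not a multiple of 4",
            lineOffset + 1L, length(buffer)), call. = FALSE)
    nrec
}

#' Count records in a FASTQ/FASTA file
#'
#' First pass of double-pass sampling; also validates FASTQ structure.
#'
#' @param path sequence file, plain or gzip.
#' @param format "fastq" or "fasta"; detected from the extension by default.
#' @return integer record count.
#' @export
countSeqRecords <- function(path, format = detectSeqFormat(path)) {
    format <- match.arg(format, c("fastq", "fasta"))
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    if (format == "fastq")
        return(.stream_fastq(path))
    con <- .open_text(path)
    on.exit(close(con))
    n <- 0L
    repeat {
        chunk <- readLines(con, n = 40000L, warn = FALSE)
        n <- n + sum(startsWith(chunk, ">"))
        if (length(chunk) < 40000L) break
    }
    n
}

#' Read a FASTQ/FASTA file into memory
#'
#' @inheritParams countSeqRecords
#' @return a list with character vectors `id`, `sequence`, and `quality`
#'   (NULL for FASTA), in file order. Multi-line FASTA sequences are
#'   concatenated; gzip input is detected by magic bytes.
#' @export
readSeqFile <- function(path, format = detectSeqFormat(path)) {
    format <- match.arg(format, c("fastq", "fasta"))
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    if (format == "fasta") {
        set <- Biostrings::readDNAStringSet(path, format = "fasta")
        return(list(id = names(set), sequence = as.character(unname(set)),
            quality = NULL))
    }
    env <- new.env(parent = emptyenv())
    env$id <- list(); env$seq <- list(); env$qual <- list()
    .stream_fastq(path, function(idx, heads, seqs, quals, seps) {
        k <- length(env$id) + 1L
        env$id[[k]] <- sub("^@", "", heads)
        env$seq[[k]] <- seqs
        env$qual[[k]] <- quals
    })
    list(
        id = unlist(env$id, use.names = FALSE) %||% character(0),
        sequence = unlist(env$seq, use.names = FALSE) %||% character(0),
        quality = unlist(env$qual, use.names = FALSE) %||% character(0)
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plan a uniform subsample of sequence records
#'
#' The target size is ceil(N * ratio / 100), raised to a floor of 5,000
#' records for FASTQ (1 for FASTA), then capped at N. Indices are drawn
#' uniformly without replacement and returned sorted, so extraction
#' preserves file order; the draw is reproducible given `seed`.
#'
#' @param N total record count (first-pass count).
#' @param ratio integer extraction percent in [1, 100].
#' @param format "fastq" (5,000-record floor) or "fasta" (no floor).
#' @param seed integer seed; NULL draws from the current RNG stream.
#' @return a list with `total`, `ratio`, `n`, sorted 1-based `indices`,
#'   `format` and `seed`.
#' @examples
#' planSample(200000, 1, "fastq", seed = 1)$n  # 5000: the FASTQ floor
#' @export
planSample <- function(N, ratio, format = c("fastq", "fasta"), seed = NULL) {
    format <- match.arg(format)
    if (length(ratio) != 1L || is.na(ratio) || ratio < 1 || ratio > 100 ||
        ratio != as.integer(ratio))
        stop("ratio must be an integer percent in [1, 100]", call. = FALSE)
    N <- as.integer(N)
    if (is.na(N) || N < 0L) stop("N must be a non-negative count", call. = FALSE)
    floorN <- if (format == "fastq") 5000L else 1L
    n <- min(N, max(as.integer(ceiling(N * ratio / 100)), floorN))
    indices <- if (n == N) seq_len(N) else
        .with_seed(seed, sort(sample.int(N, n)))
    list(total = N, ratio = as.integer(ratio), n = n, indices = indices,
        format = format, seed = seed)
}

#' Extract the records selected by a sampling plan
#'
#' Second pass of double-pass sampling: copies exactly the planned records,
#' in original order and byte-identical content, to `outPath`. FASTQ output
#' is gzip-compressed when `outPath` ends in .gz; FASTA sampling runs in
#' memory. Errors if the file's record count no longer matches the plan.
#'
#' @param path source sequence file.
#' @param plan a plan from [planSample()].
#' @param outPath destination path (.gz suffix enables compression).
#' @return the achieved record count, invisibly.
#' @export
extractSample <- function(path, plan, outPath) {
    keep <- logical(plan$total)
    keep[plan$indices] <- TRUE
    if (plan$format == "fasta") {
        set <- Biostrings::readDNAStringSet(path, format = "fasta")
        if (length(set) != plan$total)
            stop(sprintf(
                "file changed between passes: %d records found, plan expected %d",
                length(set), plan$total), call. = FALSE)
        Biostrings::writeXStringSet(set[keep], outPath,
            compress = grepl("\\.gz$", outPath))
        return(invisible(plan$n))
    }
    out <- if (grepl("\\.gz$", outPath)) gzfile(outPath, "w") else
        file(outPath, "w")
    written <- 0L
    nrec <- tryCatch({
        .stream_fastq(path, function(idx, heads, seqs, quals, seps) {
            sel <- idx <= plan$total & keep[pmin(idx, plan$total)]
            if (any(sel)) {
                writeLines(rbind(heads[sel], seqs[sel], seps[sel],
                    quals[sel]), out)
                written <<- written + sum(sel)
            }
        })
    }, finally = close(out))
    if (nrec != plan$total)
        stop(sprintf(
            "file changed between passes: %d records found, plan expected %d",
            nrec, plan$total), call. = FALSE)
    invisible(written)
}
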