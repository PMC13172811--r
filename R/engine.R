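# Screening orchestration: per-file sampling, batch decomposition,
# parallel scoring, and deterministic aggregation.

#' Construct a screening configuration
#'
#' @param threshold inclusive match threshold, percent in [0, 100].
#' @param extractRatio integer percent of records to subsample per file.
#' @param batchSize records per scoring batch.
#' @param jobs worker processes for batch scoring; defaults to the available
#'   core count, and is capped at the number of pending batches per file.
#' @param seed integer seed for subsampling; NA leaves the RNG stream alone.
#' @return a [ScreenConfig-class].
#' @export
ScreenConfig <- function(threshold = 100, extractRatio = 100,
                         batchSize = 500L, jobs = NULL, seed = NA) {
    if (is.null(jobs))
        jobs <- max(1L, parallel::detectCores(logical = FALSE))
    new("ScreenConfig", threshold = as.numeric(threshold),
        extractRatio = as.numeric(extractRatio),
        batchSize = as.integer(batchSize), jobs = as.integer(jobs),
        seed = as.integer(seed))
}

setMethod("show", "ScreenConfig", function(object) {
    cat(sprintf(
        "ScreenConfig: threshold %g%%, extract %g%%, batch %d, jobs %d, seed %s\n",
        object@threshold, object@extractRatio, object@batchSize, object@jobs,
        if (is.na(object@seed)) "<none>" else object@seed))
})

# empty per-probe count vector for a panel
.zeroCounts <- function(panel) {
    stats::setNames(integer(length(panel)), panel@names)
}

#' Score a batch of reads against a panel
#'
#' Every read is scored against every probe on both strands; a read matched
#' by k probes contributes one count to each of the k probes (a read
#' matching a probe on both strands still counts once). Reads shorter than
#' a probe are excluded from that probe's matching.
#'
#' @param records list with `id` and `sequence` character vectors (quality
#'   is ignored), as returned by [readSeqFile()].
#' @param panel a [ProbePanel-class].
#' @param threshold inclusive match threshold in [0, 100].
#' @return a list with `counts` (named integer vector, one per probe),
#'   `matches` (data.frame read_id/probe/score/strand/sequence) and
#'   `excluded` (number of (read, probe) pairs skipped as too short).
#' @export
screenBatch <- function(records, panel, threshold = 100) {
    stopifnot(is(panel, "ProbePanel"))
    reads <- toupper(records$sequence)
    if (length(reads) == 0L)
        return(list(counts = .zeroCounts(panel),
            matches = .emptyMatches(), excluded = 0L))
    res <- .scoreReadsPanel(reads, panel)
    hit <- !is.na(res$score) & res$score >= threshold
    counts <- stats::setNames(as.integer(colSums(hit)), panel@names)
    idx <- which(hit, arr.ind = TRUE)
    matches <- data.frame(
        read_id = records$id[idx[, 1L]],
        probe   = panel@names[idx[, 2L]],
        score   = res$score[hit],
        strand  = res$strand[hit],
        sequence = reads[idx[, 1L]],
        stringsAsFactors = FALSE
    )
    # keep read order, then panel order, for stable output
    matches <- matches[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    rownames(matches) <- NULL
    list(counts = counts, matches = matches,
        excluded = sum(is.na(res$score)))
}

.emptyMatches <- function() {
    data.frame(read_id = character(0), probe = character(0),
        score = numeric(0), strand = character(0), sequence = character(0),
        stringsAsFactors = FALSE)
}

#' Merge per-probe count vectors
#'
#' Elementwise sum over partial counts sharing the same probe set;
#' associative and order-invariant. An empty list yields all-zero counts.
#'
#' @param partials list of named integer vectors over the panel's probes.
#' @param panel the [ProbePanel-class] defining the probe set.
#' @return named integer vector of summed counts.
#' @export
mergeCounts <- function(partials, panel) {
    out <- .zeroCounts(panel)
    for (p in partials) {
        if (!setequal(names(p), names(out)) ||
            length(p) != length(out))
            stop("probe set mismatch between partial counts", call. = FALSE)
        out <- out + p[names(out)]
    }
    out
}

# screen one (already sampled) record set: batches + parallel scoring
.screenRecords <- function(records, panel, config) {
    n <- length(records$id)
    if (n == 0L)
        return(list(counts = .zeroCounts(panel), matches = .emptyMatches(),
            excluded = 0L, total = 0L))
    starts <- seq.int(1L, n, by = config@batchSize)
    batches <- lapply(starts, function(s) {
        e <- min(s + config@batchSize - 1L, n)
        list(id = records$id[s:e], sequence = records$sequence[s:e])
    })
    jobs <- min(config@jobs, length(batches))
    results <- if (jobs > 1L) {
        parallel::mclapply(batches, screenBatch, panel = panel,
            threshold = config@threshold, mc.cores = jobs)
    } else {
        lapply(batches, screenBatch, panel = panel,
            threshold = config@threshold)
    }
    err <- vapply(results, inherits, logical(1), "try-error")
    if (any(err))
        stop("batch scoring failed: ", results[[which(err)[1]]], call. = FALSE)
    counts <- mergeCounts(lapply(results, `[[`, "counts"), panel)
    matches <- do.call(rbind, lapply(results, `[[`, "matches"))
    rownames(matches) <- NULL
    list(counts = counts, matches = matches,
        excluded = sum(vapply(results, `[[`, integer(1), "excluded")),
        total = n)
}

# sample one input file per config; returns records (possibly via a gzip
# temporary for FASTQ) and the selected count
.sampleFile <- function(path, format, config, tmpdir) {
    N <- countSeqRecords(path, format)
    plan <- planSample(N, config@extractRatio, format,
        seed = if (is.na(config@seed)) NULL else config@seed)
    if (plan$n == plan$total) {
        records <- readSeqFile(path, format)
    } else if (format == "fastq") {
        tmp <- file.path(tmpdir, paste0("sampled_", basename(path)))
        if (!grepl("\\.gz$", tmp)) tmp <- paste0(tmp, ".gz")
        extractSample(path, plan, tmp)
        records <- readSeqFile(tmp, "fastq")
        unlink(tmp)
    } else {
        records <- readSeqFile(path, format)
        records <- list(id = records$id[plan$indices],
            sequence = records$sequence[plan$indices], quality = NULL)
    }
    list(records = records, n = plan$n)
}

#' Run a probe screen over a set of sequence files
#'
#' For each file: count records, subsample per the configured extraction
#' ratio (double-pass with gzip temporaries for FASTQ), partition into
#' batches, score the batches against the shared panel across workers, and
#' merge counts. Results are fully determined by (files, panel, config,
#' seed) regardless of worker count or batch size. Unreadable files are
#' recorded as failed entries and the run continues.
#'
#' @param files character vector of FASTQ/FASTA paths, or a directory to
#'   scan recursively for files of `format`.
#' @param panel a [ProbePanel-class].
#' @param config a [ScreenConfig-class].
#' @param format "fastq" or "fasta"; detected per file when NULL.
#' @return a [ScreenResult-class].
#' @export
runScreen <- function(files, panel, config = ScreenConfig(), format = NULL) {
    stopifnot(is(panel, "ProbePanel"), is(config, "ScreenConfig"))
    validObject(config)
    if (length(files) == 1L && dir.exists(files)) {
        stopifnot(!is.null(format))
        files <- sort(list.files(files, pattern = .SEQ_EXTENSIONS[[format]],
            recursive = TRUE, full.names = TRUE, ignore.case = TRUE))
    }
    if (length(files) == 0L) stop("no input files", call. = FALSE)
    t0 <- proc.time()[["elapsed"]]
    tmpdir <- tempfile("issm_sample_")
    dir.create(tmpdir)
    on.exit(unlink(tmpdir, recursive = TRUE))

    countRows <- list(); matchRows <- list(); fileRows <- list()
    for (path in files) {
        fname <- basename(path)
        fmt <- if (is.null(format)) tryCatch(detectSeqFormat(path),
            error = function(e) NA_character_) else format
        res <- tryCatch({
            if (is.na(fmt)) stop("unsupported file extension", call. = FALSE)
            sampled <- .sampleFile(path, fmt, config, tmpdir)
            scr <- .screenRecords(sampled$records, panel, config)
            scr
        }, error = function(e) e)
        if (inherits(res, "error")) {
            warning(sprintf("skipping %s: %s", fname, conditionMessage(res)),
                call. = FALSE)
            fileRows[[fname]] <- data.frame(file = fname, path = path,
                total_selected = NA_integer_, excluded_short = NA_integer_,
                status = "failed", message = conditionMessage(res),
                stringsAsFactors = FALSE)
            next
        }
        total <- res$total
        pct <- if (total > 0L) 100 * res$counts / total else
            rep(0, length(res$counts))
        countRows[[fname]] <- data.frame(file = fname,
            probe = panel@names, matched = as.integer(res$counts),
            total = total, percent = as.numeric(pct),
            stringsAsFactors = FALSE)
        m <- res$matches
        if (nrow(m)) m <- cbind(file = fname, m)
        matchRows[[fname]] <- m
        fileRows[[fname]] <- data.frame(file = fname, path = path,
            total_selected = total, excluded_short = res$excluded,
            status = "ok", message = "", stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, unname(countRows)) %||%
        data.frame(file = character(0), probe = character(0),
            matched = integer(0), total = integer(0), percent = numeric(0))
    matches <- do.call(rbind,
        unname(Filter(function(m) nrow(m) > 0, matchRows)))
    if (is.null(matches))
        matches <- cbind(file = character(0), .emptyMatches())
    rownames(counts) <- NULL
    rownames(matches) <- NULL
    new("ScreenResult", counts = counts, matches = matches,
        files = do.call(rbind, unname(fileRows)), panel = panel,
        config = config, elapsed = proc.time()[["elapsed"]] - t0)
}

#' @rdname ScreenResult-class
#' @export
setMethod("matchCounts", "ScreenResult", function(x) x@counts)

#' @rdname ScreenResult-class
#' @export
setMethod("matchRecords", "ScreenResult", function(x) x@matches)

#' @rdname ScreenResult-class
#' @export
setMethod("fileSummaries", "ScreenResult", function(x) x@files)

setMethod("show", "ScreenResult", function(object) {
    nf <- nrow(object@files)
    ok <- sum(object@files$status == "ok")
    cat(sprintf("ScreenResult: %d file%s (%d ok), %d probes, threshold %g%%\n",
        nf, if (nf == 1L) "" else "s", ok, length(object@panel),
        object@config@threshold))
    cat(sprintf("  matched (read, probe) pairs: %d; elapsed %.2f s\n",
        nrow(object@matches), object@elapsed))
})
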