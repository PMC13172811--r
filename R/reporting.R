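# Tabular outputs (per-file results, timestamped summary, aggregated
# totals, matched-read FASTA) and plots (bar charts, probes x files
# percentage heatmap).

.fmt_pct <- function(p) sprintf("%.4f", p)

# strip sequence-file extensions for output naming
.file_stem <- function(fname) {
    sub("\\.(fastq|fq|fasta|fa|fna)(\\.gz)?$", "", fname, ignore.case = TRUE)
}

#' Write the screening output file set
#'
#' Writes, under `outDir`:
#' \itemize{
#'   \item one `<filename>_results.txt` per input file: the total selected
#'     record count, a per-probe count/percentage table, and per-read match
#'     lines (read_id, probe, score, strand), all tab-delimited;
#'   \item `summary_result_<YYYYMMDD_HHMMSS>.txt`: per-file totals, matched
#'     counts and elapsed time;
#'   \item `total_results.txt`: one row per (file, probe) with columns
#'     file, probe, matched, total, percent;
#'   \item one `<filename>_matched_reads.fasta` per file with a match, one
#'     entry per (read, probe) pair, headers `read_id|probe|score|strand`.
#' }
#' Percentages are printed with 4 decimal places (detections below 0.01%
#' occur in practice).
#'
#' @param result a [ScreenResult-class].
#' @param outDir output directory, created if missing.
#' @param timestamp timestamp string for the summary file name; defaults to
#'   the current time, injectable for reproducible output sets.
#' @return character vector of written paths, invisibly.
#' @export
writeOutputs <- function(result, outDir,
                         timestamp = format(Sys.time(), "%Y%m%d_%H%M%S")) {
    stopifnot(is(result, "ScreenResult"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outDir) || file.access(outDir, 2L) != 0L)
        stop(sprintf("output directory not writable: %s", outDir),
            call. = FALSE)
    written <- character(0)
    counts <- result@counts
    matches <- result@matches

    for (i in seq_len(nrow(result@files))) {
        finfo <- result@files[i, ]
        if (finfo$status != "ok") next
        stem <- .file_stem(finfo$file)
        fc <- counts[counts$file == finfo$file, , drop = FALSE]
        fm <- matches[matches$file == finfo$file, , drop = FALSE]
        path <- file.path(outDir, paste0(stem, "_results.txt"))
        con <- file(path, "w")
        writeLines(sprintf("total_selected\t%d", finfo$total_selected), con)
        writeLines("probe\tmatched\tpercent", con)
        writeLines(sprintf("%s\t%d\t%s", fc$probe, fc$matched,
            .fmt_pct(fc$percent)), con)
        writeLines("read_id\tprobe\tscore\tstrand", con)
        if (nrow(fm))
            writeLines(sprintf("%s\t%s\t%s\t%s", fm$read_id, fm$probe,
                format(fm$score, trim = TRUE), fm$strand), con)
        close(con)
        written <- c(written, path)
        if (nrow(fm)) {
            fpath <- file.path(outDir, paste0(stem, "_matched_reads.fasta"))
            writeLines(paste0(">", fm$read_id, "|", fm$probe, "|",
                format(fm$score, trim = TRUE), "|", fm$strand, "\n",
                fm$sequence), fpath)
            written <- c(written, fpath)
        }
    }

    spath <- file.path(outDir, sprintf("summary_result_%s.txt", timestamp))
    con <- file(spath, "w")
    writeLines("file\tstatus\ttotal_selected\tmatched_total\tmessage", con)
    for (i in seq_len(nrow(result@files))) {
        finfo <- result@files[i, ]
        mt <- if (finfo$status == "ok")
            sum(counts$matched[counts$file == finfo$file]) else NA_integer_
        writeLines(sprintf("%s\t%s\t%s\t%s\t%s", finfo$file, finfo$status,
            finfo$total_selected, mt, finfo$message), con)
    }
    writeLines(sprintf("elapsed_seconds\t%.2f", result@elapsed), con)
    close(con)
    written <- c(written, spath)

    tpath <- file.path(outDir, "total_results.txt")
    con <- file(tpath, "w")
    writeLines("file\tprobe\tmatched\ttotal\tpercent", con)
    if (nrow(counts))
        writeLines(sprintf("%s\t%s\t%d\t%d\t%s", counts$file, counts$probe,
            counts$matched, counts$total, .fmt_pct(counts$percent)), con)
    close(con)
    written <- c(written, tpath)
    invisible(written)
}

#' Pivot screening results into a probes x files percentage matrix
#'
#' @param result a [ScreenResult-class].
#' @return numeric matrix with probe names as rows, file names as columns,
#'   and match percentages as values.
#' @export
buildMatrix <- function(result) {
    stopifnot(is(result, "ScreenResult"))
    counts <- result@counts
    files <- unique(counts$file)
    probes <- result@panel@names
    mat <- matrix(0, nrow = length(probes), ncol = length(files),
        dimnames = list(probes, files))
    if (nrow(counts))
        mat[cbind(counts$probe, counts$file)] <- counts$percent
    mat
}

# diverging blue-white-red palette in the spirit of matplotlib's coolwarm
.coolwarm <- function(n = 101L) {
    grDevices::colorRampPalette(c("#3B4CC0", "#F7F7F7", "#B40426"))(n)
}

#' Render screening plots
#'
#' Writes `Total_heatmap.png` (probes x files percentage heatmap on a
#' diverging blue-red palette) in `outDir`, per-file match-count bar charts
#' under `outDir/input_files/`, and per-probe cross-file bar charts under
#' `outDir/probes/`. All PNGs are written at 300 dpi through the file
#' device, so rendering works headless.
#'
#' @param result a [ScreenResult-class].
#' @param outDir output directory.
#' @param matrix optional precomputed [buildMatrix()] result.
#' @return character vector of written image paths, invisibly.
#' @export
renderPlots <- function(result, outDir, matrix = buildMatrix(result)) {
    stopifnot(is(result, "ScreenResult"))
    dir.create(file.path(outDir, "input_files"), recursive = TRUE,
        showWarnings = FALSE)
    dir.create(file.path(outDir, "probes"), recursive = TRUE,
        showWarnings = FALSE)
    written <- character(0)

    hpath <- file.path(outDir, "Total_heatmap.png")
    grDevices::png(hpath, width = max(6, 1 + 0.35 * ncol(matrix)),
        height = max(4, 1 + 0.22 * nrow(matrix)), units = "in", res = 300)
    # pheatmap draws onto the open 300-dpi device; clustering is disabled so
    # rows/columns keep panel and input order
    ph <- try(pheatmap::pheatmap(matrix, cluster_rows = FALSE,
        cluster_cols = FALSE, color = .coolwarm(),
        breaks = seq(0, max(100, max(matrix)), length.out = 102L),
        main = "Match percentage by probe and file", silent = TRUE),
        silent = TRUE)
    if (!inherits(ph, "try-error")) grid::grid.draw(ph$gtable)
    grDevices::dev.off()
    written <- c(written, hpath)

    counts <- result@counts
    for (f in unique(counts$file)) {
        fc <- counts[counts$file == f, , drop = FALSE]
        p <- file.path(outDir, "input_files",
            paste0(.file_stem(f), "_matches.png"))
        grDevices::png(p, width = max(6, 1 + 0.25 * nrow(fc)), height = 5,
            units = "in", res = 300)
        graphics::par(mar = c(9, 4, 3, 1))
        graphics::barplot(fc$matched, names.arg = fc$probe, las = 2,
            cex.names = 0.6, col = "#4C72B0", ylab = "matched reads",
            main = f)
        grDevices::dev.off()
        written <- c(written, p)
    }
    for (pr in result@panel@names) {
        pc <- counts[counts$probe == pr, , drop = FALSE]
        p <- file.path(outDir, "probes", paste0(gsub("[^A-Za-z0-9._-]", "_", pr),
            "_matches.png"))
        grDevices::png(p, width = max(6, 1 + 0.25 * nrow(pc)), height = 5,
            units = "in", res = 300)
        graphics::par(mar = c(9, 4, 3, 1))
        graphics::barplot(pc$matched, names.arg = pc$file, las = 2,
            cex.names = 0.6, col = "#55A868", ylab = "matched reads",
            main = pr)
        grDevices::dev.off()
        written <- c(written, p)
    }
    invisible(written)
}

#' Re-read an aggregated results table
#'
#' Parses a `total_results.txt` written by [writeOutputs()] back into a
#' data.frame; round-trips counts exactly.
#'
#' @param path path to total_results.txt.
#' @return data.frame with columns file, probe, matched, total, percent.
#' @export
readTotalResults <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE,
        colClasses = c("character", "character", "integer", "integer",
            "numeric"))
}
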