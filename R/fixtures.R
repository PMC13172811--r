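# Ground-truthed synthetic FASTQ/FASTA fixtures: probe-free background
# reads plus planted probe copies with controlled substitution/indel loads
# on either strand. The background is certified probe-free by scanning
# every read against every panel probe, so zero-match assertions are exact
# rather than probabilistic.

#' Apply an exact mutation load to a sequence
#'
#' Applies exactly `k_s` substitutions (each to a different base), `k_d`
#' deletions at distinct positions of the original sequence, then `k_i`
#' insertions at random positions, all drawn reproducibly from `seed`.
#'
#' @param seq unambiguous nucleotide sequence.
#' @param k_s,k_i,k_d substitution, insertion and deletion counts
#'   (k_s + k_d must not exceed the sequence length).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return the mutated sequence, of length nchar(seq) + k_i - k_d.
#' @examples
#' mutateSequence("ACGTACGTACGT", k_s = 1, seed = 1)
#' @export
mutateSequence <- function(seq, k_s = 0L, k_i = 0L, k_d = 0L, seed = NULL) {
    n <- nchar(seq)
    if (k_s < 0L || k_i < 0L || k_d < 0L)
        stop("mutation counts must be non-negative", call. = FALSE)
    if (k_s + k_d > n)
        stop(sprintf(
            "infeasible mutation load: k_s + k_d = %d exceeds sequence length %d",
            k_s + k_d, n), call. = FALSE)
    .with_seed(seed, {
        chars <- strsplit(toupper(seq), "")[[1]]
        bases <- c("A", "C", "G", "T")
        pos <- if (k_s + k_d > 0L) sample.int(n, k_s + k_d) else integer(0)
        sub_pos <- pos[seq_len(k_s)]
        del_pos <- pos[k_s + seq_len(k_d)]
        for (p in sub_pos)
            chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        if (length(del_pos))
            chars <- chars[-del_pos]
        for (i in seq_len(k_i)) {
            at <- sample.int(length(chars) + 1L, 1L) # 1 = before first char
            chars <- append(chars, sample(bases, 1L), after = at - 1L)
        }
        paste(chars, collapse = "")
    })
}

.random_reads <- function(n, len, alphabet) {
    vapply(seq_len(n), function(i)
        paste(sample(alphabet, len, replace = TRUE), collapse = ""),
        character(1))
}

# TRUE for reads that stay strictly below `threshold` against every panel
# probe on both strands (reads shorter than a probe are trivially clean
# for that probe)
.reads_clean <- function(reads, panel, threshold) {
    res <- .scoreReadsPanel(reads, panel)
    ok <- res$score < threshold
    ok[is.na(ok)] <- TRUE
    apply(ok, 1L, all)
}

#' Generate a ground-truthed synthetic read fixture
#'
#' Background reads are drawn from `alphabet` and rejection-sampled until
#' none reaches `threshold` against any panel probe on either strand
#' (certified by scanning every read, not by a probabilistic argument).
#' Planted copies of a probe -- optionally mutated, optionally
#' reverse-complemented for the minus strand -- are then inserted at random
#' positions in dedicated background reads; each planted read is re-checked
#' so it does not reach `threshold` for any *other* probe. The manifest
#' records the exact ground truth.
#'
#' @param nReads total reads in the fixture (background + hosts of plants).
#' @param readLen read length; must be at least the longest planted probe.
#' @param plants list of plant specifications, each a list with `probe`
#'   (name in `panel`), `copies`, and optional `k_s`, `k_i`, `k_d`,
#'   `strand` ("+" or "-").
#' @param panel the [ProbePanel-class] the fixture is screened against.
#' @param threshold the certification threshold: no background read (and no
#'   planted read, for probes other than its own) reaches this score.
#' @param format "fastq" (constant "I" quality) or "fasta".
#' @param seed integer seed; the fixture is fully reproducible from it.
#' @param outPath output file path; .gz enables compression.
#' @param alphabet background alphabet; restrict it (e.g. c("A","C")) if
#'   rejection sampling at a permissive threshold struggles.
#' @param maxAttempts rejection-sampling rounds before giving up.
#' @return the manifest: a list with generator parameters and one entry per
#'   plant recording probe, copies, mutation load, strand, planted read ids
#'   and the planted (possibly mutated) sequences.
#' @export
generateFixture <- function(nReads, readLen, plants, panel, threshold = 100,
                            format = c("fastq", "fasta"), seed = 1L,
                            outPath, alphabet = c("A", "C", "G", "T"),
                            maxAttempts = 50L) {
    format <- match.arg(format)
    stopifnot(is(panel, "ProbePanel"))
    plantProbes <- vapply(plants, `[[`, character(1), "probe")
    missing <- setdiff(plantProbes, panel@names)
    if (length(missing))
        stop(sprintf("plant probes not in panel: %s",
            paste(missing, collapse = ", ")), call. = FALSE)
    nPlanted <- sum(vapply(plants, function(p) as.integer(p$copies),
        integer(1)))
    if (nPlanted > nReads)
        stop("more planted copies than reads", call. = FALSE)
    if (length(plants)) {
        maxLen <- max(probeLengths(panel)[plantProbes])
        if (readLen < maxLen)
            stop(sprintf(
                "readLen (%d) is shorter than the longest planted probe (%d)",
                readLen, maxLen), call. = FALSE)
    }

    manifest <- .with_seed(seed, {
        # certified-clean background
        reads <- .random_reads(nReads, readLen, alphabet)
        for (attempt in seq_len(maxAttempts)) {
            clean <- .reads_clean(reads, panel, threshold)
            if (all(clean)) break
            reads[!clean] <- .random_reads(sum(!clean), readLen, alphabet)
        }
        if (!all(.reads_clean(reads, panel, threshold)))
            stop(sprintf(
                "could not generate a probe-free background after %d rounds; restrict the alphabet or raise the threshold",
                maxAttempts), call. = FALSE)

        hostIds <- sample.int(nReads, nPlanted) # dedicated host reads
        hostPtr <- 0L
        plantRecords <- list()
        for (p in plants) {
            probeSeq <- probeSequences(panel)[[p$probe]]
            exp1 <- probeExpansions(panel)[[p$probe]]
            copies <- as.integer(p$copies)
            k_s <- p$k_s %||% 0L; k_i <- p$k_i %||% 0L; k_d <- p$k_d %||% 0L
            strand <- p$strand %||% "+"
            ids <- integer(copies); insSeqs <- character(copies)
            others <- which(panel@names != p$probe)
            for (ci in seq_len(copies)) {
                hostPtr <- hostPtr + 1L
                host <- hostIds[hostPtr]
                # plant a concrete expansion, mutated per spec
                base <- if (length(exp1) > 1L) sample(exp1, 1L) else exp1
                mut <- mutateSequence(base, k_s, k_i, k_d, seed = NULL)
                # intended score of the copy in isolation; the planted read
                # must score exactly this for its own probe, so boundary
                # windows spanning copy and background never inflate it
                sIns <- max(vapply(exp1, .partial_ratio_naive_cpp,
                    numeric(1), read = mut))
                ins <- if (strand == "-") reverseComplement(mut) else mut
                ok <- FALSE
                for (attempt in seq_len(maxAttempts)) {
                    at <- sample.int(readLen - nchar(ins) + 1L, 1L)
                    cand <- paste0(substring(reads[host], 1L, at - 1L), ins,
                        substring(reads[host], at + nchar(ins), readLen))
                    cleanOthers <- if (length(others))
                        .reads_clean(cand, panel[others], threshold) else TRUE
                    sOwn <- .scoreReadsPanel(cand, panel[p$probe])$score[1L, 1L]
                    if (cleanOthers && isTRUE(abs(sOwn - sIns) < 1e-9)) {
                        reads[host] <- cand
                        ok <- TRUE
                        break
                    }
                    # redraw the host's background (re-certified) and retry
                    repeat {
                        fresh <- .random_reads(1L, readLen, alphabet)
                        if (.reads_clean(fresh, panel, threshold)) {
                            reads[host] <- fresh
                            break
                        }
                    }
                }
                if (!ok)
                    stop("could not plant a copy at its intended score without cross-matching another probe",
                        call. = FALSE)
                ids[ci] <- host
                insSeqs[ci] <- ins
            }
            plantRecords[[length(plantRecords) + 1L]] <- list(
                probe = p$probe, copies = copies, k_s = k_s, k_i = k_i,
                k_d = k_d, strand = strand, read_ids = sprintf("read_%d", ids),
                planted_sequences = insSeqs)
        }

        ids <- sprintf("read_%d", seq_len(nReads))
        if (format == "fastq") {
            con <- if (grepl("\\.gz$", outPath)) gzfile(outPath, "w") else
                file(outPath, "w")
            writeLines(rbind(paste0("@", ids), reads, rep("+", nReads),
                vapply(reads, function(s) strrep("I", nchar(s)), character(1))),
                con)
            close(con)
        } else {
            Biostrings::writeXStringSet(
                Biostrings::DNAStringSet(stats::setNames(reads, ids)),
                outPath, compress = grepl("\\.gz$", outPath))
        }
        list(
            file = outPath, format = format, n_reads = nReads,
            read_len = readLen, threshold = threshold, seed = seed,
            alphabet = paste(alphabet, collapse = ""),
            probes = stats::setNames(as.list(unname(probeSequences(panel))),
                panel@names),
            plants = plantRecords
        )
    })
    manifest
}

#' Write or read a fixture manifest
#'
#' Manifests serialise losslessly to JSON and reload to the same structure.
#'
#' @param manifest a manifest list from [generateFixture()].
#' @param path JSON path.
#' @return `readFixtureManifest` returns the manifest list.
#' @export
writeFixtureManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(path)
}

#' @rdname writeFixtureManifest
#' @export
readFixtureManifest <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Planted exact-copy counts from a manifest
#'
#' @param manifest a fixture manifest.
#' @param exactOnly count only unmutated copies (k_s = k_i = k_d = 0).
#' @return named integer vector of planted copies per probe (all panel
#'   probes, zeros included).
#' @export
manifestCounts <- function(manifest, exactOnly = TRUE) {
    out <- stats::setNames(integer(length(manifest$probes)),
        names(manifest$probes))
    for (p in manifest$plants) {
        if (exactOnly && (p$k_s + p$k_i + p$k_d) > 0L) next
        out[[p$probe]] <- out[[p$probe]] + as.integer(p$copies)
    }
    out
}
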