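# Independent scoring oracles and small generators shared by the tests.
#
# The indel similarity oracle goes through utils::adist with substitution
# cost 2 (one deletion plus one insertion), which equals the LCS form
# 100 * 2 * LCS / (|a| + |b|); the partial-ratio oracle enumerates every
# contiguous substring of the read explicitly. Both are independent of the
# package's scoring path.

oracle_indel_ratio <- function(a, b) {
    d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
    100 * (1 - d / (nchar(a) + nchar(b)))
}

oracle_partial_ratio <- function(probe, read) {
    n <- nchar(read)
    subs <- unlist(lapply(seq_len(n), function(i)
        substring(read, i, i:n)))
    d <- utils::adist(probe, subs, costs = list(ins = 1, del = 1, sub = 2))
    max(100 * (1 - d / (nchar(probe) + nchar(subs))))
}

# plain-R LCS as a second, structurally different route for indelRatio
oracle_lcs <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    dp <- matrix(0L, length(x) + 1L, length(y) + 1L)
    for (i in seq_along(x)) for (j in seq_along(y))
        dp[i + 1L, j + 1L] <- if (x[i] == y[j]) dp[i, j] + 1L else
            max(dp[i, j + 1L], dp[i + 1L, j])
    dp[length(x) + 1L, length(y) + 1L]
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_iupac <- function(len) {
    random_seq(len, strsplit("ACGTRYSWKMBDHVN", "")[[1]])
}

# all sequences of the given lengths over an alphabet
all_seqs <- function(lengths, alphabet) {
    unlist(lapply(lengths, function(L) {
        do.call(paste0, expand.grid(rep(list(alphabet), L),
            stringsAsFactors = FALSE))
    }))
}

# write a small synthetic FASTQ (constant quality) and return its path
write_fastq <- function(reads, path, ids = sprintf("read_%d", seq_along(reads))) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(rbind(paste0("@", ids), reads, rep("+", length(reads)),
        vapply(reads, function(s) strrep("I", nchar(s)), character(1))), con)
    path
}

panel_fixture_path <- function(name) {
    system.file("extdata", name, package = "issm", mustWork = TRUE)
}
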