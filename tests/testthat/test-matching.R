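# Similarity scoring: indel ratio, partial ratio, strand handling,
# thresholds, and equivalence with independent oracles.

test_that("indel ratio equals the LCS form on fixed and random pairs", {
    expect_equal(indelRatio("ACGT", "ACGT"), 100)
    expect_equal(indelRatio("AAAA", "CCCC"), 0)
    expect_equal(
        indelRatio("AGAGATGGCCACGGCTGCTT", "AGAGATGGCAACGGCTGCTT"), 95.0)
    expect_error(indelRatio("", "ACGT"), "non-empty")
    set.seed(3)
    for (i in 1:40) {
        a <- random_seq(sample(1:20, 1)); b <- random_seq(sample(1:20, 1))
        expect_equal(indelRatio(a, b), oracle_indel_ratio(a, b),
            info = paste(a, b))
        expect_equal(indelRatio(a, b),
            200 * oracle_lcs(a, b) / (nchar(a) + nchar(b)),
            info = paste(a, b))
    }
})

test_that("partial ratio matches fixed examples and rejects short reads", {
    expect_equal(partialRatio("ACGT", "TTACGTTT"), 100)
    expect_equal(partialRatio("AAAA", "CCCCCC"), 0)
    expect_equal(partialRatio("ACGT", "TTTT"), 40) # best window: one T
    expect_error(partialRatio("ACGTACGT", "ACG"), "shorter than the probe")
})

test_that("production scorer equals exhaustive oracles on an exhaustive corpus", {
    probes <- all_seqs(1:3, c("A", "C", "G"))
    reads <- all_seqs(1:5, c("A", "C", "G"))
    for (p in probes) for (r in reads) {
        if (nchar(r) < nchar(p)) next
        prod <- partialRatio(p, r)
        expect_identical(prod, issm:::.partialRatioNaive(p, r),
            info = paste(p, r))
    }
    # spot-check the naive route against the adist-based oracle
    set.seed(9)
    for (i in 1:60) {
        p <- sample(probes, 1); r <- sample(reads, 1)
        expect_equal(issm:::.partialRatioNaive(p, r),
            oracle_partial_ratio(p, r), info = paste(p, r))
    }
})

test_that("production scorer equals the naive oracle on random realistic pairs", {
    set.seed(17)
    for (i in 1:300) {
        p <- random_seq(sample(5:25, 1))
        r <- random_seq(sample(30:150, 1))
        expect_identical(partialRatio(p, r), issm:::.partialRatioNaive(p, r),
            info = paste(p, r))
    }
})

test_that("mutation loads inside an embedded 20-mer give the expected scores", {
    # interior substitutions: the best window is the whole copy, so one
    # substitution scores exactly 95 and two exactly 90 (an edge
    # substitution scores higher, 200*19/39, because the best window drops
    # the mutated edge base); a deletion anywhere scores 200*19/39. Flanks
    # of N contribute no common subsequence.
    sub_at <- function(s, i) {
        ch <- strsplit(s, "")[[1]]
        ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
        paste(ch, collapse = "")
    }
    del_at <- function(s, i) {
        ch <- strsplit(s, "")[[1]]
        paste(ch[-i], collapse = "")
    }
    embed <- function(s) paste0(strrep("N", 30), s, strrep("N", 30))
    set.seed(21)
    probe <- random_seq(20)
    expect_equal(partialRatio(probe, embed(sub_at(probe, 10))), 95.0)
    expect_equal(partialRatio(probe, embed(sub_at(sub_at(probe, 6), 14))),
        90.0)
    expect_equal(partialRatio(probe, embed(del_at(probe, 10))),
        100 * 38 / 39)
    # oracle agrees on all three
    for (r in list(sub_at(probe, 10), sub_at(sub_at(probe, 6), 14),
        del_at(probe, 10)))
        expect_equal(partialRatio(probe, embed(r)),
            issm:::.partialRatioNaive(probe, embed(r)))
    # a single-substitution copy from the fixture mutator stays at or above
    # 95 wherever the substitution lands, and a double stays below 95
    for (s in 1:8) {
        m1 <- mutateSequence(probe, k_s = 1, seed = s)
        m2 <- mutateSequence(probe, k_s = 2, seed = s)
        expect_gte(partialRatio(probe, embed(m1)), 95)
        expect_lt(partialRatio(probe, embed(m2)), 95)
    }
})

test_that("scoreRead decides matches inclusively over strands and expansions", {
    # degenerate probe: expansion "AC" is an exact substring
    m <- scoreRead("GGACGG", "AY", threshold = 100)
    expect_equal(m$status, "match")
    expect_equal(m$score, 100)
    expect_equal(m$strand, "+")
    # minus strand: reverse complement of TTGGTT contains AACC
    m2 <- scoreRead("TTGGTT", "AACC", threshold = 100)
    expect_equal(m2$status, "match")
    expect_equal(m2$strand, "-")
    # reads shorter than the probe are excluded, not scored
    m3 <- scoreRead(strrep("A", 15), strrep("A", 20), threshold = 0)
    expect_equal(m3$status, "excluded")
    expect_true(is.na(m3$score))
    # score exactly at the threshold is a match
    probe <- "AGAGATGGCCACGGCTGCTT"
    read <- paste0("TTTTT", "AGAGATGGCAACGGCTGCTT", "TTTTT")
    m4 <- scoreRead(read, probe, threshold = 95)
    expect_equal(m4$status, "match")
    expect_equal(m4$score, 95.0)
    expect_equal(scoreRead(read, probe, threshold = 95 + 1e-9)$status,
        "no_match")
})

test_that("degenerate probe score is the maximum over its expansions", {
    set.seed(31)
    for (i in 1:15) {
        s <- random_iupac(6)
        exps <- expandIUPAC(s, maxExpansions = 1e6)
        read <- random_seq(40)
        got <- scoreRead(read, s, threshold = 0)$score
        rc <- reverseComplement(read)
        want <- max(vapply(exps, function(e)
            max(partialRatio(e, read), partialRatio(e, rc)), numeric(1)))
        expect_equal(got, want, info = s)
    }
})

test_that("match decisions are strand-symmetric", {
    set.seed(41)
    panel <- ProbePanel("p", random_seq(12))
    for (i in 1:20) {
        read <- random_seq(50)
        a <- scoreRead(read, panel, threshold = 0)
        b <- scoreRead(reverseComplement(read), panel, threshold = 0)
        expect_equal(a$score, b$score)
    }
})

test_that("match sets are nested across increasing thresholds", {
    set.seed(51)
    probe <- random_seq(20)
    reads <- c(
        replicate(20, random_seq(60)),
        vapply(1:10, function(i) paste0(random_seq(20),
            mutateSequence(probe, k_s = sample(0:3, 1), seed = i),
            random_seq(20)), character(1)))
    matched <- function(thr) which(vapply(reads, function(r)
        scoreRead(r, probe, thr)$status == "match", logical(1)))
    sets <- lapply(c(90, 95, 99, 100), matched)
    for (i in 1:3)
        expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("N in a read matches nothing and lowercase reads are uppercased", {
    expect_equal(partialRatio("ACGT", "NNNN"), 0)
    expect_equal(partialRatio("ACGT", "ttacgttt"), 100)
})
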