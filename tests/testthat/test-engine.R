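# Screening orchestration: batches, merging, parallel invariance,
# failure handling.

make_panel <- function() {
    ProbePanel(c("P1", "P2"), c("AGAGATGGCCACGGCTGCTT", "CCTGTGAAAAGCCACTCAGA"))
}

test_that("screenBatch counts per probe and records every qualifying pair", {
    panel <- make_panel()
    p1 <- probeSequences(panel)[["P1"]]
    recs <- list(
        id = c("a", "b", "c", "d"),
        sequence = c(
            paste0(strrep("T", 10), p1, strrep("T", 10)), # P1 exact
            reverseComplement(paste0(strrep("T", 10), p1, strrep("T", 10))),
            strrep("AC", 20), # background
            strrep("G", 5))  # shorter than both probes: excluded
    )
    out <- screenBatch(recs, panel, threshold = 100)
    expect_equal(out$counts, c(P1 = 2L, P2 = 0L))
    expect_equal(out$excluded, 2L) # read d vs both probes
    expect_equal(out$matches$read_id, c("a", "b"))
    expect_equal(out$matches$strand, c("+", "-"))
    expect_equal(out$matches$score, c(100, 100))
})

test_that("a batch over a restricted alphabet cannot match a probe needing other bases", {
    panel <- ProbePanel("needsG", "GGGGGGGGGG")
    recs <- list(id = sprintf("r%d", 1:30),
        sequence = replicate(30, random_seq(40, c("A", "C"))))
    out <- screenBatch(recs, panel, threshold = 100)
    expect_equal(unname(out$counts), 0L)
})

test_that("batch counts are additive under concatenation", {
    set.seed(71)
    panel <- make_panel()
    p1 <- probeSequences(panel)[["P1"]]
    mk <- function(n, plant) {
        seqs <- replicate(n, random_seq(50, c("A", "C")))
        if (plant > 0)
            seqs[seq_len(plant)] <- vapply(seq_len(plant), function(i)
                paste0(random_seq(15, c("A", "C")), p1,
                    random_seq(15, c("A", "C"))), character(1))
        list(id = sprintf("r%d", seq_len(n)), sequence = seqs)
    }
    b1 <- mk(20, 3); b2 <- mk(15, 2)
    both <- list(id = c(b1$id, b2$id), sequence = c(b1$sequence, b2$sequence))
    c1 <- screenBatch(b1, panel, 100)$counts
    c2 <- screenBatch(b2, panel, 100)$counts
    cb <- screenBatch(both, panel, 100)$counts
    expect_equal(cb, c1 + c2)
    expect_equal(cb[["P1"]], 5L)
})

test_that("mergeCounts sums elementwise and is order-invariant", {
    panel <- make_panel()
    a <- c(P1 = 2L, P2 = 0L); b <- c(P2 = 5L, P1 = 1L)
    expect_equal(mergeCounts(list(a, b), panel), c(P1 = 3L, P2 = 5L))
    expect_equal(mergeCounts(list(b, a), panel), c(P1 = 3L, P2 = 5L))
    expect_equal(mergeCounts(list(), panel), c(P1 = 0L, P2 = 0L))
    expect_error(mergeCounts(list(c(XX = 1L, P1 = 1L)), panel),
        "probe set mismatch")
})

test_that("runScreen recovers planted counts and is invariant to jobs and batch size", {
    td <- withr::local_tempdir()
    panel <- make_panel()
    man <- generateFixture(nReads = 260, readLen = 70,
        plants = list(list(probe = "P1", copies = 7),
            list(probe = "P2", copies = 4, strand = "-")),
        panel = panel, threshold = 95, format = "fastq", seed = 83,
        outPath = file.path(td, "fix.fastq.gz"))
    f <- file.path(td, "fix.fastq.gz")
    base <- runScreen(f, panel, ScreenConfig(threshold = 100, jobs = 1L,
        batchSize = 500L, seed = 1))
    expect_equal(matchCounts(base)$matched, c(7L, 4L))
    expect_equal(matchCounts(base)$total, c(260L, 260L))
    variants <- list(
        runScreen(f, panel, ScreenConfig(threshold = 100, jobs = 4L,
            batchSize = 500L, seed = 1)),
        runScreen(f, panel, ScreenConfig(threshold = 100, jobs = 1L,
            batchSize = 100L, seed = 1)),
        runScreen(f, panel, ScreenConfig(threshold = 100, jobs = 4L,
            batchSize = 37L, seed = 1)))
    for (v in variants) {
        expect_identical(matchCounts(v), matchCounts(base))
        expect_identical(matchRecords(v), matchRecords(base))
    }
})

test_that("minus-strand plantings count the same as plus-strand plantings", {
    td <- withr::local_tempdir()
    panel <- ProbePanel("P", "AGAGATGGCCACGGCTGCTT")
    plus <- generateFixture(100, 60, list(list(probe = "P", copies = 6)),
        panel, threshold = 95, format = "fastq", seed = 19,
        outPath = file.path(td, "plus.fastq"))
    minus <- generateFixture(100, 60,
        list(list(probe = "P", copies = 6, strand = "-")),
        panel, threshold = 95, format = "fastq", seed = 19,
        outPath = file.path(td, "minus.fastq"))
    cfg <- ScreenConfig(threshold = 100, jobs = 1L)
    cp <- matchCounts(runScreen(file.path(td, "plus.fastq"), panel, cfg))
    cm <- matchCounts(runScreen(file.path(td, "minus.fastq"), panel, cfg))
    expect_equal(cp$matched, 6L)
    expect_equal(cm$matched, 6L)
})

test_that("unreadable files are recorded as failed without aborting the run", {
    td <- withr::local_tempdir()
    panel <- make_panel()
    good <- write_fastq(replicate(10, random_seq(30, c("A", "C"))),
        file.path(td, "good.fastq"))
    bad <- file.path(td, "missing.fastq")
    res <- suppressWarnings(
        runScreen(c(good, bad), panel, ScreenConfig(jobs = 1L)))
    fs <- fileSummaries(res)
    expect_equal(fs$status, c("ok", "failed"))
    expect_match(fs$message[2], "not found")
    expect_equal(nrow(matchCounts(res)), 2L) # only the good file's rows
})

test_that("an empty input yields a zero-count summary", {
    td <- withr::local_tempdir()
    empty <- file.path(td, "empty.fastq")
    file.create(empty)
    panel <- make_panel()
    res <- runScreen(empty, panel, ScreenConfig(jobs = 1L))
    expect_equal(matchCounts(res)$total, c(0L, 0L))
    expect_equal(matchCounts(res)$matched, c(0L, 0L))
    expect_equal(matchCounts(res)$percent, c(0, 0))
})

test_that("short reads stay in the selected total but are excluded from matching", {
    td <- withr::local_tempdir()
    panel <- ProbePanel("P", strrep("ACGT", 5))
    reads <- c(replicate(5, random_seq(50, c("A", "C"))),
        replicate(3, random_seq(10, c("A", "C")))) # shorter than the probe
    f <- write_fastq(reads, file.path(td, "mix.fastq"))
    res <- runScreen(f, panel, ScreenConfig(jobs = 1L))
    expect_equal(matchCounts(res)$total, 8L)
    expect_equal(fileSummaries(res)$excluded_short, 3L)
})

test_that("directory inputs are scanned recursively for the chosen format", {
    td <- withr::local_tempdir()
    dir.create(file.path(td, "sub"))
    write_fastq(replicate(4, random_seq(30, c("A", "C"))),
        file.path(td, "a.fastq"))
    write_fastq(replicate(4, random_seq(30, c("A", "C"))),
        file.path(td, "sub", "b.fastq.gz"))
    res <- runScreen(td, make_panel(), ScreenConfig(jobs = 1L),
        format = "fastq")
    expect_equal(sort(fileSummaries(res)$file), c("a.fastq", "b.fastq.gz"))
})
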