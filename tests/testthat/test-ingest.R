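# Annotation parsing, SAM loading with MAPQ/barcode handling, duplicate
# collapse, and coverage.

test_that("GFF3 transcript models derive UTRs and flag noncoding RNAs", {
    gff <- writeGff3(c(
        "chr1\t.\tgene\t101\t700\t.\t+\t.\tID=g1",
        "chr1\t.\tmRNA\t101\t700\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\t.\texon\t101\t700\t.\t+\t.\tID=t1.e1;Parent=t1",
        "chr1\t.\tCDS\t201\t500\t.\t+\t.\tID=t1.c1;Parent=t1",
        "chr1\t.\tgene\t1001\t1400\t.\t+\t.\tID=g2",
        "chr1\t.\tncRNA\t1001\t1400\t.\t+\t.\tID=t2;Parent=g2",
        "chr1\t.\texon\t1001\t1400\t.\t+\t.\tID=t2.e1;Parent=t2"))
    tm <- loadAnnotation(gff)
    info <- transcriptInfo(tm)
    expect_equal(nrow(info), 2)
    i1 <- which(info$transcript_id == "t1")
    expect_true(info$coding[i1])
    expect_equal(info$mature_length[i1], 600L)
    expect_equal(BiocGenerics::start(tm@utr5[["t1"]]), 101L)
    expect_equal(BiocGenerics::end(tm@utr5[["t1"]]), 200L)
    expect_equal(BiocGenerics::start(tm@utr3[["t1"]]), 501L)
    # noncoding: no CDS span, no UTRs
    expect_false(info$coding[info$transcript_id == "t2"])
    expect_length(tm@cds[["t2"]], 0)
})

test_that("minus-strand two-exon transcript puts the 3'UTR at lower coords", {
    gff <- writeGff3(c(
        "chr1\t.\tgene\t1001\t2000\t.\t-\t.\tID=g1",
        "chr1\t.\tmRNA\t1001\t2000\t.\t-\t.\tID=t1;Parent=g1",
        "chr1\t.\texon\t1001\t1400\t.\t-\t.\tID=e1;Parent=t1",
        "chr1\t.\texon\t1601\t2000\t.\t-\t.\tID=e2;Parent=t1",
        "chr1\t.\tCDS\t1201\t1400\t.\t-\t.\tID=c1;Parent=t1",
        "chr1\t.\tCDS\t1601\t1900\t.\t-\t.\tID=c2;Parent=t1"))
    tm <- loadAnnotation(gff)
    expect_equal(transcriptInfo(tm)$mature_length, 800L)
    u3 <- tm@utr3[["t1"]]
    cds <- tm@cds[["t1"]]
    expect_true(max(BiocGenerics::end(u3)) < min(BiocGenerics::start(cds)))
    u5 <- tm@utr5[["t1"]]
    expect_true(min(BiocGenerics::start(u5)) > max(BiocGenerics::end(cds)))
    # coordinate mapping round-trips through the two exons
    pos <- c(1L, 400L, 401L, 800L)
    g <- transcriptToGenomic(tm, "t1", pos)
    expect_equal(g, c(2000L, 1601L, 1400L, 1001L))
    expect_equal(genomicToTranscript(tm, "t1", g), pos)
    expect_true(is.na(genomicToTranscript(tm, "t1", 1500L)))
})

test_that("malformed annotation is rejected", {
    expect_error(loadAnnotation(writeGff3(c(
        "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=t1",
        "chr1\t.\texon\t1\t100\t.\t+\t.\tID=e1"))),
        "Parent")
    expect_warning(tm <- loadAnnotation(writeGff3(c(
        "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=t1",
        "chr1\t.\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
        "chr1\t.\tCDS\t150\t200\t.\t+\t.\tID=c1;Parent=t1"))),
        "CDS outside exons")
    expect_equal(nrow(transcriptInfo(tm)), 0)
})

test_that("SAM loading honours the MAPQ >= 20 boundary and parses CIGAR", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        "@SQ\tSN:chr1\tLN:10000",
        "r1_BC:ACGTACG\t0\tchr1\t100\t19\t35M\t*\t0\t0\t*\t*",
        "r2_BC:ACGTACG\t0\tchr1\t100\t20\t35M\t*\t0\t0\t*\t*",
        "r3_BC:TTTTAAA\t0\tchr1\t100\t42\t10M2D25M\t*\t0\t0\t*\t*",
        "r4_BC:GGGGCCC\t16\tchr1\t200\t42\t35M\t*\t0\t0\t*\t*"), sam)
    reads <- loadReads(sam)
    expect_equal(length(reads), 3)           # mapq 19 dropped, 20 kept
    expect_false("r1_BC:ACGTACG" %in% names(reads))
    r3 <- reads[names(reads) == "r3_BC:TTTTAAA"]
    # 10M: 100..109 aligned, deletion consumes reference 110..111
    expect_equal(S4Vectors::mcols(r3)$deletions[[1]], c(110L, 111L))
    expect_equal(BiocGenerics::width(r3), 37L)
    r4 <- reads[names(reads) == "r4_BC:GGGGCCC"]
    expect_equal(S4Vectors::mcols(r4)$fivePrime, BiocGenerics::end(r4))
    expect_equal(S4Vectors::mcols(reads)$barcode[1], "ACGTACG")
})

test_that("empty SAM yields an empty read set", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000"), sam)
    expect_length(loadReads(sam), 0)
})

test_that("SAM round-trip preserves spans, strands, barcodes, deletions", {
    set.seed(9)
    n <- 40
    start <- sample(1000:2000, n)
    reads <- makeReads("chr1", start, start + 34L,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       dels = lapply(start, function(s)
                           if (runif(1) < 0.3) s + 10L else integer()),
                       seqlen = 5000L)
    sam <- tempfile(fileext = ".sam")
    writeSam(reads, sam)
    back <- loadReads(sam)
    o1 <- order(names(reads)); o2 <- order(names(back))
    expect_equal(BiocGenerics::start(reads)[o1], BiocGenerics::start(back)[o2])
    expect_equal(as.character(BiocGenerics::strand(reads))[o1],
                 as.character(BiocGenerics::strand(back))[o2])
    expect_equal(S4Vectors::mcols(reads)$barcode[o1],
                 S4Vectors::mcols(back)$barcode[o2])
    expect_identical(as.list(S4Vectors::mcols(reads)$deletions[o1]),
                     as.list(S4Vectors::mcols(back)$deletions[o2]))
})

test_that("duplicate collapse keeps one read per position-barcode group", {
    r <- makeReads("chr1", rep(100L, 5), rep(134L, 5),
                   barcode = rep("AAAA", 5))
    expect_length(collapseDuplicates(r), 1)
    r2 <- makeReads("chr1", rep(100L, 3), rep(134L, 3),
                    barcode = c("AAAA", "CCCC", "GGGG"))
    expect_length(collapseDuplicates(r2), 3)
    # longest kept; ties by lexicographically smallest name
    r3 <- makeReads("chr1", c(100L, 100L), c(130L, 134L),
                    barcode = c("AAAA", "AAAA"))
    kept <- collapseDuplicates(r3)
    expect_equal(BiocGenerics::width(kept), 35L)
    # idempotence and order-independence
    once <- collapseDuplicates(r3)
    expect_identical(names(collapseDuplicates(once)), names(once))
    shuffled <- r3[c(2, 1)]
    expect_identical(names(collapseDuplicates(shuffled)), names(once))
    # 5' position defines the group on the minus strand
    r4 <- makeReads("chr1", c(100L, 90L), c(134L, 134L), strand = "-",
                    barcode = c("AAAA", "AAAA"))
    expect_length(collapseDuplicates(r4), 1)
})

test_that("pooling negative-control replicates collapses across the pool", {
    a <- makeReads("chr1", c(100L, 200L), c(134L, 234L),
                   barcode = c("AAAA", "CCCC"))
    b <- makeReads("chr1", c(100L, 300L), c(134L, 334L),
                   barcode = c("AAAA", "TTTT"))
    pooled <- poolReads(list(a, b))
    expect_length(pooled, 3)
})

test_that("coverage counts read overlap per base and conserves mass", {
    # single read spanning 10..14 (five positions)
    r <- makeReads("chr1", 10L, 14L, seqlen = 30L)
    cov <- readCoverage(r, "chr1", "+")
    v <- as.integer(cov)
    expect_equal(which(v == 1L), 10:14)
    # abutting reads never stack
    r2 <- makeReads("chr1", c(1L, 6L), c(5L, 10L), seqlen = 30L)
    expect_equal(max(as.integer(readCoverage(r2, "chr1", "+"))), 1L)
    # random fixture equals a brute-force per-base recount
    set.seed(4)
    n <- 50
    s <- sample(1:400, n, replace = TRUE)
    r3 <- makeReads("chr1", s, s + sample(10:40, n, replace = TRUE),
                    seqlen = 500L)
    v3 <- as.integer(readCoverage(r3, "chr1", "+"))
    brute <- integer(500)
    for (i in seq_len(n)) {
        ix <- BiocGenerics::start(r3)[i]:BiocGenerics::end(r3)[i]
        brute[ix] <- brute[ix] + 1L
    }
    expect_equal(v3, brute)
    expect_equal(sum(v3), sum(BiocGenerics::width(r3)))
})
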