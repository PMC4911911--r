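# Synthetic-data generator: determinism, planted-site statistics, read
# chemistry (truncation / deletion / barcodes / PCR duplicates), controls.

test_that("empty and degenerate configurations are handled", {
    sim0 <- makeTranscriptome(simConfig(nTranscripts = 0L, seed = 1L))
    expect_length(genomeSeq(sim0), 0)
    expect_equal(nrow(truthSites(sim0)), 0)
    expect_error(makeTranscriptome(simConfig(nTranscripts = 5L,
                                             transcriptLengthRange = c(60L, 80L),
                                             seed = 1L)),
                 "too short")
    expect_error(simConfig(truncationProb = 1.5), "probabilities")
    expect_error(simConfig(affinityLevels = c(canonical_context = 10,
                                              canonical = 20, sevenmer = 5,
                                              alternate = 2, none = 0)),
                 "ordering")
})

test_that("the seed fully determines the generated world and reads", {
    cfg <- simConfig(nTranscripts = 20L, seed = 7L)
    a <- makeTranscriptome(cfg)
    b <- makeTranscriptome(cfg)
    expect_identical(as.character(genomeSeq(a)), as.character(genomeSeq(b)))
    expect_identical(as.data.frame(truthSites(a)[, 1:3]),
                     as.data.frame(truthSites(b)[, 1:3]))
    expect_identical(transcriptAbundance(a), transcriptAbundance(b))
    r1 <- simulateIclip(a, 1); r2 <- simulateIclip(b, 1)
    expect_identical(names(r1), names(r2))
    expect_identical(BiocGenerics::start(r1), BiocGenerics::start(r2))
    c1 <- simulateControls(a); c2 <- simulateControls(b)
    expect_identical(names(c1$control), names(c2$control))
    # and the serialized form is byte-identical
    d1 <- tempfile(); d2 <- tempfile()
    writeSimulation(a, d1); writeSimulation(b, d2)
    for (f in c("genome.fa", "annotation.gff3", "truth.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("target fraction controls the number of site-bearing transcripts", {
    sim <- makeTranscriptome(simConfig(nTranscripts = 100L,
                                       targetFraction = 0.5, seed = 99L))
    nTargets <- length(unique(truthSites(sim)$transcript_id))
    # 99.9% binomial interval for Binomial(100, 0.5)
    expect_gte(nTargets, qbinom(0.0005, 100, 0.5))
    expect_lte(nTargets, qbinom(0.9995, 100, 0.5))
})

test_that("planted sites carry their class motif and upstream context", {
    sim <- smallSim()
    tr <- truthSites(sim)
    fbe <- motifDef("fbe", "UGUNNNAU")
    sev <- motifDef("sevenmer", "UGURNAU")
    for (j in seq_len(nrow(tr))) {
        g <- genomeSeq(sim)[[tr$chromosome[j]]]
        u1 <- tr$genomic_u1[j]
        if (tr$strand[j] == "+") {
            s <- as.character(Biostrings::subseq(g, u1 - 4L, u1 + 9L))
        } else {
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::subseq(g, u1 - 9L, u1 + 4L)))
        }
        hits <- switch(tr$site_class[j],
            canonical_context = ,
            canonical = scanMotif(s, fbe),
            sevenmer = scanMotif(s, sev),
            alternate = scanMotif(s, motifDef("alt", "UGUGUUGU")))
        expect_true(5 %in% hits$offset,
                    label = paste("motif at planted position, site", j))
        if (tr$site_class[j] == "canonical_context") {
            h <- hits[hits$offset == 5, ]
            expect_true(h$c_m1 || h$c_m2)
        }
        if (tr$site_class[j] == "canonical") {
            h <- hits[hits$offset == 5, ]
            expect_false(h$c_m1 || h$c_m2)
        }
    }
})

test_that("planted crosslink offsets are upstream-skewed in aggregate", {
    sim <- makeTranscriptome(simConfig(nTranscripts = 150L, seed = 5L))
    offs <- unlist(truthSites(sim)$crosslink_offsets)
    tab <- table(offs)
    mode <- as.integer(names(tab)[which.max(tab)])
    expect_lt(mode, 0)
    expect_gt(mean(offs < 0), 0.5)
})

test_that("forced truncation puts every read 5' end at crosslink + 1", {
    cfg <- simConfig(nTranscripts = 25L, truncationProb = 1,
                     deletionProb = 0, backgroundRate = 0,
                     pcrDuplicateRate = 0, seed = 12L)
    sim <- makeTranscriptome(cfg)
    reads <- simulateIclip(sim, 1)
    tr <- truthSites(sim)
    tm <- sim@transcripts
    allowed <- unlist(lapply(seq_len(nrow(tr)), function(j)
        transcriptToGenomic(tm, tr$transcript_id[j],
            tr$site_position[j] + tr$crosslink_offsets[[j]] + 1L)))
    fp <- S4Vectors::mcols(reads)$fivePrime
    expect_true(all(fp %in% allowed))
    expect_equal(sum(S4Vectors::elementNROWS(
        S4Vectors::mcols(reads)$deletions)), 0)
})

test_that("background-only read counts track abundance", {
    cfg <- simConfig(nTranscripts = 200L, targetFraction = 0,
                     backgroundRate = 30, hotspotFrac = 0,
                     pcrDuplicateRate = 0, seed = 31L)
    sim <- makeTranscriptome(cfg)
    reads <- simulateIclip(sim, 1)
    tm <- sim@transcripts
    info <- transcriptInfo(sim)
    fpGr <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(reads)),
        IRanges::IRanges(S4Vectors::mcols(reads)$fivePrime,
                         S4Vectors::mcols(reads)$fivePrime),
        strand = BiocGenerics::strand(reads))
    counts <- vapply(seq_len(nrow(info)), function(i)
        sum(GenomicRanges::countOverlaps(transcriptExons(sim)[[i]], fpGr)),
        integer(1))
    rho <- cor(counts, transcriptAbundance(sim), method = "spearman")
    expect_gt(rho, 0.8)
})

test_that("PCR duplicate rate zero leaves all (position, barcode) unique", {
    cfg <- simConfig(nTranscripts = 20L, pcrDuplicateRate = 0, seed = 3L)
    sim <- makeTranscriptome(cfg)
    reads <- simulateIclip(sim, 2)
    key <- paste(S4Vectors::mcols(reads)$fivePrime,
                 as.character(BiocGenerics::strand(reads)),
                 S4Vectors::mcols(reads)$barcode)
    expect_false(any(duplicated(key)))
    expect_error(simulateIclip(sim, 99), "out of range")
})

test_that("controls carry background only", {
    cfg <- simConfig(nTranscripts = 60L, seed = 17L)
    sim <- makeTranscriptome(cfg)
    ctrl <- simulateControls(sim)
    tr <- truthSites(sim)
    tm <- sim@transcripts
    # deletions in the control at planted crosslink positions are no more
    # frequent than the global background deletion rate allows
    clPos <- truthCrosslinkPositions(sim)
    dels <- unlist(S4Vectors::mcols(ctrl$control)$deletions)
    nAtSites <- sum(dels %in% clPos)
    totCov <- sum(BiocGenerics::width(ctrl$control))
    rate <- max(length(dels), 1) / totCov
    # binomial upper bound on deletions expected at the ~2*sites positions
    nPos <- length(clPos)
    expect_lte(nAtSites, qbinom(0.999, size = nPos * 60L, prob = rate) + 2)
    # uniform-abundance RNA-seq counts show Poisson-like dispersion
    cfg2 <- simConfig(nTranscripts = 150L, abundanceSdlog = 1e-9,
                      targetFraction = 0, seed = 8L)
    sim2 <- makeTranscriptome(cfg2)
    rs <- simulateControls(sim2)$rnaseq
    fp <- S4Vectors::mcols(rs)$fivePrime
    fpGr <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(rs)),
        IRanges::IRanges(fp, fp), strand = BiocGenerics::strand(rs))
    counts <- vapply(seq_len(150L), function(i)
        sum(GenomicRanges::countOverlaps(transcriptExons(sim2)[[i]], fpGr)),
        integer(1))
    disp <- var(counts) / mean(counts)
    # chi-square bounds on the index of dispersion under Poisson
    expect_gt(disp, qchisq(0.001, 149) / 149)
    expect_lt(disp, qchisq(0.999, 149) / 149)
})
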