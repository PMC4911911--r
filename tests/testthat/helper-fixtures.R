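# Shared fixtures. Heavy simulations are built lazily and cached so that
# multiple test files can reuse them within one run.

.fixtureCache <- new.env(parent = emptyenv())

# A small world: quick to simulate, enough signal for structural checks.
smallSim <- function() {
    if (is.null(.fixtureCache$smallSim))
        .fixtureCache$smallSim <- makeTranscriptome(
            simConfig(nTranscripts = 30L, seed = 42L))
    .fixtureCache$smallSim
}

# Default-scale world shared by the acceptance tests: ~200 transcripts,
# 3 replicates, the stated defaults.
acceptanceRun <- function() {
    if (is.null(.fixtureCache$acceptanceRun)) {
        cfg <- simConfig(seed = 20160701L)
        sim <- makeTranscriptome(cfg)
        ctrl <- simulateControls(sim)
        control <- collapseDuplicates(ctrl$control)
        rnaseq <- ctrl$rnaseq
        reps <- lapply(seq_len(cfg@nReplicates), function(r)
            collapseDuplicates(simulateIclip(sim, r)))
        chrom <- names(genomeSeq(sim))
        pc <- peakCallConfig()
        cands <- lapply(reps, function(rd)
            suppressWarnings(c(
                findCandidatePeaks(readCoverage(rd, chrom, "+"), chrom, "+", pc),
                findCandidatePeaks(readCoverage(rd, chrom, "-"), chrom, "-", pc))))
        .fixtureCache$acceptanceRun <- list(
            cfg = cfg, sim = sim, control = control, rnaseq = rnaseq,
            reps = reps, cands = cands, pc = pc, chrom = chrom)
    }
    .fixtureCache$acceptanceRun
}

# Truth-site windows (+-50 nt around the planted motif) as GRanges.
truthWindows <- function(sim, pad = 50L) {
    tr <- truthSites(sim)
    GenomicRanges::GRanges(tr$chromosome,
        IRanges::IRanges(tr$genomic_u1 - pad, tr$genomic_u1 + pad),
        strand = tr$strand)
}

# Genomic coordinates of all planted crosslink positions.
truthCrosslinkPositions <- function(sim) {
    tr <- truthSites(sim)
    tm <- sim@transcripts
    unlist(lapply(seq_len(nrow(tr)), function(j)
        transcriptToGenomic(tm, tr$transcript_id[j],
                            tr$site_position[j] + tr$crosslink_offsets[[j]])))
}

# Build a ClipReads object from a compact spec (1-based closed coords).
makeReads <- function(chrom, start, end, strand = "+",
                      barcode = NULL, mapq = 42L, dels = NULL,
                      seqlen = NA_integer_) {
    n <- length(start)
    if (is.null(barcode))
        barcode <- sprintf("BC%04d", seq_len(n))
    if (is.null(dels)) dels <- rep(list(integer()), n)
    si <- if (!is.na(seqlen))
        GenomeInfoDb::Seqinfo(chrom[1], seqlen) else NULL
    gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
        IRanges::IRanges(start, end),
        strand = rep(strand, length.out = n))
    if (!is.null(si)) GenomeInfoDb::seqinfo(gr) <- si
    names(gr) <- sprintf("read%04d_BC:%s", seq_len(n), barcode)
    clipReads(gr, mapq = rep(mapq, length.out = n), barcode = barcode,
              deletions = IRanges::IntegerList(dels))
}

# Brute-force candidate-peak finder: scan every position, apply the
# 20%-border definition directly. The independent oracle for
# findCandidatePeaks().
bruteCandidates <- function(v, minHeight, borderFrac) {
    n <- length(v)
    spans <- NULL
    for (i in seq_len(n)) {
        left <- if (i > 1) v[i - 1] else -Inf
        right <- if (i < n) v[i + 1] else -Inf
        if (v[i] >= minHeight && v[i] >= left && v[i] >= right) {
            thr <- borderFrac * v[i]
            lo <- i; while (lo > 1 && v[lo - 1] >= thr) lo <- lo - 1
            hi <- i; while (hi < n && v[hi + 1] >= thr) hi <- hi + 1
            spans <- rbind(spans, c(lo, hi))
        }
    }
    if (is.null(spans)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(spans[, 1], spans[, 2]))
    cbind(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
}

# Write a GFF3 fixture and return its path.
writeGff3 <- function(lines) {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), path)
    path
}
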