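# Synthetic-data generator: a seeded genome + annotation + ground-truth
# binding sites, and iCLIP / negative-control / RNA-seq read sets with the
# statistical structure the downstream analysis assumes.

MOTIF_CLASS_PATTERNS <- c(
    canonical_context = "UGUNNNAU",   # plus a forced C at -1 or -2
    canonical         = "UGUNNNAU",   # -1/-2 forced non-C
    sevenmer          = "UGURNAU",
    alternate         = "UGUGUUGU"    # U/G-rich in-vitro-style element
)

#' Build a simulation configuration
#'
#' Returns a validated [SimConfig-class]. Defaults describe a desk-scale
#' world: 200 transcripts of 0.8-3 kb, 35% of them carrying one planted
#' binding site, log-normal expression, an abundance-coupled nonspecific
#' background with sticky crosslink "hotspots" shared between experiment and
#' negative control, 80% cDNA truncation at the crosslink, 60% deletion rate
#' on read-through, 7-nt random barcodes and one expected PCR duplicate per
#' molecule, over 3 replicates. Crosslink offsets relative to motif start are
#' drawn from a skewed distribution on -10..+8 with mode -2 (upstream).
#'
#' @param nTranscripts,transcriptLengthRange,targetFraction,affinityLevels,classProbs,abundanceMeanlog,abundanceSdlog,backgroundRate,truncationProb,deletionProb,bgDeletionProb,barcodeLength,pcrDuplicateRate,nReplicates,readLength,hotspotRate,hotspotFrac,controlRate,rnaseqRate,crosslinkOffsets,crosslinkWeights,spacer,seed see [SimConfig-class].
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nTranscripts = 10, seed = 1)
#' @export
simConfig <- function(nTranscripts = 200L,
                      transcriptLengthRange = c(800L, 3000L),
                      targetFraction = 0.35,
                      affinityLevels = c(canonical_context = 80,
                                         canonical = 60,
                                         sevenmer = 45,
                                         alternate = 35,
                                         none = 0),
                      classProbs = c(canonical_context = 0.35,
                                     canonical = 0.30,
                                     sevenmer = 0.20,
                                     alternate = 0.15),
                      abundanceMeanlog = 0,
                      abundanceSdlog = 0.5,
                      backgroundRate = 30,
                      truncationProb = 0.8,
                      deletionProb = 0.6,
                      bgDeletionProb = 0.002,
                      barcodeLength = 7L,
                      pcrDuplicateRate = 1,
                      nReplicates = 3L,
                      readLength = 35L,
                      hotspotRate = 2,
                      hotspotFrac = 0.4,
                      controlRate = 10,
                      rnaseqRate = 100,
                      crosslinkOffsets = -10:8,
                      crosslinkWeights = c(1, 2, 3, 5, 8, 12, 16, 20, 24,
                                           18, 12, 8, 5, 4, 3, 2, 2, 1, 1),
                      spacer = 150L,
                      seed = 1L) {
    new("SimConfig",
        nTranscripts = as.integer(nTranscripts),
        transcriptLengthRange = as.integer(transcriptLengthRange),
        targetFraction = targetFraction,
        affinityLevels = affinityLevels,
        classProbs = classProbs,
        abundanceMeanlog = abundanceMeanlog,
        abundanceSdlog = abundanceSdlog,
        backgroundRate = backgroundRate,
        truncationProb = truncationProb,
        deletionProb = deletionProb,
        bgDeletionProb = bgDeletionProb,
        barcodeLength = as.integer(barcodeLength),
        pcrDuplicateRate = pcrDuplicateRate,
        nReplicates = as.integer(nReplicates),
        readLength = as.integer(readLength),
        hotspotRate = hotspotRate,
        hotspotFrac = hotspotFrac,
        controlRate = controlRate,
        rnaseqRate = rnaseqRate,
        crosslinkOffsets = as.integer(crosslinkOffsets),
        crosslinkWeights = crosslinkWeights,
        spacer = as.integer(spacer),
        seed = as.integer(seed))
}

# Instantiate a planted motif plus its 4-nt upstream context as RNA chars.
.instantiateSite <- function(cls) {
    pat <- .toRnaChars(MOTIF_CLASS_PATTERNS[[cls]])
    core <- vapply(pat, function(ch) sample(IUPAC_RNA[[ch]], 1L), character(1))
    nonC <- c("A", "G", "U")
    up <- sample(nonC, 4L, replace = TRUE)       # -4..-1
    if (cls == "canonical_context") {
        up[sample(3:4, 1L)] <- "C"               # C at -2 or -1
    }
    paste0(c(up, core), collapse = "")
}

#' Generate a synthetic transcriptome with planted binding sites
#'
#' Lays out single-exon transcripts non-overlapping on both strands of one
#' synthetic chromosome (separated by at least `spacer` nt), assigns each a
#' log-normal abundance and Poisson-distributed background crosslink
#' hotspots, and plants one binding site (motif plus controlled upstream
#' context) on a Bernoulli(`targetFraction`) subset. Sites land mostly in
#' 3'UTRs with a bias toward the 3' end; each carries two planted crosslink
#' positions drawn from the configured upstream-skewed offset distribution.
#' All output is a deterministic function of `seed`.
#'
#' @param config a [SimConfig-class] object.
#' @return a [ClipSimulation-class] object.
#' @export
makeTranscriptome <- function(config) {
    validObject(config)
    set.seed(config@seed)
    n <- config@nTranscripts
    maxMotif <- max(nchar(MOTIF_CLASS_PATTERNS)) + 4L
    if (n > 0L && config@transcriptLengthRange[1] < 4L * maxMotif + 60L)
        stop("transcript length too short to host requested motifs (need >= ",
             4L * maxMotif + 60L, " nt)")
    emptyTruth <- S4Vectors::DataFrame(
        transcript_id = character(), site_position = integer(),
        site_class = character(),
        crosslink_offsets = IRanges::IntegerList(),
        feature_region = character(), chromosome = character(),
        strand = character(), genomic_u1 = integer())
    if (n == 0L) {
        tm <- .newTranscriptModels(
            S4Vectors::DataFrame(gene_id = character(),
                transcript_id = character(), chromosome = character(),
                strand = character(), coding = logical(),
                mature_length = integer()),
            GenomicRanges::GRangesList(), GenomicRanges::GRangesList(),
            GenomicRanges::GRangesList(), GenomicRanges::GRangesList())
        return(new("ClipSimulation",
                   genome = Biostrings::DNAStringSet(),
                   transcripts = tm, truth = emptyTruth,
                   abundance = numeric(),
                   hotspots = IRanges::IntegerList(),
                   config = config))
    }
    lens <- sample(seq(config@transcriptLengthRange[1],
                       config@transcriptLengthRange[2]), n, replace = TRUE)
    strands <- rep(c("+", "-"), length.out = n)
    gaps <- config@spacer
    gstart <- cumsum(c(gaps + 1L, lens[-n] + gaps))
    gend <- gstart + lens - 1L
    chromLen <- gend[n] + gaps
    chrom <- "simChr1"
    seqChars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)

    txId <- sprintf("tx%04d", seq_len(n))
    geneId <- sprintf("gene%04d", seq_len(n))
    # feature structure in transcript coordinates
    u5len <- pmax(50L, as.integer(round(0.10 * lens)))
    cdslen <- as.integer(round(0.50 * lens))
    u3start <- u5len + cdslen + 1L

    abundance <- stats::rlnorm(n, config@abundanceMeanlog, config@abundanceSdlog)
    names(abundance) <- txId

    # planted sites
    isTarget <- stats::runif(n) < config@targetFraction
    truthRows <- list()
    for (i in which(isTarget)) {
        cls <- sample(names(config@classProbs), 1L, prob = config@classProbs)
        region <- sample(c("5UTR", "CDS", "3UTR"), 1L,
                         prob = c(0.05, 0.10, 0.85))
        motifLen <- nchar(MOTIF_CLASS_PATTERNS[[cls]])
        L <- lens[i]
        if (region == "3UTR") {
            lo <- u3start[i]; hi <- L - motifLen - 12L
            frac <- stats::rbeta(1, 3, 1)            # 3'-end biased
            pos <- lo + as.integer(floor(frac * (hi - lo)))
        } else if (region == "CDS") {
            pos <- sample(seq(u5len[i] + 1L, u5len[i] + cdslen[i] - motifLen),
                          1L)
        } else {
            pos <- sample(seq(13L, u5len[i] - motifLen), 1L)
        }
        offs <- sort(sample(config@crosslinkOffsets, 2L,
                            prob = config@crosslinkWeights))
        siteSeq <- .instantiateSite(cls)             # -4..-1 context + motif
        # write into the genome (strand-aware), window starts at pos-4
        win <- chartr("U", "T", siteSeq)
        wlen <- nchar(win)
        gpos <- if (strands[i] == "+") gstart[i] + (pos - 4L) - 1L
                else gend[i] - (pos - 4L) + 1L
        if (strands[i] == "+") {
            seqChars[gpos:(gpos + wlen - 1L)] <-
                strsplit(win, "")[[1]]
        } else {
            rc <- strsplit(as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(win))), "")[[1]]
            seqChars[(gpos - wlen + 1L):gpos] <- rc
        }
        gu1 <- if (strands[i] == "+") gstart[i] + pos - 1L
               else gend[i] - pos + 1L
        truthRows[[length(truthRows) + 1L]] <- list(
            transcript_id = txId[i], site_position = pos, site_class = cls,
            crosslink_offsets = offs, feature_region = region,
            chromosome = chrom, strand = strands[i], genomic_u1 = gu1)
    }
    if (length(truthRows)) {
        truth <- S4Vectors::DataFrame(
            transcript_id = vapply(truthRows, `[[`, character(1),
                                   "transcript_id"),
            site_position = vapply(truthRows, `[[`, integer(1),
                                   "site_position"),
            site_class = vapply(truthRows, `[[`, character(1), "site_class"),
            crosslink_offsets = IRanges::IntegerList(
                lapply(truthRows, `[[`, "crosslink_offsets")),
            feature_region = vapply(truthRows, `[[`, character(1),
                                    "feature_region"),
            chromosome = vapply(truthRows, `[[`, character(1), "chromosome"),
            strand = vapply(truthRows, `[[`, character(1), "strand"),
            genomic_u1 = vapply(truthRows, `[[`, integer(1), "genomic_u1"))
    } else truth <- emptyTruth

    # background hotspots: sticky nonspecific crosslink positions, kept clear
    # of planted sites (they model independent background contacts)
    hot <- vector("list", n)
    for (i in seq_len(n)) {
        nh <- stats::rpois(1, config@hotspotRate)
        if (nh == 0L) { hot[[i]] <- integer(); next }
        avoid <- truth$site_position[truth$transcript_id == txId[i]]
        ok <- seq(1L, lens[i] - config@readLength)
        if (length(avoid))
            ok <- ok[abs(ok - avoid) > 60L]
        hot[[i]] <- sort(sample(ok, min(nh, length(ok))))
    }
    hotspots <- IRanges::IntegerList(hot)
    names(hotspots) <- txId

    genome <- Biostrings::DNAStringSet(paste0(seqChars, collapse = ""))
    names(genome) <- chrom

    exons <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(gstart[i], gend[i]), strand = strands[i])))
    toG <- function(i, lo, hi) {   # transcript interval -> genomic GRanges
        if (hi < lo) return(GenomicRanges::GRanges())
        g1 <- if (strands[i] == "+") gstart[i] + lo - 1L else gend[i] - hi + 1L
        g2 <- if (strands[i] == "+") gstart[i] + hi - 1L else gend[i] - lo + 1L
        GenomicRanges::GRanges(chrom, IRanges::IRanges(g1, g2),
                               strand = strands[i])
    }
    cds <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
        toG(i, u5len[i] + 1L, u5len[i] + cdslen[i])))
    utr5 <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
        toG(i, 1L, u5len[i])))
    utr3 <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
        toG(i, u5len[i] + cdslen[i] + 1L, lens[i])))
    names(exons) <- names(cds) <- names(utr5) <- names(utr3) <- txId

    info <- S4Vectors::DataFrame(
        gene_id = geneId, transcript_id = txId,
        chromosome = chrom, strand = strands,
        coding = rep(TRUE, n), mature_length = as.integer(lens))
    tm <- .newTranscriptModels(info, exons, cds, utr5, utr3)
    new("ClipSimulation", genome = genome, transcripts = tm, truth = truth,
        abundance = abundance, hotspots = hotspots, config = config)
}

# Background molecule 5' starts (transcript coords) for one transcript.
.backgroundStarts <- function(nbg, L, hot, readLength, hotspotFrac) {
    if (nbg == 0L) return(integer())
    useHot <- length(hot) > 0L &
        stats::runif(nbg) < hotspotFrac
    p5 <- integer(nbg)
    if (any(useHot))
        p5[useHot] <- sample(rep(hot, 2L), sum(useHot), replace = TRUE)
    if (any(!useHot))
        p5[!useHot] <- sample(seq_len(max(1L, L - readLength + 1L)),
                              sum(!useHot), replace = TRUE)
    p5
}

# Assemble a ClipReads object from per-molecule transcript-coordinate data.
# mol: data.frame(tx_index, p5, width, delT (NA or transcript coord))
.moleculesToReads <- function(sim, mol, prefix, barcodeLength,
                              pcrDuplicateRate) {
    config <- sim@config
    info <- sim@transcripts@info
    if (nrow(mol) == 0L)
        return(clipReads(GenomicRanges::GRanges(
            seqinfo = GenomeInfoDb::Seqinfo(names(sim@genome),
                                            BiocGenerics::width(sim@genome))),
            mapq = integer(), barcode = character(),
            deletions = IRanges::IntegerList()))
    bc <- if (barcodeLength > 0L)
        .randomBarcodes(nrow(mol), barcodeLength) else rep("", nrow(mol))
    copies <- 1L + stats::rpois(nrow(mol), pcrDuplicateRate)
    idx <- rep(seq_len(nrow(mol)), copies)
    mol <- mol[idx, , drop = FALSE]
    bc <- bc[idx]
    dup <- sequence(copies)

    strand <- info$strand[mol$tx_index]
    # transcript span -> genomic span (single-exon transcripts)
    ex <- sim@transcripts@exons
    gs <- vapply(ex, function(g) BiocGenerics::start(g)[1], integer(1))
    ge <- vapply(ex, function(g) BiocGenerics::end(g)[1], integer(1))
    txs <- gs[mol$tx_index]; txe <- ge[mol$tx_index]
    t1 <- mol$p5; t2 <- mol$p5 + mol$width - 1L
    plus <- strand == "+"
    g1 <- ifelse(plus, txs + t1 - 1L, txe - t2 + 1L)
    g2 <- ifelse(plus, txs + t2 - 1L, txe - t1 + 1L)
    fp <- ifelse(plus, g1, g2)
    delG <- ifelse(is.na(mol$delT), NA_integer_,
                   as.integer(ifelse(plus, txs + mol$delT - 1L,
                                     txe - mol$delT + 1L)))
    dl <- as.list(delG)
    dl[is.na(delG)] <- list(integer())
    dels <- IRanges::IntegerList(dl)
    gr <- GenomicRanges::GRanges(
        info$chromosome[mol$tx_index],
        IRanges::IRanges(g1, g2), strand = strand,
        seqinfo = GenomeInfoDb::Seqinfo(names(sim@genome),
                                        BiocGenerics::width(sim@genome)))
    names(gr) <- sprintf("%s_m%06d_c%d_BC:%s", prefix, idx, dup, bc)
    clipReads(gr, mapq = rep(42L, length(gr)), barcode = bc, deletions = dels)
}

#' Simulate one iCLIP replicate
#'
#' Draws, per planted site, Poisson(`affinity * abundance`) specific
#' crosslinked molecules: each picks one of the site's planted crosslink
#' positions, truncates there (read 5' end at crosslink + 1) with probability
#' `truncationProb`, and otherwise reads through, acquiring a 1-nt deletion
#' at the crosslink with probability `deletionProb`. Background molecules are
#' Poisson(`backgroundRate * abundance`) per transcript, starting at a shared
#' nonspecific hotspot with probability `hotspotFrac` and uniformly
#' otherwise. Every molecule receives a random barcode and is emitted
#' `1 + Poisson(pcrDuplicateRate)` times.
#'
#' @param sim a [ClipSimulation-class] from [makeTranscriptome()].
#' @param replicate replicate index in `1..nReplicates`.
#' @return a [ClipReads-class] object (deduplicated only by accident; run
#'   [collapseDuplicates()] as in a real pipeline).
#' @export
simulateIclip <- function(sim, replicate) {
    config <- sim@config
    if (replicate < 1L || replicate > config@nReplicates)
        stop("replicate index out of range 1..", config@nReplicates)
    set.seed(.deriveSeed(config@seed, replicate))
    info <- sim@transcripts@info
    truth <- sim@truth
    lens <- info$mature_length
    rl <- config@readLength
    rows <- list()
    # specific molecules
    for (j in seq_len(nrow(truth))) {
        i <- match(truth$transcript_id[j], info$transcript_id)
        lambda <- config@affinityLevels[[truth$site_class[j]]] *
            sim@abundance[i]
        nmol <- stats::rpois(1, lambda)
        if (nmol == 0L) next
        cl <- truth$site_position[j] +
            sample(rep(truth$crosslink_offsets[[j]], 2L), nmol, replace = TRUE)
        trunc <- stats::runif(nmol) < config@truncationProb
        u <- sample(3:15, nmol, replace = TRUE)
        p5 <- ifelse(trunc, cl + 1L, pmax(1L, cl - u))
        hasDel <- !trunc & stats::runif(nmol) < config@deletionProb
        t2 <- pmin(p5 + rl - 1L, lens[i])
        w <- t2 - p5 + 1L
        keep <- w >= 18L & p5 >= 1L
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
            tx_index = i, p5 = as.integer(p5[keep]),
            width = as.integer(w[keep]),
            delT = ifelse(hasDel[keep], as.integer(cl[keep]), NA_integer_))
    }
    # background molecules
    for (i in seq_len(nrow(info))) {
        nbg <- stats::rpois(1, config@backgroundRate * sim@abundance[i])
        if (nbg == 0L) next
        p5 <- .backgroundStarts(nbg, lens[i], sim@hotspots[[i]], rl,
                                config@hotspotFrac)
        t2 <- pmin(p5 + rl - 1L, lens[i])
        w <- t2 - p5 + 1L
        hasDel <- stats::runif(nbg) < config@bgDeletionProb
        delT <- ifelse(hasDel & w >= 3L,
                       p5 + pmax(1L, as.integer(stats::runif(nbg) * (w - 2L))),
                       NA_integer_)
        keep <- w >= 18L
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
            tx_index = i, p5 = as.integer(p5[keep]),
            width = as.integer(w[keep]), delT = as.integer(delT[keep]))
    }
    mol <- if (length(rows)) do.call(rbind, rows)
           else data.frame(tx_index = integer(), p5 = integer(),
                           width = integer(), delT = integer())
    .moleculesToReads(sim, mol, sprintf("iclip_rep%d", replicate),
                      config@barcodeLength, config@pcrDuplicateRate)
}

#' Simulate negative-control iCLIP and RNA-seq read sets
#'
#' The negative control is drawn only from the background process (same
#' hotspots and abundance coupling as the experiment, rate `controlRate`),
#' with barcodes and PCR duplicates. RNA-seq reads start uniformly along each
#' transcript with count proportional to abundance (rate `rnaseqRate`), no
#' barcodes, no duplicates.
#'
#' @param sim a [ClipSimulation-class].
#' @return list with elements `control` and `rnaseq`, both [ClipReads-class].
#' @export
simulateControls <- function(sim) {
    config <- sim@config
    set.seed(.deriveSeed(config@seed, 900001L))
    info <- sim@transcripts@info
    lens <- info$mature_length
    rl <- config@readLength
    mkSet <- function(rate, useHotspots, prefix, barcoded, dupRate,
                      delProb) {
        rows <- list()
        for (i in seq_len(nrow(info))) {
            nr <- stats::rpois(1, rate * sim@abundance[i])
            if (nr == 0L) next
            p5 <- if (useHotspots)
                .backgroundStarts(nr, lens[i], sim@hotspots[[i]], rl,
                                  config@hotspotFrac)
            else sample(seq_len(max(1L, lens[i] - rl + 1L)), nr,
                        replace = TRUE)
            t2 <- pmin(p5 + rl - 1L, lens[i])
            w <- t2 - p5 + 1L
            hasDel <- stats::runif(nr) < delProb
            delT <- ifelse(hasDel & w >= 3L,
                           p5 + pmax(1L, as.integer(stats::runif(nr) *
                                                    (w - 2L))),
                           NA_integer_)
            keep <- w >= 18L
            if (!any(keep)) next
            rows[[length(rows) + 1L]] <- data.frame(
                tx_index = i, p5 = as.integer(p5[keep]),
                width = as.integer(w[keep]), delT = as.integer(delT[keep]))
        }
        mol <- if (length(rows)) do.call(rbind, rows)
               else data.frame(tx_index = integer(), p5 = integer(),
                               width = integer(), delT = integer())
        .moleculesToReads(sim, mol, prefix,
                          if (barcoded) config@barcodeLength else 0L, dupRate)
    }
    list(control = mkSet(config@controlRate, TRUE, "ctrl", TRUE,
                         config@pcrDuplicateRate, config@bgDeletionProb),
         rnaseq = mkSet(config@rnaseqRate, FALSE, "rnaseq", FALSE, 0,
                        config@bgDeletionProb))
}
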