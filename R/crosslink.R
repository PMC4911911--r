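# Crosslink-site inference: CIMS (crosslink-induced deletion sites, exact
# binomial test against the global deletion rate) and CITS (truncation
# sites, Poisson pile-up test of read 5' starts against the containing
# gene's mean start rate), replicate reproducibility, and FBE-relative
# positional profiles.

#' CIMS: deletion-based crosslink sites
#'
#' For every position carrying at least one CIGAR deletion, tests the
#' deletion count k against Binomial(n, r) where n is the read depth at the
#' position and r the global deletion rate (total deletions over total
#' covered bases, per strand pooled genome-wide). Positions with upper-tail
#' p below `pCut` are reported.
#'
#' @param reads a collapsed [ClipReads-class].
#' @param pCut significance threshold (default 0.001).
#' @return `GRanges` with `kind = "CIMS"`, `eventCount`, `depth`, `pValue`.
#' @export
findCIMS <- function(reads, pCut = 0.001) {
    empty <- GenomicRanges::GRanges(kind = character(),
        eventCount = integer(), depth = integer(), pValue = numeric())
    if (length(reads) == 0L) return(empty)
    totCov <- sum(as.numeric(BiocGenerics::width(reads)))
    dels <- S4Vectors::mcols(reads)$deletions
    nDel <- sum(S4Vectors::elementNROWS(dels))
    if (totCov == 0 || nDel == 0L) return(empty)
    r <- nDel / totCov
    chrom <- as.character(GenomeInfoDb::seqnames(reads))
    strand <- as.character(BiocGenerics::strand(reads))
    who <- rep(seq_along(reads), S4Vectors::elementNROWS(dels))
    pos <- unlist(dels)
    key <- paste(chrom[who], strand[who], pos, sep = "\r")
    tab <- table(key)
    uk <- names(tab)
    parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    uchrom <- parts[, 1]; ustrand <- parts[, 2]
    upos <- as.integer(parts[, 3])
    k <- as.integer(tab)
    # depth at each deletion position
    n <- integer(length(uk))
    for (cs in unique(paste(uchrom, ustrand))) {
        sel <- paste(uchrom, ustrand) == cs
        c1 <- uchrom[sel][1]; s1 <- ustrand[sel][1]
        cov <- readCoverage(reads, c1, s1)
        covVec <- as.integer(cov)
        n[sel] <- covVec[upos[sel]]
    }
    p <- stats::pbinom(k - 1L, n, r, lower.tail = FALSE)
    keep <- p < pCut
    if (!any(keep)) return(empty)
    GenomicRanges::GRanges(uchrom[keep],
        IRanges::IRanges(upos[keep], upos[keep]), strand = ustrand[keep],
        kind = "CIMS", eventCount = k[keep], depth = n[keep],
        pValue = .clamp01(p[keep]))
}

#' CITS: truncation-based crosslink sites
#'
#' The inferred crosslink is the base immediately 5' (on the read strand) of
#' the read start: start - 1 on `+`, end + 1 on `-`. For every position with
#' k read starts, the null is Poisson with lambda equal to the mean start
#' rate over the containing gene's exonic span; reads outside annotation are
#' pooled into a per-strand genome background rate. Positions with survival
#' p below `pCut` are reported.
#'
#' @param reads a collapsed [ClipReads-class].
#' @param tm a [TranscriptModels-class].
#' @param pCut significance threshold (default 0.001).
#' @return `GRanges` with `kind = "CITS"`, `eventCount` (starts), `depth`
#'   (reads in the containing gene or strand background), `pValue`.
#' @export
findCITS <- function(reads, tm, pCut = 0.001) {
    empty <- GenomicRanges::GRanges(kind = character(),
        eventCount = integer(), depth = integer(), pValue = numeric())
    if (length(reads) == 0L) return(empty)
    chrom <- as.character(GenomeInfoDb::seqnames(reads))
    strand <- as.character(BiocGenerics::strand(reads))
    fp <- S4Vectors::mcols(reads)$fivePrime
    # assign reads to transcripts by 5' position
    info <- tm@info
    exAll <- unlist(tm@exons)
    exTx <- rep(names(tm@exons), S4Vectors::elementNROWS(tm@exons))
    fpGr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(fp, fp),
                                   strand = strand)
    hit <- GenomicRanges::findOverlaps(fpGr, exAll)
    txOf <- rep(NA_character_, length(reads))
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    ml <- info$mature_length[match(exTx[sh], info$transcript_id)]
    o <- order(qh, -ml, exTx[sh])
    first <- !duplicated(qh[o])
    txOf[qh[o][first]] <- exTx[sh][o][first]
    # per-transcript start rates
    txCounts <- table(txOf[!is.na(txOf)])
    lamTx <- as.numeric(txCounts) /
        info$mature_length[match(names(txCounts), info$transcript_id)]
    names(lamTx) <- names(txCounts)
    # strand-level background for unannotated reads
    sl <- GenomeInfoDb::seqlengths(reads)
    out <- is.na(txOf)
    lamBg <- vapply(unique(strand), function(s) {
        len <- sum(as.numeric(sl), na.rm = TRUE)
        if (is.na(len) || len == 0) len <- max(fp)
        sum(out & strand == s) / len
    }, numeric(1))
    key <- paste(chrom, strand, fp, sep = "\r")
    sp <- split(seq_along(reads), key)
    uk <- names(sp)
    k <- S4Vectors::elementNROWS(sp)
    firstIx <- vapply(sp, `[[`, integer(1), 1L)
    lam <- ifelse(is.na(txOf[firstIx]),
                  lamBg[strand[firstIx]],
                  lamTx[txOf[firstIx]])
    depth <- ifelse(is.na(txOf[firstIx]),
                    vapply(strand[firstIx], function(s)
                        sum(out & strand == s), integer(1)),
                    as.integer(txCounts[txOf[firstIx]]))
    p <- stats::ppois(k - 1L, lam, lower.tail = FALSE)
    keep <- p < pCut
    if (!any(keep)) return(empty)
    fpK <- unname(fp[firstIx][keep])
    sK <- unname(strand[firstIx][keep])
    site <- ifelse(sK == "-", fpK + 1L, fpK - 1L)
    GenomicRanges::GRanges(unname(chrom[firstIx][keep]),
        IRanges::IRanges(site, site), strand = sK,
        kind = "CITS", eventCount = unname(as.integer(k[keep])),
        depth = unname(depth[keep]), pValue = unname(.clamp01(p[keep])))
}

#' Replicate-reproducible crosslink sites
#'
#' Keeps sites significant at the identical (chromosome, strand, position,
#' kind) in at least `minSupport` replicate site lists; event counts are
#' summed over supporting replicates.
#'
#' @param siteLists list of per-replicate `GRanges` from [findCIMS()] /
#'   [findCITS()].
#' @param minSupport replicates required (default 2).
#' @return merged `GRanges` with `replicateSupport` and summed `eventCount`.
#' @export
reproducibleSites <- function(siteLists, minSupport = 2L) {
    all <- do.call(c, lapply(seq_along(siteLists), function(i) {
        g <- siteLists[[i]]
        if (length(g)) g$replicate <- i
        g
    }))
    if (length(all) == 0L) return(all)
    key <- paste(as.character(GenomeInfoDb::seqnames(all)),
                 as.character(BiocGenerics::strand(all)),
                 BiocGenerics::start(all), all$kind, sep = "\r")
    sp <- split(seq_along(all), key)
    support <- vapply(sp, function(ix)
        length(unique(all$replicate[ix])), integer(1))
    keep <- support >= minSupport
    firstIx <- vapply(sp, `[[`, integer(1), 1L)
    out <- all[firstIx[keep]]
    names(out) <- NULL
    out$eventCount <- unname(vapply(sp[keep], function(ix)
        sum(all$eventCount[ix]), numeric(1)))
    out$pValue <- unname(vapply(sp[keep], function(ix)
        min(all$pValue[ix]), numeric(1)))
    out$replicateSupport <- unname(support[keep])
    out$replicate <- NULL
    BiocGenerics::sort(out)
}

#' Crosslink-site profile relative to the FBE
#'
#' Counts crosslink sites at each strand-aware offset relative to the start
#' (U1, offset 0) of FBE matches, over `-window..window`, normalized to sum
#' one; optionally emits the 21-nt sequence windows around the sites for
#' motif search.
#'
#' @param sites `GRanges` of crosslink sites.
#' @param fbeHits `GRanges` of FBE motif starts (the range start on `+`, the
#'   range end on `-`, marks U1).
#' @param window maximum absolute offset (default 20).
#' @param genome optional `DNAStringSet`; when given, 21-nt windows around
#'   each site are returned.
#' @return list with `profile` (`data.frame`: offset, count, fraction) and
#'   `windows` (character vector, possibly empty).
#' @export
crosslinkProfile <- function(sites, fbeHits, window = 20L, genome = NULL) {
    offs <- seq(-window, window)
    counts <- integer(length(offs))
    if (length(fbeHits) == 0L || length(sites) == 0L)
        return(list(profile = data.frame(offset = offs, count = counts,
                                         fraction = rep(NA_real_,
                                                        length(offs))),
                    windows = character()))
    u1 <- ifelse(as.character(BiocGenerics::strand(fbeHits)) == "-",
                 BiocGenerics::end(fbeHits), BiocGenerics::start(fbeHits))
    fchrom <- as.character(GenomeInfoDb::seqnames(fbeHits))
    fstrand <- as.character(BiocGenerics::strand(fbeHits))
    schrom <- as.character(GenomeInfoDb::seqnames(sites))
    sstrand <- as.character(BiocGenerics::strand(sites))
    spos <- BiocGenerics::start(sites)
    for (j in seq_along(fbeHits)) {
        sel <- schrom == fchrom[j] & sstrand == fstrand[j] &
            abs(spos - u1[j]) <= window
        if (!any(sel)) next
        d <- spos[sel] - u1[j]
        if (fstrand[j] == "-") d <- -d
        counts <- counts + tabulate(d + window + 1L, nbins = length(offs))
    }
    frac <- if (sum(counts)) counts / sum(counts) else rep(NA_real_,
                                                           length(offs))
    windows <- character()
    if (!is.null(genome) && length(sites)) {
        windows <- vapply(seq_along(sites), function(k)
            .windowSequence(genome, schrom[k], sstrand[k], spos[k],
                            10L)$seq, character(1))
    }
    list(profile = data.frame(offset = offs, count = counts,
                              fraction = frac),
         windows = windows)
}
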