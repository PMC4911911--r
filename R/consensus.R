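# Secondary fold-enrichment filter, k-of-n replicate consensus, abundance
# normalization and target-list construction.

#' Consensus/filter configuration
#'
#' @param minRatio minimum experimental/control read ratio in the local
#'   window (the fivefold secondary filter).
#' @param window width of the enrichment window centered on the peak
#'   maximum (nt).
#' @param kRequired replicates that must contribute an overlapping call
#'   (3-of-3 per protein; 5-of-6 for a combined list).
#' @param mergedRatio,perReplicateRatio alternative normalized reads-in-peak
#'   cutoffs used only for replicate-Venn style reporting.
#' @return a list of class `FilterConfig`.
#' @export
filterConfig <- function(minRatio = 5, window = 500L, kRequired = 3L,
                         mergedRatio = 3, perReplicateRatio = 2.5) {
    stopifnot(minRatio >= 0, window >= 1L, kRequired >= 1L)
    structure(list(minRatio = minRatio, window = as.integer(window),
                   kRequired = as.integer(kRequired),
                   mergedRatio = mergedRatio,
                   perReplicateRatio = perReplicateRatio),
              class = "FilterConfig")
}

# reads overlapping the window centered on each peak maximum
.windowCounts <- function(peaks, reads, window) {
    half <- window %/% 2L
    win <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(peaks),
        IRanges::IRanges(pmax(1L, peaks$maxPos - half),
                         peaks$maxPos + half - 1L),
        strand = BiocGenerics::strand(peaks))
    GenomicRanges::countOverlaps(win, reads)
}

#' Fold-enrichment secondary filter
#'
#' Keeps a peak when experimental reads overlapping the `window`-nt window
#' centered on its maximum are at least `minRatio` times the negative-
#' control reads in the same window; a control with no reads is assigned one
#' read. The boundary is inclusive (ratio exactly `minRatio` is kept); at
#' `minRatio = 0` the filter is the identity.
#'
#' @param peaks `GRanges` of peak calls (with `maxPos`).
#' @param expReads,controlReads [ClipReads-class] objects.
#' @param config a [filterConfig()].
#' @return the filtered `GRanges`, with an `enrichmentRatio` column added.
#' @export
enrichmentFilter <- function(peaks, expReads, controlReads,
                             config = filterConfig()) {
    if (length(peaks) == 0L) { peaks$enrichmentRatio <- numeric(); return(peaks) }
    ex <- .windowCounts(peaks, expReads, config$window)
    ct <- pmax(.windowCounts(peaks, controlReads, config$window), 1L)
    ratio <- ex / ct
    peaks$enrichmentRatio <- ratio
    peaks[ratio >= config$minRatio]
}

#' Replicate-consensus peaks
#'
#' Clusters peaks across replicates by single-linkage span overlap (at least
#' 1 nt, same strand); the consensus span is the union of member spans,
#' support is the number of replicates contributing an overlapping call, and
#' height the maximum member height. Clusters with support below
#' `kRequired` are dropped.
#'
#' @param peakSets list of per-replicate peak `GRanges` (with `height`,
#'   `maxPos`).
#' @param kRequired replicates required (default 3, the 3-of-3 rule; use 5
#'   with six replicate sets for a combined two-protein list).
#' @return consensus `GRanges` with `support`, `height`, `maxPos`.
#' @export
reproduciblePeaks <- function(peakSets, kRequired = 3L) {
    stopifnot(length(peakSets) >= 1L)
    grl <- lapply(seq_along(peakSets), function(i) {
        g <- GenomicRanges::granges(peakSets[[i]])
        g$height <- peakSets[[i]]$height
        g$maxPos <- peakSets[[i]]$maxPos
        g$replicate <- i
        g
    })
    all <- do.call(c, grl)
    if (length(all) == 0L)
        return(GenomicRanges::GRanges(support = integer(), height = integer(),
                                      maxPos = integer()))
    clusters <- GenomicRanges::reduce(all)   # strand-aware single linkage
    hit <- GenomicRanges::findOverlaps(all, clusters)
    cl <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    support <- vapply(split(all$replicate, cl), function(x)
        length(unique(x)), integer(1))
    height <- vapply(split(all$height, cl), max, numeric(1))
    tallest <- vapply(split(seq_along(all), cl), function(ix)
        ix[which.max(all$height[ix])], integer(1))
    out <- clusters[as.integer(names(support))]
    out$support <- as.integer(support)
    out$height <- height
    out$maxPos <- all$maxPos[tallest]
    out[out$support >= kRequired]
}

#' Normalize peak heights to RNA abundance
#'
#' Divides each peak height by its gene's RNA-seq density, defined as reads
#' per nucleotide of mature transcript per million mapped RNA-seq reads;
#' genes with no RNA-seq signal use the floor `eps` (flagged in
#' `lowAbundance`). Peaks not assignable to a gene get `NA`.
#'
#' @param peaks consensus `GRanges` (a `gene_id` column is added when
#'   absent, via max-position assignment).
#' @param rnaseqReads [ClipReads-class] RNA-seq reads.
#' @param tm [TranscriptModels-class].
#' @param eps density floor (default 0.1).
#' @return `peaks` with `rnaseqDensity`, `normalizedHeight`, `lowAbundance`.
#' @export
normalizeHeight <- function(peaks, rnaseqReads, tm, eps = 0.1) {
    peaks <- assignPeaksToGenes(peaks, tm)
    total <- max(length(rnaseqReads), 1L)   # empty library -> zero density
    info <- tm@info
    dens <- rep(NA_real_, length(peaks))
    for (k in seq_along(peaks)) {
        txId <- peaks$transcript_id[k]
        if (is.na(txId)) next
        i <- match(txId, info$transcript_id)
        cnt <- sum(GenomicRanges::countOverlaps(tm@exons[[i]], rnaseqReads))
        dens[k] <- cnt / info$mature_length[i] / (total / 1e6)
    }
    peaks$rnaseqDensity <- dens
    peaks$lowAbundance <- !is.na(dens) & dens < eps
    peaks$normalizedHeight <- peaks$height / pmax(dens, eps)
    peaks$normalizedHeight[is.na(dens)] <- NA_real_
    peaks
}

#' Assign peaks to genes by their maximum position
#'
#' A peak belongs to the transcript whose exons contain its `maxPos` (same
#' strand); when several transcripts qualify the longest mature transcript
#' wins. Unassignable peaks get NA.
#'
#' @param peaks `GRanges` with `maxPos`.
#' @param tm [TranscriptModels-class].
#' @return `peaks` with `transcript_id` and `gene_id` columns.
#' @export
assignPeaksToGenes <- function(peaks, tm) {
    info <- tm@info
    txId <- .containingTranscripts(
        tm, as.character(GenomeInfoDb::seqnames(peaks)),
        as.character(BiocGenerics::strand(peaks)), peaks$maxPos)
    peaks$transcript_id <- txId
    peaks$gene_id <- info$gene_id[match(txId, info$transcript_id)]
    peaks
}

#' Build the per-gene target list
#'
#' One row per gene carrying at least one consensus peak: peak count,
#' tallest peak height and location, and rank by tallest normalized height
#' (raw height when normalization is absent); ties broken by lexicographic
#' gene order. Peaks in unannotated space are returned separately.
#'
#' @param peaks consensus `GRanges`, ideally after [normalizeHeight()].
#' @param tm [TranscriptModels-class].
#' @return list with `targets` (data.frame) and `unassigned` (`GRanges`).
#' @export
buildTargetList <- function(peaks, tm) {
    if (!("gene_id" %in% colnames(S4Vectors::mcols(peaks))))
        peaks <- assignPeaksToGenes(peaks, tm)
    assigned <- peaks[!is.na(peaks$gene_id)]
    unassigned <- peaks[is.na(peaks$gene_id)]
    if (length(assigned) == 0L)
        return(list(targets = data.frame(gene_id = character(),
            peak_count = integer(), tallest_height = numeric(),
            tallest_chrom = character(), tallest_maxPos = integer(),
            rank_height = numeric(), rank = integer()),
            unassigned = unassigned))
    rankBy <- if ("normalizedHeight" %in%
                  colnames(S4Vectors::mcols(assigned)) &&
                  !all(is.na(assigned$normalizedHeight)))
        assigned$normalizedHeight else assigned$height
    sp <- split(seq_along(assigned), assigned$gene_id)
    rows <- lapply(names(sp), function(g) {
        ix <- sp[[g]]
        top <- ix[which.max(assigned$height[ix])]
        data.frame(gene_id = g, peak_count = length(ix),
                   tallest_height = assigned$height[top],
                   tallest_chrom = as.character(
                       GenomeInfoDb::seqnames(assigned[top])),
                   tallest_maxPos = assigned$maxPos[top],
                   rank_height = max(rankBy[ix], na.rm = TRUE))
    })
    targets <- do.call(rbind, rows)
    targets <- targets[order(-targets$rank_height, targets$gene_id), ]
    targets$rank <- seq_len(nrow(targets))
    rownames(targets) <- NULL
    list(targets = targets, unassigned = unassigned)
}
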