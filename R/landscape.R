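# Binding-landscape statistics: feature assignment, primary/secondary peak
# decomposition ("un-merging"), 3'-end bias, and generic target-list overlap
# and rank-correlation tests.

#' Assign peaks to transcript features
#'
#' The region label is decided by the position of the peak maximum: the
#' transcript interval (5'UTR, CDS or 3'UTR) containing `maxPos`, `ncRNA`
#' for noncoding transcripts, `intergenic` outside all transcripts.
#' Multi-isoform positions use the longest mature isoform. The distance to
#' the transcript 3' end is computed in mature-transcript coordinates.
#'
#' @param peaks `GRanges` with `maxPos`.
#' @param tm a [TranscriptModels-class].
#' @return `peaks` with `gene_id`, `transcript_id`, `region` and
#'   `distance_to_3p_end` columns.
#' @export
assignFeature <- function(peaks, tm) {
    peaks <- assignPeaksToGenes(peaks, tm)
    info <- tm@info
    region <- rep("intergenic", length(peaks))
    dist3p <- rep(NA_integer_, length(peaks))
    for (k in seq_along(peaks)) {
        txId <- peaks$transcript_id[k]
        if (is.na(txId)) next
        i <- match(txId, info$transcript_id)
        mp <- peaks$maxPos[k]
        if (!info$coding[i]) {
            region[k] <- "ncRNA"
        } else {
            inAny <- function(grl) {
                g <- grl[[i]]
                length(g) && any(mp >= BiocGenerics::start(g) &
                                 mp <= BiocGenerics::end(g))
            }
            region[k] <- if (inAny(tm@utr5)) "5UTR"
                         else if (inAny(tm@utr3)) "3UTR"
                         else "CDS"
        }
        tpos <- genomicToTranscript(tm, txId, mp)
        dist3p[k] <- info$mature_length[i] - tpos
    }
    peaks$region <- region
    peaks$distance_to_3p_end <- dist3p
    peaks
}

#' Un-merge a consensus peak into sub-peaks
#'
#' Re-applies peak finding within the peak span with merging disabled: local
#' maxima separated by a valley strictly below `borderFrac` times the
#' smaller neighbouring height become distinct sub-peaks (a valley exactly
#' at threshold keeps them merged). Sub-peak spans use the 20%-border rule
#' within the parent span; sub-peaks are returned ordered by height.
#'
#' @param peak a length-1 `GRanges` (the consensus span).
#' @param cov coverage `Rle` for the peak's chromosome and strand.
#' @param config a [peakCallConfig()].
#' @return `GRanges` of sub-peaks with `height`, `maxPos` and
#'   `sub_peak_index` (1 = primary).
#' @export
unmergePeak <- function(peak, cov, config = peakCallConfig()) {
    s0 <- BiocGenerics::start(peak); e0 <- BiocGenerics::end(peak)
    v <- as.integer(cov)[s0:e0]
    r <- rle(v)
    nr <- length(r$values)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    prev <- c(-Inf, r$values[-nr]); nxt <- c(r$values[-1], -Inf)
    maxRuns <- which(r$values >= config$minHeight &
                     r$values >= prev & r$values >= nxt)
    if (!length(maxRuns))
        return(GenomicRanges::GRanges(height = integer(), maxPos = integer(),
                                      sub_peak_index = integer()))
    # merge neighbouring maxima whose separating valley is not deep enough
    groups <- list(maxRuns[1])
    if (length(maxRuns) > 1L) {
        for (j in 2:length(maxRuns)) {
            a <- maxRuns[j - 1L]; b <- maxRuns[j]
            valley <- min(r$values[(a + 1L):(b - 1L)])
            h <- min(r$values[a], r$values[b])
            if (valley < config$borderFrac * h) {
                groups[[length(groups) + 1L]] <- b
            } else {
                groups[[length(groups)]] <-
                    unique(c(groups[[length(groups)]], b))
            }
        }
    }
    subs <- lapply(groups, function(g) {
        top <- g[which.max(r$values[g])]
        h <- r$values[top]
        thr <- config$borderFrac * h
        l <- min(g); u <- max(g)
        while (l > 1L && r$values[l - 1L] >= thr) l <- l - 1L
        while (u < nr && r$values[u + 1L] >= thr) u <- u + 1L
        seg <- v[starts[l]:ends[u]]
        c(start = starts[l], end = ends[u], height = h,
          maxPos = starts[l] + which.max(seg) - 1L)
    })
    m <- do.call(rbind, subs)
    o <- order(-m[, "height"], m[, "start"])
    m <- m[o, , drop = FALSE]
    GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(peak)),
        IRanges::IRanges(s0 + m[, "start"] - 1L, s0 + m[, "end"] - 1L),
        strand = BiocGenerics::strand(peak),
        height = as.integer(m[, "height"]),
        maxPos = as.integer(s0 + m[, "maxPos"] - 1L),
        sub_peak_index = seq_len(nrow(m)))
}

#' Per-gene multi-peak summary and transcript-length comparison
#'
#' Counts distinct (un-merged) peaks per gene and compares mature transcript
#' lengths of multi-peak versus single-peak targets with a two-sided
#' rank-sum test.
#'
#' @param peaks `GRanges` of (sub-)peaks with `gene_id` (see
#'   [assignPeaksToGenes()]).
#' @param tm a [TranscriptModels-class].
#' @return list with `perGene` (data.frame gene_id, peak_count,
#'   mature_length), `multiPeakFraction`, `medianLengths` (multi, single)
#'   and `lengthTest` (wilcoxon p-value, NA when a group is empty).
#' @export
multiPeakSummary <- function(peaks, tm) {
    peaks <- peaks[!is.na(peaks$gene_id)]
    info <- tm@info
    cnt <- table(peaks$gene_id)
    perGene <- data.frame(gene_id = names(cnt),
                          peak_count = as.integer(cnt))
    tx <- peaks$transcript_id[match(perGene$gene_id, peaks$gene_id)]
    perGene$mature_length <-
        info$mature_length[match(tx, info$transcript_id)]
    multi <- perGene$peak_count > 1L
    p <- NA_real_
    if (any(multi) && any(!multi))
        p <- stats::wilcox.test(perGene$mature_length[multi],
                                perGene$mature_length[!multi],
                                alternative = "two.sided", exact = FALSE)$p.value
    list(perGene = perGene,
         multiPeakFraction = mean(multi),
         medianLengths = c(multi = stats::median(
                               perGene$mature_length[multi]),
                           single = stats::median(
                               perGene$mature_length[!multi])),
         lengthTest = p)
}

#' 3'-end bias of FBE read coverage
#'
#' Spearman rank correlation between the read coverage over 3'UTR FBEs and
#' their proximity to the transcript 3' end (proximity = negative distance,
#' so positive rho means taller coverage closer to the 3' end). Ties take
#' average ranks. Fewer than 3 points is undefined (NA, flagged).
#'
#' @param coverageAtFbe numeric read coverage per FBE site.
#' @param distanceTo3p nt from the FBE to the transcript 3' end.
#' @return list with `rho`, `p`, `n`, `defined`.
#' @export
threePrimeBias <- function(coverageAtFbe, distanceTo3p) {
    ok <- !is.na(coverageAtFbe) & !is.na(distanceTo3p)
    n <- sum(ok)
    if (n < 3L)
        return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(coverageAtFbe[ok],
                                           -distanceTo3p[ok],
                                           method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Overlap of two gene lists (Fisher's exact test)
#'
#' Builds the 2x2 membership table of two lists within a common universe and
#' returns the odds ratio and the two-sided Fisher exact p-value.
#'
#' @param listA,listB character vectors (subsets of the universe).
#' @param universe character vector of all possible genes (non-empty).
#' @return list with `oddsRatio`, `p` and the 2x2 `table`.
#' @export
overlapTest <- function(listA, listB, universe) {
    if (length(universe) == 0L) stop("empty universe")
    a <- universe %in% listA
    b <- universe %in% listB
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                  nrow = 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(oddsRatio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Rank correlation of two ordered target lists
#'
#' Spearman correlation over the items shared by two ranked lists (each
#' given best-first); p-value by exact permutation distribution for n <= 9
#' and the t-approximation otherwise.
#'
#' @param rankedA,rankedB character vectors in rank order.
#' @return list with `rho`, `p`, `n` (NA rho when fewer than 3 shared).
#' @export
rankCorrelation <- function(rankedA, rankedB) {
    shared <- intersect(rankedA, rankedB)
    n <- length(shared)
    if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
    x <- match(shared, rankedA)
    y <- match(shared, rankedB)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = (n <= 9L)))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
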