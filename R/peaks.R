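# Candidate peak discovery and the six background-model peak-calling
# strategies: {RNA-seq, negative-control iCLIP, self iCLIP} backgrounds
# crossed with {whole mature transcript, local 500-bp} regions. The maximum
# 50-nt bin of read 5' ends in the region is tested against the background
# distribution; Bonferroni (per peak, times the number of modelled bins) and
# Benjamini-Hochberg (over all candidates, 1% FDR) control follow.

#' Peak-calling configuration
#'
#' @param binWidth width of 5'-end bins (nt).
#' @param localWindow width of the local background region centered on the
#'   peak maximum (nt).
#' @param borderFrac peak borders are placed where coverage falls below this
#'   fraction of the peak height.
#' @param minHeight minimum coverage for a candidate peak maximum (reads).
#' @param fdrQ Benjamini-Hochberg FDR cutoff.
#' @param backgroundModel distribution fitted to background bins for methods
#'   1-4: `"gaussian"` (default), `"poisson"` or `"negbinom"`. Methods 5 and
#'   6 (self background) always use Poisson.
#' @return a validated list of class `PeakCallConfig`.
#' @export
peakCallConfig <- function(binWidth = 50L, localWindow = 500L,
                           borderFrac = 0.2, minHeight = 10L,
                           fdrQ = 0.01,
                           backgroundModel = c("gaussian", "poisson",
                                               "negbinom")) {
    backgroundModel <- match.arg(backgroundModel)
    stopifnot(binWidth >= 1L, localWindow >= binWidth,
              borderFrac > 0, borderFrac < 1, minHeight >= 1L,
              fdrQ > 0, fdrQ <= 1)
    structure(list(binWidth = as.integer(binWidth),
                   localWindow = as.integer(localWindow),
                   borderFrac = borderFrac,
                   minHeight = as.integer(minHeight),
                   fdrQ = fdrQ, backgroundModel = backgroundModel),
              class = "PeakCallConfig")
}

# Local maxima of an integer coverage vector, as run indices of the rle.
.peakSpansFromVector <- function(v, minHeight, borderFrac, merge = TRUE) {
    r <- rle(v)
    nr <- length(r$values)
    if (nr == 0L) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    prev <- c(-Inf, r$values[-nr])
    nxt <- c(r$values[-1], -Inf)
    isMax <- r$values >= minHeight & r$values >= prev & r$values >= nxt
    idx <- which(isMax)
    if (!length(idx)) return(NULL)
    spans <- matrix(0L, nrow = length(idx), ncol = 2L)
    for (k in seq_along(idx)) {
        h <- r$values[idx[k]]
        thr <- borderFrac * h
        # extend over whole runs while run value >= thr
        l <- idx[k]
        while (l > 1L && r$values[l - 1L] >= thr) l <- l - 1L
        u <- idx[k]
        while (u < nr && r$values[u + 1L] >= thr) u <- u + 1L
        spans[k, ] <- c(starts[l], ends[u])
    }
    ir <- IRanges::IRanges(spans[, 1], spans[, 2])
    if (merge) ir <- IRanges::reduce(ir)
    else ir <- unique(ir)
    ir
}

#' Find candidate peaks in a coverage track
#'
#' Scans for local coverage maxima of at least `minHeight` reads, extends
#' each bidirectionally until coverage falls below `borderFrac` times the
#' peak height (the 20%-of-height border rule), and merges overlapping
#' spans; the merged height is the maximum over members and `maxPos` the
#' leftmost position attaining it.
#'
#' @param cov an integer `Rle` from [readCoverage()].
#' @param chrom,strand placed on the returned ranges.
#' @param config a [peakCallConfig()].
#' @return `GRanges` with metadata columns `height` and `maxPos`.
#' @export
findCandidatePeaks <- function(cov, chrom = "chr", strand = "+",
                               config = peakCallConfig()) {
    v <- as.integer(cov)
    ir <- .peakSpansFromVector(v, config$minHeight, config$borderFrac,
                               merge = TRUE)
    if (is.null(ir) || length(ir) == 0L)
        return(GenomicRanges::GRanges(height = integer(), maxPos = integer()))
    height <- maxPos <- integer(length(ir))
    for (k in seq_along(ir)) {
        seg <- v[BiocGenerics::start(ir)[k]:BiocGenerics::end(ir)[k]]
        height[k] <- max(seg)
        maxPos[k] <- BiocGenerics::start(ir)[k] + which.max(seg) - 1L
    }
    GenomicRanges::GRanges(chrom, ir, strand = strand,
                           height = height, maxPos = maxPos)
}

#' Bin read 5' ends over a region
#'
#' Non-overlapping `binWidth`-nt bins are tiled from the region start; a
#' partial final bin is kept. Multi-interval regions (whole-transcript mode)
#' are binned along their concatenated length.
#'
#' @param reads a [ClipReads-class].
#' @param region a `GRanges` of one or more same-strand intervals.
#' @param binWidth bin width in nt (default 50).
#' @return integer vector of counts of read 5' ends per bin.
#' @export
binReads <- function(reads, region, binWidth = 50L) {
    totalLen <- sum(BiocGenerics::width(region))
    if (totalLen < binWidth) stop("region shorter than one bin")
    nb <- as.integer(ceiling(totalLen / binWidth))
    fp <- S4Vectors::mcols(reads)$fivePrime
    sel <- as.character(GenomeInfoDb::seqnames(reads)) ==
        as.character(GenomeInfoDb::seqnames(region))[1]
    regStrand <- as.character(BiocGenerics::strand(region))[1]
    if (regStrand != "*")
        sel <- sel & as.character(BiocGenerics::strand(reads)) == regStrand
    fp <- fp[sel]
    # map 5' positions to concatenated-region offsets (genomic order)
    region <- BiocGenerics::sort(region)
    offs <- integer(0)
    base <- 0L
    for (k in seq_along(region)) {
        s <- BiocGenerics::start(region)[k]; e <- BiocGenerics::end(region)[k]
        ink <- fp >= s & fp <= e
        offs <- c(offs, base + fp[ink] - s + 1L)
        base <- base + (e - s + 1L)
    }
    tabulate((offs - 1L) %/% binWidth + 1L, nbins = nb)
}

#' Background tail probability for the tallest bin
#'
#' P(X >= xMax) under a background distribution fitted to the bin counts:
#' `gaussian` fits a Normal by moments with the standard deviation floored
#' at 1 read; `poisson` uses the bin mean (floored at 1/number-of-bins when
#' the background is empty); `negbinom` fits by method of moments with a
#' Poisson fallback when the variance does not exceed the mean. Returns a
#' value in (0, 1]; `xMax = 0` always gives 1.
#'
#' @param xMax observed maximum bin count (nonnegative integer).
#' @param bgBins integer vector of background bin counts (non-empty).
#' @param model `"gaussian"`, `"poisson"` or `"negbinom"`.
#' @return a single p-value.
#' @export
backgroundPvalue <- function(xMax, bgBins,
                             model = c("gaussian", "poisson", "negbinom")) {
    model <- match.arg(model)
    if (length(bgBins) == 0L) stop("background_bins must be non-empty")
    if (is.na(xMax) || xMax < 0) stop("x_max must be a nonnegative count")
    if (xMax == 0) return(1)
    m <- mean(bgBins)
    if (model == "gaussian") {
        s <- stats::sd(bgBins)
        if (is.na(s) || s < 1) s <- 1     # integer counts: floor sigma
        return(.clamp01(stats::pnorm(xMax, mean = m, sd = s,
                                     lower.tail = FALSE)))
    }
    lam <- max(m, 1 / length(bgBins))
    if (model == "negbinom") {
        v <- stats::var(bgBins)
        if (!is.na(v) && v > m && m > 0) {
            size <- m^2 / (v - m)
            return(.clamp01(stats::pnbinom(xMax - 1, size = size, mu = m,
                                           lower.tail = FALSE)))
        }
        # fall through to Poisson
    }
    .clamp01(stats::ppois(xMax - 1, lambda = lam, lower.tail = FALSE))
}

# method index -> (background source, region mode, model)
.methodSpec <- function(method, config) {
    if (!(method %in% 1:6)) stop("method must be in 1..6")
    bg <- c("rnaseq", "rnaseq", "control", "control", "self", "self")[method]
    regionMode <- if (method %% 2L == 1L) "whole_gene" else "local"
    model <- if (bg == "self") "poisson" else config$backgroundModel
    list(background = bg, regionMode = regionMode, model = model)
}

# Region GRanges for one candidate under a region mode; falls back to local
# (with a warning) when no transcript contains the maximum. txId may be a
# precomputed assignment (NA = unassigned).
.candidateRegion <- function(cand, regionMode, tm, config, seqLen,
                             txId = NULL) {
    chrom <- as.character(GenomeInfoDb::seqnames(cand))
    strand <- as.character(BiocGenerics::strand(cand))
    mp <- cand$maxPos
    local <- function() {
        half <- config$localWindow %/% 2L
        lo <- max(1L, mp - half)
        hi <- mp + half - 1L
        if (!is.na(seqLen)) hi <- min(hi, seqLen)
        GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi),
                               strand = strand)
    }
    if (regionMode == "local") return(local())
    if (is.null(txId)) txId <- .containingTranscript(tm, chrom, strand, mp)
    if (is.na(txId)) {
        warning("candidate at ", chrom, ":", mp,
                " outside all transcripts; using local region")
        return(local())
    }
    .exonicSpan(tm, txId)
}

#' Call peaks with one of the six background methods
#'
#' For each candidate peak, the tallest `binWidth`-nt bin of experimental
#' read 5' ends in the method's region (local window centered on the peak
#' maximum, or all exons of the containing transcript) is tested against the
#' method's background read source binned over the same region. Methods 1/2
#' use RNA-seq background, 3/4 the negative-control iCLIP, 5/6 the
#' experimental signal itself (always Poisson); odd methods use the
#' whole-transcript region, even methods the local window. Bonferroni
#' multiplies each p-value by the number of modelled bins; Benjamini-
#' Hochberg q-values are computed over the full candidate set.
#'
#' @param candidates `GRanges` from [findCandidatePeaks()].
#' @param expReads experimental [ClipReads-class].
#' @param controlReads pooled negative-control [ClipReads-class] (methods
#'   3/4).
#' @param rnaseqReads RNA-seq [ClipReads-class] (methods 1/2).
#' @param tm a [TranscriptModels-class] (whole-transcript regions).
#' @param method integer 1..6.
#' @param config a [peakCallConfig()].
#' @param depthNormalize scale background bin counts by the ratio of total
#'   experimental to total background reads before fitting, so that
#'   background libraries of different depth (negative-control iCLIP
#'   libraries are typically much shallower) are compared on the
#'   experimental scale. Identity for the self background.
#' @return `GRanges` with `height`, `maxPos`, `method`, `maxBinCount`,
#'   `nBins`, `pRaw`, `pBonferroni`, `qBH` and `significant` (q <= `fdrQ`).
#' @export
callPeaks <- function(candidates, expReads, controlReads = NULL,
                      rnaseqReads = NULL, tm = NULL, method = 4L,
                      config = peakCallConfig(), depthNormalize = TRUE) {
    spec <- .methodSpec(method, config)
    bgReads <- switch(spec$background,
                      rnaseq = rnaseqReads,
                      control = controlReads,
                      self = expReads)
    if (is.null(bgReads))
        stop("method ", method, " needs ", spec$background, " reads")
    if (spec$regionMode == "whole_gene" && is.null(tm))
        stop("whole-gene methods need transcript models")
    n <- length(candidates)
    pRaw <- numeric(n)
    xMax <- nBins <- integer(n)
    scale <- 1
    if (depthNormalize && spec$background != "self" && length(bgReads))
        scale <- length(expReads) / length(bgReads)
    sl <- GenomeInfoDb::seqlengths(expReads)
    txAssign <- if (spec$regionMode == "whole_gene" && n)
        .containingTranscripts(tm,
            as.character(GenomeInfoDb::seqnames(candidates)),
            as.character(BiocGenerics::strand(candidates)),
            candidates$maxPos)
    else rep(NA_character_, n)
    for (k in seq_len(n)) {
        cand <- candidates[k]
        seqLen <- sl[as.character(GenomeInfoDb::seqnames(cand))]
        region <- .candidateRegion(cand, spec$regionMode, tm, config,
                                   if (length(seqLen)) seqLen else NA,
                                   txId = if (spec$regionMode == "whole_gene")
                                       txAssign[k] else NULL)
        # the test statistic is the tallest bin within the candidate span;
        # the region only defines the background model
        span <- GenomicRanges::granges(cand)
        if (BiocGenerics::width(span) < config$binWidth) {
            pad <- config$binWidth - BiocGenerics::width(span)
            span <- GenomicRanges::resize(span,
                                          config$binWidth,
                                          fix = "center")
            span <- GenomicRanges::shift(span,
                max(0L, 1L - BiocGenerics::start(span)))
        }
        expBins <- binReads(expReads, span, config$binWidth)
        bgBins <- binReads(bgReads, region, config$binWidth) * scale
        xMax[k] <- max(expBins)
        nBins[k] <- length(bgBins)
        pRaw[k] <- backgroundPvalue(xMax[k], bgBins, spec$model)
    }
    out <- candidates
    out$method <- method
    out$maxBinCount <- xMax
    out$nBins <- nBins
    out$pRaw <- pRaw
    out$pBonferroni <- pmin(1, pRaw * nBins)
    # BH runs over the full candidate set, on the per-peak Bonferroni-
    # corrected values (corrections applied sequentially)
    out$qBH <- bhAdjust(out$pBonferroni)
    out$significant <- out$qBH <= config$fdrQ
    out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over a p-value vector: the i-th smallest p becomes
#' `min_{j >= i} (n/j) p_(j)`, capped at 1. Rejecting all q-values at or
#' below a cutoff reproduces the BH step-up rule at that FDR.
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values in the input order.
#' @export
bhAdjust <- function(p) {
    n <- length(p)
    if (n == 0L) return(numeric())
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

#' Keep only significant peak calls
#'
#' @param calls output of [callPeaks()].
#' @param fdrQ FDR cutoff on the BH q-value (default 0.01).
#' @return the subset with `qBH <= fdrQ`.
#' @export
significantPeaks <- function(calls, fdrQ = 0.01) {
    calls[!is.na(calls$qBH) & calls$qBH <= fdrQ]
}
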