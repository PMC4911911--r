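# Motif scanning and enrichment: IUPAC scanning of the PUF binding element
# (FBE, UGUNNNAU) and alternate motifs, upstream-cytosine context flags,
# consensus mismatch scoring against -1/-2C + UGURCCAUR, FBE masking, and
# empirical enrichment against mononucleotide-shuffled peak sequences.

#' Define a motif
#'
#' @param name motif name.
#' @param pattern IUPAC RNA string (T is treated as U).
#' @param context optional required upstream context, e.g. `"C@-1"` or
#'   `"C@-2"` (base and offset upstream of the motif start).
#' @return a list of class `MotifDef`.
#' @export
motifDef <- function(name, pattern, context = NA_character_) {
    pat <- .toRnaChars(pattern)
    if (!length(pat)) stop("pattern must be nonempty")
    if (any(pat == "X")) stop("pattern may not contain the mask character")
    ctx <- NULL
    if (!is.na(context) && nzchar(context)) {
        m <- regmatches(context, regexec("^([ACGU])@(-[0-9]+)$", context))[[1]]
        if (length(m) != 3L) stop("context must look like 'C@-1'")
        ctx <- list(base = m[2], offset = as.integer(m[3]))
    }
    structure(list(name = name, pattern = toupper(pattern), chars = pat,
                   context = ctx), class = "MotifDef")
}

#' Bundled motif definitions
#'
#' Loads the packaged motif table (or a user-edited copy): the canonical FBE
#' (UGUNNNAU), the FBE-like 7-mer (UGURNAU) and its refined variant
#' (UGUGAAUR), UGU/CUGU half-mers, four U/G-rich in-vitro-style alternate
#' elements (placeholder strings, user-editable), and the neuronal
#' UGUGUAUAUA element.
#'
#' @param path a TSV with columns `name`, `pattern`, `context`; default the
#'   packaged table.
#' @return named list of [motifDef()] objects.
#' @export
loadMotifTable <- function(path = system.file("extdata", "motif_defs.tsv",
                                              package = "pufclip")) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    defs <- lapply(seq_len(nrow(tab)), function(i)
        motifDef(tab$name[i], tab$pattern[i],
                 if ("context" %in% names(tab)) tab$context[i] else NA))
    names(defs) <- tab$name
    defs
}

#' Scan a sequence for motif matches
#'
#' Reports every (possibly overlapping) offset whose bases satisfy the
#' motif's IUPAC pattern, with upstream-cytosine context flags at -1..-4
#' where those positions exist. Masked positions (`X`, from [maskFBE()])
#' match nothing; other non-IUPAC characters are an error.
#'
#' @param seq a nucleotide string (RNA or DNA alphabet).
#' @param motif a [motifDef()].
#' @return `data.frame` with `offset` (1-based), `motif`, `matched`,
#'   `c_m1`..`c_m4` (logical upstream-C flags).
#' @export
scanMotif <- function(seq, motif) {
    empty <- data.frame(offset = integer(), motif = character(),
                        matched = character(),
                        c_m1 = logical(), c_m2 = logical(),
                        c_m3 = logical(), c_m4 = logical())
    s <- .toRnaChars(seq)
    m <- length(motif$chars)
    n <- length(s)
    if (n < m) return(empty)
    ok <- rep(TRUE, n - m + 1L)
    for (k in seq_len(m)) {
        allowed <- IUPAC_RNA[[motif$chars[k]]]
        ok <- ok & (s[k:(n - m + k)] %in% allowed)
    }
    if (!is.null(motif$context)) {
        off <- motif$context$offset     # negative
        idx <- seq_len(n - m + 1L) + off
        ctxOk <- idx >= 1L & s[pmax(idx, 1L)] == motif$context$base
        ok <- ok & ctxOk
    }
    hits <- which(ok)
    if (!length(hits)) return(empty)
    upC <- function(d) {
        idx <- hits - d
        idx >= 1L & s[pmax(idx, 1L)] == "C"
    }
    data.frame(offset = hits, motif = motif$name,
               matched = vapply(hits, function(h)
                   paste0(s[h:(h + m - 1L)], collapse = ""), character(1)),
               c_m1 = upC(1L), c_m2 = upC(2L), c_m3 = upC(3L), c_m4 = upC(4L))
}

#' Mismatches against the in-vivo consensus
#'
#' Aligns the consensus core `UGURCCAUR` at the site's UGU anchor and counts
#' violated positions among core positions 4-9 plus the upstream context
#' requirement (a C at -1 or -2; absent at both costs one mismatch). When
#' several UGU anchors have sufficient flanks the one minimizing the
#' mismatch count is scored. A site without a usable UGU anchor is an error.
#'
#' @param site nucleotide string containing the site with at least 2 nt of
#'   upstream and 6 nt of downstream flank around the UGU.
#' @return list with `count` and `positions` (core positions 4-9 violated;
#'   0 denotes the upstream-context violation).
#' @export
consensusMismatches <- function(site) {
    s <- .toRnaChars(site)
    core <- .toRnaChars("UGURCCAUR")
    n <- length(s)
    anchors <- which(vapply(seq_len(max(0L, n - 2L)), function(i)
        all(s[i:(i + 2L)] == c("U", "G", "U")), logical(1)))
    anchors <- anchors[anchors >= 3L & anchors + 8L <= n]
    if (!length(anchors)) stop("no UGU anchor with sufficient flanks")
    best <- NULL
    for (a in anchors) {
        bad <- integer()
        for (k in 4:9) {
            if (!(s[a + k - 1L] %in% IUPAC_RNA[[core[k]]]))
                bad <- c(bad, k)
        }
        if (!(s[a - 1L] == "C" || s[a - 2L] == "C"))
            bad <- c(0L, bad)
        if (is.null(best) || length(bad) < length(best$positions))
            best <- list(count = length(bad), positions = bad, anchor = a)
    }
    best
}

#' Mask canonical FBE matches in a sequence
#'
#' Replaces every position covered by a canonical-FBE match (union of
#' overlapping match spans) with the placeholder `X`, which no subsequent
#' [scanMotif()] call can match; all other positions are unchanged.
#'
#' @param seq nucleotide string.
#' @param motif the motif to mask (default the canonical FBE).
#' @return the masked sequence string (RNA alphabet).
#' @export
maskFBE <- function(seq, motif = motifDef("fbe", "UGUNNNAU")) {
    s <- .toRnaChars(seq)
    hits <- scanMotif(seq, motif)
    if (nrow(hits)) {
        m <- length(motif$chars)
        for (h in hits$offset) s[h:(h + m - 1L)] <- "X"
    }
    paste0(s, collapse = "")
}

#' Motif enrichment against shuffled sequences
#'
#' The observed statistic is the fraction of sequences containing at least
#' one motif match. Each of `nShuffles` rounds permutes the letters of every
#' sequence independently (mononucleotide shuffle) and recomputes the
#' fraction; the empirical p-value is
#' `(1 + #(shuffled fraction >= observed)) / (nShuffles + 1)`.
#'
#' @param seqs character vector of peak sequences (non-empty).
#' @param motif a [motifDef()].
#' @param nShuffles number of shuffles (default 1000; must be >= 1).
#' @param seed RNG seed for the shuffles.
#' @return list with `observed` (fraction with a hit) and `p`.
#' @export
shuffleEnrichment <- function(seqs, motif, nShuffles = 1000L, seed = 1L) {
    if (length(seqs) == 0L) stop("need at least one sequence")
    if (nShuffles < 1L) stop("nShuffles must be >= 1")
    frac <- function(ss) mean(vapply(ss, function(x)
        nrow(scanMotif(x, motif)) > 0L, logical(1)))
    observed <- frac(seqs)
    chars <- lapply(seqs, .toRnaChars)
    set.seed(seed)
    hitsGE <- 0L
    for (b in seq_len(nShuffles)) {
        shuffled <- vapply(chars, function(cs)
            paste0(cs[sample.int(length(cs))], collapse = ""), character(1))
        if (frac(shuffled) >= observed) hitsGE <- hitsGE + 1L
    }
    list(observed = observed, p = (1 + hitsGE) / (nShuffles + 1))
}

# strand-aware window sequence around a genomic position (RNA sense)
.windowSequence <- function(genome, chrom, strand, center, flank) {
    len <- BiocGenerics::width(genome)[match(chrom, names(genome))]
    lo <- max(1L, center - flank)
    hi <- min(len, center + flank)
    s <- Biostrings::subseq(genome[[chrom]], lo, hi)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    list(seq = chartr("T", "U", as.character(s)),
         clipped = (lo != center - flank) || (hi != center + flank),
         lo = lo, hi = hi)
}

#' Per-peak motif summary
#'
#' Extracts the `window`-nt sequence centered on each peak maximum (reverse
#' complemented for minus-strand peaks), scans it with each motif
#' definition, and classifies the FBE upstream context (-1C / -2C / both /
#' none). Windows running off a chromosome end are clipped and flagged.
#'
#' @param peaks `GRanges` with `maxPos` and `height`.
#' @param genome a `DNAStringSet`.
#' @param motifs named list of [motifDef()]s (default the bundled table).
#' @param window window width in nt (default 71, i.e. maximum +/- 35).
#' @return `data.frame`, one row per peak: `has_<motif>` logicals,
#'   `fbe_context`, `clipped`, `height`, plus peak coordinates.
#' @export
peakMotifSummary <- function(peaks, genome, motifs = loadMotifTable(),
                             window = 71L) {
    flank <- (window - 1L) %/% 2L
    fbe <- motifs[[1]]
    if (!is.null(motifs$fbe)) fbe <- motifs$fbe
    rows <- vector("list", length(peaks))
    for (k in seq_along(peaks)) {
        chrom <- as.character(GenomeInfoDb::seqnames(peaks[k]))
        strand <- as.character(BiocGenerics::strand(peaks[k]))
        w <- .windowSequence(genome, chrom, strand, peaks$maxPos[k], flank)
        row <- list(chrom = chrom, strand = strand,
                    maxPos = peaks$maxPos[k],
                    height = peaks$height[k], clipped = w$clipped)
        fbeHits <- NULL
        for (nm in names(motifs)) {
            hits <- scanMotif(w$seq, motifs[[nm]])
            row[[paste0("has_", nm)]] <- nrow(hits) > 0L
            if (identical(motifs[[nm]]$pattern, fbe$pattern))
                fbeHits <- if (is.null(fbeHits)) hits else fbeHits
        }
        ctx <- "none"
        if (!is.null(fbeHits) && nrow(fbeHits)) {
            m1 <- any(fbeHits$c_m1); m2 <- any(fbeHits$c_m2)
            ctx <- if (m1 && m2) "both" else if (m1) "-1C"
                   else if (m2) "-2C" else "none"
        }
        row$fbe_context <- ctx
        rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(data.frame())
    do.call(rbind, rows)
}

#' FBE fraction by peak-height rank decile
#'
#' Curve data relating peak rank (by height, tallest first) to the fraction
#' of peaks whose window contains a canonical FBE.
#'
#' @param summary output of [peakMotifSummary()] (needs `has_fbe`,
#'   `height`).
#' @param nBins number of rank bins (default 10).
#' @return `data.frame` with `decile`, `n`, `fbe_fraction`.
#' @export
fbeRankCurve <- function(summary, nBins = 10L) {
    o <- order(-summary$height)
    dec <- ceiling(seq_along(o) / (length(o) / nBins))
    dec <- pmin(dec, nBins)
    data.frame(decile = seq_len(nBins),
               n = as.integer(table(factor(dec, levels = seq_len(nBins)))),
               fbe_fraction = vapply(seq_len(nBins), function(d)
                   mean(summary$has_fbe[o][dec == d]), numeric(1)))
}
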