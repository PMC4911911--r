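# Strand-aware per-base read coverage.

#' Strand-aware coverage track
#'
#' Per-base read-overlap counts for one strand of one chromosome: position i
#' counts the reads whose reference span contains i. The track length is
#' taken from the reads' seqlengths when set, otherwise from the rightmost
#' read end.
#'
#' @param reads a [ClipReads-class] object (or any stranded `GRanges`).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return an integer `Rle` of per-base counts.
#' @export
readCoverage <- function(reads, chrom, strand) {
    sel <- as.character(GenomeInfoDb::seqnames(reads)) == chrom &
        as.character(BiocGenerics::strand(reads)) == strand
    r <- reads[sel]
    sl <- GenomeInfoDb::seqlengths(reads)[chrom]
    len <- if (!is.na(sl)) as.integer(sl)
           else if (length(r)) max(BiocGenerics::end(r)) else 0L
    if (len == 0L) return(S4Vectors::Rle(integer()))
    IRanges::coverage(IRanges::ranges(r), width = len)
}

#' Write a coverage track as bedGraph
#'
#' @param cov an `Rle` from [readCoverage()].
#' @param chrom chromosome name used in the output.
#' @param path output file.
#' @export
writeCoverageBedGraph <- function(cov, chrom, path) {
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl)
    starts <- ends - rl + 1L
    keep <- rv != 0
    df <- data.frame(chrom = chrom, start = starts[keep] - 1L,
                     end = ends[keep], value = rv[keep])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
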