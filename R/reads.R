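# Read ingest: SAM loading with MAPQ filtering, barcode parsing, CIGAR
# deletion extraction, barcode-based duplicate collapse and replicate
# pooling.

#' Construct a ClipReads object
#'
#' Wraps a `GRanges` of read reference spans into a validated
#' [ClipReads-class], computing the strand-aware `fivePrime` coordinate.
#'
#' @param gr a `GRanges` (names are read names).
#' @param mapq integer mapping qualities.
#' @param barcode character random barcodes (may be empty strings).
#' @param deletions an `IntegerList` of genomic deletion coordinates, one
#'   element per read.
#' @return a [ClipReads-class] object.
#' @export
clipReads <- function(gr, mapq = rep(255L, length(gr)),
                      barcode = rep("", length(gr)),
                      deletions = IRanges::IntegerList(
                          rep(list(integer()), length(gr)))) {
    plus <- as.character(BiocGenerics::strand(gr)) != "-"
    S4Vectors::mcols(gr)$mapq <- as.integer(mapq)
    S4Vectors::mcols(gr)$barcode <- barcode
    S4Vectors::mcols(gr)$fivePrime <- ifelse(plus, BiocGenerics::start(gr),
                                             BiocGenerics::end(gr))
    S4Vectors::mcols(gr)$deletions <- deletions
    new("ClipReads", gr)
}

#' Load mapped reads from a SAM/BAM file
#'
#' Unmapped reads and reads with MAPQ below `minMapq` are removed (the
#' default keeps MAPQ 20 and drops 19). Deletions are extracted from CIGAR
#' `D` operations; the random barcode is parsed from the `_BC:<seq>` suffix
#' of the read name.
#'
#' @param path a SAM (text) or BAM file.
#' @param minMapq minimum MAPQ retained (default 20).
#' @param strict error (rather than empty barcode) when a read name carries
#'   no `_BC:` suffix.
#' @return a [ClipReads-class] object.
#' @export
loadReads <- function(path, minMapq = 20L, strict = FALSE) {
    isBam <- grepl("\\.bam$", path, ignore.case = TRUE)
    bam <- if (isBam) path
           else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                 indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
        bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq")))
    mq <- S4Vectors::mcols(ga)$mapq
    mq[is.na(mq)] <- -1L
    ga <- ga[mq >= minMapq]
    qname <- S4Vectors::mcols(ga)$qname
    hasBC <- grepl("_BC:", qname, fixed = TRUE)
    if (strict && any(!hasBC))
        stop("reads without _BC: barcode suffix in strict mode")
    barcode <- ifelse(hasBC, sub(".*_BC:", "", qname), "")
    irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        GenomicAlignments::cigar(ga), ops = "D",
        pos = BiocGenerics::start(ga))
    nr <- S4Vectors::elementNROWS(irl)
    if (sum(nr)) {
        flat <- unlist(irl)
        pos <- unlist(Map(seq.int, BiocGenerics::start(flat),
                          BiocGenerics::end(flat)))
        who <- rep(rep(seq_along(irl), nr), BiocGenerics::width(flat))
        dels <- S4Vectors::splitAsList(
            as.integer(pos), factor(who, levels = seq_along(irl)))
        names(dels) <- NULL
    } else {
        dels <- IRanges::IntegerList(rep(list(integer()), length(ga)))
    }
    gr <- GenomicRanges::granges(ga)
    names(gr) <- qname
    mq <- S4Vectors::mcols(ga)$mapq
    clipReads(gr, mapq = mq, barcode = barcode, deletions = dels)
}

#' Collapse PCR duplicates by position and random barcode
#'
#' Retains exactly one read per (chromosome, strand, 5'-end position,
#' barcode) group: the longest read, ties broken by the lexicographically
#' smallest read name. Idempotent and order-independent.
#'
#' @param reads a [ClipReads-class] object.
#' @return a [ClipReads-class] with one read per group, in genomic order.
#' @export
collapseDuplicates <- function(reads) {
    if (length(reads) == 0L) return(reads)
    key <- paste(as.character(GenomeInfoDb::seqnames(reads)),
                 as.character(BiocGenerics::strand(reads)),
                 S4Vectors::mcols(reads)$fivePrime,
                 S4Vectors::mcols(reads)$barcode, sep = "\r")
    nm <- names(reads)
    if (is.null(nm)) nm <- rep("", length(reads))
    o <- order(key, -BiocGenerics::width(reads), nm)
    reads <- reads[o]
    keep <- !duplicated(key[o])
    out <- reads[keep]
    out[order(as.character(GenomeInfoDb::seqnames(out)),
              BiocGenerics::start(out),
              as.character(BiocGenerics::strand(out)))]
}

#' Pool read sets and collapse duplicates
#'
#' Concatenates replicate read sets (e.g. negative-control replicates into a
#' single control data set) and collapses barcode duplicates across the pool.
#'
#' @param readsList list of [ClipReads-class] objects.
#' @return a pooled, collapsed [ClipReads-class].
#' @export
poolReads <- function(readsList) {
    gr <- do.call(c, lapply(readsList, function(x) as(x, "GRanges")))
    collapseDuplicates(new("ClipReads", gr))
}
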