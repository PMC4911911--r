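# Annotation ingest: GFF3 -> TranscriptModels, and transcript/genome
# coordinate mapping. Genomic coordinates are 1-based, closed (the GRanges
# convention); transcript (mature) coordinates are 1-based along the spliced
# transcript in 5'->3' orientation.

.newTranscriptModels <- function(info, exons, cds, utr5, utr3) {
    new("TranscriptModels",
        info = info,
        exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
}

# Order exon ranges 5'->3' in transcript orientation.
.orientExons <- function(gr, strand) {
    o <- order(BiocGenerics::start(gr),
               decreasing = identical(strand, "-"))
    gr[o]
}

#' Load transcript models from a GFF3 file
#'
#' Parses gene/mRNA (or ncRNA)/exon/CDS features into one model per
#' transcript. 5' and 3' UTR intervals are derived as the exonic sequence
#' outside the CDS span, split by transcript orientation; transcripts without
#' CDS records are flagged noncoding. Transcripts whose CDS falls outside
#' their exons are rejected with a warning; exon or CDS records lacking a
#' `Parent` link are an error.
#'
#' @param path path to a GFF3 file.
#' @return a [TranscriptModels-class] object.
#' @export
loadAnnotation <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gff$type)
    firstParent <- function(x) {
        vapply(x, function(p) if (length(p)) p[[1]] else NA_character_,
               character(1))
    }
    tx <- gff[type %in% c("mRNA", "ncRNA", "transcript")]
    if (length(tx) == 0L) stop("no mRNA/ncRNA/transcript features in ", path)
    txId <- tx$ID
    txGene <- firstParent(tx$Parent)
    txGene[is.na(txGene)] <- txId[is.na(txGene)]

    kids <- gff[type %in% c("exon", "CDS")]
    if (is.null(kids$Parent) && length(kids))
        stop("exon/CDS records without a Parent link")
    kidParent <- firstParent(kids$Parent)
    if (anyNA(kidParent))
        stop("exon/CDS records without a Parent link")

    exL <- cdsL <- u5L <- u3L <- vector("list", length(tx))
    keep <- rep(TRUE, length(tx))
    coding <- logical(length(tx))
    for (i in seq_along(tx)) {
        mine <- kids[kidParent == txId[i]]
        ex <- mine[as.character(mine$type) == "exon"]
        cds <- mine[as.character(mine$type) == "CDS"]
        if (length(ex) == 0L) ex <- tx[i]  # implicit single exon
        strand_i <- as.character(BiocGenerics::strand(tx[i]))
        exr <- IRanges::reduce(IRanges::ranges(ex))
        if (length(cds)) {
            cdsr <- IRanges::reduce(IRanges::ranges(cds))
            if (sum(IRanges::width(IRanges::intersect(cdsr, exr))) <
                sum(IRanges::width(cdsr))) {
                warning("CDS outside exons for transcript ", txId[i],
                        "; record rejected")
                keep[i] <- FALSE
                next
            }
            coding[i] <- TRUE
            span <- range(cdsr)
            out <- IRanges::setdiff(exr, span)
            left <- out[BiocGenerics::end(out) < BiocGenerics::start(span)]
            right <- out[BiocGenerics::start(out) > BiocGenerics::end(span)]
            if (strand_i == "-") { tmp <- left; left <- right; right <- tmp }
            u5 <- left; u3 <- right
        } else {
            cdsr <- IRanges::IRanges()
            u5 <- u3 <- IRanges::IRanges()
        }
        chr <- as.character(GenomeInfoDb::seqnames(tx[i]))
        mk <- function(r) {
            if (length(r) == 0L) return(GenomicRanges::GRanges())
            gr <- GenomicRanges::GRanges(chr, r, strand = strand_i)
            .orientExons(gr, strand_i)
        }
        exL[[i]] <- mk(exr); cdsL[[i]] <- mk(cdsr)
        u5L[[i]] <- mk(u5); u3L[[i]] <- mk(u3)
    }
    idx <- which(keep)
    info <- S4Vectors::DataFrame(
        gene_id = txGene[idx],
        transcript_id = txId[idx],
        chromosome = as.character(GenomeInfoDb::seqnames(tx))[idx],
        strand = as.character(BiocGenerics::strand(tx))[idx],
        coding = coding[idx],
        mature_length = vapply(exL[idx], function(g)
            sum(BiocGenerics::width(g)), integer(1))
    )
    grl <- function(l) {
        out <- GenomicRanges::GRangesList(l[idx])
        names(out) <- info$transcript_id
        out
    }
    .newTranscriptModels(info, grl(exL), grl(cdsL), grl(u5L), grl(u3L))
}

#' Map transcript coordinates to the genome
#'
#' Converts 1-based positions along the mature (spliced) transcript into
#' genomic coordinates, honouring strand and exon structure.
#'
#' @param tm a [TranscriptModels-class] object.
#' @param txId a transcript identifier present in `tm`.
#' @param pos integer vector of mature-transcript positions (1-based).
#' @return integer vector of genomic coordinates (NA outside the transcript).
#' @export
transcriptToGenomic <- function(tm, txId, pos) {
    ex <- tm@exons[[txId]]
    if (is.null(ex)) stop("unknown transcript: ", txId)
    w <- BiocGenerics::width(ex)
    ends <- cumsum(w)
    starts <- ends - w + 1L
    minus <- as.character(BiocGenerics::strand(ex)[1]) == "-"
    out <- rep(NA_integer_, length(pos))
    for (k in seq_along(ex)) {
        ink <- !is.na(pos) & pos >= starts[k] & pos <= ends[k]
        off <- pos[ink] - starts[k]
        out[ink] <- if (minus) BiocGenerics::end(ex)[k] - off
                    else BiocGenerics::start(ex)[k] + off
    }
    out
}

#' Map genomic coordinates into a transcript
#'
#' Inverse of [transcriptToGenomic()]; genomic positions not covered by the
#' transcript's exons map to NA.
#'
#' @inheritParams transcriptToGenomic
#' @param gpos integer vector of genomic coordinates.
#' @return integer vector of 1-based mature-transcript positions.
#' @export
genomicToTranscript <- function(tm, txId, gpos) {
    ex <- tm@exons[[txId]]
    if (is.null(ex)) stop("unknown transcript: ", txId)
    w <- BiocGenerics::width(ex)
    ends <- cumsum(w)
    starts <- ends - w + 1L
    minus <- as.character(BiocGenerics::strand(ex)[1]) == "-"
    out <- rep(NA_integer_, length(gpos))
    for (k in seq_along(ex)) {
        lo <- BiocGenerics::start(ex)[k]; hi <- BiocGenerics::end(ex)[k]
        ink <- !is.na(gpos) & gpos >= lo & gpos <= hi
        out[ink] <- if (minus) starts[k] + (hi - gpos[ink])
                    else starts[k] + (gpos[ink] - lo)
    }
    out
}

# Exonic span GRanges (reduced, genomic order) for one transcript.
.exonicSpan <- function(tm, txId) {
    GenomicRanges::reduce(BiocGenerics::sort(tm@exons[[txId]]))
}

# transcript_id of the transcript whose exons contain each genomic
# position (vectorized); ties broken by longest mature transcript, then
# lexicographic transcript id. NA outside all transcripts.
.containingTranscripts <- function(tm, chrom, strand, gpos) {
    out <- rep(NA_character_, length(gpos))
    if (!length(gpos) || !nrow(tm@info)) return(out)
    info <- tm@info
    exAll <- unlist(tm@exons)
    exTx <- rep(names(tm@exons), S4Vectors::elementNROWS(tm@exons))
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gpos, gpos),
                                strand = strand)
    hit <- GenomicRanges::findOverlaps(q, exAll)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    if (!length(qh)) return(out)
    ml <- info$mature_length[match(exTx[sh], info$transcript_id)]
    o <- order(qh, -ml, exTx[sh])
    first <- !duplicated(qh[o])
    out[qh[o][first]] <- exTx[sh][o][first]
    out
}

.containingTranscript <- function(tm, chrom, strand, gpos) {
    .containingTranscripts(tm, chrom, strand, gpos)[1]
}
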