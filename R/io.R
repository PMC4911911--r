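# File output: SAM for simulated reads, FASTA/GFF3/TSV for the simulated
# world, BED for peaks and sites, flat key=value configuration files.

# Build a CIGAR string for a read span with 1-nt (or longer) deletions.
.cigarFor <- function(s, e, dels) {
    if (length(dels) == 0L) return(paste0(e - s + 1L, "M"))
    dels <- sort(unique(dels))
    runs <- split(dels, cumsum(c(1L, diff(dels) != 1L)))
    out <- character()
    cur <- s
    for (r in runs) {
        m <- r[1] - cur
        out <- c(out, paste0(m, "M"), paste0(length(r), "D"))
        cur <- r[length(r)] + 1L
    }
    if (cur <= e) out <- c(out, paste0(e - cur + 1L, "M"))
    paste0(out, collapse = "")
}

#' Write reads as SAM
#'
#' Emits a text SAM file with `@SQ` headers taken from the reads'
#' seqlengths; deletions are encoded as CIGAR `D` operations and the random
#' barcode travels in the read name (`_BC:<seq>` suffix).
#'
#' @param reads a [ClipReads-class] object with seqlengths set.
#' @param path output file.
#' @export
writeSam <- function(reads, path) {
    sl <- GenomeInfoDb::seqlengths(reads)
    if (anyNA(sl)) stop("reads must carry seqlengths to write SAM")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    for (i in seq_along(sl))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl)[i], sl[i]), con)
    if (length(reads)) {
        qn <- names(reads)
        if (is.null(qn)) qn <- sprintf("read%06d_BC:%s", seq_along(reads),
                                       S4Vectors::mcols(reads)$barcode)
        flag <- ifelse(as.character(BiocGenerics::strand(reads)) == "-",
                       16L, 0L)
        dels <- S4Vectors::mcols(reads)$deletions
        cig <- vapply(seq_along(reads), function(i)
            .cigarFor(BiocGenerics::start(reads)[i],
                      BiocGenerics::end(reads)[i], dels[[i]]),
            character(1))
        lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                         qn, flag,
                         as.character(GenomeInfoDb::seqnames(reads)),
                         BiocGenerics::start(reads),
                         S4Vectors::mcols(reads)$mapq, cig)
        writeLines(lines, con)
    }
    invisible(path)
}

#' Write the synthetic world to disk
#'
#' Writes the genome as FASTA, the annotation as GFF3 (1-based, closed
#' intervals; gene/mRNA/exon/CDS records) and the ground-truth table as TSV
#' (`truth.tsv`; `site_position` and `genomic_u1` are 1-based).
#'
#' @param sim a [ClipSimulation-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(sim@genome, file.path(dir, "genome.fa"))
    rtracklayer::export(annotationAsGFF(sim@transcripts),
                        file.path(dir, "annotation.gff3"), format = "gff3")
    tr <- as.data.frame(sim@truth)
    if (nrow(tr))
        tr$crosslink_offsets <- vapply(sim@truth$crosslink_offsets,
                                       paste, character(1), collapse = ",")
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Render transcript models as GFF3-style GRanges
#'
#' @param tm a [TranscriptModels-class].
#' @return a `GRanges` with `type`, `ID` and `Parent` columns, suitable for
#'   `rtracklayer::export(..., format = "gff3")`.
#' @export
annotationAsGFF <- function(tm) {
    info <- tm@info
    recs <- list()
    for (i in seq_len(nrow(info))) {
        ex <- BiocGenerics::sort(tm@exons[[i]])
        cds <- tm@cds[[i]]
        span <- range(ex)
        gid <- info$gene_id[i]; tid <- info$transcript_id[i]
        g <- span; g$type <- "gene"; g$ID <- gid; g$Parent <- ""
        t <- span
        t$type <- if (info$coding[i]) "mRNA" else "ncRNA"
        t$ID <- tid; t$Parent <- gid
        ex$type <- "exon"
        ex$ID <- sprintf("%s.exon%d", tid, seq_along(ex))
        ex$Parent <- tid
        recs[[length(recs) + 1L]] <- c(g, t, ex)
        if (length(cds)) {
            cds <- BiocGenerics::sort(cds)
            cds$type <- "CDS"
            cds$phase <- 0L
            cds$ID <- sprintf("%s.cds%d", tid, seq_along(cds))
            cds$Parent <- tid
            recs[[length(recs)]] <- c(recs[[length(recs)]], cds)
        }
    }
    out <- if (length(recs)) do.call(c, recs) else GenomicRanges::GRanges()
    if (length(out)) {
        par <- out$Parent
        out$Parent <- IRanges::CharacterList(
            ifelse(par == "", list(character()), as.list(par)))
    }
    out
}

#' Write stranded intervals as BED6(+)
#'
#' @param gr a stranded `GRanges`; `name` and `score` columns are taken from
#'   `names(gr)` and `scoreCol` when present.
#' @param path output file.
#' @param scoreCol metadata column used for the BED score (default none).
#' @export
writeBed <- function(gr, path, scoreCol = NULL) {
    score <- if (!is.null(scoreCol) &&
                 scoreCol %in% colnames(S4Vectors::mcols(gr)))
        S4Vectors::mcols(gr)[[scoreCol]] else rep(0, length(gr))
    nm <- names(gr)
    if (is.null(nm)) nm <- sprintf("feature%d", seq_along(gr))
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = nm, score = score,
        strand = as.character(BiocGenerics::strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments ignored.
#' Values that parse as numbers become numeric; comma-separated values become
#' vectors. Keys mirror the [simConfig()] arguments.
#'
#' @param path configuration file.
#' @return named list of values.
#' @export
readKeyValueConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
        if (length(m) != 3L) stop("cannot parse config line: ", ln)
        key <- trimws(m[2]); val <- trimws(m[3])
        parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        num <- suppressWarnings(as.numeric(parts))
        out[[key]] <- if (!anyNA(num)) num else parts
    }
    out
}
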