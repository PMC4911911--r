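#' @import methods
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges IRanges CompressedIntegerList
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Simulation configuration for synthetic iCLIP experiments
#'
#' A validity-checked container for every parameter of the synthetic-data
#' generator: transcriptome layout, planted binding-site classes and their
#' mean crosslink rates, the abundance model, the background (nonspecific)
#' read process, iCLIP chemistry (truncation/deletion probabilities), PCR
#' amplification and random barcodes, and the master seed. Create instances
#' with [simConfig()].
#'
#' @slot nTranscripts number of transcripts laid out on the synthetic genome.
#' @slot transcriptLengthRange integer pair, min/max mature length (nt).
#' @slot targetFraction fraction of transcripts carrying one planted site.
#' @slot affinityLevels named numeric: mean specific crosslinked molecules per
#'   unit abundance for site classes `canonical_context`, `canonical`,
#'   `sevenmer`, `alternate`, `none`.
#' @slot classProbs named numeric, sampling probabilities of the four planted
#'   site classes among target transcripts.
#' @slot abundanceMeanlog,abundanceSdlog log-normal parameters of per-
#'   transcript expression.
#' @slot backgroundRate mean nonspecific iCLIP reads per transcript per unit
#'   abundance.
#' @slot truncationProb probability a cDNA truncates at the crosslink (CITS
#'   signal); the complement reads through.
#' @slot deletionProb probability of a crosslink-induced deletion given
#'   read-through (CIMS signal).
#' @slot bgDeletionProb per-read rate of spurious (non-crosslink) deletions.
#' @slot barcodeLength random-barcode length (nt).
#' @slot pcrDuplicateRate mean extra PCR copies per unique molecule.
#' @slot nReplicates number of iCLIP replicates.
#' @slot readLength fixed read length (nt).
#' @slot hotspotRate mean number of nonspecific crosslink hotspots per
#'   transcript (shared between experiment and negative control).
#' @slot hotspotFrac fraction of background reads that truncate at a hotspot
#'   rather than starting uniformly.
#' @slot controlRate mean negative-control iCLIP reads per transcript per unit
#'   abundance.
#' @slot rnaseqRate mean RNA-seq reads per transcript per unit abundance.
#' @slot crosslinkOffsets,crosslinkWeights support and weights of the
#'   discretized crosslink-offset distribution relative to motif start.
#' @slot spacer minimum gap between transcripts on the genome (nt).
#' @slot seed master seed; fully determines all generator output.
#' @export
setClass("SimConfig", representation(
    nTranscripts = "integer",
    transcriptLengthRange = "integer",
    targetFraction = "numeric",
    affinityLevels = "numeric",
    classProbs = "numeric",
    abundanceMeanlog = "numeric",
    abundanceSdlog = "numeric",
    backgroundRate = "numeric",
    truncationProb = "numeric",
    deletionProb = "numeric",
    bgDeletionProb = "numeric",
    barcodeLength = "integer",
    pcrDuplicateRate = "numeric",
    nReplicates = "integer",
    readLength = "integer",
    hotspotRate = "numeric",
    hotspotFrac = "numeric",
    controlRate = "numeric",
    rnaseqRate = "numeric",
    crosslinkOffsets = "integer",
    crosslinkWeights = "numeric",
    spacer = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    pr <- c(targetFraction = object@targetFraction,
            truncationProb = object@truncationProb,
            deletionProb = object@deletionProb,
            bgDeletionProb = object@bgDeletionProb,
            hotspotFrac = object@hotspotFrac)
    bad <- pr < 0 | pr > 1
    if (any(bad))
        msg <- c(msg, paste0("probabilities outside [0,1]: ",
                             paste(names(pr)[bad], collapse = ", ")))
    need <- c("canonical_context", "canonical", "sevenmer", "alternate", "none")
    if (!all(need %in% names(object@affinityLevels))) {
        msg <- c(msg, "affinityLevels must name all five site classes")
    } else {
        a <- object@affinityLevels[need]
        if (!(a[1] >= a[2] && a[2] >= a[3] && a[3] >= a[4] && a[4] > a[5]))
            msg <- c(msg, paste("affinity ordering violated:",
                "canonical_context >= canonical >= sevenmer >= alternate > none"))
    }
    if (length(object@transcriptLengthRange) != 2L ||
        object@transcriptLengthRange[1] > object@transcriptLengthRange[2])
        msg <- c(msg, "transcriptLengthRange must be an increasing pair")
    if (object@nTranscripts < 0L) msg <- c(msg, "nTranscripts must be >= 0")
    if (length(object@crosslinkOffsets) != length(object@crosslinkWeights))
        msg <- c(msg, "crosslinkOffsets and crosslinkWeights differ in length")
    if (any(object@crosslinkWeights < 0) || sum(object@crosslinkWeights) <= 0)
        msg <- c(msg, "crosslinkWeights must be nonnegative with positive sum")
    if (object@readLength < 18L) msg <- c(msg, "readLength must be >= 18")
    if (length(msg)) msg else TRUE
})

#' Transcript models derived from annotation
#'
#' Holds one model per transcript: exon structure, CDS span and derived
#' 5'/3'UTR intervals, mature length and coding status. Built by
#' [loadAnnotation()] or by the synthetic generator. Exon lists are ordered
#' 5' to 3' in transcript orientation; UTRs partition the mature transcript
#' together with the CDS for coding transcripts.
#'
#' @slot info `DataFrame` with columns `gene_id`, `transcript_id`,
#'   `chromosome`, `strand`, `coding`, `mature_length`.
#' @slot exons,cds,utr5,utr3 `GRangesList` objects named by transcript_id;
#'   `cds`, `utr5`, `utr3` may hold empty elements (noncoding, or UTR absent).
#' @export
setClass("TranscriptModels", representation(
    info = "DataFrame",
    exons = "CompressedGRangesList",
    cds = "CompressedGRangesList",
    utr5 = "CompressedGRangesList",
    utr3 = "CompressedGRangesList"
))

setValidity("TranscriptModels", function(object) {
    msg <- character()
    ids <- object@info$transcript_id
    if (is.null(ids)) return("info must have a transcript_id column")
    for (sl in c("exons", "cds", "utr5", "utr3")) {
        x <- slot(object, sl)
        if (length(ids) == 0L && length(x) == 0L) next
        if (!identical(names(x), ids))
            msg <- c(msg, paste0("names of @", sl, " must equal transcript_id"))
    }
    if (!length(msg) && length(ids)) {
        w <- sum(IRanges::width(object@exons))
        if (!all(w == object@info$mature_length))
            msg <- c(msg, "mature_length must equal the sum of exon widths")
        if (any(S4Vectors::elementNROWS(
                IRanges::reduce(IRanges::ranges(object@exons))) !=
                S4Vectors::elementNROWS(object@exons)))
            msg <- c(msg, "exons within a transcript must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' iCLIP read alignments
#'
#' A `GRanges` subclass for cleaned read alignments. Ranges are the
#' reference span of each read (1-based, closed); required metadata columns
#' are `mapq` (integer), `barcode` (random-barcode string, possibly empty),
#' `fivePrime` (strand-aware genomic coordinate of the read 5' end: `start`
#' on `+`, `end` on `-`) and `deletions` (an `IntegerList` of genomic
#' coordinates of crosslink-induced CIGAR deletions). Construct with
#' [clipReads()].
#'
#' @export
setClass("ClipReads", contains = "GRanges")

setValidity("ClipReads", function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    need <- c("mapq", "barcode", "fivePrime", "deletions")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste0("missing metadata columns: ", paste(miss, collapse = ", ")))
    if (length(object)) {
        plus <- as.character(BiocGenerics::strand(object)) != "-"
        fp <- ifelse(plus, BiocGenerics::start(object), BiocGenerics::end(object))
        if (!all(mc$fivePrime == fp))
            msg <- c(msg, "fivePrime must be start on + and end on - strand")
        del <- unlist(mc$deletions)
        if (length(del)) {
            lo <- rep(BiocGenerics::start(object),
                      S4Vectors::elementNROWS(mc$deletions))
            hi <- rep(BiocGenerics::end(object),
                      S4Vectors::elementNROWS(mc$deletions))
            if (any(del < lo | del > hi))
                msg <- c(msg, "deletion positions must lie within the read span")
        }
    }
    if (length(msg)) msg else TRUE
})

#' A complete synthetic iCLIP world
#'
#' Output of [makeTranscriptome()]: genome sequence, transcript models,
#' per-transcript abundance and background hotspots, the ground-truth table
#' of planted binding sites, and the generating configuration.
#'
#' @slot genome `DNAStringSet` of synthetic chromosome(s).
#' @slot transcripts [TranscriptModels-class] laid out on the genome.
#' @slot truth `DataFrame`, one row per planted site: `transcript_id`,
#'   `site_position` (1-based transcript coordinate of motif start),
#'   `site_class`, `crosslink_offsets` (`IntegerList`, offsets of planted
#'   crosslinks relative to motif start), `feature_region`, plus genomic
#'   coordinates of the motif start.
#' @slot abundance named numeric, relative expression per transcript.
#' @slot hotspots `IntegerList` named by transcript: transcript coordinates of
#'   nonspecific crosslink hotspots shared by experiment and control.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("ClipSimulation", representation(
    genome = "DNAStringSet",
    transcripts = "TranscriptModels",
    truth = "DataFrame",
    abundance = "numeric",
    hotspots = "CompressedIntegerList",
    config = "SimConfig"
))

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nTranscripts, "transcripts,",
        object@nReplicates, "replicates, seed", object@seed, "\n")
    cat("  target fraction", object@targetFraction,
        "| background rate", object@backgroundRate,
        "| truncation", object@truncationProb,
        "| deletion", object@deletionProb, "\n")
})

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels with", nrow(object@info), "transcripts (",
        sum(object@info$coding), "coding )\n")
})

setMethod("show", "ClipSimulation", function(object) {
    cat("ClipSimulation:", nrow(object@transcripts@info), "transcripts on",
        length(object@genome), "chromosome(s);",
        nrow(object@truth), "planted sites; seed",
        object@config@seed, "\n")
})

#' @describeIn TranscriptModels-class accessor for the per-transcript summary
#'   table.
#' @param x,object a `TranscriptModels` or `ClipSimulation` object.
#' @export
transcriptInfo <- function(x) {
    if (is(x, "ClipSimulation")) x <- x@transcripts
    x@info
}

#' @describeIn TranscriptModels-class accessor for exon structures
#'   (`GRangesList` named by transcript).
#' @export
transcriptExons <- function(x) {
    if (is(x, "ClipSimulation")) x <- x@transcripts
    x@exons
}

#' @describeIn ClipSimulation-class ground-truth table of planted sites.
#' @export
truthSites <- function(x) x@truth

#' @describeIn ClipSimulation-class genome sequence accessor.
#' @export
genomeSeq <- function(x) x@genome

#' @describeIn ClipSimulation-class per-transcript abundance accessor.
#' @export
transcriptAbundance <- function(x) x@abundance
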