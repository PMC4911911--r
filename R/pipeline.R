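# End-to-end driver: simulate -> ingest -> peak calling -> consensus ->
# motifs -> crosslink sites -> landscape, with TSV/BED outputs and a run
# manifest. Also the workhorse behind the command-line wrapper in
# inst/scripts/pufclip.R.

#' Run the full synthetic-data pipeline
#'
#' Generates a synthetic world, simulates iCLIP replicates plus negative
#' control and RNA-seq, collapses barcode duplicates, calls peaks per
#' replicate with the chosen background method, applies the fold-enrichment
#' secondary filter and the k-of-n replicate consensus, normalizes heights
#' to RNA abundance, builds the target list, summarizes motif content,
#' infers CIMS/CITS crosslink sites with reproducibility filtering and the
#' FBE-relative profile, and assigns peaks to transcript features. When
#' `outdir` is given, tables (TSV), peaks/sites (BED) and a JSON run
#' manifest are written.
#'
#' @param config a [simConfig()].
#' @param method peak-calling method 1..6 (default 4: negative-control
#'   background, local region).
#' @param peakConfig a [peakCallConfig()].
#' @param filtConfig a [filterConfig()].
#' @param outdir optional output directory.
#' @return list with the simulation, per-replicate reads and calls, the
#'   consensus peaks, target list, motif summary, crosslink sites and
#'   profile, and feature assignments.
#' @export
runPipeline <- function(config = simConfig(), method = 4L,
                        peakConfig = peakCallConfig(),
                        filtConfig = filterConfig(),
                        outdir = NULL) {
    sim <- makeTranscriptome(config)
    tm <- sim@transcripts
    ctrl <- simulateControls(sim)
    control <- collapseDuplicates(ctrl$control)
    rnaseq <- ctrl$rnaseq
    reps <- lapply(seq_len(config@nReplicates), function(r)
        collapseDuplicates(simulateIclip(sim, r)))

    chrom <- names(sim@genome)
    callsPerRep <- lapply(reps, function(rd) {
        cands <- do.call(c, lapply(c("+", "-"), function(s)
            findCandidatePeaks(readCoverage(rd, chrom, s), chrom, s,
                               peakConfig)))
        calls <- callPeaks(cands, rd, controlReads = control,
                           rnaseqReads = rnaseq, tm = tm, method = method,
                           config = peakConfig)
        sig <- significantPeaks(calls, peakConfig$fdrQ)
        enrichmentFilter(sig, rd, control, filtConfig)
    })
    consensus <- reproduciblePeaks(callsPerRep, filtConfig$kRequired)
    consensus <- normalizeHeight(consensus, rnaseq, tm)
    targetList <- buildTargetList(consensus, tm)
    motifSummary <- if (length(consensus))
        peakMotifSummary(consensus, sim@genome) else data.frame()

    # CIMS and CITS reproducibility are assessed per kind, then combined
    cims <- lapply(reps, findCIMS)
    cits <- lapply(reps, function(rd) findCITS(rd, tm))
    sitesCIMS <- reproducibleSites(cims, 2L)
    sitesCITS <- reproducibleSites(cits, 2L)
    sites <- suppressWarnings(c(sitesCIMS, sitesCITS))

    fbeHits <- truthFbeRanges(sim)
    profile <- crosslinkProfile(sites, fbeHits, genome = sim@genome)
    features <- if (length(consensus)) assignFeature(consensus, tm)
                else consensus

    res <- list(sim = sim, reads = reps, control = control, rnaseq = rnaseq,
                callsPerRep = callsPerRep, consensus = consensus,
                targets = targetList$targets,
                unassigned = targetList$unassigned,
                motifSummary = motifSummary,
                sites = sites, profile = profile$profile,
                features = features)
    if (!is.null(outdir)) .writePipelineOutputs(res, outdir, config, method)
    res
}

#' Genomic ranges of planted FBE-class sites
#'
#' Motif-start (U1-anchored) ranges of the planted canonical-FBE sites of a
#' simulation, usable as the `fbeHits` argument of [crosslinkProfile()].
#'
#' @param sim a [ClipSimulation-class].
#' @param classes site classes to include.
#' @return a stranded `GRanges` (U1 at `start` on `+`, at `end` on `-`).
#' @export
truthFbeRanges <- function(sim, classes = c("canonical_context",
                                            "canonical")) {
    tr <- sim@truth
    tr <- tr[tr$site_class %in% classes, , drop = FALSE]
    if (nrow(tr) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(tr$chromosome,
                           IRanges::IRanges(tr$genomic_u1, tr$genomic_u1),
                           strand = tr$strand)
}

.writePipelineOutputs <- function(res, outdir, config, method) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeSimulation(res$sim, file.path(outdir, "sim"))
    wtsv <- function(df, name) utils::write.table(
        df, file.path(outdir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    cons <- res$consensus
    if (length(cons)) {
        df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(cons)),
                         start = BiocGenerics::start(cons),
                         end = BiocGenerics::end(cons),
                         strand = as.character(BiocGenerics::strand(cons)),
                         as.data.frame(S4Vectors::mcols(cons)))
        wtsv(df, "consensus_peaks.tsv")
        writeBed(cons, file.path(outdir, "consensus_peaks.bed"),
                 scoreCol = "height")
    }
    wtsv(res$targets, "targets.tsv")
    if (nrow(res$motifSummary)) wtsv(res$motifSummary, "peak_motifs.tsv")
    if (length(res$sites)) {
        st <- res$sites
        st2 <- st
        st2$score <- -log10(pmax(st$pValue, 1e-300))
        writeBed(st2, file.path(outdir, "crosslink_sites.bed"),
                 scoreCol = "score")
    }
    wtsv(res$profile, "crosslink_profile.tsv")
    manifest <- list(
        package = "pufclip",
        version = as.character(utils::packageVersion("pufclip")),
        date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        seed = config@seed, method = method,
        n_transcripts = config@nTranscripts,
        n_replicates = config@nReplicates)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(outdir)
}
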