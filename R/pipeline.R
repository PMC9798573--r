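#' Run the full IR screening pipeline on alignment files
#'
#' Convenience end-to-end driver: quantifies every sample against the
#' intron reference, applies read-depth QC and the cohort filters,
#' counts per-sample IR events and calls differentially retained introns
#' by beta regression.  Deterministic given its inputs; optionally
#' writes the standard TSV outputs.
#'
#' @param samFiles named character vector of SAM/BAM paths (names become
#'   sample ids).
#' @param groups group label per sample.
#' @param introns intron reference \code{GRanges}.
#' @param exons exon \code{GRanges} (gene models); defaults to the
#'   reference's flanking exons.
#' @param minReads read-depth QC threshold (see \code{\link{sampleQC}});
#'   use 0 to disable.
#' @param params cohort filter parameters (\code{\link{filterParams}}).
#' @param irThreshold IR-event ratio threshold.
#' @param deltaThreshold,qThreshold differential-retention call
#'   thresholds.
#' @param outDir when non-NULL, writes \code{mask.tsv},
#'   \code{events.tsv} and \code{dir.tsv} there.
#' @return list with the \code{cohort} (\code{\linkS4class{IRCohort}}),
#'   \code{mask}, \code{events} and \code{dir} (differential-retention
#'   table).
#' @export
runIRPipeline <- function(samFiles, groups, introns,
                          exons = flankExons(introns), minReads = 0,
                          params = filterParams(), irThreshold = 0.1,
                          deltaThreshold = 0.1, qThreshold = 0.05,
                          outDir = NULL) {
    if (is.null(names(samFiles)))
        names(samFiles) <- sub("\\.(sam|bam)$", "", basename(samFiles))
    quants <- lapply(names(samFiles), function(id)
        collectAlignments(samFiles[[id]], introns, exons, sampleId = id))
    keep <- sampleQC(quants, minReads)
    sel <- vapply(quants, function(q) q@sampleId %in% keep, logical(1))
    cohort <- makeIRCohort(quants[sel], groups[sel], introns)
    mask <- applyCohortFilters(cohort, params)
    events <- countIREvents(cohort, mask, irThreshold)
    dir <- callDIR(cohort, mask, deltaThreshold = deltaThreshold,
                   qThreshold = qThreshold)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeTsv(as.data.frame(mask), file.path(outDir, "mask.tsv"))
        writeTsv(data.frame(sample_id = names(events),
                            n_ir_events = as.integer(events)),
                 file.path(outDir, "events.tsv"))
        writeTsv(as.data.frame(dir), file.path(outDir, "dir.tsv"))
    }
    list(cohort = cohort, mask = mask, events = events, dir = dir)
}
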