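#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
NULL

#' IRCohort: introns-by-samples container for intron retention metrics
#'
#' An \code{IRCohort} extends
#' \code{\link[SummarizedExperiment]{RangedSummarizedExperiment}} and stores
#' the six per-intron, per-sample IR metrics as assays: \code{ID} (median
#' per-base intronic read depth), \code{coverage} (fraction of intronic
#' nucleotides with at least one read), \code{SL} and \code{SR} (junction
#' reads anchoring the 5' and 3' flanking exon to another exon of the same
#' gene, in transcript orientation), \code{SE} (reads spanning exactly the
#' exon-exon junction formed by excising the intron) and \code{irRatio}
#' (\code{ID / (ID + max(SL, SR))}).  Rows are introns (a \code{GRanges}
#' with flanking-exon coordinates in its metadata columns), columns are
#' samples, and \code{colData} carries the \code{group} factor (e.g.
#' normal vs cancer) plus \code{totalReads} for read-depth QC.
#'
#' @aliases IRCohort
#' @exportClass IRCohort
setClass("IRCohort", contains = "RangedSummarizedExperiment")

.IRCOHORT_ASSAYS <- c("ID", "coverage", "SL", "SR", "SE", "irRatio")

setValidity("IRCohort", function(object) {
    msg <- NULL
    missing <- setdiff(.IRCOHORT_ASSAYS,
                       SummarizedExperiment::assayNames(object))
    if (length(missing))
        msg <- c(msg, paste("missing assays:", paste(missing, collapse = ", ")))
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (nlevels(factor(object$group)) < 1L)
        msg <- c(msg, "at least one sample group is required")
    if (is.null(msg)) TRUE else msg
})

#' RBPMotif: a position weight matrix with background model
#'
#' Per-position nucleotide probabilities (columns A, C, G, T; U is mapped
#' to T on input) describing an RNA-binding-protein binding motif, together
#' with the i.i.d. background distribution used for log-odds scoring and
#' the pseudocount that was folded into the matrix.  Rows sum to one after
#' pseudocount regularisation.
#'
#' @slot motifId single string identifying the motif.
#' @slot rbpName RNA-binding protein the motif belongs to (may be "").
#' @slot matrix numeric L x 4 probability matrix, columns A, C, G, T.
#' @slot background length-4 background probabilities (A, C, G, T).
#' @slot pseudocount the pseudocount applied during regularisation.
#' @exportClass RBPMotif
setClass("RBPMotif", representation(
    motifId = "character",
    rbpName = "character",
    matrix = "matrix",
    background = "numeric",
    pseudocount = "numeric"
))

setValidity("RBPMotif", function(object) {
    msg <- NULL
    m <- object@matrix
    if (ncol(m) != 4L || !identical(colnames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "matrix must have columns A, C, G, T")
    else {
        if (any(m < 0)) msg <- c(msg, "matrix entries must be non-negative")
        if (any(abs(rowSums(m) - 1) > 1e-9))
            msg <- c(msg, "matrix rows must each sum to 1 (tolerance 1e-9)")
    }
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "background must be 4 probabilities summing to 1")
    if (length(object@pseudocount) != 1L || object@pseudocount < 0)
        msg <- c(msg, "pseudocount must be a single non-negative number")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn RBPMotif motif length (number of positions).
#' @param x,object an \code{RBPMotif}.
#' @export
setMethod("length", "RBPMotif", function(x) nrow(x@matrix))

#' @describeIn RBPMotif display a short summary.
#' @export
setMethod("show", "RBPMotif", function(object) {
    cat("RBPMotif", object@motifId,
        if (nzchar(object@rbpName)) paste0("(", object@rbpName, ")") else "",
        "- length", nrow(object@matrix), "\n")
    cat("consensus:", motifConsensus(object), "\n")
})

#' Accessors for RBPMotif slots
#'
#' @param x an \code{RBPMotif}.
#' @return \code{motifId}: the motif identifier; \code{rbpName}: the RBP
#'   name; \code{motifMatrix}: the L x 4 probability matrix;
#'   \code{motifBackground}: the background probabilities;
#'   \code{motifConsensus}: the highest-probability base at each position,
#'   as a string.
#' @name RBPMotif-accessors
NULL

#' @rdname RBPMotif-accessors
#' @export
motifId <- function(x) x@motifId

#' @rdname RBPMotif-accessors
#' @export
rbpName <- function(x) x@rbpName

#' @rdname RBPMotif-accessors
#' @export
motifMatrix <- function(x) x@matrix

#' @rdname RBPMotif-accessors
#' @export
motifBackground <- function(x) x@background

#' @rdname RBPMotif-accessors
#' @export
motifConsensus <- function(x)
    paste(colnames(x@matrix)[max.col(x@matrix, ties.method = "first")],
          collapse = "")

#' SimDesign: parameters of a synthetic IR cohort
#'
#' Describes the genome geometry, cohort size and retention model used by
#' the simulators.  \code{thetaNormal} and \code{thetaCancer} give the true
#' per-intron retention fractions for the two groups (recycled across the
#' \code{nGenes * intronsPerGene} introns); \code{phiSim} is the beta
#' precision governing sample-to-sample variability of the realised
#' retention fraction around its group mean; \code{depth} is the expected
#' number of junction-region fragments per intron per sample.
#'
#' @slot nGenes,intronsPerGene genome geometry (genes, introns per gene).
#' @slot exonLen,intronLen,readLen lengths in base pairs.
#' @slot nNormal,nCancer samples per group.
#' @slot thetaNormal,thetaCancer per-intron true retention fractions in
#'   [0, 1], recycled to the number of introns.
#' @slot phiSim beta precision for across-sample IR variability.
#' @slot depth expected fragments per intron per sample (Poisson mean).
#' @slot seed integer master seed; all outputs are pure functions of the
#'   design and this seed.
#' @exportClass SimDesign
setClass("SimDesign", representation(
    nGenes = "integer", intronsPerGene = "integer",
    exonLen = "integer", intronLen = "integer", readLen = "integer",
    nNormal = "integer", nCancer = "integer",
    thetaNormal = "numeric", thetaCancer = "numeric",
    phiSim = "numeric", depth = "numeric", seed = "integer"
))

setValidity("SimDesign", function(object) {
    msg <- NULL
    counts <- c(nGenes = object@nGenes, intronsPerGene = object@intronsPerGene,
                exonLen = object@exonLen, intronLen = object@intronLen,
                readLen = object@readLen)
    if (any(counts <= 0L))
        msg <- c(msg, "genome geometry fields must be positive integers")
    if (object@nNormal < 0L || object@nCancer < 0L)
        msg <- c(msg, "sample counts must be non-negative")
    th <- c(object@thetaNormal, object@thetaCancer)
    if (any(th < 0 | th > 1))
        msg <- c(msg, "theta values must lie in [0, 1]")
    if (object@phiSim <= 0) msg <- c(msg, "phiSim must be positive")
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (object@readLen >= object@exonLen)
        msg <- c(msg, "readLen must be smaller than exonLen (junction anchors)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a simulation design
#'
#' @param nGenes number of simulated genes (one contig per gene).
#' @param intronsPerGene introns per gene; each gene has
#'   \code{intronsPerGene + 1} exons.
#' @param exonLen,intronLen exon and intron lengths in bp.
#' @param readLen read length for spliced (junction) reads.
#' @param nNormal,nCancer samples per group.
#' @param thetaNormal,thetaCancer true retention fractions, recycled
#'   per intron.
#' @param phiSim beta precision of across-sample retention variability.
#' @param depth expected junction-region fragments per intron per sample.
#' @param seed master RNG seed.
#' @return a validated \code{\linkS4class{SimDesign}}.
#' @examples
#' simDesign(nGenes = 5, thetaNormal = 0.2, thetaCancer = 0.4, seed = 1)
#' @export
simDesign <- function(nGenes = 10L, intronsPerGene = 2L, exonLen = 150L,
                      intronLen = 300L, readLen = 75L, nNormal = 20L,
                      nCancer = 20L, thetaNormal = 0.2, thetaCancer = 0.2,
                      phiSim = 20, depth = 100, seed = 1L) {
    new("SimDesign",
        nGenes = as.integer(nGenes), intronsPerGene = as.integer(intronsPerGene),
        exonLen = as.integer(exonLen), intronLen = as.integer(intronLen),
        readLen = as.integer(readLen), nNormal = as.integer(nNormal),
        nCancer = as.integer(nCancer),
        thetaNormal = as.numeric(thetaNormal),
        thetaCancer = as.numeric(thetaCancer),
        phiSim = as.numeric(phiSim), depth = as.numeric(depth),
        seed = as.integer(seed))
}

#' @describeIn SimDesign display a short summary.
#' @param object a \code{SimDesign}.
#' @export
setMethod("show", "SimDesign", function(object) {
    cat("SimDesign:", object@nGenes, "genes x", object@intronsPerGene,
        "introns;", object@nNormal, "normal +", object@nCancer,
        "cancer samples\n")
    cat("  exon", object@exonLen, "bp, intron", object@intronLen,
        "bp, reads", object@readLen, "bp, depth", object@depth,
        "fragments/intron, phi", object@phiSim, ", seed", object@seed, "\n")
})

#' @describeIn SimDesign total number of introns in the design.
#' @export
nIntrons <- function(object) object@nGenes * object@intronsPerGene
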