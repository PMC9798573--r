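#' SampleQuant: per-sample intron retention metrics
#'
#' One sample's IR quantification: the total number of aligned reads used
#' (supporting read-depth QC) and a \code{DataFrame} with one row per
#' reference intron and columns \code{intron_id}, \code{ID},
#' \code{coverage}, \code{SL}, \code{SR}, \code{SE}, \code{irRatio}.
#'
#' @slot sampleId sample identifier.
#' @slot totalReads number of primary aligned reads counted.
#' @slot metrics per-intron metric \code{DataFrame}.
#' @exportClass SampleQuant
setClass("SampleQuant", representation(
    sampleId = "character", totalReads = "numeric", metrics = "DataFrame"))

setValidity("SampleQuant", function(object) {
    need <- c("intron_id", "ID", "coverage", "SL", "SR", "SE", "irRatio")
    msg <- NULL
    if (!all(need %in% colnames(object@metrics)))
        msg <- c(msg, paste("metrics must have columns",
                            paste(need, collapse = ", ")))
    if (object@totalReads < 0) msg <- c(msg, "totalReads must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SampleQuant display a short summary.
#' @param object a \code{SampleQuant}.
#' @export
setMethod("show", "SampleQuant", function(object) {
    cat("SampleQuant", object@sampleId, "-", nrow(object@metrics),
        "introns,", object@totalReads, "aligned reads\n")
})

#' @describeIn SampleQuant total primary aligned reads in the sample.
#' @param x a \code{SampleQuant}.
#' @export
totalReads <- function(x) x@totalReads

#' @describeIn SampleQuant the per-intron metric \code{DataFrame}.
#' @export
quantMetrics <- function(x) x@metrics

#' IR ratio of an intron
#'
#' The fraction of a gene's transcripts estimated to retain the intron:
#' \code{ID / (ID + max(SL, SR))}, where \code{ID} is the median per-base
#' intronic read depth and \code{SL}, \code{SR} are the junction read
#' counts anchored in the 5' and 3' flanking exons.  Defined as 0 when
#' both \code{ID} and \code{max(SL, SR)} are 0.  All arguments are
#' vectorised.
#'
#' @param ID median per-base intron depth (non-negative).
#' @param SL,SR flanking-exon junction read counts (non-negative).
#' @return IR ratio in [0, 1].
#' @examples
#' irRatio(2, 8, 6)   # 0.2
#' irRatio(5, 0, 0)   # 1
#' irRatio(0, 0, 0)   # 0
#' @export
irRatio <- function(ID, SL, SR) {
    if (any(ID < 0) || any(SL < 0) || any(SR < 0))
        stop("ID, SL and SR must be non-negative")
    denom <- ID + pmax(SL, SR)
    ifelse(denom > 0, ID / denom, 0)
}

#' Intron depth and coverage from a per-base depth vector
#'
#' \code{intronDepth} is the median read depth across the intron's
#' nucleotides (the average of the two central values for even lengths);
#' \code{intronCoverage} is the fraction of intronic nucleotides covered
#' by at least one read.
#'
#' @param depth integer vector of per-base read depths over the intron,
#'   one element per nucleotide.
#' @return \code{intronDepth}: a non-negative real;
#'   \code{intronCoverage}: a real in [0, 1].
#' @examples
#' intronDepth(c(0, 0, 3, 5, 2))     # 2
#' intronCoverage(c(0, 0, 3, 5, 2))  # 0.6
#' @export
intronDepth <- function(depth) {
    if (!length(depth)) stop("depth vector must be non-empty")
    stats::median(depth)
}

#' @rdname intronDepth
#' @export
intronCoverage <- function(depth) {
    if (!length(depth)) stop("depth vector must be non-empty")
    mean(depth >= 1)
}

#' Quantify intron retention metrics for one sample
#'
#' Computes the per-intron metrics ID, coverage, SL, SR, SE and the IR
#' ratio from a spliced alignment file.  Per-base intronic depth is
#' accumulated from aligned (M/=/X) CIGAR segments; deletions (D) do not
#' contribute depth.  Junction counting uses N-gap CIGAR operations: a gap
#' exactly matching the intron increments SE; any gap whose donor equals
#' the intron start and whose acceptor lands in an exon of the same gene
#' increments the genomic-left junction counter, and symmetrically for a
#' gap whose acceptor equals the intron end.  SL and SR are reported in
#' transcript orientation, so on the minus strand the genomic-right
#' counter becomes SL.  An exact junction read therefore contributes to
#' SE, SL and SR (its far ends lie in the flanking exons).  Duplicate,
#' secondary, supplementary and unmapped records are skipped by flag;
#' reads on reference sequences absent from the intron reference are
#' skipped with a warning.
#'
#' @param file path to a SAM or BAM file (SAM is converted on the fly).
#' @param introns intron reference \code{GRanges} from
#'   \code{\link{buildIntronReference}}.
#' @param exons exon \code{GRanges} with a \code{gene_id} column used to
#'   validate junction far ends; defaults to the flanking exons recorded
#'   in the reference.  Pass \code{parseGTF} output for the complete gene
#'   models.
#' @param sampleId sample identifier stored in the result.
#' @param keepDepth when TRUE, the per-intron per-base depth vectors are
#'   retained in \code{S4Vectors::metadata(quantMetrics(x))$depth} (a
#'   list named by intron id), for depth-level diagnostics.
#' @return a \code{\linkS4class{SampleQuant}}.
#' @export
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments junctions grglist coverage
#' @importFrom GenomicRanges granges
collectAlignments <- function(file, introns, exons = flankExons(introns),
                              sampleId = sub("\\.(sam|bam)$", "",
                                             basename(file)),
                              keepDepth = FALSE) {
    if (!file.exists(file)) stop("alignment file not found: ", file)
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- suppressMessages(
            asBam(file, destination = dest, overwrite = TRUE,
                  indexDestination = FALSE))
    }
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isDuplicate = FALSE, isSupplementaryAlignment = FALSE)
    gal <- readGAlignments(file, param = ScanBamParam(flag = flag))
    known <- unique(as.character(seqnames(introns)))
    onKnown <- as.character(GenomicAlignments::seqnames(gal)) %in% known
    if (length(gal) && !all(onKnown)) {
        warning(sum(!onKnown),
                " read(s) on reference sequences absent from the intron ",
                "reference were skipped")
    }
    total <- length(gal)
    gal <- gal[onKnown]
    n <- length(introns)
    ID <- numeric(n); cov <- numeric(n)
    glLeft <- integer(n); glRight <- integer(n); SE <- integer(n)
    depthList <- if (keepDepth) vector("list", n) else NULL
    if (length(gal)) {
        # per-base depth from M/=/X segments (N gaps and deletions excluded)
        depthRle <- coverage(grglist(gal, drop.D.ranges = TRUE))
        ichr <- as.character(seqnames(introns))
        for (i in seq_len(n)) {
            cv <- depthRle[[ichr[i]]]
            s <- start(introns)[i]; e <- end(introns)[i]
            v <- if (is.null(cv) || length(cv) < s) integer(e - s + 1L)
                 else as.integer(S4Vectors::window(
                     c(cv, S4Vectors::Rle(0L, max(0L, e - length(cv)))), s, e))
            ID[i] <- intronDepth(v)
            cov[i] <- intronCoverage(v)
            if (keepDepth) depthList[[i]] <- v
        }
        jx <- unlist(junctions(gal), use.names = FALSE)
        if (length(jx)) {
            SE <- GenomicRanges::countOverlaps(introns, jx, type = "equal",
                                               ignore.strand = TRUE)
            glLeft <- .countFlankJunctions(jx, introns, exons, side = "left")
            glRight <- .countFlankJunctions(jx, introns, exons, side = "right")
        }
    }
    minus <- as.character(strand(introns)) == "-"
    SL <- ifelse(minus, glRight, glLeft)
    SR <- ifelse(minus, glLeft, glRight)
    metrics <- DataFrame(intron_id = introns$intron_id, ID = ID,
                         coverage = cov, SL = as.integer(SL),
                         SR = as.integer(SR), SE = as.integer(SE),
                         irRatio = irRatio(ID, SL, SR))
    if (keepDepth) {
        if (!length(gal))
            depthList <- lapply(width(introns), integer)
        names(depthList) <- introns$intron_id
        metadata(metrics)$depth <- depthList
    }
    new("SampleQuant", sampleId = sampleId, totalReads = as.numeric(total),
        metrics = metrics)
}

# Count junction gaps anchored on one side of each intron whose far end
# lands in an exon of the intron's gene. side = "left": gap start equals
# intron start, acceptor base (gap end + 1) must lie in a gene exon;
# side = "right": gap end equals intron end, donor base (gap start - 1)
# must lie in a gene exon.
#' @importFrom S4Vectors queryHits subjectHits
.countFlankJunctions <- function(jx, introns, exons, side = c("left", "right")) {
    side <- match.arg(side)
    type <- if (side == "left") "start" else "end"
    hits <- GenomicRanges::findOverlaps(jx, introns, type = type,
                                        ignore.strand = TRUE)
    counts <- integer(length(introns))
    if (!length(hits)) return(counts)
    q <- queryHits(hits); s <- subjectHits(hits)
    # anchored overlap can still differ on the anchored end for zero-width
    # corner cases; enforce exact boundary match
    ok <- if (side == "left") start(jx)[q] == start(introns)[s]
          else end(jx)[q] == end(introns)[s]
    q <- q[ok]; s <- s[ok]
    if (!length(q)) return(counts)
    farPos <- if (side == "left") end(jx)[q] + 1L else start(jx)[q] - 1L
    far <- GRanges(seqnames(jx)[q], IRanges(farPos, farPos))
    eh <- GenomicRanges::findOverlaps(far, exons, ignore.strand = TRUE)
    geneOK <- logical(length(q))
    if (length(eh)) {
        match <- introns$gene_id[s[queryHits(eh)]] ==
            exons$gene_id[subjectHits(eh)]
        geneOK[unique(queryHits(eh)[match])] <- TRUE
    }
    tab <- tabulate(s[geneOK], nbins = length(introns))
    as.integer(tab)
}

#' Assemble per-sample quantifications into an IRCohort
#'
#' Combines \code{\linkS4class{SampleQuant}} objects that share an intron
#' reference into an \code{\linkS4class{IRCohort}}
#' (a \code{RangedSummarizedExperiment} with assays ID, coverage, SL, SR,
#' SE and irRatio), attaching the group label of each sample.
#'
#' @param quants list of \code{SampleQuant}, one per sample.
#' @param groups factor or character vector of group labels, one per
#'   sample (e.g. \code{"normal"} / \code{"cancer"}).
#' @param introns the shared intron reference \code{GRanges}.
#' @return an \code{\linkS4class{IRCohort}}.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
makeIRCohort <- function(quants, groups, introns) {
    stopifnot(length(quants) > 0L, length(groups) == length(quants))
    ids <- introns$intron_id
    pull <- function(col) {
        m <- vapply(quants, function(q) {
            mm <- q@metrics
            if (!identical(as.character(mm$intron_id), as.character(ids)))
                stop("sample ", q@sampleId,
                     " was quantified on a different intron reference")
            as.numeric(mm[[col]])
        }, numeric(length(ids)))
        m <- matrix(m, nrow = length(ids))
        rownames(m) <- ids
        colnames(m) <- vapply(quants, function(q) q@sampleId, character(1))
        m
    }
    assays <- lapply(stats::setNames(.IRCOHORT_ASSAYS, .IRCOHORT_ASSAYS), pull)
    cd <- DataFrame(group = factor(groups),
                    totalReads = vapply(quants, totalReads, numeric(1)),
                    row.names = colnames(assays[[1L]]))
    se <- SummarizedExperiment(assays = assays, rowRanges = introns,
                               colData = cd)
    new("IRCohort", se)
}

#' Write / read one sample's quantification as TSV
#'
#' Plain TSV with columns intron_id, sample_id, ID, coverage, SL, SR, SE,
#' ir_ratio; the total aligned read count is stored in a
#' \code{#total_reads=} header comment so read-depth QC survives the round
#' trip.
#'
#' @param quant a \code{SampleQuant}.
#' @param path file path.
#' @return \code{writeQuantTsv}: the path, invisibly;
#'   \code{readQuantTsv}: a \code{SampleQuant}.
#' @export
writeQuantTsv <- function(quant, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#total_reads=", fmtNum(quant@totalReads)), con)
    m <- quant@metrics
    df <- data.frame(intron_id = m$intron_id, sample_id = quant@sampleId,
                     ID = fmtNum(m$ID), coverage = fmtNum(m$coverage),
                     SL = m$SL, SR = m$SR, SE = m$SE,
                     ir_ratio = fmtNum(m$irRatio))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeQuantTsv
#' @export
readQuantTsv <- function(path) {
    first <- readLines(path, n = 1L)
    total <- if (grepl("^#total_reads=", first))
        as.numeric(sub("^#total_reads=", "", first)) else NA_real_
    df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    new("SampleQuant", sampleId = as.character(df$sample_id[1L]),
        totalReads = total,
        metrics = DataFrame(intron_id = df$intron_id, ID = df$ID,
                            coverage = df$coverage, SL = as.integer(df$SL),
                            SR = as.integer(df$SR), SE = as.integer(df$SE),
                            irRatio = df$ir_ratio))
}
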