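#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for count normalisation: each sample's
#' factor is the median, over genes positive in every sample, of the
#' ratio of its count to the gene's geometric mean, rescaled so the
#' factors have unit geometric mean.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param pseudocount optional pseudocount added to all counts before
#'   estimation, for matrices with no gene positive in every sample.
#' @return named positive numeric vector, one factor per sample, with
#'   geometric mean 1.
#' @examples
#' computeSizeFactors(cbind(s1 = c(10, 20), s2 = c(20, 40)))
#' @export
computeSizeFactors <- function(counts, pseudocount = 0) {
    counts <- as.matrix(counts) + pseudocount
    allPos <- rowSums(counts <= 0) == 0L
    if (!any(allPos))
        stop("no gene has positive counts in every sample; ",
             "consider pseudocount > 0")
    lc <- log(counts[allPos, , drop = FALSE])
    geo <- rowMeans(lc)
    sf <- exp(apply(lc - geo, 2L, stats::median))
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(counts))
}

#' Log2 fold change of normalised group means
#'
#' \code{log2((mean normalised case + pseudocount) /
#' (mean normalised reference + pseudocount))} per gene.
#'
#' @param counts genes x samples count matrix.
#' @param groups group label per sample.
#' @param sizeFactors per-sample size factors
#'   (\code{\link{computeSizeFactors}} by default).
#' @param contrast length-2 character (case, reference); defaults to
#'   \code{c("cancer", "normal")} when present, otherwise the last and
#'   first group levels.
#' @param pseudocount added to both group means before the ratio.
#' @return named per-gene log2 fold changes.
#' @export
log2FoldChange <- function(counts, groups,
                           sizeFactors = computeSizeFactors(counts),
                           contrast = NULL, pseudocount = 1) {
    counts <- as.matrix(counts)
    grp <- factor(groups)
    if (is.null(contrast)) {
        lv <- levels(grp)
        contrast <- if (all(c("cancer", "normal") %in% lv))
            c("cancer", "normal") else c(lv[length(lv)], lv[1L])
    }
    if (!all(contrast %in% levels(grp)))
        stop("contrast groups not present")
    norm <- sweep(counts, 2L, sizeFactors, "/")
    mCase <- rowMeans(norm[, grp == contrast[1L], drop = FALSE])
    mRef <- rowMeans(norm[, grp == contrast[2L], drop = FALSE])
    log2((mCase + pseudocount) / (mRef + pseudocount))
}

#' Mean-count gene filter
#'
#' Keeps genes whose mean raw count across all samples is strictly
#' greater than \code{minMean} (default 10).
#'
#' @param counts genes x samples count matrix with gene rownames.
#' @param minMean strict lower bound on the per-gene mean count.
#' @return character vector of retained gene ids.
#' @export
meanCountFilter <- function(counts, minMean = 10) {
    counts <- as.matrix(counts)
    rownames(counts)[rowMeans(counts) > minMean]
}

#' Genes differentially expressed only in the reference condition
#'
#' Set difference: the reference condition's DE gene set minus the union
#' of the DE sets of every other condition.
#'
#' @param deSets named list of character vectors (one DE gene set per
#'   condition).
#' @param reference name of the reference condition in \code{deSets}.
#' @return character vector of reference-exclusive genes.
#' @examples
#' exclusiveDEGenes(list(brca = c("a", "b", "c"), x = "b", y = c("c", "d")),
#'                  "brca")  # "a"
#' @export
exclusiveDEGenes <- function(deSets, reference) {
    if (!reference %in% names(deSets))
        stop("reference condition '", reference, "' missing from deSets")
    others <- unlist(deSets[setdiff(names(deSets), reference)],
                     use.names = FALSE)
    setdiff(deSets[[reference]], others)
}

#' Cross-condition specificity z-score of a log fold change
#'
#' Measures how extreme the reference condition's log fold change is
#' relative to the same gene's fold changes across all conditions:
#' \code{(lfc[reference] - mean(lfc)) / sd(lfc)} with the sample (n - 1)
#' standard deviation.  Zero standard deviation yields z = 0 with a
#' warning.
#'
#' @param lfc numeric vector of per-condition log fold changes (>= 3
#'   conditions).
#' @param referenceIndex position of the reference condition in
#'   \code{lfc}.
#' @param excludeReference if TRUE the mean and sd are computed over the
#'   non-reference conditions only.
#' @return the z-score.
#' @examples
#' specificityZScore(c(3, rep(1, 8)), 1)  # about 2.667
#' @export
specificityZScore <- function(lfc, referenceIndex = 1L,
                              excludeReference = FALSE) {
    if (length(lfc) < 3L) stop("at least 3 conditions are required")
    if (referenceIndex < 1L || referenceIndex > length(lfc))
        stop("referenceIndex out of range")
    pool <- if (excludeReference) lfc[-referenceIndex] else lfc
    s <- stats::sd(pool)
    if (!is.finite(s) || s == 0) {
        warning("zero cross-condition standard deviation; z set to 0")
        return(0)
    }
    (lfc[referenceIndex] - mean(pool)) / s
}

#' Specificity screen over a per-condition fold-change table
#'
#' Applies \code{\link{specificityZScore}} to each gene of a genes x
#' conditions log fold change matrix.
#'
#' @param lfcTable genes x conditions numeric matrix with dimnames.
#' @param reference reference condition (column name or index).
#' @param exclusiveGenes optional character vector marking genes that are
#'   DE only in the reference condition (fills the \code{exclusive}
#'   column).
#' @param excludeReference see \code{\link{specificityZScore}}.
#' @return a \code{DataFrame} with columns \code{gene_id}, one column per
#'   condition, \code{z} and \code{exclusive}.
#' @export
specificityScreen <- function(lfcTable, reference,
                              exclusiveGenes = character(0),
                              excludeReference = FALSE) {
    lfcTable <- as.matrix(lfcTable)
    refIdx <- if (is.character(reference))
        match(reference, colnames(lfcTable)) else as.integer(reference)
    if (is.na(refIdx)) stop("reference condition not found")
    z <- apply(lfcTable, 1L, function(v)
        suppressWarnings(specificityZScore(v, refIdx, excludeReference)))
    out <- DataFrame(gene_id = rownames(lfcTable))
    for (j in colnames(lfcTable)) out[[paste0("lfc_", j)]] <- lfcTable[, j]
    out$z <- unname(z)
    out$exclusive <- out$gene_id %in% exclusiveGenes
    out
}

#' Correlate per-sample IR event counts with gene expression
#'
#' Pearson correlation, per gene, between \code{log10(events + 1)} and
#' \code{log10(normalised count + 1)} across samples.  Genes (or an
#' event vector) with zero variance on the transformed scale get r = 0
#' and are flagged.
#'
#' @param eventCounts named per-sample IR event counts
#'   (\code{\link{countIREvents}}).
#' @param counts genes x samples count matrix over the same samples (same
#'   order).
#' @param sizeFactors per-sample size factors; computed from
#'   \code{counts} when omitted.
#' @return a \code{DataFrame} with columns \code{gene_id}, \code{r},
#'   \code{degenerate}.
#' @export
correlateIRExpression <- function(eventCounts, counts,
                                  sizeFactors = computeSizeFactors(counts)) {
    counts <- as.matrix(counts)
    if (length(eventCounts) != ncol(counts))
        stop("eventCounts and counts have different sample counts")
    if (length(eventCounts) < 3L) stop("at least 3 samples are required")
    x <- log10(as.numeric(eventCounts) + 1)
    norm <- sweep(counts, 2L, sizeFactors, "/")
    ly <- log10(norm + 1)
    xs <- stats::sd(x)
    ys <- apply(ly, 1L, stats::sd)
    degen <- !is.finite(ys) | ys == 0 | !is.finite(xs) | xs == 0
    r <- numeric(nrow(ly))
    if (xs > 0 && any(!degen))
        r[!degen] <- as.numeric(stats::cor(x, t(ly[!degen, , drop = FALSE])))
    DataFrame(gene_id = rownames(counts), r = r, degenerate = degen)
}

#' Extreme-correlation gene sets
#'
#' The \code{ceiling(fraction * n)} genes with the largest and smallest
#' correlation coefficients; ties broken by gene id for determinism.
#'
#' @param r named numeric vector of per-gene correlations, or the
#'   \code{DataFrame} from \code{\link{correlateIRExpression}}.
#' @param fraction tail fraction in (0, 0.5); default 0.05 (top/bottom
#'   5 percent).
#' @return list with character vectors \code{top} and \code{bottom}.
#' @export
topPercentileGenes <- function(r, fraction = 0.05) {
    if (fraction <= 0 || fraction >= 0.5)
        stop("fraction must lie in (0, 0.5)")
    if (is(r, "DataFrame") || is.data.frame(r))
        r <- stats::setNames(r$r, r$gene_id)
    n <- length(r)
    k <- ceiling(fraction * n)
    ids <- names(r)
    topOrd <- order(-r, ids)
    botOrd <- order(r, ids)
    list(top = ids[topOrd[seq_len(k)]], bottom = ids[botOrd[seq_len(k)]])
}
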