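#' Splice-junction balance predicate
#'
#' True when the 5'/3' junction counts are balanced:
#' \code{0.7 <= SL/SR <= 1.3} with inclusive bounds.  A balanced ratio is
#' evidence that the flanking exons are constitutive; strong imbalance
#' indicates alternative 5' or 3' splice-site usage.  False when
#' \code{SR == 0} (no evidence).  Vectorised.
#'
#' @param SL,SR junction read counts (non-negative integers).
#' @param low,high inclusive window bounds on \code{SL/SR}.
#' @return logical vector.
#' @examples
#' spliceBalance(7, 10)   # TRUE, ratio exactly 0.7
#' spliceBalance(10, 7)   # FALSE, ratio about 1.43
#' spliceBalance(0, 0)    # FALSE
#' @export
spliceBalance <- function(SL, SR, low = 0.7, high = 1.3) {
    stopifnot(all(SL >= 0), all(SR >= 0))
    SR > 0 & SL / SR >= low & SL / SR <= high
}

#' Filter parameters for cohort-level intron selection
#'
#' Defaults follow the selection rules used for IR-event counting:
#' junction balance window [0.7, 1.3]; junction support
#' \code{(SL + SR) > 10} in at least 50\% of samples; intronic
#' \code{coverage > 0.5} in at least 50\% of samples; IR ratio
#' \code{> 0.05} in at least 50\% of the samples of at least one
#' designated group (normal or cancer).  Comparison operators are strict
#' and the 50\% occupancy bound is inclusive.
#'
#' @param balanceLow,balanceHigh inclusive bounds of the SL/SR window.
#' @param minJunction strict lower bound on \code{SL + SR}.
#' @param minCoverage strict lower bound on intron coverage.
#' @param irFloor strict lower bound on the IR ratio for the group rule.
#' @param sampleFrac inclusive occupancy fraction for all rules.
#' @return a named list of parameters.
#' @export
filterParams <- function(balanceLow = 0.7, balanceHigh = 1.3,
                         minJunction = 10, minCoverage = 0.5,
                         irFloor = 0.05, sampleFrac = 0.5) {
    list(balanceLow = balanceLow, balanceHigh = balanceHigh,
         minJunction = minJunction, minCoverage = minCoverage,
         irFloor = irFloor, sampleFrac = sampleFrac)
}

#' Apply cohort-level intron filters
#'
#' Evaluates the four intron selection rules across the cohort and
#' returns a per-intron mask.  Each rule is evaluated per sample, then
#' aggregated: \code{pass_balance}, \code{pass_junction_support} and
#' \code{pass_coverage} require their per-sample predicate to hold in at
#' least \code{sampleFrac} of all samples; \code{pass_ir_floor} requires
#' the IR ratio to exceed \code{irFloor} in at least \code{sampleFrac} of
#' the samples of at least one group in \code{irFloorGroups}.
#' Samples with zero junction support contribute a failing vote to the
#' balance rule (missing evidence is not passing evidence).
#'
#' @param cohort an \code{\linkS4class{IRCohort}}.
#' @param params parameter list from \code{\link{filterParams}}.
#' @param irFloorGroups group labels eligible for the IR-floor rule;
#'   defaults to all groups present.
#' @return a \code{DataFrame} with one row per intron and logical columns
#'   \code{pass_balance}, \code{pass_junction_support},
#'   \code{pass_coverage}, \code{pass_ir_floor} and their conjunction
#'   \code{pass_all}.
#' @export
#' @importFrom SummarizedExperiment assay
applyCohortFilters <- function(cohort, params = filterParams(),
                               irFloorGroups = levels(factor(cohort$group))) {
    stopifnot(is(cohort, "IRCohort"))
    grp <- factor(cohort$group)
    missing <- setdiff(irFloorGroups, levels(grp))
    if (length(missing))
        stop("irFloorGroups not present in the cohort: ",
             paste(missing, collapse = ", "))
    SL <- assay(cohort, "SL"); SR <- assay(cohort, "SR")
    cov <- assay(cohort, "coverage"); ir <- assay(cohort, "irRatio")
    nS <- ncol(cohort)
    frac <- params$sampleFrac
    balOK <- matrix(spliceBalance(SL, SR, params$balanceLow,
                                  params$balanceHigh), nrow = nrow(SL))
    passBalance <- rowMeans(balOK) >= frac
    passJunction <- rowMeans(SL + SR > params$minJunction) >= frac
    passCoverage <- rowMeans(cov > params$minCoverage) >= frac
    irOK <- ir > params$irFloor
    perGroup <- vapply(irFloorGroups, function(g)
        rowMeans(irOK[, grp == g, drop = FALSE]) >= frac,
        logical(nrow(ir)))
    passIRFloor <- apply(matrix(perGroup, nrow = nrow(ir)), 1L, any)
    DataFrame(intron_id = rownames(cohort),
              pass_balance = unname(passBalance),
              pass_junction_support = unname(passJunction),
              pass_coverage = unname(passCoverage),
              pass_ir_floor = unname(passIRFloor),
              pass_all = unname(passBalance & passJunction &
                                passCoverage & passIRFloor))
}

#' Count IR events per sample
#'
#' An IR event is an intron that passes all cohort filters and has an IR
#' ratio strictly greater than \code{threshold} in the sample.
#'
#' @param cohort an \code{\linkS4class{IRCohort}}.
#' @param mask filter mask from \code{\link{applyCohortFilters}},
#'   computed on the same cohort.
#' @param threshold strict IR-ratio lower bound (default 0.1).
#' @return named integer vector of event counts, one per sample.
#' @export
countIREvents <- function(cohort, mask, threshold = 0.1) {
    stopifnot(is(cohort, "IRCohort"),
              identical(as.character(mask$intron_id), rownames(cohort)))
    ir <- assay(cohort, "irRatio")
    pass <- mask$pass_all
    counts <- colSums(ir[pass, , drop = FALSE] > threshold)
    stats::setNames(as.integer(counts), colnames(cohort))
}

#' Read-depth sample QC
#'
#' Retains samples whose total aligned read count meets the minimum
#' sequencing depth (default 40 million reads).
#'
#' @param quants list of \code{\linkS4class{SampleQuant}} objects, or an
#'   \code{\linkS4class{IRCohort}} (whose \code{colData$totalReads} is
#'   used).
#' @param minReads inclusive minimum read count.
#' @return character vector of retained sample ids.
#' @examples
#' # a 39,999,999-read sample fails, a 40,000,000-read sample passes
#' @export
sampleQC <- function(quants, minReads = 4e7) {
    if (is(quants, "IRCohort")) {
        tot <- quants$totalReads
        ids <- colnames(quants)
    } else {
        tot <- vapply(quants, totalReads, numeric(1))
        ids <- vapply(quants, function(q) q@sampleId, character(1))
    }
    ids[tot >= minReads]
}
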