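# Small constructors for toy annotation, alignments and cohorts.

writeToyGTF <- function(exons, path = tempfile(fileext = ".gtf")) {
    # exons: data.frame(chrom, start, end, strand, gene, tx)
    writeLines(sprintf(
        "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        exons$chrom, exons$start, exons$end, exons$strand, exons$gene,
        exons$tx), path)
    path
}

writeToySAM <- function(contigs, reads, path = tempfile(fileext = ".sam")) {
    # contigs: named integer vector of lengths; reads: data.frame(qname,
    # flag, chrom, pos, cigar)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
    body <- if (nrow(reads)) sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                                     reads$qname, reads$flag, reads$chrom,
                                     reads$pos, reads$cigar)
            else character(0)
    writeLines(c(header, body), path)
    path
}

# two-gene toy annotation: gene gA (+, 3 exons) on chrA, gene gB (-, 3
# exons) on chrB; exons [1,100], [201,300], [401,500]
toyExonsDf <- function() {
    rbind(
        data.frame(chrom = "chrA", start = c(1L, 201L, 401L),
                   end = c(100L, 300L, 500L), strand = "+", gene = "gA",
                   tx = "tA1", stringsAsFactors = FALSE),
        data.frame(chrom = "chrB", start = c(1L, 201L, 401L),
                   end = c(100L, 300L, 500L), strand = "-", gene = "gB",
                   tx = "tB1", stringsAsFactors = FALSE))
}

toyReference <- function() {
    buildIntronReference(parseGTF(writeToyGTF(toyExonsDf())))
}

# build an IRCohort directly from metric matrices (rows = introns)
makeTestCohort <- function(irRatio, groups, SL = NULL, SR = NULL,
                           coverage = NULL, ID = NULL, SE = NULL,
                           totalReads = NULL) {
    n <- nrow(irRatio); m <- ncol(irRatio)
    zero <- matrix(0, n, m)
    if (is.null(SL)) SL <- zero
    if (is.null(SR)) SR <- zero
    if (is.null(coverage)) coverage <- matrix(1, n, m)
    if (is.null(ID)) ID <- zero
    if (is.null(SE)) SE <- zero
    ids <- if (!is.null(rownames(irRatio))) rownames(irRatio)
           else sprintf("I%02d", seq_len(n))
    sampleIds <- if (!is.null(colnames(irRatio))) colnames(irRatio)
                 else sprintf("s%02d", seq_len(m))
    introns <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(seq_len(n) * 1000L + 101L,
                                 seq_len(n) * 1000L + 300L), strand = "+")
    S4Vectors::mcols(introns) <- S4Vectors::DataFrame(
        intron_id = ids, gene_id = "g1",
        leftExonStart = seq_len(n) * 1000L + 1L,
        leftExonEnd = seq_len(n) * 1000L + 100L,
        rightExonStart = seq_len(n) * 1000L + 301L,
        rightExonEnd = seq_len(n) * 1000L + 400L)
    fix <- function(x) {
        x <- matrix(as.numeric(x), n, m)
        dimnames(x) <- list(ids, sampleIds)
        x
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ID = fix(ID), coverage = fix(coverage), SL = fix(SL),
                      SR = fix(SR), SE = fix(SE), irRatio = fix(irRatio)),
        rowRanges = introns,
        colData = S4Vectors::DataFrame(
            group = factor(groups),
            totalReads = if (is.null(totalReads)) rep(0, m) else totalReads,
            row.names = sampleIds))
    new("IRCohort", se)
}

# hand-built 6-intron x 8-sample cohort whose expected mask and event
# counts were worked out by hand from the four selection rules
filterFixture <- function() {
    rep8 <- function(x) matrix(x, nrow = 1)
    SL <- rbind(rep(10, 8),
                c(rep(7, 4), rep(14, 4)),
                c(rep(5, 4), rep(5, 4)),
                rep(10, 8),
                rep(10, 8),
                rep(0, 8))
    SR <- rbind(rep(10, 8),
                rep(10, 8),
                c(rep(6, 4), rep(5, 4)),
                rep(10, 8),
                rep(10, 8),
                rep(20, 8))
    cov <- rbind(rep(0.8, 8),
                 rep(0.6, 8),
                 rep(0.9, 8),
                 c(rep(0.6, 3), rep(0.4, 5)),
                 rep(0.8, 8),
                 rep(0.7, 8))
    ir <- rbind(c(rep(0.2, 7), 0.10),
                rep(0.06, 8),
                rep(0.5, 8),
                rep(0.2, 8),
                c(0.06, 0.02, 0.02, 0.02, 0.06, 0.06, 0.02, 0.02),
                rep(0.3, 8))
    rownames(SL) <- rownames(SR) <- rownames(cov) <- rownames(ir) <-
        sprintf("I%02d", 1:6)
    groups <- c(rep("normal", 4), rep("cancer", 4))
    list(cohort = makeTestCohort(ir, groups, SL = SL, SR = SR,
                                 coverage = cov),
         expectedMask = data.frame(
             pass_balance = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
             pass_junction_support = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
             pass_coverage = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
             pass_ir_floor = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
             pass_all = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)),
         expectedEvents = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L))
}

# simple PWM fixtures
unifBg <- rep(0.25, 4)

singleBasePWM <- function(p = 0.97, pseudocount = 0) {
    rbpMotif("single", matrix(c(p, rep((1 - p) / 3, 3)), 1, 4),
             pseudocount = pseudocount)
}

randomPWM <- function(L, seed, pseudocount = 1e-3) {
    set.seed(seed)
    m <- matrix(stats::rgamma(L * 4, 1), L, 4)
    m <- m / rowSums(m)
    rbpMotif(paste0("rand", L, "_", seed), m, pseudocount = pseudocount)
}

randomSeq <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
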