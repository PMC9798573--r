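memeFixture <- function() {
    path <- tempfile(fileext = ".meme")
    writeLines(c(
        "MEME version 4", "", "ALPHABET= ACGT", "",
        "Background letter frequencies",
        "A 0.25 C 0.25 G 0.25 T 0.25", "",
        "MOTIF m1 RBP1",
        "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
        "0.970000 0.010000 0.010000 0.010000",
        "0.010000 0.970000 0.010000 0.010000",
        "0.010000 0.010000 0.970000 0.010000", ""), path)
    path
}

test_that("MEME minimal files parse into probability matrices", {
    pwms <- readPWMs(memeFixture(), "meme", pseudocount = 0)
    expect_length(pwms, 1L)
    p <- pwms[["m1"]]
    expect_equal(length(p), 3L)
    expect_equal(rbpName(p), "RBP1")
    expect_equal(motifConsensus(p), "ACG")
    expect_equal(unname(motifMatrix(p)[1, ]), c(0.97, 0.01, 0.01, 0.01))
    expect_error(readPWMs(tempfile(fileext = ".meme"), "meme"))
})

test_that("ATtRACT-style tab files parse with U mapped to T", {
    path <- tempfile(fileext = ".txt")
    writeLines(c(">M001\tSRSF1",
                 "0.9\t0.05\t0.03\t0.02",
                 "0.1\t0.1\t0.1\t0.7"), path)
    pwms <- readPWMs(path, "attract-tab", pseudocount = 0)
    p <- pwms[["M001"]]
    expect_equal(length(p), 2L)
    expect_equal(rbpName(p), "SRSF1")
    expect_equal(unname(motifMatrix(p)[2, "T"]), 0.7)
})

test_that("rows not summing to one are renormalised with a warning", {
    expect_warning(p <- rbpMotif("x", matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4),
                                 pseudocount = 1e-3), "renormalised")
    expect_equal(sum(motifMatrix(p)), 1)
    expect_true(all(motifMatrix(p) > 0))
})

test_that("MEME write-read round trip preserves matrices to 1e-9", {
    pwms <- list(randomPWM(4, 1), randomPWM(6, 2))
    names(pwms) <- vapply(pwms, motifId, character(1))
    path <- tempfile(fileext = ".meme")
    writePWMsMeme(pwms, path)
    back <- readPWMs(path, "meme", pseudocount = 0)
    for (nm in names(pwms))
        expect_equal(motifMatrix(back[[nm]]), motifMatrix(pwms[[nm]]),
                     tolerance = 1e-7)
})

test_that("PWM scoring matches hand-computed log odds", {
    # single position, A probability 1, uniform background: 2 bits
    one <- rbpMotif("a", matrix(c(1, 0, 0, 0), 1, 4), pseudocount = 0)
    expect_equal(pwmScore("A", one), 2)
    # window matching the background exactly scores 0
    flat <- rbpMotif("f", matrix(0.25, 2, 4), pseudocount = 0)
    expect_equal(pwmScore("AG", flat), 0)
    # 3-mer: position-by-position manual sum
    pwms <- readPWMs(memeFixture(), "meme", pseudocount = 0)
    p <- pwms[["m1"]]
    manual <- log2(0.97 / 0.25) + log2(0.01 / 0.25) + log2(0.97 / 0.25)
    expect_equal(pwmScore("AAG", p), manual)
    # N contributes zero
    expect_equal(pwmScore("ANG", p),
                 log2(0.97 / 0.25) + log2(0.97 / 0.25))
    expect_error(pwmScore("AXG", p), "outside")
    expect_error(pwmScore("AC", p), "length")
})

test_that("the DP score distribution is a proper distribution matching enumeration", {
    for (pwm in list(singleBasePWM(), randomPWM(3, 5), randomPWM(5, 6),
                     randomPWM(8, 7))) {
        d <- scoreDistribution(pwm)
        expect_lt(abs(sum(d$prob) - 1), 1e-9)
        e <- enumPWMDist(pwm)
        merged <- merge(d, e, by = "score", all = TRUE)
        merged[is.na(merged)] <- 0
        tv <- sum(abs(merged$prob.x - merged$prob.y)) / 2
        expect_lt(tv, 1e-9)
    }
})

test_that("threshold calibration matches enumerable cases and is monotone", {
    # single-position PWM (A 0.97), uniform background, pTarget 0.25:
    # only A qualifies, so the threshold sits at (just below) score('A')
    p <- singleBasePWM(0.97)
    thr <- scoreThreshold(p, 0.25)
    sA <- pwmScore("A", p)
    expect_lte(thr, sA)
    expect_gt(thr, sA - 0.011)          # within one bin
    expect_gt(thr, pwmScore("C", p))    # non-consensus bases excluded
    # pTarget = 1 admits every window: threshold at the minimum score
    thrAll <- scoreThreshold(p, 1)
    expect_lte(thrAll, pwmScore("C", p))
    expect_gt(thrAll, pwmScore("C", p) - 0.011)
    # smaller pTarget never lowers the threshold
    ps <- c(0.5, 0.25, 0.1, 0.01, 1e-3)
    thrs <- vapply(ps, function(pt) scoreThreshold(randomPWM(6, 8), pt),
                   numeric(1))
    expect_true(all(diff(thrs) >= 0))
})

test_that("region scanning equals the exhaustive window scan", {
    pwm <- randomPWM(6, 12)
    thr <- scoreThreshold(pwm, 0.01)
    seq1k <- randomSeq(1000, 13)
    expect_equal(scanRegion(seq1k, pwm, thr),
                 bruteForceScan(seq1k, pwm, thr))
    # shorter than the motif: zero hits
    expect_equal(scanRegion("ACG", pwm, thr), 0L)
    # planted consensus at threshold = consensus score is found exactly
    cons <- motifConsensus(pwm)
    planted <- paste0(substr(seq1k, 1, 100), cons,
                      substr(seq1k, 101, 200), cons)
    consScore <- pwmScore(cons, pwm)
    extra <- bruteForceScan(planted, pwm, consScore)
    expect_gte(extra, 2L)
    expect_equal(scanRegion(planted, pwm, consScore), extra)
})

test_that("scanning is shift-equivariant when prepending background", {
    pwm <- randomPWM(5, 21)
    thr <- scoreThreshold(pwm, 0.02)
    body <- randomSeq(300, 22)
    prefix <- randomSeq(40, 23)
    whole <- paste0(prefix, body)
    prefixHits <- scanRegion(substr(whole, 1, 40 + 4), pwm, thr)
    expect_equal(scanRegion(whole, pwm, thr),
                 prefixHits + scanRegion(body, pwm, thr))
})

test_that("flank regions are extracted in transcript orientation", {
    d <- simDesign(nGenes = 2, intronsPerGene = 1, exonLen = 120,
                   intronLen = 200, seed = 31)
    ref <- simulateGenome(d)
    fl <- extractFlanks(ref$genome, ref$introns, width = 50)
    expect_equal(nrow(fl), 2L * 4L)
    expect_true(all(nchar(fl$seq) == 50))
    expect_true(!any(fl$truncated))
    # plus-strand gene (chr1): 5p_intron is the literal first 50 intronic nt
    ip <- ref$introns[as.character(BiocGenerics::strand(ref$introns)) == "+"]
    s <- BiocGenerics::start(ip); e <- BiocGenerics::end(ip)
    chr <- as.character(GenomicRanges::seqnames(ip))
    lit <- as.character(Biostrings::subseq(ref$genome[[chr]], s, s + 49))
    got <- fl$seq[fl$intron_id == ip$intron_id & fl$region == "5p_intron"]
    expect_equal(got, lit)
    # minus-strand gene: 5p_intron is the reverse complement of the last
    # 50 genomic nt of the intron
    im <- ref$introns[as.character(BiocGenerics::strand(ref$introns)) == "-"]
    sM <- BiocGenerics::start(im); eM <- BiocGenerics::end(im)
    chrM <- as.character(GenomicRanges::seqnames(im))
    litM <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(ref$genome[[chrM]], eM - 49, eM)))
    gotM <- fl$seq[fl$intron_id == im$intron_id & fl$region == "5p_intron"]
    expect_equal(gotM, litM)
    # short exons truncate with a flag
    d2 <- simDesign(nGenes = 1, intronsPerGene = 1, exonLen = 30,
                    intronLen = 200, readLen = 20, seed = 32)
    ref2 <- simulateGenome(d2)
    fl2 <- extractFlanks(ref2$genome, ref2$introns, width = 50)
    exonic <- fl2$region %in% c("5p_exon", "3p_exon")
    expect_true(all(nchar(fl2$seq[exonic]) == 30))
    expect_true(all(fl2$truncated[exonic]))
})

test_that("region enrichment handles the degenerate and hand-computable cases", {
    same <- regionEnrichment(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_false(same$degenerate)
    # both groups constant but different: zero pooled variance
    deg <- regionEnrichment(c(2, 2, 2, 2), c(0, 0, 0, 0))
    expect_equal(deg$meanIR - deg$meanNR, 2)
    expect_equal(deg$p, 0)
    expect_true(deg$degenerate)
    # non-degenerate case against the standard pooled-variance formula
    a <- c(3, 1, 2, 2); b <- c(0, 1, 0, 1)
    e <- regionEnrichment(a, b)
    sp2 <- (3 * var(a) + 3 * var(b)) / 6
    tManual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    expect_equal(e$t, tManual)
    expect_equal(e$p, 2 * pt(-abs(tManual), 6))
    # binary mode reduces counts to presence/absence
    eb <- regionEnrichment(c(0, 5, 2, 0), c(0, 1, 0, 0), binary = TRUE)
    expect_equal(eb$meanIR, 0.5)
    expect_equal(eb$meanNR, 0.25)
})

test_that("planted motifs are rediscovered where they were planted", {
    d <- simDesign(nGenes = 30, intronsPerGene = 1, exonLen = 120,
                   intronLen = 200, seed = 41)
    ref <- simulateGenome(d)
    cons <- "TGCATGCA"
    irClass <- ref$introns$intron_id[1:15]
    pm <- plantMotifs(ref$genome, ref$introns, cons, "5p_exon",
                      irIntrons = irClass, rateIR = 1, rateNR = 0,
                      width = 50, seed = 42)
    expect_true(all(pm$truth$planted[pm$truth$class == "IR"]))
    expect_false(any(pm$truth$planted[pm$truth$class == "NR"]))
    pwm <- rbpMotif("cons", t(vapply(strsplit(cons, "")[[1]], function(b)
        as.numeric(c("A", "C", "G", "T") == b), numeric(4))),
        pseudocount = 0)
    consScore <- pwmScore(cons, pwm)
    fl <- extractFlanks(pm$genome, ref$introns, width = 50)
    sel <- fl$region == "5p_exon"
    hits <- vapply(fl$seq[sel], scanRegion, integer(1), pwm = pwm,
                   threshold = consScore, USE.NAMES = FALSE)
    planted <- pm$truth$planted[match(fl$intron_id[sel], pm$truth$intron_id)]
    expect_true(all(hits[planted] >= 1L))
    expect_true(all(hits[!planted] == 0L))
})

test_that("the motif enrichment table detects a planted class difference", {
    d <- simDesign(nGenes = 40, intronsPerGene = 1, exonLen = 120,
                   intronLen = 200, seed = 51)
    ref <- simulateGenome(d)
    cons <- "TGCATGC"
    irClass <- ref$introns$intron_id[1:20]
    pm <- plantMotifs(ref$genome, ref$introns, cons, "5p_intron",
                      irIntrons = irClass, rateIR = 1, rateNR = 0,
                      width = 50, seed = 52)
    pwm <- rbpMotif("cons", t(vapply(strsplit(cons, "")[[1]], function(b)
        as.numeric(c("A", "C", "G", "T") == b), numeric(4))),
        rbpName = "TESTRBP", pseudocount = 1e-3)
    fl <- extractFlanks(pm$genome, ref$introns, width = 50)
    tab <- motifEnrichmentTable(fl, irClass, list(pwm), pTarget = 1e-4)
    row <- tab[tab$region == "5p_intron", ]
    expect_gt(row$mean_ir, row$mean_nr)
    expect_lt(row$p, 0.01)
})
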