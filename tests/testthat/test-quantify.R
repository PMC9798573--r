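test_that("IR ratio follows its defining formula and boundaries", {
    expect_equal(irRatio(2, 8, 6), 0.2)
    expect_equal(irRatio(0, 10, 10), 0)
    expect_equal(irRatio(5, 0, 0), 1)
    expect_equal(irRatio(0, 0, 0), 0)
    expect_error(irRatio(-1, 0, 0), "non-negative")
    # monotone increasing in ID, non-increasing in max(SL, SR)
    ids <- seq(0, 10, by = 0.5)
    expect_true(all(diff(irRatio(ids, 5, 5)) > 0))
    sls <- 0:20
    expect_true(all(diff(irRatio(3, sls, 0)) <= 0))
})

test_that("intron depth is the median and coverage the covered fraction", {
    expect_equal(intronDepth(c(0, 0, 3, 5, 2)), 2)
    expect_equal(intronDepth(c(0, 0, 0, 0)), 0)
    expect_equal(intronDepth(c(1, 3)), 2)  # even length: central average
    expect_equal(intronCoverage(c(0, 0, 3, 5, 2)), 0.6)
    expect_equal(intronCoverage(c(0, 0, 0, 0)), 0)
    expect_equal(intronCoverage(c(2, 1, 1)), 1)
    expect_error(intronDepth(numeric(0)))
    expect_error(intronCoverage(numeric(0)))
})

test_that("an exact junction read increments SE, SL and SR but not depth", {
    introns <- toyReference()
    # gA intron 1 on chrA: [101, 200]; read 10M100N10M starting at 91
    sam <- writeToySAM(c(chrA = 600L, chrB = 600L),
                       data.frame(qname = "r1", flag = 0L, chrom = "chrA",
                                  pos = 91L, cigar = "10M100N10M"))
    q <- collectAlignments(sam, introns, parseGTF(writeToyGTF(toyExonsDf())))
    m <- as.data.frame(quantMetrics(q))
    i1 <- m[m$intron_id == "chrA:100-200:+:gA", ]
    expect_equal(i1$SE, 1L)
    expect_equal(i1$SL, 1L)
    expect_equal(i1$SR, 1L)
    expect_equal(i1$ID, 0)
    expect_equal(i1$irRatio, 0)
})

test_that("a read inside the intron contributes depth but no junctions", {
    introns <- toyReference()
    sam <- writeToySAM(c(chrA = 600L, chrB = 600L),
                       data.frame(qname = "r1", flag = 0L, chrom = "chrA",
                                  pos = 121L, cigar = "20M"))
    q <- collectAlignments(sam, introns)
    m <- as.data.frame(quantMetrics(q))
    i1 <- m[m$intron_id == "chrA:100-200:+:gA", ]
    # 20 covered bases of 100: median depth 0, coverage 0.2
    expect_equal(i1$ID, 0)
    expect_equal(i1$coverage, 0.2)
    expect_equal(i1$SL + i1$SR + i1$SE, 0L)
})

test_that("minus-strand introns swap the genomic junction counters", {
    introns <- toyReference()
    # gB is on the minus strand of chrB. An exon-skipping junction from
    # exon1 to exon3 spans [101, 400]: its donor matches intron1's start
    # and its acceptor (401) is in a gB exon, so it increments the
    # genomic-LEFT counter of intron [101,200] - which in transcript
    # orientation is SR for a minus-strand gene.
    sam <- writeToySAM(c(chrA = 600L, chrB = 600L),
                       data.frame(qname = "r1", flag = 0L, chrom = "chrB",
                                  pos = 91L, cigar = "10M300N10M"))
    q <- collectAlignments(sam, introns, parseGTF(writeToyGTF(toyExonsDf())))
    m <- as.data.frame(quantMetrics(q))
    i1 <- m[m$intron_id == "chrB:100-200:-:gB", ]
    expect_equal(i1$SR, 1L)
    expect_equal(i1$SL, 0L)
    expect_equal(i1$SE, 0L)
    # and an exact junction on the minus strand still yields SL = SR = SE = 1
    sam2 <- writeToySAM(c(chrA = 600L, chrB = 600L),
                        data.frame(qname = "r2", flag = 0L, chrom = "chrB",
                                   pos = 91L, cigar = "10M100N10M"))
    m2 <- as.data.frame(quantMetrics(collectAlignments(
        sam2, introns, parseGTF(writeToyGTF(toyExonsDf())))))
    i2 <- m2[m2$intron_id == "chrB:100-200:-:gB", ]
    expect_equal(c(i2$SL, i2$SR, i2$SE), c(1L, 1L, 1L))
})

test_that("junction far ends outside the gene's exons are not counted", {
    introns <- toyReference()
    # gap starts at intron start but the acceptor (331) falls between
    # gA's exons -> neither SL nor SR
    sam <- writeToySAM(c(chrA = 600L, chrB = 600L),
                       data.frame(qname = "r1", flag = 0L, chrom = "chrA",
                                  pos = 91L, cigar = "10M230N10M"))
    m <- as.data.frame(quantMetrics(collectAlignments(
        sam, introns, parseGTF(writeToyGTF(toyExonsDf())))))
    i1 <- m[m$intron_id == "chrA:100-200:+:gA", ]
    expect_equal(c(i1$SL, i1$SR, i1$SE), c(0L, 0L, 0L))
})

test_that("secondary/duplicate/unmapped records are skipped by flag", {
    introns <- toyReference()
    sam <- writeToySAM(c(chrA = 600L, chrB = 600L), data.frame(
        qname = c("p", "sec", "dup"), flag = c(0L, 256L, 1024L),
        chrom = "chrA", pos = 91L, cigar = "10M100N10M"))
    q <- collectAlignments(sam, introns, parseGTF(writeToyGTF(toyExonsDf())))
    expect_equal(totalReads(q), 1)
    m <- as.data.frame(quantMetrics(q))
    expect_equal(m$SE[m$intron_id == "chrA:100-200:+:gA"], 1L)
})

test_that("quantification equals the brute-force counter on a simulated sample", {
    d <- simDesign(nGenes = 5, intronsPerGene = 2, nNormal = 1, nCancer = 0,
                   thetaNormal = c(0.1, 0.4), depth = 30, seed = 11)
    ref <- simulateGenome(d)
    out <- simulateSampleReads(d, ref, "normal", sampleSeed = 42)
    q <- collectAlignments(out$sam, ref$introns, ref$exons)
    oracle <- bruteForceCounter(out$sam, grToDf(ref$introns),
                                exonsToDf(ref$exons))
    m <- as.data.frame(quantMetrics(q))
    expect_equal(m$SL, as.integer(oracle$SL))
    expect_equal(m$SR, as.integer(oracle$SR))
    expect_equal(m$SE, as.integer(oracle$SE))
    expect_equal(m$ID, oracle$ID)
    expect_equal(m$coverage, oracle$coverage)
    expect_equal(totalReads(q), oracle$totalReads)
})

test_that("quant TSV round trip preserves metrics and total reads", {
    d <- simDesign(nGenes = 2, intronsPerGene = 2, thetaNormal = 0.3,
                   depth = 20, seed = 3)
    ref <- simulateGenome(d)
    out <- simulateSampleReads(d, ref, "normal", sampleSeed = 5)
    q <- collectAlignments(out$sam, ref$introns, ref$exons, sampleId = "sA")
    path <- tempfile(fileext = ".tsv")
    writeQuantTsv(q, path)
    back <- readQuantTsv(path)
    expect_equal(back@sampleId, "sA")
    expect_equal(totalReads(back), totalReads(q))
    expect_equal(as.data.frame(quantMetrics(back)),
                 as.data.frame(quantMetrics(q)))
})
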