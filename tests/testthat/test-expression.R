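test_that("size factors recover depth ratios with unit geometric mean", {
    counts <- cbind(s1 = c(10, 20), s2 = c(20, 40))
    sf <- computeSizeFactors(counts)
    expect_equal(unname(sf[2] / sf[1]), 2)
    expect_equal(exp(mean(log(sf))), 1)
    # identical samples -> all ones
    same <- matrix(c(5, 9, 30), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
    expect_equal(unname(computeSizeFactors(same)), rep(1, 4))
    # scaling one sample by c scales its factor by c (ratios preserved)
    set.seed(2)
    m <- matrix(rpois(60, 50) + 1, 10, 6)
    colnames(m) <- paste0("s", 1:6)
    m2 <- m; m2[, 3] <- m2[, 3] * 4
    sf1 <- computeSizeFactors(m); sf2 <- computeSizeFactors(m2)
    expect_equal(unname(sf2[3] / sf2[1]), unname(4 * sf1[3] / sf1[1]),
                 tolerance = 1e-12)
    # permutation equivariance
    perm <- c(4, 1, 6, 3, 2, 5)
    expect_equal(computeSizeFactors(m[, perm]), computeSizeFactors(m)[perm])
    expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)),
                 "pseudocount")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
    skip_if_not_installed("DESeq2")
    set.seed(31)
    m <- matrix(rnbinom(200 * 8, mu = 80, size = 5) + 1, 200, 8)
    colnames(m) <- paste0("s", 1:8)
    ours <- computeSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("log2 fold change is antisymmetric and hits known ratios", {
    groups <- rep(c("normal", "cancer"), each = 3)
    counts <- rbind(gEq = rep(100, 6),
                    g4x = c(rep(1000, 3), rep(4000, 3)))
    sf <- setNames(rep(1, 6), paste0("s", 1:6))
    colnames(counts) <- names(sf)
    lfc <- log2FoldChange(counts, groups, sf)
    expect_equal(unname(lfc["gEq"]), 0)
    expect_equal(unname(lfc["g4x"]), 2, tolerance = 1e-2)
    flipped <- log2FoldChange(counts, groups, sf,
                              contrast = c("normal", "cancer"))
    expect_equal(unname(flipped), -unname(lfc))
})

test_that("mean-count filter is strict at its boundary", {
    counts <- rbind(lo = rep(5, 4), boundary = rep(10, 4),
                    above = c(10, 11, 10, 11), hi = rep(200, 4))
    expect_equal(meanCountFilter(counts), c("above", "hi"))
    expect_equal(meanCountFilter(rbind(z = rep(0, 4))), character(0))
})

test_that("exclusive DE genes are the reference set minus all others", {
    expect_equal(exclusiveDEGenes(list(ref = c("a", "b", "c"), o1 = "b",
                                       o2 = c("c", "d")), "ref"), "a")
    expect_equal(exclusiveDEGenes(list(ref = c("a", "b"), o1 = "x"), "ref"),
                 c("a", "b"))
    expect_equal(exclusiveDEGenes(list(ref = c("a", "b"),
                                       o1 = c("a", "b", "c")), "ref"),
                 character(0))
    expect_error(exclusiveDEGenes(list(o1 = "x"), "ref"), "missing")
    # output never intersects any non-reference set
    set.seed(5)
    sets <- lapply(1:5, function(i) sample(letters, 8))
    names(sets) <- paste0("c", 1:5)
    excl <- exclusiveDEGenes(sets, "c1")
    for (nm in paste0("c", 2:5))
        expect_length(intersect(excl, sets[[nm]]), 0L)
})

test_that("specificity z-score matches the hand computation and is affine-invariant", {
    lfc <- c(3, rep(1, 8))
    # mean 11/9 = 1.2222, sd (n-1) = 0.6667, z = 1.7778/0.6667
    expect_equal(specificityZScore(lfc, 1), 2.666667, tolerance = 1e-3)
    expect_equal(specificityZScore(lfc + 5.3, 1), specificityZScore(lfc, 1),
                 tolerance = 1e-9)
    expect_warning(z0 <- specificityZScore(rep(2, 9), 1), "zero")
    expect_equal(z0, 0)
    expect_error(specificityZScore(c(1, 2), 1), "3 conditions")
    # excluding the reference changes the pool, not the scored value:
    # the other 8 are all equal, so the pooled sd degenerates to zero
    expect_warning(zEx <- specificityZScore(lfc, 1, excludeReference = TRUE),
                   "zero")
    expect_equal(zEx, 0)
})

test_that("specificity screen tables z-scores across a fold-change panel", {
    sim <- simulateSpecificityPanel(nGenes = 60, nExclusive = 6, seed = 9)
    scr <- specificityScreen(sim$lfcTable, sim$reference,
                             exclusiveGenes = exclusiveDEGenes(
                                 sim$deSets, sim$reference))
    expect_equal(nrow(scr), 60L)
    # planted exclusive genes have the largest specificity z-scores
    planted <- scr$gene_id %in% sim$exclusiveTruth
    expect_gt(min(scr$z[planted]), max(scr$z[!planted]))
    # thresholded truth sets recover the planted exclusive genes exactly
    expect_setequal(exclusiveDEGenes(sim$deSets, sim$reference),
                    sim$exclusiveTruth)
})

test_that("IR-expression correlation hits the exact and planted cases", {
    events <- setNames(c(10, 100, 1000, 31, 310), paste0("s", 1:5))
    x <- log10(as.numeric(events) + 1)
    # y exactly proportional to x on the transformed scale -> r = 1
    perfect <- matrix(10^(2 * x) - 1, 1, 5,
                      dimnames = list("gPos", names(events)))
    sf <- setNames(rep(1, 5), names(events))
    r <- correlateIRExpression(events, perfect, sf)
    expect_equal(r$r, 1, tolerance = 1e-12)
    # reversed -> r = -1
    rev <- matrix(10^(max(2 * x) - 2 * x) - 1, 1, 5,
                  dimnames = list("gNeg", names(events)))
    expect_equal(correlateIRExpression(events, rev, sf)$r, -1,
                 tolerance = 1e-12)
    # zero-variance gene is flagged with r = 0
    flat <- matrix(7, 1, 5, dimnames = list("gFlat", names(events)))
    rf <- correlateIRExpression(events, flat, sf)
    expect_true(rf$degenerate)
    expect_equal(rf$r, 0)
})

test_that("planted IR-coupled genes rank in the top decile of correlation", {
    sim <- simulateExpression(nGenes = 50, nPlantedPos = 5, nPlantedNeg = 0,
                              nSamples = 40, seed = 17)
    r <- correlateIRExpression(sim$eventCounts, sim$counts)
    ranks <- rank(-r$r)
    planted <- sim$truth$planted == "pos"
    expect_true(all(ranks[planted] <= ceiling(0.1 * nrow(r))))
    # unplanted genes stay near zero
    expect_lt(median(abs(r$r[!planted])), 0.2)
})

test_that("top-percentile selection uses ceil and deterministic ties", {
    r <- setNames(seq(0.01, 1, length.out = 100), sprintf("g%03d", 1:100))
    sets <- topPercentileGenes(r, 0.05)
    expect_length(sets$top, 5L)
    expect_equal(sets$top, names(sort(r, decreasing = TRUE))[1:5])
    expect_equal(sets$bottom, names(sort(r))[1:5])
    r10 <- r[1:10]
    sets10 <- topPercentileGenes(r10, 0.05)
    expect_length(sets10$top, 1L)  # ceil(0.5) = 1
    # ties broken by gene id
    tied <- setNames(rep(0.5, 4), c("d", "b", "a", "c"))
    expect_equal(topPercentileGenes(tied, 0.3)$top, c("a", "b"))
    expect_error(topPercentileGenes(r, 0.7), "0, 0.5")
})
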