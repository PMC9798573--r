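#' Simulate a genome and annotation for an IR cohort
#'
#' Emits one contig per gene, each carrying a single multi-exon gene with
#' alternating exon/intron structure of the designed lengths; sequence is
#' i.i.d. uniform over A/C/G/T.  Gene strands alternate between + and -
#' so strand handling is exercised end to end.  Writes a wrapped FASTA
#' and a valid Ensembl-dialect GTF; both are byte-identical across runs
#' with the same design.
#'
#' @param design a \code{\linkS4class{SimDesign}}.
#' @param dir output directory (created if needed).
#' @return list with \code{fasta} and \code{gtf} paths, the genome as a
#'   \code{DNAStringSet}, the exon \code{GRanges}, the intron reference
#'   \code{GRanges}, and \code{intronOrder} (intron ids in design order:
#'   gene-major, then position).
#' @export
#' @importFrom Biostrings DNAStringSet
simulateGenome <- function(design, dir = tempfile("irsim")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    k <- design@intronsPerGene
    pad <- 10L
    geneLen <- (k + 1L) * design@exonLen + k * design@intronLen
    contigLen <- geneLen + 2L * pad
    seqs <- withSeed(design@seed, {
        vapply(seq_len(design@nGenes), function(g)
            paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE),
                  collapse = ""), character(1))
    })
    chroms <- sprintf("chr%d", seq_len(design@nGenes))
    names(seqs) <- chroms
    genome <- DNAStringSet(seqs)
    gtfLines <- character(0)
    intronOrder <- character(0)
    for (g in seq_len(design@nGenes)) {
        strand <- if (g %% 2L == 1L) "+" else "-"
        exonStarts <- pad + 1L +
            (seq_len(k + 1L) - 1L) * (design@exonLen + design@intronLen)
        exonEnds <- exonStarts + design@exonLen - 1L
        gtfLines <- c(gtfLines, sprintf(
            "%s\tirsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"g%d\"; transcript_id \"t%d.1\";",
            chroms[g], exonStarts, exonEnds, strand, g, g))
        iStart <- exonEnds[seq_len(k)] + 1L
        iEnd <- exonStarts[seq_len(k) + 1L] - 1L
        ids <- sprintf("%s:%d-%d:%s:g%d", chroms[g], iStart - 1L, iEnd,
                       strand, g)
        # transcript order: genomic order on +, reversed on -
        intronOrder <- c(intronOrder, if (strand == "+") ids else rev(ids))
    }
    fastaPath <- file.path(dir, "genome.fa")
    .writeFasta(genome, fastaPath)
    gtfPath <- file.path(dir, "annotation.gtf")
    writeLines(gtfLines, gtfPath)
    exons <- parseGTF(gtfPath)
    introns <- buildIntronReference(exons)
    list(fasta = fastaPath, gtf = gtfPath, genome = genome, exons = exons,
         introns = introns, intronOrder = intronOrder)
}

.writeFasta <- function(seqs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        s <- as.character(seqs[[nm]])
        starts <- seq(1L, nchar(s), by = 70L)
        writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
    }
    invisible(path)
}

#' Simulate one sample's spliced alignments
#'
#' Read model: for each intron the sample-level retention fraction
#' \code{pi} is drawn from Beta with mean equal to the group's true
#' retention \code{theta} and precision \code{phiSim}; the number of
#' junction-region fragments is Poisson(\code{depth}); each fragment is
#' unspliced with probability \code{pi}, yielding a single M read
#' covering the whole intron (so the per-base intronic depth is exactly
#' the unspliced fragment count), and otherwise yields a spliced read
#' whose N gap matches the intron exactly, anchored half a read length
#' into each flanking exon.  With this model the downstream IR ratio is
#' the binomial proportion of unspliced fragments and converges to
#' \code{pi}.
#'
#' @param design a \code{\linkS4class{SimDesign}}.
#' @param ref genome/annotation list from \code{\link{simulateGenome}}.
#' @param group \code{"normal"} or \code{"cancer"} (selects the theta
#'   vector).
#' @param sampleSeed RNG seed for this sample.
#' @param samPath output SAM path.
#' @return list with \code{sam} (path), \code{truth} (data.frame of
#'   \code{intron_id}, \code{theta}, \code{pi}, \code{nFragments},
#'   \code{nUnspliced}) and \code{totalReads}.
#' @export
simulateSampleReads <- function(design, ref, group = c("normal", "cancer"),
                                sampleSeed = design@seed,
                                samPath = tempfile(fileext = ".sam")) {
    group <- match.arg(group)
    theta <- rep(if (group == "normal") design@thetaNormal
                 else design@thetaCancer, length.out = nIntrons(design))
    introns <- ref$introns
    ord <- match(ref$intronOrder, introns$intron_id)
    stopifnot(!anyNA(ord))
    anchor <- max(1L, design@readLen %/% 2L)
    sim <- withSeed(sampleSeed, {
        rows <- vector("list", length(ord))
        readLines <- vector("list", length(ord))
        for (j in seq_along(ord)) {
            i <- ord[j]
            th <- theta[j]
            pi <- if (th <= 0 || th >= 1) th
                  else stats::rbeta(1L, th * design@phiSim,
                                    (1 - th) * design@phiSim)
            nFrag <- stats::rpois(1L, design@depth)
            nU <- stats::rbinom(1L, nFrag, pi)
            nS <- nFrag - nU
            chr <- as.character(seqnames(introns))[i]
            s <- start(introns)[i]; e <- end(introns)[i]
            ilen <- e - s + 1L
            rl <- character(0)
            if (nU > 0L)
                rl <- c(rl, sprintf(
                    "u%d_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                    j, seq_len(nU), chr, s, ilen))
            if (nS > 0L)
                rl <- c(rl, sprintf(
                    "s%d_%d\t0\t%s\t%d\t60\t%dM%dN%dM\t*\t0\t0\t*\t*",
                    j, seq_len(nS), chr, s - anchor, anchor, ilen, anchor))
            readLines[[j]] <- rl
            rows[[j]] <- data.frame(intron_id = introns$intron_id[i],
                                    theta = th, pi = pi, nFragments = nFrag,
                                    nUnspliced = nU,
                                    stringsAsFactors = FALSE)
        }
        list(truth = do.call(rbind, rows),
             lines = unlist(readLines, use.names = FALSE))
    })
    truth <- sim$truth
    lines <- if (is.null(sim$lines)) character(0) else sim$lines
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                        Biostrings::width(ref$genome)))
    writeLines(c(header, lines), samPath)
    list(sam = samPath, truth = truth, totalReads = length(lines))
}

#' Simulate a tumour/normal IR cohort with known ground truth
#'
#' Generates the genome and annotation once, then one SAM per sample
#' (\code{nNormal} normal + \code{nCancer} cancer), a sample metadata
#' TSV, and a truth table marking which introns are differential
#' (\code{thetaCancer != thetaNormal}).  Everything is a pure function of
#' the design (including its seed).
#'
#' @param design a \code{\linkS4class{SimDesign}}.
#' @param dir output directory.
#' @return list with the \code{ref} genome list, \code{samples}
#'   (data.frame of sample_id, group, sam path, totalReads),
#'   \code{metadata} (TSV path), \code{truth} (data.frame with
#'   \code{intron_id}, \code{theta_normal}, \code{theta_cancer},
#'   \code{is_differential}; also written to \code{truth.tsv}), and
#'   \code{piMatrix} (introns x samples realised retention fractions).
#' @export
simulateCohort <- function(design, dir = tempfile("ircohort")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ref <- simulateGenome(design, dir)
    nI <- nIntrons(design)
    thetaN <- rep(design@thetaNormal, length.out = nI)
    thetaC <- rep(design@thetaCancer, length.out = nI)
    groups <- c(rep("normal", design@nNormal), rep("cancer", design@nCancer))
    ids <- sprintf("%s_%02d", groups,
                   c(seq_len(design@nNormal), seq_len(design@nCancer)))
    piMat <- matrix(NA_real_, nI, length(ids),
                    dimnames = list(ref$intronOrder, ids))
    samples <- data.frame(sample_id = ids, group = groups,
                          sam = file.path(dir, paste0(ids, ".sam")),
                          totalReads = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_along(ids)) {
        out <- simulateSampleReads(design, ref, group = groups[j],
                                   sampleSeed = subSeed(design@seed, j),
                                   samPath = samples$sam[j])
        piMat[, j] <- out$truth$pi
        samples$totalReads[j] <- out$totalReads
    }
    metaPath <- file.path(dir, "metadata.tsv")
    writeTsv(samples[c("sample_id", "group")], metaPath)
    truth <- data.frame(intron_id = ref$intronOrder,
                        theta_normal = thetaN, theta_cancer = thetaC,
                        is_differential = thetaN != thetaC,
                        stringsAsFactors = FALSE)
    writeTsv(truth, file.path(dir, "truth.tsv"))
    list(dir = dir, ref = ref, samples = samples, metadata = metaPath,
         truth = truth, piMatrix = piMat)
}

#' Quantify a simulated cohort into an IRCohort
#'
#' Convenience wrapper: runs \code{\link{collectAlignments}} on every
#' sample of a \code{\link{simulateCohort}} result and assembles the
#' \code{\linkS4class{IRCohort}}.
#'
#' @param cohortSim result of \code{\link{simulateCohort}}.
#' @return an \code{\linkS4class{IRCohort}}.
#' @export
quantifyCohort <- function(cohortSim) {
    introns <- cohortSim$ref$introns
    exons <- cohortSim$ref$exons
    quants <- lapply(seq_len(nrow(cohortSim$samples)), function(j)
        collectAlignments(cohortSim$samples$sam[j], introns, exons,
                          sampleId = cohortSim$samples$sample_id[j]))
    makeIRCohort(quants, cohortSim$samples$group, introns)
}

#' Simulate expression counts with planted IR-correlated genes
#'
#' Negative-binomial gene-by-sample counts with log-normal library-size
#' variation (sd 0.3 on the log scale).  A planted subset of genes has
#' its log10 mean tied linearly to the standardised log10 IR event count
#' of each sample, with positive or negative coupling; remaining genes
#' are independent of the event counts.
#'
#' @param eventCounts named per-sample IR event counts; when NULL,
#'   log-normal counts are generated internally.
#' @param nGenes total genes.
#' @param nPlantedPos,nPlantedNeg planted positively / negatively
#'   IR-coupled genes.
#' @param coupling absolute coupling coefficient on the log10 scale
#'   (applied to the standardised log10 event count).
#' @param nbSize negative-binomial size (inverse dispersion).
#' @param libSdLog sd of the log-normal library-size factors.
#' @param nSamples number of samples when \code{eventCounts} is NULL.
#' @param seed RNG seed.
#' @return list with \code{counts} (matrix), \code{eventCounts},
#'   \code{truth} (data.frame gene_id, planted in
#'   \{"pos", "neg", "none"\}), and \code{trueSizeFactors}.
#' @export
simulateExpression <- function(eventCounts = NULL, nGenes = 200L,
                               nPlantedPos = 10L, nPlantedNeg = 10L,
                               coupling = 2, nbSize = 20, libSdLog = 0.3,
                               nSamples = 40L, seed = 1L) {
    withSeed(seed, {
        if (is.null(eventCounts)) {
            eventCounts <- stats::setNames(
                as.integer(round(10^stats::rnorm(nSamples, 3, 0.2))),
                sprintf("s%02d", seq_len(nSamples)))
        }
        nS <- length(eventCounts)
        x <- log10(as.numeric(eventCounts) + 1)
        xz <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
              else rep(0, nS)
        lib <- exp(stats::rnorm(nS, 0, libSdLog))
        lib <- lib / exp(mean(log(lib)))
        genes <- sprintf("gene%03d", seq_len(nGenes))
        planted <- rep("none", nGenes)
        planted[seq_len(nPlantedPos)] <- "pos"
        planted[nPlantedPos + seq_len(nPlantedNeg)] <- "neg"
        base <- stats::runif(nGenes, log10(100), log10(1000))
        beta <- ifelse(planted == "pos", coupling,
                       ifelse(planted == "neg", -coupling, 0))
        # log10 mean per gene per sample; coupling acts on the z-scored
        # log10 event count, scaled to a plausible biological amplitude
        logMu <- outer(base, rep(1, nS)) + outer(beta, xz) * 0.15
        mu <- sweep(10^logMu, 2L, lib, "*")
        counts <- matrix(stats::rnbinom(nGenes * nS, mu = mu, size = nbSize),
                         nGenes, nS,
                         dimnames = list(genes, names(eventCounts)))
        list(counts = counts, eventCounts = eventCounts,
             truth = data.frame(gene_id = genes, planted = planted,
                                stringsAsFactors = FALSE),
             trueSizeFactors = stats::setNames(lib, names(eventCounts)))
    })
}

#' Simulate a multi-condition fold-change panel with exclusive DE genes
#'
#' Per-gene log2 fold changes across several conditions, with a planted
#' subset of genes differentially expressed exclusively in the reference
#' condition.  Per-condition DE sets are derived from the simulated fold
#' changes by thresholding, so set algebra downstream can be checked
#' against the planted truth exactly.
#'
#' @param nGenes total genes.
#' @param nConditions number of conditions (default 9).
#' @param nExclusive genes DE only in the reference condition.
#' @param reference reference condition index.
#' @param exclusiveLfc planted log2 fold change of exclusive genes in the
#'   reference condition.
#' @param noiseSd sd of background log2 fold changes.
#' @param deThreshold |lfc| threshold defining the per-condition DE sets.
#' @param seed RNG seed.
#' @return list with \code{lfcTable} (genes x conditions), \code{deSets}
#'   (list of per-condition DE gene id vectors), \code{exclusiveTruth}
#'   (character vector), \code{reference} (condition name).
#' @export
simulateSpecificityPanel <- function(nGenes = 200L, nConditions = 9L,
                                     nExclusive = 10L, reference = 1L,
                                     exclusiveLfc = 3, noiseSd = 0.3,
                                     deThreshold = 1, seed = 1L) {
    withSeed(seed, {
        genes <- sprintf("gene%03d", seq_len(nGenes))
        conds <- sprintf("cond%d", seq_len(nConditions))
        lfc <- matrix(stats::rnorm(nGenes * nConditions, 0, noiseSd),
                      nGenes, nConditions, dimnames = list(genes, conds))
        excl <- genes[seq_len(nExclusive)]
        lfc[excl, reference] <- exclusiveLfc +
            stats::rnorm(nExclusive, 0, noiseSd / 3)
        deSets <- lapply(conds, function(cd)
            genes[abs(lfc[, cd]) > deThreshold])
        names(deSets) <- conds
        list(lfcTable = lfc, deSets = deSets, exclusiveTruth = excl,
             reference = conds[reference])
    })
}

#' Plant a consensus motif into splice-site flank regions
#'
#' Writes a consensus substring at a uniform random offset within the
#' named flank region (transcript orientation; reverse-complemented into
#' the genome on minus-strand introns) for a Bernoulli-selected subset of
#' each intron class: rate \code{rateIR} for introns in \code{irIntrons},
#' \code{rateNR} for the rest.  Regions too short for the consensus are
#' skipped with a warning.
#'
#' @param genome a \code{DNAStringSet} (modified copy is returned).
#' @param introns intron reference \code{GRanges}.
#' @param consensus consensus string to plant (transcript orientation).
#' @param regionTag one of \code{"5p_exon"}, \code{"5p_intron"},
#'   \code{"3p_intron"}, \code{"3p_exon"}.
#' @param irIntrons intron ids of the IR class.
#' @param rateIR,rateNR planting probabilities per class.
#' @param width flank region width (must match the downstream
#'   \code{\link{extractFlanks}} call).
#' @param seed RNG seed.
#' @return list with \code{genome} (modified \code{DNAStringSet}) and
#'   \code{truth} (data.frame intron_id, class, planted, genomicStart).
#' @export
plantMotifs <- function(genome, introns, consensus,
                        regionTag = c("5p_exon", "5p_intron", "3p_intron",
                                      "3p_exon"),
                        irIntrons, rateIR = 0.6, rateNR = 0.1, width = 50L,
                        seed = 1L) {
    regionTag <- match.arg(regionTag)
    clen <- nchar(consensus)
    rows <- vector("list", length(introns))
    withSeed(seed, {
        for (i in seq_along(introns)) {
            chr <- as.character(seqnames(introns))[i]
            minus <- as.character(strand(introns))[i] == "-"
            s <- start(introns)[i]; e <- end(introns)[i]
            les <- introns$leftExonStart[i]; ree <- introns$rightExonEnd[i]
            chrLen <- Biostrings::width(genome[chr])
            win <- switch(.genomicWindowName(regionTag, minus),
                leftExon = c(max(les, s - width, 1L), s - 1L),
                intronLeft = c(s, min(e, s + width - 1L)),
                intronRight = c(max(s, e - width + 1L), e),
                rightExon = c(e + 1L, min(ree, e + width, chrLen)))
            isIR <- introns$intron_id[i] %in% irIntrons
            rate <- if (isIR) rateIR else rateNR
            plant <- stats::runif(1L) < rate
            gStart <- NA_integer_
            if (plant) {
                regLen <- win[2L] - win[1L] + 1L
                if (regLen < clen) {
                    warning("intron ", introns$intron_id[i], ": region ",
                            regionTag, " shorter than the consensus; skipped")
                    plant <- FALSE
                } else {
                    off <- sample.int(regLen - clen + 1L, 1L) - 1L
                    gStart <- if (minus) win[2L] - off - clen + 1L
                              else win[1L] + off
                    ins <- if (minus)
                        as.character(reverseComplement(
                            DNAStringSet(consensus))[[1L]])
                    else consensus
                    Biostrings::subseq(genome[[chr]], gStart,
                                       gStart + clen - 1L) <-
                        Biostrings::DNAString(ins)
                }
            }
            rows[[i]] <- data.frame(
                intron_id = introns$intron_id[i],
                class = if (isIR) "IR" else "NR",
                planted = plant, genomicStart = gStart,
                stringsAsFactors = FALSE)
        }
    })
    list(genome = genome, truth = do.call(rbind, rows))
}

# transcript-orientation region tag -> genomic window name, by strand
.genomicWindowName <- function(tag, minus) {
    if (!minus)
        switch(tag, "5p_exon" = "leftExon", "5p_intron" = "intronLeft",
               "3p_intron" = "intronRight", "3p_exon" = "rightExon")
    else
        switch(tag, "5p_exon" = "rightExon", "5p_intron" = "intronRight",
               "3p_intron" = "intronLeft", "3p_exon" = "leftExon")
}
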