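# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain loops over text records, grids,
# exhaustive enumeration) without calling the package's counting or
# fitting code paths.

# Exhaustive per-base / per-junction counter over a SAM text file.
# introns/exons are plain data.frames: introns(chrom, start, end, strand,
# gene), exons(chrom, start, end, gene); 1-based closed coordinates.
bruteForceCounter <- function(samPath, introns, exons) {
    lines <- readLines(samPath)
    reads <- lines[!grepl("^@", lines)]
    nI <- nrow(introns)
    depth <- lapply(seq_len(nI), function(i)
        integer(introns$end[i] - introns$start[i] + 1L))
    glLeft <- integer(nI); glRight <- integer(nI); SE <- integer(nI)
    total <- 0L
    for (r in reads) {
        f <- strsplit(r, "\t", fixed = TRUE)[[1L]]
        flag <- as.integer(f[2L])
        if (bitwAnd(flag, 0x4 + 0x100 + 0x400 + 0x800) != 0L) next
        total <- total + 1L
        chrom <- f[3L]; pos <- as.integer(f[4L]); cigar <- f[6L]
        ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
        refpos <- pos
        segs <- NULL; gaps <- NULL
        for (op in ops) {
            len <- as.integer(sub("[MIDNSHP=X]$", "", op))
            type <- sub("^\\d+", "", op)
            if (type %in% c("M", "=", "X")) {
                segs <- rbind(segs, c(refpos, refpos + len - 1L))
                refpos <- refpos + len
            } else if (type == "D") {
                refpos <- refpos + len
            } else if (type == "N") {
                gaps <- rbind(gaps, c(refpos, refpos + len - 1L))
                refpos <- refpos + len
            }  # I, S, H, P consume no reference
        }
        for (i in seq_len(nI)) {
            if (introns$chrom[i] != chrom) next
            s <- introns$start[i]; e <- introns$end[i]
            if (!is.null(segs)) for (k in seq_len(nrow(segs))) {
                a <- max(segs[k, 1L], s); b <- min(segs[k, 2L], e)
                if (a <= b)
                    depth[[i]][(a - s + 1L):(b - s + 1L)] <-
                        depth[[i]][(a - s + 1L):(b - s + 1L)] + 1L
            }
            if (!is.null(gaps)) for (k in seq_len(nrow(gaps))) {
                gs <- gaps[k, 1L]; ge <- gaps[k, 2L]
                if (gs == s && ge == e) SE[i] <- SE[i] + 1L
                inGeneExon <- function(p) any(
                    exons$chrom == chrom & exons$gene == introns$gene[i] &
                    exons$start <= p & exons$end >= p)
                if (gs == s && inGeneExon(ge + 1L))
                    glLeft[i] <- glLeft[i] + 1L
                if (ge == e && inGeneExon(gs - 1L))
                    glRight[i] <- glRight[i] + 1L
            }
        }
    }
    minus <- introns$strand == "-"
    list(depth = depth,
         ID = vapply(depth, function(d) stats::median(d), numeric(1)),
         coverage = vapply(depth, function(d) mean(d >= 1), numeric(1)),
         SL = ifelse(minus, glRight, glLeft),
         SR = ifelse(minus, glLeft, glRight),
         SE = SE, totalReads = total)
}

grToDf <- function(introns) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(introns)),
               start = BiocGenerics::start(introns),
               end = BiocGenerics::end(introns),
               strand = as.character(BiocGenerics::strand(introns)),
               gene = introns$gene_id, stringsAsFactors = FALSE)
}

exonsToDf <- function(exons) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(exons)),
               start = BiocGenerics::start(exons),
               end = BiocGenerics::end(exons),
               gene = exons$gene_id, stringsAsFactors = FALSE)
}

# Coarse-to-fine grid search MLE for the two-group beta regression,
# maximising the summed beta log density directly.
gridSearchBetaReg <- function(y, group, rounds = 5L) {
    ll <- function(b0, b1, lphi) {
        mu <- 1 / (1 + exp(-(b0 + b1 * group)))
        phi <- exp(lphi)
        sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
    }
    ctr <- c(0, 0, log(10))
    span <- c(4, 4, 3)
    best <- NULL
    for (r in seq_len(rounds)) {
        g0 <- seq(ctr[1L] - span[1L], ctr[1L] + span[1L], length.out = 17L)
        g1 <- seq(ctr[2L] - span[2L], ctr[2L] + span[2L], length.out = 17L)
        gp <- seq(ctr[3L] - span[3L], ctr[3L] + span[3L], length.out = 17L)
        bestVal <- -Inf
        for (a in g0) for (b in g1) for (p in gp) {
            v <- ll(a, b, p)
            if (is.finite(v) && v > bestVal) {
                bestVal <- v; best <- c(a, b, p)
            }
        }
        ctr <- best
        span <- span * (2 / 16)   # one grid step each side, refined
    }
    c(beta0 = best[1L], beta1 = best[2L], phi = exp(best[3L]),
      loglik = ll(best[1L], best[2L], best[3L]))
}

# Direct tail summation for the library-count test, in plain space with
# a generous cap.
directACTwoSided <- function(x, y, N1, N2) {
    r <- N2 / N1
    pmf <- function(k) exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) -
                           lgamma(k + 1) - (x + k + 1) * log(1 + r))
    cap <- ceiling(x + y + 20 * sqrt(x + y + 1) + 200)
    all <- pmf(0:cap)
    lower <- sum(all[seq_len(y + 1L)])
    upper <- sum(all[(y + 1L):(cap + 1L)])
    min(1, 2 * min(lower, upper))
}

# Exhaustive PWM score distribution over all 4^L windows, binned the
# same way as the package DP (per-position bins, then summed).
enumPWMDist <- function(pwm, binWidth = 0.01) {
    m <- motifMatrix(pwm); bg <- motifBackground(pwm)
    L <- nrow(m)
    slog <- log2(m / rep(bg, each = L))
    bins <- round(slog / binWidth)
    combos <- as.matrix(expand.grid(rep(list(1:4), L)))
    binSum <- integer(nrow(combos))
    logp <- numeric(nrow(combos))
    for (j in seq_len(L)) {
        binSum <- binSum + bins[j, combos[, j]]
        logp <- logp + log(bg[combos[, j]])
    }
    agg <- tapply(exp(logp), binSum, sum)
    data.frame(score = as.numeric(names(agg)) * binWidth,
               prob = as.numeric(agg))
}

# Exhaustive window scan with direct per-window scoring.
bruteForceScan <- function(seq, pwm, threshold) {
    m <- motifMatrix(pwm); bg <- motifBackground(pwm)
    L <- nrow(m)
    slog <- cbind(log2(m / rep(bg, each = L)), 0)  # 5th column for N
    chars <- strsplit(seq, "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T", "N"))
    n <- length(idx) - L + 1L
    if (n < 1L) return(0L)
    hits <- 0L
    for (s in seq_len(n)) {
        sc <- 0
        for (j in seq_len(L)) sc <- sc + slog[j, idx[s + j - 1L]]
        if (sc >= threshold) hits <- hits + 1L
    }
    hits
}
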