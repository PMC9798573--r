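#' Construct an RBPMotif with pseudocount regularisation
#'
#' Builds a position weight matrix object from raw per-position base
#' probabilities.  A pseudocount is added to every cell and rows are
#' renormalised, so all entries are strictly positive and log-odds scores
#' are finite.  Column order is A, C, G, T (U is treated as T).
#'
#' @param motifId motif identifier.
#' @param matrix L x 4 numeric matrix of probabilities (columns A, C, G,
#'   T/U); rows not summing to ~1 are renormalised with a warning.
#' @param rbpName RNA-binding protein name (optional).
#' @param background length-4 background probabilities; uniform by
#'   default.
#' @param pseudocount added to each cell before renormalisation.
#' @return an \code{\linkS4class{RBPMotif}}.
#' @export
rbpMotif <- function(motifId, matrix, rbpName = "",
                     background = rep(0.25, 4), pseudocount = 1e-3) {
    matrix <- as.matrix(matrix)
    if (ncol(matrix) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
    rs <- rowSums(matrix)
    if (any(abs(rs - 1) > 1e-3)) {
        warning("PWM '", motifId, "': rows not summing to 1 renormalised")
    }
    matrix <- matrix / rs
    matrix <- (matrix + pseudocount) / (1 + 4 * pseudocount)
    matrix <- matrix / rowSums(matrix)
    colnames(matrix) <- c("A", "C", "G", "T")
    rownames(matrix) <- NULL
    new("RBPMotif", motifId = as.character(motifId),
        rbpName = as.character(rbpName), matrix = matrix,
        background = background / sum(background),
        pseudocount = pseudocount)
}

#' Read PWM collections (MEME minimal or ATtRACT-style tab format)
#'
#' MEME minimal: a \code{MOTIF} line (id and optional alternate/RBP
#' name), a \code{letter-probability matrix:} line with \code{w=}, then
#' one row of four probabilities per position; a
#' \code{Background letter frequencies} block, when present, sets the
#' background for all motifs.  ATtRACT-style tab: a header line
#' \code{>motif_id<TAB>rbp_name} followed by one tab-separated row of
#' four probabilities (A, C, G, U/T) per position.
#'
#' @param path file path.
#' @param format \code{"meme"} or \code{"attract-tab"}.
#' @param pseudocount,background passed to \code{\link{rbpMotif}}.
#' @return named list of \code{\linkS4class{RBPMotif}} objects.
#' @export
readPWMs <- function(path, format = c("meme", "attract-tab"),
                     pseudocount = 1e-3, background = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("PWM file not found: ", path)
    lines <- readLines(path)
    out <- if (format == "meme")
        .readMeme(lines, pseudocount, background)
    else .readAttract(lines, pseudocount, background)
    if (!length(out)) stop("no motifs found in ", path)
    stats::setNames(out, vapply(out, motifId, character(1)))
}

.readMeme <- function(lines, pseudocount, background) {
    bg <- c(0.25, 0.25, 0.25, 0.25)
    bgLine <- grep("^Background letter frequencies", lines)
    if (length(bgLine)) {
        tok <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
        vals <- suppressWarnings(as.numeric(tok[c(FALSE, TRUE)]))
        names(vals) <- toupper(tok[c(TRUE, FALSE)])
        names(vals)[names(vals) == "U"] <- "T"
        if (all(c("A", "C", "G", "T") %in% names(vals)))
            bg <- unname(vals[c("A", "C", "G", "T")])
    }
    if (!is.null(background)) bg <- background
    motifStarts <- grep("^MOTIF\\b", lines)
    lapply(motifStarts, function(ms) {
        tok <- strsplit(trimws(lines[ms]), "\\s+")[[1L]]
        id <- tok[2L]
        rbp <- if (length(tok) >= 3L) tok[3L] else ""
        hdrRel <- grep("^letter-probability matrix:",
                       lines[seq(ms, length(lines))])[1L]
        if (is.na(hdrRel)) stop("MOTIF ", id, ": no probability matrix")
        hdr <- ms + hdrRel - 1L
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
        if (is.na(w)) stop("MOTIF ", id, ": cannot parse matrix width")
        rows <- lines[(hdr + 1L):(hdr + w)]
        m <- do.call(rbind, lapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4])))
        rbpMotif(id, m, rbpName = rbp, background = bg,
                 pseudocount = pseudocount)
    })
}

.readAttract <- function(lines, pseudocount, background) {
    bg <- if (is.null(background)) rep(0.25, 4) else background
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    if (!length(heads)) return(list())
    bounds <- c(heads, length(lines) + 1L)
    lapply(seq_along(heads), function(i) {
        tok <- strsplit(sub("^>", "", lines[heads[i]]), "\t")[[1L]]
        id <- trimws(tok[1L])
        rbp <- if (length(tok) >= 2L) trimws(tok[2L]) else ""
        rows <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
        m <- do.call(rbind, lapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "[\t ]+")[[1L]][1:4])))
        rbpMotif(id, m, rbpName = rbp, background = bg,
                 pseudocount = pseudocount)
    })
}

#' Write motifs in MEME minimal format
#'
#' @param pwms list of \code{\linkS4class{RBPMotif}} objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePWMsMeme <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
    bg <- motifBackground(pwms[[1L]])
    writeLines(c("Background letter frequencies",
                 sprintf("A %.6f C %.6f G %.6f T %.6f",
                         bg[1L], bg[2L], bg[3L], bg[4L]), ""), con)
    for (p in pwms) {
        m <- motifMatrix(p)
        writeLines(sprintf("MOTIF %s %s", motifId(p),
                           if (nzchar(rbpName(p))) rbpName(p) else motifId(p)),
                   con)
        writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                           nrow(m)), con)
        writeLines(apply(m, 1L, function(r)
            paste(sprintf("%.9f", r), collapse = " ")), con)
        writeLines("", con)
    }
    invisible(path)
}

.REGION_TAGS <- c("5p_exon", "5p_intron", "3p_intron", "3p_exon")

#' Extract splice-site flanking sequences in transcript orientation
#'
#' For every intron, four regions around its two splice sites: the last
#' \code{width} nt of the upstream (5') exon, the first \code{width} nt
#' of the intron, the last \code{width} nt of the intron, and the first
#' \code{width} nt of the downstream (3') exon — all in transcript
#' orientation.  On the minus strand the genomic windows are mirrored and
#' reverse-complemented, and the region tags swap accordingly.  Regions
#' shorter than \code{width} (short exons/introns, contig edges) are
#' truncated and flagged.
#'
#' @param genome a \code{\link[Biostrings]{DNAStringSet}} or FASTA path.
#' @param introns intron reference \code{GRanges}
#'   (\code{\link{buildIntronReference}}).
#' @param width region width in nt (default 50).
#' @return a \code{DataFrame} with columns \code{intron_id},
#'   \code{region} (one of \code{5p_exon}, \code{5p_intron},
#'   \code{3p_intron}, \code{3p_exon}), \code{seq}, \code{truncated}.
#' @export
#' @importFrom Biostrings DNAStringSet readDNAStringSet reverseComplement
#'   subseq
extractFlanks <- function(genome, introns, width = 50L) {
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    width <- as.integer(width)
    rows <- vector("list", length(introns) * 4L)
    k <- 0L
    for (i in seq_along(introns)) {
        chr <- as.character(seqnames(introns))[i]
        if (!chr %in% names(genome))
            stop("chromosome ", chr, " absent from the genome")
        chrLen <- Biostrings::width(genome[chr])
        s <- start(introns)[i]; e <- end(introns)[i]
        les <- introns$leftExonStart[i]; ree <- introns$rightExonEnd[i]
        minus <- as.character(strand(introns))[i] == "-"
        # genomic windows clipped to the flanking exon / intron / contig
        win <- list(
            leftExon = c(max(les, s - width, 1L), s - 1L),
            intronLeft = c(s, min(e, s + width - 1L)),
            intronRight = c(max(s, e - width + 1L), e),
            rightExon = c(e + 1L, min(ree, e + width, chrLen)))
        tags <- if (minus)
            c(leftExon = "3p_exon", intronLeft = "3p_intron",
              intronRight = "5p_intron", rightExon = "5p_exon")
        else c(leftExon = "5p_exon", intronLeft = "5p_intron",
               intronRight = "3p_intron", rightExon = "3p_exon")
        for (w in names(win)) {
            a <- win[[w]][1L]; b <- win[[w]][2L]
            sq <- if (b < a) "" else
                as.character(subseq(genome[[chr]], a, b))
            if (minus && nzchar(sq))
                sq <- as.character(reverseComplement(DNAStringSet(sq)))
            k <- k + 1L
            rows[[k]] <- data.frame(intron_id = introns$intron_id[i],
                                    region = tags[[w]], seq = sq,
                                    truncated = nchar(sq) < width,
                                    stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(intron_id = character(0), region = character(0),
                         seq = character(0), truncated = logical(0))
    DataFrame(df[order(match(df$region, .REGION_TAGS)), , drop = FALSE])
}

# per-position log2-odds lookup matrix, with an N column contributing 0
.scoreLookup <- function(pwm) {
    slog <- log2(motifMatrix(pwm) / rep(motifBackground(pwm),
                                        each = nrow(motifMatrix(pwm))))
    cbind(slog, N = 0)
}

.encodeSeq <- function(seq) {
    chars <- strsplit(toupper(seq), "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T", "N"))
    if (anyNA(idx))
        stop("sequence contains characters outside {A, C, G, T, N}: ",
             paste(unique(chars[is.na(idx)]), collapse = ", "))
    idx
}

#' Log2-odds PWM score of a single window
#'
#' Sum over positions of \code{log2(p(base at position) / background)};
#' N contributes 0.  The window length must equal the motif length.
#'
#' @param window nucleotide string of length \code{length(pwm)}.
#' @param pwm an \code{\linkS4class{RBPMotif}}.
#' @return the score in bits.
#' @export
pwmScore <- function(window, pwm) {
    idx <- .encodeSeq(window)
    if (length(idx) != length(pwm))
        stop("window length ", length(idx), " != motif length ", length(pwm))
    slog <- .scoreLookup(pwm)
    sum(slog[cbind(seq_along(idx), idx)])
}

#' Exact score distribution of a PWM under the background model
#'
#' Distribution of the log2-odds score of a random window drawn i.i.d.
#' from the motif's background, computed exactly by dynamic programming
#' over scores discretised to bins of \code{binWidth} bits (scores are
#' rounded to the nearest bin centre).  Total probability mass is 1 up to
#' numerical tolerance.
#'
#' @param pwm an \code{\linkS4class{RBPMotif}}.
#' @param binWidth score bin width in bits (default 0.01).
#' @param maxBins guard on the DP table size.
#' @return data.frame with columns \code{score} (bin centres) and
#'   \code{prob}.
#' @export
scoreDistribution <- function(pwm, binWidth = 0.01, maxBins = 2e7) {
    slog <- log2(motifMatrix(pwm) / rep(motifBackground(pwm),
                                        each = length(pwm)))
    bins <- round(slog / binWidth)
    lo <- sum(apply(bins, 1L, min)); hi <- sum(apply(bins, 1L, max))
    if (hi - lo + 1 > maxBins)
        stop("DP table would need ", hi - lo + 1,
             " bins; increase binWidth for a coarser discretisation")
    bg <- motifBackground(pwm)
    offset <- 1L - lo
    v <- numeric(hi - lo + 1L)
    v[0L + offset] <- 1
    curLo <- 0L; curHi <- 0L
    for (pos in seq_len(length(pwm))) {
        nv <- numeric(length(v))
        rng <- (curLo:curHi) + offset
        for (b in 1:4) {
            sh <- bins[pos, b]
            nv[rng + sh] <- nv[rng + sh] + bg[b] * v[rng]
        }
        curLo <- curLo + min(bins[pos, ]); curHi <- curHi + max(bins[pos, ])
        v <- nv
    }
    nz <- which(v > 0)
    data.frame(score = (nz - offset) * binWidth, prob = v[nz])
}

#' Calibrate a PWM score threshold at a target tail probability
#'
#' The smallest score \code{s} such that a random background window
#' scores \code{>= s} with probability at most \code{pTarget}, from the
#' exact discretised score distribution.  The returned value is the lower
#' edge of the qualifying bin on the raw score scale: since scores are
#' discretised per position, a window in the qualifying bin can have a
#' raw score up to \code{L * binWidth / 2} below the bin centre, and the
#' threshold is lowered by that amount so no qualifying window is missed
#' (conservative with respect to the discretisation).
#'
#' @inheritParams scoreDistribution
#' @param pTarget tail probability in (0, 1].
#' @return the score threshold in bits.
#' @export
scoreThreshold <- function(pwm, pTarget = 1e-4, binWidth = 0.01,
                           maxBins = 2e7) {
    if (pTarget <= 0 || pTarget > 1) stop("pTarget must lie in (0, 1]")
    d <- scoreDistribution(pwm, binWidth, maxBins)
    tail <- rev(cumsum(rev(d$prob)))
    ok <- which(tail <= pTarget + 1e-12)
    slack <- length(pwm) * binWidth / 2
    # no bin qualifies: place the threshold above the maximum raw score
    if (!length(ok)) return(max(d$score) + slack + binWidth)
    d$score[ok[1L]] - slack
}

#' Count PWM hits in a region (sense strand, step 1)
#'
#' Number of windows of the region whose log2-odds score is at least
#' \code{threshold}.  Only the given (transcript/sense) orientation is
#' scanned, since RBP motifs bind RNA.  Sequences shorter than the motif
#' yield 0.
#'
#' @param seq nucleotide string (a flank-region sequence).
#' @param pwm an \code{\linkS4class{RBPMotif}}.
#' @param threshold score threshold (\code{\link{scoreThreshold}}).
#' @return integer hit count.
#' @export
scanRegion <- function(seq, pwm, threshold) {
    L <- length(pwm)
    if (nchar(seq) < L) return(0L)
    idx <- .encodeSeq(seq)
    slog <- .scoreLookup(pwm)
    n <- length(idx) - L + 1L
    hits <- 0L
    posSeq <- seq_len(L)
    for (s in seq_len(n)) {
        sc <- sum(slog[cbind(posSeq, idx[s + posSeq - 1L])])
        if (sc >= threshold) hits <- hits + 1L
    }
    hits
}

#' Compare motif hit frequencies between intron classes
#'
#' Two-sample Student's t test (pooled variance, two-sided) on
#' per-sequence hit counts of a motif in the flank regions of
#' differentially retained (IR) versus non-retained (NR) introns.  When
#' both groups are constant and equal the result is t = 0, p = 1; when
#' both are constant but different, the difference is infinitely
#' significant relative to zero within-group variance and is reported as
#' p = 0 with the \code{degenerate} flag set.
#'
#' @param hitsIR,hitsNR per-sequence hit counts (>= 2 sequences each).
#' @param binary if TRUE, counts are reduced to presence/absence before
#'   testing (fraction of sequences with at least one hit).
#' @return list with \code{meanIR}, \code{meanNR}, \code{t}, \code{p},
#'   \code{degenerate}.
#' @export
regionEnrichment <- function(hitsIR, hitsNR, binary = FALSE) {
    if (length(hitsIR) < 2L || length(hitsNR) < 2L)
        stop("at least 2 sequences per group are required")
    if (binary) {
        hitsIR <- as.numeric(hitsIR > 0)
        hitsNR <- as.numeric(hitsNR > 0)
    }
    mIR <- mean(hitsIR); mNR <- mean(hitsNR)
    if (stats::var(hitsIR) == 0 && stats::var(hitsNR) == 0) {
        if (mIR == mNR)
            return(list(meanIR = mIR, meanNR = mNR, t = 0, p = 1,
                        degenerate = FALSE))
        return(list(meanIR = mIR, meanNR = mNR,
                    t = sign(mIR - mNR) * Inf, p = 0, degenerate = TRUE))
    }
    tt <- stats::t.test(hitsIR, hitsNR, var.equal = TRUE)
    list(meanIR = mIR, meanNR = mNR, t = unname(tt$statistic),
         p = tt$p.value, degenerate = FALSE)
}

#' Motif-by-region enrichment table
#'
#' Scans every motif against every flank region, splits introns into an
#' IR class (e.g. differentially retained) and the remainder, and runs
#' \code{\link{regionEnrichment}} per motif and region tag.  BH q values
#' are computed across all motif-region combinations.
#'
#' @param flanks flank-region \code{DataFrame}
#'   (\code{\link{extractFlanks}}).
#' @param irIntrons intron ids forming the IR class.
#' @param pwms list of \code{\linkS4class{RBPMotif}} objects.
#' @param pTarget tail probability for \code{\link{scoreThreshold}}.
#' @param binary passed to \code{\link{regionEnrichment}}.
#' @return a \code{DataFrame} with columns \code{motif_id}, \code{rbp},
#'   \code{region}, \code{mean_ir}, \code{mean_nr}, \code{t}, \code{p},
#'   \code{q}, \code{degenerate}.
#' @export
motifEnrichmentTable <- function(flanks, irIntrons, pwms, pTarget = 1e-4,
                                 binary = FALSE) {
    isIR <- flanks$intron_id %in% irIntrons
    rows <- list()
    for (p in pwms) {
        thr <- scoreThreshold(p, pTarget)
        for (tag in .REGION_TAGS) {
            sel <- flanks$region == tag
            seqsIR <- flanks$seq[sel & isIR]
            seqsNR <- flanks$seq[sel & !isIR]
            if (length(seqsIR) < 2L || length(seqsNR) < 2L) next
            hIR <- vapply(seqsIR, scanRegion, integer(1), pwm = p,
                          threshold = thr, USE.NAMES = FALSE)
            hNR <- vapply(seqsNR, scanRegion, integer(1), pwm = p,
                          threshold = thr, USE.NAMES = FALSE)
            e <- regionEnrichment(hIR, hNR, binary = binary)
            rows[[length(rows) + 1L]] <- data.frame(
                motif_id = motifId(p), rbp = rbpName(p), region = tag,
                mean_ir = e$meanIR, mean_nr = e$meanNR, t = e$t, p = e$p,
                degenerate = e$degenerate, stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) stop("no motif-region combination had enough sequences")
    df$q <- bhAdjust(df$p)
    DataFrame(df[c("motif_id", "rbp", "region", "mean_ir", "mean_nr",
                   "t", "p", "q", "degenerate")])
}
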