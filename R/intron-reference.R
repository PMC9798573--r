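#' Parse exon features from an Ensembl-style GTF file
#'
#' Reads a GTF annotation and returns its exon features as a
#' \code{\link[GenomicRanges]{GRanges}} (1-based closed coordinates, the
#' native GTF and Bioconductor convention) with metadata columns
#' \code{gene_id} and \code{transcript_id}.  Together these columns define
#' the gene models: one gene per \code{gene_id}, exons grouped by
#' transcript.
#'
#' @param path path to a GTF file (Ensembl dialect; \code{gene_id} and
#'   \code{transcript_id} attributes quoted).
#' @return a \code{GRanges} of exons with \code{gene_id} and
#'   \code{transcript_id} metadata columns; empty for an empty file.
#' @seealso \code{\link{buildIntronReference}}
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", c(1, 201), c(100, 300), ".",
#'                  "+", ".",
#'                  "gene_id \"g1\"; transcript_id \"t1\";", sep = "\t"),
#'            gtf)
#' parseGTF(gtf)
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
parseGTF <- function(path) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    idx <- which(keep)
    if (!length(idx))
        return(GRanges(gene_id = character(0), transcript_id = character(0)))
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9L))
        stop("GTF parse error at line ", idx[which(nf != 9L)[1L]],
             ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
    m <- do.call(rbind, fields)
    isExon <- m[, 3L] == "exon"
    if (!any(isExon))
        return(GRanges(gene_id = character(0), transcript_id = character(0)))
    m <- m[isExon, , drop = FALSE]
    exonLine <- idx[isExon]
    start <- suppressWarnings(as.integer(m[, 4L]))
    end <- suppressWarnings(as.integer(m[, 5L]))
    bad <- which(is.na(start) | is.na(end) | end < start)
    if (length(bad))
        stop("GTF parse error at line ", exonLine[bad[1L]],
             ": invalid start/end coordinates")
    if (!all(m[, 7L] %in% c("+", "-")))
        stop("GTF parse error at line ",
             exonLine[which(!m[, 7L] %in% c("+", "-"))[1L]],
             ": strand must be '+' or '-'")
    gene <- .gtfAttr(m[, 9L], "gene_id")
    tx <- .gtfAttr(m[, 9L], "transcript_id")
    if (anyNA(gene))
        stop("GTF parse error at line ", exonLine[which(is.na(gene))[1L]],
             ": exon record lacks a gene_id attribute")
    if (anyNA(tx))
        stop("GTF record error at line ", exonLine[which(is.na(tx))[1L]],
             ": exon record lacks a transcript_id attribute")
    GRanges(m[, 1L], IRanges(start, end), strand = m[, 7L],
            gene_id = gene, transcript_id = tx)
}

.gtfAttr <- function(attrs, key) {
    pat <- paste0(key, "\\s+\"([^\"]*)\"")
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- m > 0L
    out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
    out
}

#' Derive the measurable intron set from gene models
#'
#' For each gene, introns are the gaps between consecutive exons of each
#' transcript (union-consensus rule).  Introns contributed identically by
#' several transcripts are emitted once; when contributing transcripts
#' disagree on the flanking exons, the shortest flanks are recorded.
#' Introns overlapping any exon of their own gene (from any transcript)
#' are dropped, as are introns with identical coordinates in two different
#' genes, to avoid cross-gene read misassignment.
#'
#' @param exons a \code{GRanges} of exons as returned by
#'   \code{\link{parseGTF}}.
#' @return a sorted \code{GRanges} of introns with metadata columns
#'   \code{intron_id} (\code{chrom:start-end:strand:gene}, 0-based
#'   half-open coordinates as in BED), \code{gene_id}, and the flanking
#'   exon boundaries \code{leftExonStart}, \code{leftExonEnd},
#'   \code{rightExonStart}, \code{rightExonEnd} (1-based closed, genomic
#'   orientation: "left" is the lower-coordinate flank).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", c(1, 201), c(100, 300), ".",
#'                  "+", ".",
#'                  "gene_id \"g1\"; transcript_id \"t1\";", sep = "\t"),
#'            gtf)
#' buildIntronReference(parseGTF(gtf))
#' @export
#' @importFrom GenomicRanges GRanges seqnames strand findOverlaps
#' @importFrom BiocGenerics start end sort unlist
#' @importFrom S4Vectors queryHits subjectHits
buildIntronReference <- function(exons, mode = c("union-consensus")) {
    mode <- match.arg(mode)
    if (!length(exons)) return(.emptyIntronGRanges())
    df <- data.frame(chrom = as.character(seqnames(exons)),
                     start = start(exons), end = end(exons),
                     strand = as.character(strand(exons)),
                     gene = exons$gene_id, tx = exons$transcript_id,
                     stringsAsFactors = FALSE)
    recs <- list()
    for (g in unique(df$gene)) {
        gd <- df[df$gene == g, , drop = FALSE]
        if (length(unique(gd$chrom)) > 1L || length(unique(gd$strand)) > 1L)
            stop("gene ", g, ": exons span multiple chromosomes or strands")
        gi <- list()
        for (t in unique(gd$tx)) {
            td <- gd[gd$tx == t, , drop = FALSE]
            td <- td[order(td$start), , drop = FALSE]
            if (nrow(td) >= 2L &&
                any(td$start[-1L] <= td$end[-nrow(td)]))
                stop("gene ", g, " transcript ", t,
                     ": exons overlap within the transcript")
            if (nrow(td) < 2L) next
            k <- nrow(td) - 1L
            gi[[t]] <- data.frame(
                chrom = td$chrom[1L], strand = td$strand[1L], gene = g,
                start = td$end[seq_len(k)] + 1L,
                end = td$start[seq_len(k) + 1L] - 1L,
                leftExonStart = td$start[seq_len(k)],
                leftExonEnd = td$end[seq_len(k)],
                rightExonStart = td$start[seq_len(k) + 1L],
                rightExonEnd = td$end[seq_len(k) + 1L],
                stringsAsFactors = FALSE)
        }
        if (!length(gi)) next
        gi <- do.call(rbind, gi)
        # merge identical introns across transcripts; keep shortest flanks
        key <- paste(gi$start, gi$end)
        gi <- do.call(rbind, lapply(split(gi, key), function(x) {
            x$leftExonStart[1L] <- max(x$leftExonStart)
            x$rightExonEnd[1L] <- min(x$rightExonEnd)
            x[1L, , drop = FALSE]
        }))
        # drop introns overlapping any exon of the same gene
        ovl <- vapply(seq_len(nrow(gi)), function(i) {
            any(gd$start <= gi$end[i] & gd$end >= gi$start[i])
        }, logical(1))
        recs[[g]] <- gi[!ovl, , drop = FALSE]
    }
    if (!length(recs)) return(.emptyIntronGRanges())
    all <- do.call(rbind, recs)
    rownames(all) <- NULL
    # identical intron claimed by two genes -> ambiguous, drop all copies
    key <- paste(all$chrom, all$start, all$end)
    all <- all[!(key %in% key[duplicated(key)]), , drop = FALSE]
    if (!nrow(all)) return(.emptyIntronGRanges())
    gr <- GRanges(all$chrom, IRanges(all$start, all$end), strand = all$strand)
    mcols(gr) <- DataFrame(
        intron_id = sprintf("%s:%d-%d:%s:%s", all$chrom, all$start - 1L,
                            all$end, all$strand, all$gene),
        gene_id = all$gene,
        leftExonStart = all$leftExonStart, leftExonEnd = all$leftExonEnd,
        rightExonStart = all$rightExonStart, rightExonEnd = all$rightExonEnd)
    sort(gr, ignore.strand = TRUE)
}

.emptyIntronGRanges <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(intron_id = character(0), gene_id = character(0),
                           leftExonStart = integer(0), leftExonEnd = integer(0),
                           rightExonStart = integer(0), rightExonEnd = integer(0))
    gr
}

#' Write / read an intron reference as BED
#'
#' \code{writeIntronBed} serialises an intron reference to a BED6+2 file:
#' the six standard BED columns (0-based half-open interval, name =
#' \code{intron_id}, score = 0, strand) plus two extra columns holding the
#' outer flanking-exon boundaries (\code{leftExonStart - 1} and
#' \code{rightExonEnd}, BED scale) so that \code{readIntronBed} can
#' reconstruct the full record (the inner boundaries are implied:
#' the left exon ends where the intron starts and the right exon starts
#' where it ends).  BED-consuming tools ignore the extra columns.
#'
#' @param introns intron \code{GRanges} from
#'   \code{\link{buildIntronReference}}.
#' @param path output (input) file path.
#' @return \code{writeIntronBed}: the path, invisibly.
#'   \code{readIntronBed}: an intron \code{GRanges} identical to the one
#'   written.
#' @export
writeIntronBed <- function(introns, path) {
    if (!length(introns)) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d",
                     as.character(seqnames(introns)),
                     start(introns) - 1L, end(introns),
                     introns$intron_id, as.character(strand(introns)),
                     introns$leftExonStart - 1L, introns$rightExonEnd)
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeIntronBed
#' @export
readIntronBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(.emptyIntronGRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
        stop("BED parse error at line ", which(nf < 6L)[1L],
             ": fewer than 6 columns")
    m <- do.call(rbind, lapply(fields, `[`, seq_len(max(nf))))
    bedStart <- as.integer(m[, 2L]); bedEnd <- as.integer(m[, 3L])
    bad <- which(is.na(bedStart) | is.na(bedEnd) | bedEnd <= bedStart)
    if (length(bad))
        stop("BED parse error at line ", bad[1L],
             ": end must exceed start")
    gene <- vapply(strsplit(m[, 4L], ":", fixed = TRUE),
                   function(x) x[length(x)], character(1))
    hasFlank <- ncol(m) >= 8L && !anyNA(suppressWarnings(as.integer(m[, 7L])))
    gr <- GRanges(m[, 1L], IRanges(bedStart + 1L, bedEnd), strand = m[, 6L])
    mcols(gr) <- DataFrame(
        intron_id = m[, 4L], gene_id = gene,
        leftExonStart = if (hasFlank) as.integer(m[, 7L]) + 1L
                        else rep(NA_integer_, nrow(m)),
        leftExonEnd = bedStart,
        rightExonStart = bedEnd + 1L,
        rightExonEnd = if (hasFlank) as.integer(m[, 8L])
                       else rep(NA_integer_, nrow(m)))
    gr
}

#' Flanking and gene exons of an intron reference, as a GRanges
#'
#' Expands an intron reference into the set of exon intervals it records
#' (the left and right flanking exon of every intron), tagged by gene.
#' Used by \code{\link{collectAlignments}} to decide whether a junction
#' read's far end lands in an exon of the same gene.
#'
#' @param introns intron \code{GRanges}.
#' @return \code{GRanges} of unique exon intervals with a \code{gene_id}
#'   column.
#' @export
flankExons <- function(introns) {
    if (!length(introns)) {
        gr <- GRanges(); mcols(gr) <- DataFrame(gene_id = character(0))
        return(gr)
    }
    chrom <- rep(as.character(seqnames(introns)), 2L)
    st <- rep(as.character(strand(introns)), 2L)
    gene <- rep(introns$gene_id, 2L)
    s <- c(introns$leftExonStart, introns$rightExonStart)
    e <- c(introns$leftExonEnd, introns$rightExonEnd)
    gr <- GRanges(chrom, IRanges(s, e), strand = st, gene_id = gene)
    unique(gr)
}
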