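#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges IntegerList
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Assemble a GeneIndex from 1-based inclusive transcript/exon coordinates.
.makeGeneIndex <- function(name, chrom, strand, txStart, txEnd,
                           exonStarts, exonEnds) {
    if (!length(name)) {
        empty <- GRanges()
        mcols(empty)$txName <- character()
        tx <- empty
        mcols(tx)$exonStarts <- IntegerList()
        mcols(tx)$exonEnds <- IntegerList()
        ex <- GRanges()
        mcols(ex)$txName <- character()
        return(new("GeneIndex", transcripts = tx, exons = ex))
    }
    tx <- GRanges(chrom, IRanges(txStart, txEnd), strand = strand)
    mcols(tx)$txName <- name
    mcols(tx)$exonStarts <- IntegerList(exonStarts)
    mcols(tx)$exonEnds <- IntegerList(exonEnds)
    nex <- lengths(exonStarts)
    ex <- GRanges(rep(chrom, nex),
                  IRanges(unlist(exonStarts, use.names = FALSE),
                          unlist(exonEnds, use.names = FALSE)),
                  strand = rep(strand, nex))
    mcols(ex)$txName <- rep(name, nex)
    new("GeneIndex", transcripts = tx, exons = ex)
}

.splitIntList <- function(x) {
    lapply(strsplit(x, ",", fixed = TRUE), function(v)
        as.integer(v[nzchar(v)]))
}

#' Load a transcript/exon annotation
#'
#' Reads a refGene-style flat table (UCSC dialect: bin, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds, ...)
#' or BED12 into a \linkS4class{GeneIndex}. Source coordinates are 0-based
#' half-open and are converted to 1-based inclusive at load time; all later
#' interval arithmetic is 1-based inclusive. Rows whose exon count
#' disagrees with the exon list length are rejected with a warning.
#' Transcripts on unplaced contigs are retained.
#'
#' @param path annotation file path.
#' @param dialect \code{"refgene_flat"} or \code{"bed12"}.
#' @return a \linkS4class{GeneIndex}.
#' @export
loadGeneAnnotation <- function(path, dialect = c("refgene_flat", "bed12")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("annotation file not found: ", path)
    if (file.size(path) == 0L ||
        !length(readLines(path, n = 1L)))
        return(.makeGeneIndex(character(), character(), character(),
                              integer(), integer(), list(), list()))
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             data.table = FALSE, colClasses = "character")
    if (dialect == "refgene_flat") {
        if (ncol(tab) < 11L)
            stop("refGene table needs at least 11 columns; got ", ncol(tab))
        starts0 <- .splitIntList(tab[[10L]])
        ends0 <- .splitIntList(tab[[11L]])
        ec <- as.integer(tab[[9L]])
        ok <- lengths(starts0) == ec & lengths(ends0) == ec
        if (any(!ok))
            warning(sprintf(
                "rejected %d annotation row(s): exonCount != exon list length",
                sum(!ok)), call. = FALSE)
        name <- tab[[2L]][ok]; chrom <- tab[[3L]][ok]
        strand <- ifelse(tab[[4L]][ok] == "-", "-", "+")
        txStart <- as.integer(tab[[5L]][ok]) + 1L
        txEnd <- as.integer(tab[[6L]][ok])
        exonStarts <- lapply(starts0[ok], `+`, 1L)
        exonEnds <- ends0[ok]
    } else {
        if (ncol(tab) < 12L)
            stop("BED12 needs 12 columns; got ", ncol(tab))
        sizes <- .splitIntList(tab[[11L]])
        offs <- .splitIntList(tab[[12L]])
        bc <- as.integer(tab[[10L]])
        ok <- lengths(sizes) == bc & lengths(offs) == bc
        if (any(!ok))
            warning(sprintf(
                "rejected %d BED12 row(s): blockCount != block list length",
                sum(!ok)), call. = FALSE)
        name <- tab[[4L]][ok]; chrom <- tab[[1L]][ok]
        strand <- ifelse(tab[[6L]][ok] == "-", "-", "+")
        cs0 <- as.integer(tab[[2L]])[ok]
        txStart <- cs0 + 1L
        txEnd <- as.integer(tab[[3L]])[ok]
        exonStarts <- Map(function(c0, o) c0 + o + 1L, cs0, offs[ok])
        exonEnds <- Map(function(s1, sz) s1 + sz - 1L, exonStarts, sizes[ok])
    }
    .makeGeneIndex(name, chrom, strand, txStart, txEnd, exonStarts, exonEnds)
}

.queryHitsIn <- function(subject, chrom, start, end) {
    if (!length(subject) ||
        !(chrom %in% GenomeInfoDb::seqlevels(subject)))
        return(integer())
    q <- GRanges(chrom, IRanges(start, end))
    subjectHits(findOverlaps(q, subject, ignore.strand = TRUE))
}

#' Transcripts overlapping an interval
#'
#' Returns the transcripts whose span (introns included) intersects the
#' 1-based inclusive query, ordered by start then name. An unknown contig
#' yields an empty result, not an error.
#'
#' @param index a \linkS4class{GeneIndex}.
#' @param chrom,start,end query interval (1-based inclusive).
#' @return \code{GRanges} of transcript spans with \code{txName},
#'   \code{exonStarts}, \code{exonEnds} metadata.
#' @export
transcriptsOverlapping <- function(index, chrom, start, end) {
    hits <- .queryHitsIn(index@transcripts, chrom, start, end)
    out <- index@transcripts[hits]
    out[order(start(out), mcols(out)$txName)]
}

#' Does an interval overlap any exon?
#'
#' TRUE iff at least one exon intersects the query (1-based inclusive;
#' intervals abutting an exon without sharing a base do not overlap).
#' Transcript-span overlap alone is not sufficient.
#'
#' @inheritParams transcriptsOverlapping
#' @return a single logical.
#' @export
overlapsExon <- function(index, chrom, start, end) {
    length(.queryHitsIn(index@exons, chrom, start, end)) > 0L
}

## Batched strict-containment lookup: which transcripts have
## txStart < pos < txEnd, for many (chrom, pos) at once.
## Returns data.frame(query, txName, txStart, txEnd, strand) plus exon
## boundary lists for optional exon-restricted truncation.
.transcriptsContaining <- function(index, chrom, pos) {
    tx <- index@transcripts
    if (!length(tx) || !length(pos)) {
        out <- data.frame(query = integer(), txName = character(),
                          txStart = integer(), txEnd = integer(),
                          strand = character())
        out$exonStarts <- list()
        out$exonEnds <- list()
        return(out)
    }
    keep <- chrom %in% GenomeInfoDb::seqlevels(tx)
    q <- GRanges(chrom[keep], IRanges(pos[keep], pos[keep]))
    ov <- findOverlaps(q, tx, ignore.strand = TRUE)
    qi <- which(keep)[queryHits(ov)]
    ti <- subjectHits(ov)
    strict <- start(tx)[ti] < pos[qi] & pos[qi] < end(tx)[ti]
    qi <- qi[strict]; ti <- ti[strict]
    out <- data.frame(query = qi, txName = mcols(tx)$txName[ti],
                      txStart = start(tx)[ti], txEnd = end(tx)[ti],
                      strand = as.character(strand(tx))[ti],
                      stringsAsFactors = FALSE)
    out$exonStarts <- as.list(mcols(tx)$exonStarts[ti])
    out$exonEnds <- as.list(mcols(tx)$exonEnds[ti])
    out
}

## Batched exon-overlap test for many intervals.
.overlapsExonBatch <- function(index, chrom, start, end) {
    ex <- index@exons
    out <- logical(length(chrom))
    if (!length(ex) || !length(chrom)) return(out)
    keep <- chrom %in% GenomeInfoDb::seqlevels(ex)
    if (!any(keep)) return(out)
    q <- GRanges(chrom[keep], IRanges(start[keep], end[keep]))
    ov <- findOverlaps(q, ex, ignore.strand = TRUE)
    out[which(keep)[unique(queryHits(ov))]] <- TRUE
    out
}
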