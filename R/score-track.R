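#' Open a per-base pathogenicity score track
#'
#' A handle over a position-sorted tab-separated score file. Two dialects
#' are recognised automatically: CADD-style (Chrom, Pos, Ref, Alt,
#' RawScore, PHRED; the PHRED column is the score) and a minimal
#' chrom/pos/score 3-column layout; explicit column indices override
#' detection. The file must be bgzip-compressed with a tabix index alongside
#' unless \code{preload = TRUE}, in which case the whole (desk-scale) track
#' is held in memory as dense per-contig vectors, which serves repeated
#' queries much faster and yields identical results. Positions with several
#' rows (one per alternate allele) are reduced to one score per position,
#' by default the maximum across alleles.
#'
#' @param path score file path (bgzipped TSV; a plain TSV is accepted with
#'   \code{preload = TRUE}).
#' @param dialect \code{"auto"}, \code{"cadd"} or \code{"minimal"}.
#' @param columns named integer vector \code{c(chrom=, pos=, score=)}
#'   overriding the dialect.
#' @param preload hold the track in memory instead of querying tabix.
#' @param reduce multi-allele per-position reduction: \code{"max"} (default)
#'   or \code{"mean"}.
#' @return a \linkS4class{ScoreTrack}.
#' @export
scoreTrack <- function(path, dialect = c("auto", "cadd", "minimal"),
                       columns = NULL, preload = FALSE,
                       reduce = c("max", "mean")) {
    dialect <- match.arg(dialect)
    reduce <- match.arg(reduce)
    if (!file.exists(path)) stop("score track not found: ", path)
    if (is.null(columns)) {
        if (dialect == "auto") {
            con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "rt")
                   else file(path, "rt")
            head <- readLines(con, n = 50L)
            close(con)
            head <- head[!startsWith(head, "#")]
            if (!length(head))
                stop("cannot detect score-track dialect: no data rows")
            nc <- length(strsplit(head[1L], "\t", fixed = TRUE)[[1L]])
            dialect <- if (nc >= 6L) "cadd" else if (nc == 3L) "minimal"
                       else stop("cannot detect score-track dialect (",
                                 nc, " columns); pass 'columns'")
        }
        columns <- switch(dialect,
            cadd = c(chrom = 1L, pos = 2L, score = 6L),
            minimal = c(chrom = 1L, pos = 2L, score = 3L))
    }
    stopifnot(all(c("chrom", "pos", "score") %in% names(columns)))
    data <- new.env(parent = emptyenv())
    tbx <- NULL
    if (preload) {
        .preloadTrack(path, columns, reduce, data)
    } else {
        idx <- paste0(path, ".tbi")
        if (!file.exists(idx))
            stop("tabix index not found: ", idx,
                 " (create it with indexTabix, or use preload = TRUE)")
        tbx <- Rsamtools::TabixFile(path)
    }
    new("ScoreTrack", path = path, tabix = tbx,
        chromCol = as.integer(columns[["chrom"]]),
        posCol = as.integer(columns[["pos"]]),
        scoreCol = as.integer(columns[["score"]]),
        reduce = reduce, preloaded = isTRUE(preload), data = data)
}

.preloadTrack <- function(path, columns, reduce, data) {
    con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "rt")
           else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) return(invisible(data))
    cols <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
    dt <- data.table::data.table(
        chrom = cols[[columns[["chrom"]]]],
        pos = as.integer(cols[[columns[["pos"]]]]),
        score = as.numeric(cols[[columns[["score"]]]]))
    dt <- if (reduce == "max")
        dt[, list(score = max(score)), by = c("chrom", "pos")]
    else
        dt[, list(score = mean(score)), by = c("chrom", "pos")]
    for (ch in unique(dt$chrom)) {
        sub <- dt[dt$chrom == ch]
        v <- rep(NA_real_, max(sub$pos))
        v[sub$pos] <- sub$score
        assign(ch, v, envir = data)
    }
    invisible(data)
}

## Batched fetch: parallel chrom/start/end vectors -> list of
## list(pos=, score=) per query, ascending positions, multi-allele reduced.
.fetchScoresBatch <- function(track, chrom, start, end) {
    n <- length(chrom)
    empty <- list(pos = integer(), score = numeric())
    out <- rep(list(empty), n)
    if (!n) return(out)
    start <- pmax(as.integer(start), 1L)
    end <- as.integer(end)
    if (track@preloaded) {
        for (i in seq_len(n)) {
            v <- get0(chrom[i], envir = track@data, inherits = FALSE)
            if (is.null(v)) next
            s <- start[i]; e <- min(length(v), end[i])
            if (e < s) next
            seg <- v[s:e]
            keep <- which(!is.na(seg))
            if (length(keep))
                out[[i]] <- list(pos = s + keep - 1L, score = seg[keep])
        }
        return(out)
    }
    known <- chrom %in% Rsamtools::seqnamesTabix(track@tabix) & start <= end
    if (!any(known)) return(out)
    qi <- which(known)
    gr <- GRanges(chrom[qi], IRanges(start[qi], end[qi]))
    res <- Rsamtools::scanTabix(track@tabix, param = gr)
    lens <- lengths(res)
    all <- unlist(res, use.names = FALSE)
    if (!length(all)) return(out)
    cols <- data.table::tstrsplit(all, "\t", fixed = TRUE)
    dt <- data.table::data.table(
        q = rep(qi, lens),
        pos = as.integer(cols[[track@posCol]]),
        score = as.numeric(cols[[track@scoreCol]]))
    dt <- dt[dt$pos >= start[dt$q] & dt$pos <= end[dt$q]]
    if (!nrow(dt)) return(out)
    dt <- if (track@reduce == "max")
        dt[, list(score = max(score)), keyby = c("q", "pos")]
    else
        dt[, list(score = mean(score)), keyby = c("q", "pos")]
    for (grp in split(seq_len(nrow(dt)), dt$q)) {
        i <- dt$q[grp[1L]]
        out[[i]] <- list(pos = dt$pos[grp], score = dt$score[grp])
    }
    out
}

#' Fetch per-base scores for an interval
#'
#' Returns one row per track position inside the 1-based inclusive query,
#' in ascending position order, after multi-allele reduction. Positions
#' absent from the track are omitted (never imputed as zero: phred-like
#' tracks have no natural zero).
#'
#' @param track a \linkS4class{ScoreTrack}.
#' @param chrom,start,end query interval (1-based inclusive).
#' @return data.frame with columns \code{pos}, \code{score}.
#' @export
fetchScores <- function(track, chrom, start, end) {
    r <- .fetchScoresBatch(track, chrom, start, end)[[1L]]
    data.frame(pos = r$pos, score = r$score)
}
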