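## Interval selection rules, by SV type:
##   LEFT/RIGHT  breakpoint CIs            every type
##   SPAN        between most likely bnds  DEL, DUP, CNV
##   LTRUNC/RTRUNC transcript remainder    DEL, INV, MEI, INS
TRUNC_TYPES <- c("DEL", "INV", "MEI", "INS")
SPAN_TYPES <- c("DEL", "DUP", "CNV")
INTERVAL_LABELS <- c("LEFT", "RIGHT", "SPAN", "LTRUNC", "RTRUNC")

.emptyIntervalTable <- function() {
    data.frame(variant = integer(), label = character(),
               chrom = character(), start = integer(), end = integer(),
               transcript = character(), weights = I(list()),
               stringsAsFactors = FALSE)
}

## Clamp [start, end] (+ aligned weights) to [1, contig length].
.clampRow <- function(start, end, w, chrom, contigLengths) {
    lo <- 1L
    hi <- if (chrom %in% names(contigLengths))
        as.integer(contigLengths[[chrom]]) else NA_integer_
    s <- max(start, lo)
    e <- if (is.na(hi)) end else min(end, hi)
    if (!is.null(w) && (s != start || e != end)) {
        if (e < s) w <- numeric()
        else w <- w[(s - start + 1L):(e - start + 1L)]
        if (length(w) && sum(w) <= 0) w <- NULL
    }
    list(start = s, end = e, weights = w)
}

## One table of scoring intervals for a list of variants. Truncation lookups
## are batched through a single findOverlaps call. With exonRestricted,
## each truncation interval is clipped to the transcript's exonic bases
## (one sub-interval per downstream exon segment).
.intervalTable <- function(vars, index, useWeights = TRUE,
                           contigLengths = numeric(),
                           exonRestricted = FALSE) {
    if (!length(vars)) return(.emptyIntervalTable())
    rows <- vector("list", length(vars) * 4L)
    nr <- 0L
    push <- function(variant, label, chrom, start, end,
                     transcript = NA_character_, weights = NULL) {
        if (end < start) return()
        cl <- .clampRow(start, end, weights, chrom, contigLengths)
        if (cl$end < cl$start) return()
        nr <<- nr + 1L
        rows[[nr]] <<- list(variant = variant, label = label, chrom = chrom,
                            start = cl$start, end = cl$end,
                            transcript = transcript,
                            weights = list(cl$weights))
    }
    bndVar <- integer(); bndSide <- character()
    bndChrom <- character(); bndPos <- integer()
    for (i in seq_along(vars)) {
        v <- vars[[i]]
        l <- v@left
        lw <- if (useWeights && length(l@prob)) l@prob else NULL
        push(i, "LEFT", l@chrom, l@pos + l@ciLo, l@pos + l@ciHi,
             weights = lw)
        r <- v@right
        if (!is.null(r)) {
            rw <- if (useWeights && length(r@prob)) r@prob else NULL
            push(i, "RIGHT", r@chrom, r@pos + r@ciLo, r@pos + r@ciHi,
                 weights = rw)
        }
        if (v@svtype %in% SPAN_TYPES) {
            if (is.null(r) || l@pos > r@pos)
                stop(sprintf(
                    "record '%s': cannot form SPAN (left breakpoint after right)",
                    v@ids[1L]))
            push(i, "SPAN", l@chrom, l@pos, r@pos)
        }
        if (v@svtype %in% TRUNC_TYPES) {
            bndVar <- c(bndVar, i); bndSide <- c(bndSide, "L")
            bndChrom <- c(bndChrom, l@chrom); bndPos <- c(bndPos, l@pos)
            ## point-event insertions: the two breakends coincide and
            ## contribute a single truncation per transcript
            if (!is.null(r) && !(r@chrom == l@chrom && r@pos == l@pos)) {
                bndVar <- c(bndVar, i); bndSide <- c(bndSide, "R")
                bndChrom <- c(bndChrom, r@chrom); bndPos <- c(bndPos, r@pos)
            }
        }
    }
    if (length(bndVar) && !is.null(index)) {
        hits <- .transcriptsContaining(index, bndChrom, bndPos)
        if (nrow(hits)) {
            ord <- order(bndVar[hits$query],
                         match(bndSide[hits$query], c("L", "R")),
                         hits$txName)
            hits <- hits[ord, , drop = FALSE]
            for (k in seq_len(nrow(hits))) {
                q <- hits$query[k]
                pos <- bndPos[q]
                lab <- if (bndSide[q] == "L") "LTRUNC" else "RTRUNC"
                rng <- if (hits$strand[k] == "+") c(pos, hits$txEnd[k])
                       else c(hits$txStart[k], pos)
                if (!exonRestricted) {
                    push(bndVar[q], lab, bndChrom[q], rng[1L], rng[2L],
                         transcript = hits$txName[k])
                } else {
                    es <- pmax(hits$exonStarts[[k]], rng[1L])
                    ee <- pmin(hits$exonEnds[[k]], rng[2L])
                    ok <- es <= ee
                    for (j in which(ok))
                        push(bndVar[q], lab, bndChrom[q], es[j], ee[j],
                             transcript = hits$txName[k])
                }
            }
        }
    }
    rows <- rows[seq_len(nr)]
    out <- data.frame(
        variant = vapply(rows, `[[`, 0L, "variant"),
        label = vapply(rows, `[[`, "", "label"),
        chrom = vapply(rows, `[[`, "", "chrom"),
        start = vapply(rows, `[[`, 0L, "start"),
        end = vapply(rows, `[[`, 0L, "end"),
        transcript = vapply(rows, `[[`, "", "transcript"),
        stringsAsFactors = FALSE)
    out$weights <- I(lapply(rows, function(x) x$weights[[1L]]))
    ## per-variant label order: LEFT, RIGHT, SPAN, truncations (L before R,
    ## then by transcript) -- the push order above already guarantees it
    ## within each variant; sort by variant only (stable)
    out[order(out$variant), , drop = FALSE]
}

.intervalTableToGRanges <- function(tab) {
    if (!nrow(tab)) {
        gr <- GRanges()
        mcols(gr)$label <- character()
        mcols(gr)$transcript <- character()
        mcols(gr)$weights <- IRanges::NumericList()
        return(gr)
    }
    gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
    mcols(gr)$label <- tab$label
    mcols(gr)$transcript <- tab$transcript
    mcols(gr)$weights <- IRanges::NumericList(lapply(tab$weights,
        function(w) if (is.null(w)) numeric() else w))
    gr
}

#' Resolve the scoring intervals for a variant
#'
#' Applies the type-aware interval rules: a LEFT (and, when a right breakend
#' exists, RIGHT) interval covering each breakpoint confidence interval for
#' every variant type; a SPAN interval between the most likely breakpoints
#' for copy-number-changing types (DEL, DUP, CNV); and per-transcript
#' truncation intervals (LTRUNC/RTRUNC) for DEL, INV, MEI and INS variants
#' whose most likely breakpoint falls strictly inside a transcript span.
#' Breakpoint-probability weights are attached to CI intervals when present
#' and requested; SPAN and truncation intervals are never weighted. All
#' intervals are clamped to [1, contig length] when contig lengths are
#' known. Output order is deterministic: LEFT, RIGHT, SPAN, then truncations
#' (left breakend first, then by transcript name).
#'
#' @param sv a \linkS4class{StructuralVariant}.
#' @param index a \linkS4class{GeneIndex} (may be empty or NULL: no
#'   truncation intervals).
#' @param useWeights attach PRPOS/PREND weights to the CI intervals.
#' @param contigLengths named contig-length vector used for clamping.
#' @param exonRestrictedTruncation clip truncation intervals to the
#'   transcript's exonic bases (default: full downstream span).
#' @return \code{GRanges} with metadata columns \code{label},
#'   \code{transcript} (NA outside truncations) and \code{weights}
#'   (\code{NumericList}; empty when unweighted).
#' @export
resolveIntervals <- function(sv, index = NULL, useWeights = TRUE,
                             contigLengths = numeric(),
                             exonRestrictedTruncation = FALSE) {
    .intervalTableToGRanges(.intervalTable(list(sv), index, useWeights,
                                           contigLengths,
                                           exonRestrictedTruncation))
}

#' Resolve only the truncation intervals for a variant
#'
#' For each breakend of a DEL, INV, MEI or INS variant whose most likely
#' position lies strictly inside a transcript span, emits the portion of the
#' transcript downstream of the breakpoint in transcription order
#' (\code{[pos, txEnd]} on '+', \code{[txStart, pos]} on '-'), labelled
#' LTRUNC for the left breakend and RTRUNC for the right, one interval per
#' (breakend, transcript) pair. Other variant types yield no intervals.
#'
#' @inheritParams resolveIntervals
#' @return \code{GRanges} as in \code{\link{resolveIntervals}}.
#' @export
resolveTruncationIntervals <- function(sv, index,
                                       contigLengths = numeric(),
                                       exonRestrictedTruncation = FALSE) {
    tab <- .intervalTable(list(sv), index, FALSE, contigLengths,
                          exonRestrictedTruncation)
    .intervalTableToGRanges(tab[tab$label %in% c("LTRUNC", "RTRUNC"), ,
                                drop = FALSE])
}
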