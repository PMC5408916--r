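## (op, n, INFO key) triples for a configuration, in emission order
.opTable <- function(config) {
    ops <- list()
    for (op in config@operations) {
        if (op == "topn")
            for (n in config@topN)
                ops[[length(ops) + 1L]] <-
                    list(op = "topn", n = n, key = paste0("SVSCORETOP", n))
        else
            ops[[length(ops) + 1L]] <- list(op = op, n = NA_integer_,
                key = switch(op, max = "SVSCOREMAX", sum = "SVSCORESUM",
                             mean = "SVSCOREMEAN"))
    }
    ops
}

## Score many variants with one interval resolution and one batched fetch.
.scoreVariantsBatch <- function(vars, track, index, config,
                                contigLengths = numeric(),
                                exonRestricted = FALSE) {
    ops <- .opTable(config)
    tab <- .intervalTable(vars, index, config@useWeights, contigLengths,
                          exonRestricted)
    fetched <- .fetchScoresBatch(track, tab$chrom, tab$start, tab$end)
    nIv <- nrow(tab)
    scoreMat <- matrix(NA_real_, nrow = nIv, ncol = length(ops))
    for (i in seq_len(nIv)) {
        f <- fetched[[i]]
        if (!length(f$pos)) next
        w <- tab$weights[[i]]
        if (!is.null(w)) w <- w[f$pos - tab$start[i] + 1L]
        ctx <- sprintf("%s/%s", vars[[tab$variant[i]]]@ids[1L],
                       tab$label[i])
        for (k in seq_along(ops))
            scoreMat[i, k] <- aggregateScores(f$score, w, ops[[k]]$op,
                                              ops[[k]]$n, context = ctx)
    }
    keys <- vapply(ops, `[[`, "", "key")
    out <- vector("list", length(vars))
    rowsOf <- split(seq_len(nIv), factor(tab$variant,
                                         levels = seq_along(vars)))
    txClean <- ifelse(is.na(tab$transcript) | tab$transcript == "",
                      NA_character_, tab$transcript)
    for (v in seq_along(vars)) {
        rows <- rowsOf[[v]]
        nr <- length(rows)
        pi <- structure(list(
            op = rep(keys, each = nr),
            label = rep(tab$label[rows], length(ops)),
            transcript = rep(txClean[rows], length(ops)),
            score = as.vector(scoreMat[rows, , drop = FALSE])),
            class = "data.frame",
            row.names = if (nr) c(NA_integer_, -(nr * length(ops)))
                        else integer())
        anyScored <- nr > 0L &&
            any(!is.na(scoreMat[rows, , drop = FALSE]))
        perOp <- setNames(rep(NA_real_, length(keys)), keys)
        if (anyScored)
            for (k in seq_along(keys)) {
                sc <- scoreMat[rows, k]
                if (any(!is.na(sc))) perOp[k] <- max(sc, na.rm = TRUE)
            }
        out[[v]] <- S4Vectors::new2("VariantScoreSet",
                        variantIds = vars[[v]]@ids,
                        perOperation = perOp, perInterval = pi,
                        missing = !anyScored, check = FALSE)
    }
    out
}

#' Score one structural variant
#'
#' Resolves the variant's scoring intervals, fetches per-base scores for
#' each, applies every configured operation per interval, and reports the
#' maximum over interval scores as the variant's final score for each
#' operation. A variant with no scorable base in any interval is flagged
#' missing (serialised as the -1 sentinel in VCF output).
#'
#' @param sv a \linkS4class{StructuralVariant}.
#' @param track a \linkS4class{ScoreTrack}.
#' @param index a \linkS4class{GeneIndex} or NULL (no truncation scoring).
#' @param config an \linkS4class{AggregationConfig}.
#' @param contigLengths named contig-length vector for interval clamping.
#' @param exonRestrictedTruncation clip truncation intervals to exonic
#'   bases.
#' @return a \linkS4class{VariantScoreSet}.
#' @export
scoreVariant <- function(sv, track, index = NULL,
                         config = aggregationConfig(),
                         contigLengths = numeric(),
                         exonRestrictedTruncation = FALSE) {
    .scoreVariantsBatch(list(sv), track, index, config, contigLengths,
                        exonRestrictedTruncation)[[1L]]
}

#' Score a whole callset and annotate its VCF
#'
#' End-to-end composition: parse the VCF, pair BND mates, resolve intervals,
#' fetch and aggregate per-base scores, and (when \code{output} is given)
#' write the annotated VCF. Deterministic given identical inputs.
#'
#' @param vcf VCF path or an already parsed \linkS4class{SVCallset}.
#' @param track score-track path or a \linkS4class{ScoreTrack}.
#' @param annotation annotation path, \linkS4class{GeneIndex}, or NULL.
#' @param output annotated VCF path, or NULL to skip writing.
#' @param config an \linkS4class{AggregationConfig}.
#' @param afKey INFO key carrying the allele frequency.
#' @param annotationDialect passed to \code{\link{loadGeneAnnotation}}.
#' @param verboseIntervals emit the per-interval breakdown INFO key.
#' @param exonRestrictedTruncation clip truncation intervals to exonic
#'   bases.
#' @return invisibly, a list with \code{callset}, \code{scores} (list of
#'   \linkS4class{VariantScoreSet}) and \code{summary} (counts of records,
#'   variants, scored, missing, skipped).
#' @export
scoreCallset <- function(vcf, track, annotation = NULL, output = NULL,
                         config = aggregationConfig(), afKey = "AF",
                         annotationDialect = "refgene_flat",
                         verboseIntervals = FALSE,
                         exonRestrictedTruncation = FALSE) {
    callset <- if (is(vcf, "SVCallset")) vcf else parseSvVcf(vcf, afKey)
    callset <- pairBndMates(callset)
    if (is.character(track)) track <- scoreTrack(track)
    index <- if (is.null(annotation)) NULL
             else if (is(annotation, "GeneIndex")) annotation
             else loadGeneAnnotation(annotation, annotationDialect)
    scores <- .scoreVariantsBatch(callset@variants, track, index, config,
                                  callset@contigLengths,
                                  exonRestrictedTruncation)
    if (!is.null(output))
        writeAnnotatedVcf(callset, scores, output, config, verboseIntervals)
    nMissing <- sum(vapply(scores, isMissing, TRUE))
    summary <- list(
        n_records = length(callset@records),
        n_variants = length(callset@variants),
        n_scored = length(scores) - nMissing,
        n_missing = nMissing,
        n_skipped = length(callset@skipped))
    invisible(list(callset = callset, scores = scores, summary = summary))
}
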