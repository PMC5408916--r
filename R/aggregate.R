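#' Summarise an interval's per-base scores
#'
#' The supported operations over the scores of one interval are:
#' \describe{
#'   \item{max}{maximum score (weights ignored).}
#'   \item{sum}{sum of scores (weights ignored).}
#'   \item{mean}{weighted mean \eqn{\sum w_i s_i / \sum w_i}; uniform
#'     weights when none are given.}
#'   \item{topn}{restrict to the \code{n} highest-scoring bases (ties broken
#'     by ascending position), then take the weighted mean of that subset
#'     with its weights renormalised.}
#' }
#' An empty score vector yields \code{NA} (the missing marker). Scores are
#' expected in ascending position order, so tie-breaking by index equals
#' tie-breaking by genomic position.
#'
#' @param scores numeric per-base scores, ascending position order.
#' @param weights optional non-negative weights aligned 1:1 with
#'   \code{scores}, with positive sum.
#' @param op one of \code{"max"}, \code{"sum"}, \code{"mean"},
#'   \code{"topn"}.
#' @param n subset size for \code{"topn"}.
#' @param context label (variant/interval) used in error messages.
#' @return a single numeric score, or \code{NA} when no base was scorable.
#' @export
aggregateScores <- function(scores, weights = NULL,
                            op = c("max", "sum", "mean", "topn"),
                            n = NULL, context = "interval") {
    op <- match.arg(op)
    if (!length(scores)) return(NA_real_)
    if (!is.null(weights)) {
        if (length(weights) != length(scores))
            stop(context, ": weights not aligned with scores (",
                 length(weights), " vs ", length(scores), ")")
        if (any(weights < 0))
            stop(context, ": negative weight entry")
        if (sum(weights) <= 0)
            stop(context, ": weights sum to zero")
    }
    switch(op,
        max = max(scores),
        sum = sum(scores),
        mean = {
            if (is.null(weights)) mean(scores)
            else sum(weights * scores) / sum(weights)
        },
        topn = {
            if (is.null(n) || n < 1L)
                stop(context, ": topn requires a positive n")
            idx <- order(-scores, seq_along(scores))[
                seq_len(min(n, length(scores)))]
            if (is.null(weights)) mean(scores[idx])
            else {
                w <- weights[idx]
                if (sum(w) <= 0)
                    stop(context, ": top-", n,
                         " subset carries zero weight")
                sum(w * scores[idx]) / sum(w)
            }
        })
}
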