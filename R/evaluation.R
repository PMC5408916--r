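## Nearest-rank empirical quantile: the smallest element whose rank is
## >= ceil(p * n). Reproducible, estimator-free.
nearestRankQuantile <- function(x, p) {
    s <- sort(x)
    s[max(1L, ceiling(p * length(s)))]
}

#' Percentile-based pathogenicity classes
#'
#' Classifies impact scores into pathogenic (at or above the configured
#' pathogenic percentile, default 90th), benign (below the benign
#' percentile, default 50th) and intermediate (all others). Percentiles are
#' the nearest-rank empirical quantiles of the non-missing scores; ties at
#' the pathogenic boundary classify as pathogenic. \code{NA} entries are
#' classed unscored and excluded from the percentile computation.
#'
#' @param scores numeric scores; \code{NA} marks a missing score.
#' @param thresholds a \linkS4class{ClassThresholds}.
#' @return character vector over \code{pathogenic}, \code{intermediate},
#'   \code{benign}, \code{unscored}.
#' @export
classifyByScore <- function(scores, thresholds = classThresholds()) {
    usable <- !is.na(scores)
    if (sum(usable) < 10L)
        stop("fewer than 10 non-missing scores; percentiles are unstable")
    p90 <- nearestRankQuantile(scores[usable],
                               thresholds@pathogenicPercentile)
    p50 <- nearestRankQuantile(scores[usable], thresholds@benignPercentile)
    out <- rep("unscored", length(scores))
    out[usable & scores >= p90] <- "pathogenic"
    out[usable & scores < p90 & scores >= p50] <- "intermediate"
    out[usable & scores < p50] <- "benign"
    out
}

#' Allele-frequency classes
#'
#' @param af numeric allele frequencies; \code{NA} marks an absent AF.
#' @param thresholds a \linkS4class{ClassThresholds}: AF strictly below
#'   \code{rareAF} (default 0.01) is rare, at or above \code{commonAF}
#'   (default 0.05) is common.
#' @return character vector over \code{rare}, \code{intermediate_af},
#'   \code{common}, \code{missing}.
#' @export
classifyByAF <- function(af, thresholds = classThresholds()) {
    out <- rep("missing", length(af))
    usable <- !is.na(af)
    out[usable & af < thresholds@rareAF] <- "rare"
    out[usable & af >= thresholds@commonAF] <- "common"
    out[usable & af >= thresholds@rareAF & af < thresholds@commonAF] <-
        "intermediate_af"
    out
}

#' Rare-versus-common odds ratio with Fisher's exact test
#'
#' For the 2x2 table (rare/common x pathogenic/benign) computes the sample
#' odds ratio \eqn{(a d)/(b c)} with a = rare & pathogenic, b = common &
#' pathogenic, c = rare & benign, d = common & benign, the two-sided
#' Fisher's exact p-value, and a 95\% CI from the standard log-OR normal
#' approximation. Tables with a zero cell are computed with a 0.5 continuity
#' correction and flagged; a table with an entirely empty margin is an
#' error (the comparison is undefined).
#'
#' @param counts numeric of length 4 in the order rarePathogenic,
#'   commonPathogenic, rareBenign, commonBenign (names optional).
#' @return list with \code{or}, \code{p}, \code{ci95} (length 2),
#'   \code{corrected} (continuity-correction flag) and \code{counts}.
#' @importFrom stats fisher.test setNames qnorm quantile rgamma runif
#'   rbinom
#' @export
oddsRatio <- function(counts) {
    stopifnot(length(counts) == 4L, all(counts >= 0))
    a <- counts[[1L]]; b <- counts[[2L]]
    cc <- counts[[3L]]; d <- counts[[4L]]
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0)
        stop("a margin of the contingency table is entirely zero; ",
             "the rare-versus-common comparison is undefined")
    corrected <- any(c(a, b, cc, d) == 0)
    h <- if (corrected) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
    p <- stats::fisher.test(matrix(c(a, cc, b, d), nrow = 2L),
                            conf.int = FALSE)$p.value
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
    list(or = unname(or), p = p, ci95 = unname(ci), corrected = corrected,
         counts = stats::setNames(as.numeric(c(a, b, cc, d)),
             c("rarePathogenic", "commonPathogenic", "rareBenign",
               "commonBenign")))
}

#' Length-percentile classifier
#'
#' Alternative classifier using SV length alone: the same nearest-rank
#' percentile logic as \code{\link{classifyByScore}} applied to variant
#' lengths. Variants with undefined length (BND, unmated breakends) are
#' unscored.
#'
#' @param svs list of \linkS4class{StructuralVariant}.
#' @param thresholds a \linkS4class{ClassThresholds}.
#' @return character class vector as in \code{\link{classifyByScore}}.
#' @export
lengthClassifier <- function(svs, thresholds = classThresholds()) {
    lens <- vapply(svs, function(v)
        if (is.na(v@svLength)) NA_real_ else as.numeric(v@svLength), 0)
    classifyByScore(lens, thresholds)
}

#' Exon-overlap classifier
#'
#' Alternative binary classifier: a variant is pathogenic iff any of its
#' LEFT, RIGHT or SPAN intervals overlaps an annotated exon; all others are
#' benign. Truncation intervals are excluded from this test, and transcript
#' (intronic) overlap alone is not sufficient.
#'
#' @param svs list of \linkS4class{StructuralVariant}.
#' @param index a \linkS4class{GeneIndex}.
#' @param contigLengths named contig-length vector for interval clamping.
#' @return character vector over \code{pathogenic}, \code{benign}.
#' @export
exonOverlapClassifier <- function(svs, index, contigLengths = numeric()) {
    tab <- .intervalTable(svs, NULL, FALSE, contigLengths)
    tab <- tab[tab$label %in% c("LEFT", "RIGHT", "SPAN"), , drop = FALSE]
    hit <- .overlapsExonBatch(index, tab$chrom, tab$start, tab$end)
    out <- rep("benign", length(svs))
    out[unique(tab$variant[hit])] <- "pathogenic"
    out
}

#' Allele-frequency spectrum cross-tabulation
#'
#' Cross-tabulates score classes against AF classes (unscored / missing
#' entries dropped) and derives the 2x2 rare/common x pathogenic/benign
#' contingency table by discarding the intermediate rows and columns.
#'
#' @param scoreClass character vector from \code{\link{classifyByScore}} (or
#'   an alternative classifier).
#' @param afClass character vector from \code{\link{classifyByAF}}.
#' @return list with \code{spectrum} (3x3 table) and \code{contingency}
#'   (named length-4 vector as taken by \code{\link{oddsRatio}}).
#' @export
afSpectrum <- function(scoreClass, afClass) {
    stopifnot(length(scoreClass) == length(afClass))
    spectrum <- table(
        score = factor(scoreClass,
                       levels = c("pathogenic", "intermediate", "benign")),
        af = factor(afClass,
                    levels = c("rare", "intermediate_af", "common")))
    contingency <- c(
        rarePathogenic = spectrum["pathogenic", "rare"],
        commonPathogenic = spectrum["pathogenic", "common"],
        rareBenign = spectrum["benign", "rare"],
        commonBenign = spectrum["benign", "common"])
    list(spectrum = spectrum, contingency = contingency)
}

## INFO map for every record of a callset: list of named character vectors
.recordInfo <- function(callset) {
    lapply(callset@records, function(line) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        parseInfoString(f[8L])
    })
}

#' Evaluate a score-annotated VCF
#'
#' Reads the impact scores (one \code{SVSCORE*} INFO key) and allele
#' frequencies back from an annotated VCF, classifies variants by score
#' percentile and by AF, and computes the AF spectrum and the rare-vs-common
#' odds ratio with Fisher's exact test. Mated BND pairs are collapsed so
#' each variant is counted once. Records carrying the missing sentinel are
#' classed unscored.
#'
#' @param path annotated VCF path.
#' @param scoreKey INFO key to evaluate (default \code{"SVSCORETOP10"}, the
#'   weighted mean of the top 10 bases per interval).
#' @param afKey INFO key carrying the allele frequency.
#' @param thresholds a \linkS4class{ClassThresholds}.
#' @return list with \code{classes} (data.frame: id, svtype, score, af,
#'   scoreClass, afClass), \code{spectrum}, \code{contingency}, \code{or}
#'   (the \code{\link{oddsRatio}} result) and \code{summary} counts.
#' @export
evaluateScoredVcf <- function(path, scoreKey = "SVSCORETOP10",
                              afKey = "AF",
                              thresholds = classThresholds()) {
    callset <- pairBndMates(parseSvVcf(path, afKey))
    infos <- .recordInfo(callset)
    names(infos) <- callset@recordIds
    if (!any(vapply(infos, function(i) scoreKey %in% names(i), TRUE)))
        stop("no record carries the score key '", scoreKey,
             "'; annotate the VCF first")
    score <- vapply(callset@variants, function(v) {
        info <- infos[[v@ids[1L]]]
        val <- suppressWarnings(as.numeric(infoField(info, scoreKey)))
        if (is.na(val) || "SVSCORE_MISSING" %in% names(info) || val < 0)
            NA_real_ else val
    }, 0)
    af <- vapply(callset@variants, alleleFreq, 0)
    if (all(is.na(af)))
        stop("no record carries the allele-frequency key '", afKey, "'")
    scoreClass <- classifyByScore(score, thresholds)
    afClass <- classifyByAF(af, thresholds)
    spec <- afSpectrum(scoreClass, afClass)
    or <- oddsRatio(spec$contingency)
    data <- data.frame(
        id = vapply(callset@variants, function(v) v@ids[1L], ""),
        svtype = vapply(callset@variants, svType, ""),
        score = score, af = af, scoreClass = scoreClass,
        afClass = afClass, stringsAsFactors = FALSE)
    list(classes = data, spectrum = spec$spectrum,
         contingency = spec$contingency, or = or,
         summary = list(n_variants = length(callset@variants),
                        n_scored = sum(!is.na(score)),
                        n_with_af = sum(!is.na(af))))
}
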