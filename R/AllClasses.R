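#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Breakend with confidence interval
#'
#' One side of a structural-variant junction: the most likely breakpoint
#' position plus a confidence interval (CI) expressed as signed offsets, and
#' an optional per-base breakpoint probability vector aligned to the CI (as
#' emitted by SV callers such as LUMPY via \code{PRPOS}/\code{PREND}).
#'
#' @slot chrom contig name.
#' @slot pos 1-based most likely breakpoint position.
#' @slot ciLo signed offset (<= 0) of the CI start relative to \code{pos}.
#' @slot ciHi signed offset (>= 0) of the CI end relative to \code{pos}.
#' @slot prob optional numeric vector of breakpoint probabilities, one entry
#'   per base of the CI (length \code{ciHi - ciLo + 1}); length 0 when unset.
#'
#' @exportClass Breakend
setClass("Breakend",
    representation(chrom = "character", pos = "integer",
                   ciLo = "integer", ciHi = "integer", prob = "numeric"))

setValidity("Breakend", function(object) {
    msg <- character()
    if (length(object@chrom) != 1L || is.na(object@chrom))
        msg <- c(msg, "'chrom' must be a single contig name")
    if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
        msg <- c(msg, "'pos' must be a single 1-based position")
    if (object@ciLo > 0L || object@ciHi < 0L)
        msg <- c(msg, "CI offsets must satisfy ciLo <= 0 <= ciHi")
    if (length(object@prob)) {
        width <- object@ciHi - object@ciLo + 1L
        if (length(object@prob) != width)
            msg <- c(msg, sprintf(
                "probability vector length (%d) != CI width (%d)",
                length(object@prob), width))
        if (any(object@prob < 0) || sum(object@prob) <= 0)
            msg <- c(msg, "probabilities must be >= 0 with positive sum")
    }
    if (length(msg)) msg else TRUE
})

setClassUnion("BreakendOrNULL", c("Breakend", "NULL"))

#' Structural variant record
#'
#' A typed SV parsed from VCF: variant type, one or two breakends with their
#' confidence intervals, optional allele frequency and length. A merged BND
#' mate pair carries both original record identifiers so that both VCF lines
#' receive identical scores.
#'
#' @slot ids record identifier(s); two after BND mate merging.
#' @slot svtype one of DEL, DUP, CNV, INV, INS, MEI, BND.
#' @slot left left (or only) breakend.
#' @slot right right breakend, or \code{NULL} for an unmated BND.
#' @slot mateId identifier of the partner BND record (length 0 when absent).
#' @slot alleleFreq allele frequency in [0, 1] (length 0 when absent).
#' @slot svLength |END - POS| where defined; \code{NA} otherwise.
#'
#' @exportClass StructuralVariant
setClass("StructuralVariant",
    representation(ids = "character", svtype = "character",
                   left = "Breakend", right = "BreakendOrNULL",
                   mateId = "character", alleleFreq = "numeric",
                   svLength = "integer"))

SV_TYPES <- c("DEL", "DUP", "CNV", "INV", "INS", "MEI", "BND")

setValidity("StructuralVariant", function(object) {
    msg <- character()
    if (!length(object@ids))
        msg <- c(msg, "at least one record id required")
    if (!(object@svtype %in% SV_TYPES))
        msg <- c(msg, sprintf("unknown svtype '%s'", object@svtype))
    if (object@svtype %in% c("DEL", "DUP", "CNV", "INV") &&
        !is.null(object@right)) {
        if (object@left@chrom != object@right@chrom)
            msg <- c(msg, "intrachromosomal SV with breakends on two contigs")
        else if (object@left@pos > object@right@pos)
            msg <- c(msg, "left breakend after right breakend")
    }
    if (length(object@alleleFreq) &&
        (object@alleleFreq < 0 || object@alleleFreq > 1))
        msg <- c(msg, "allele frequency outside [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Parsed SV callset with round-trip payload
#'
#' Holds the typed variants together with the verbatim header and record
#' lines of the source VCF, so that annotation can write the input back
#' byte-identically apart from INFO additions.
#'
#' @slot variants list of \linkS4class{StructuralVariant}.
#' @slot header verbatim header lines (including the #CHROM line).
#' @slot records verbatim data lines.
#' @slot recordIds id of each data line (parallel to \code{records}).
#' @slot contigLengths named vector of contig lengths from ##contig headers.
#' @slot skipped ids of records retained unscored (unknown SVTYPE).
#'
#' @exportClass SVCallset
setClass("SVCallset",
    representation(variants = "list", header = "character",
                   records = "character", recordIds = "character",
                   contigLengths = "numeric", skipped = "character"))

setValidity("SVCallset", function(object) {
    if (length(object@records) != length(object@recordIds))
        return("one record id required per record line")
    TRUE
})

#' Transcript/exon interval index
#'
#' Per-contig interval index over transcript spans and exons, backed by
#' \link[GenomicRanges]{GRanges}, answering the overlap queries used for
#' truncation detection and coding/noncoding classification.
#'
#' @slot transcripts \code{GRanges} of transcript spans (1-based inclusive)
#'   with metadata columns \code{txName}, \code{exonStarts}, \code{exonEnds}
#'   (IntegerList) and strand set.
#' @slot exons \code{GRanges} of exons with metadata column \code{txName}.
#'
#' @exportClass GeneIndex
setClass("GeneIndex",
    representation(transcripts = "GRanges", exons = "GRanges"))

#' Random-access per-base score track
#'
#' Handle over a position-sorted tab-separated score file (CADD-style or a
#' minimal chrom/pos/score dialect), bgzip-compressed and tabix-indexed.
#' Queries yield one score per covered position after reducing multi-allelic
#' rows; positions absent from the track are omitted. An optional preloaded
#' in-memory representation serves repeated desk-scale queries.
#'
#' @slot path path of the bgzipped score file.
#' @slot tabix \link[Rsamtools]{TabixFile} handle (or NULL when preloaded).
#' @slot chromCol,posCol,scoreCol 1-based column indices.
#' @slot reduce multi-allele per-position reduction policy (\code{"max"}).
#' @slot preloaded whether the track is held in memory.
#' @slot data environment mapping contig -> dense score vector (preloaded).
#'
#' @exportClass ScoreTrack
setClass("ScoreTrack",
    representation(path = "character", tabix = "ANY",
                   chromCol = "integer", posCol = "integer",
                   scoreCol = "integer", reduce = "character",
                   preloaded = "logical", data = "environment"))

#' Aggregation configuration
#'
#' Which summary operations to apply to each interval's per-base scores, the
#' N values for the top-N mean, whether breakpoint-probability weights are
#' used inside CIs, and the serialisation precision for INFO values.
#'
#' @slot operations subset of \code{c("max", "sum", "mean", "topn")}.
#' @slot topN positive integers for the top-N mean (default 10 and 100).
#' @slot useWeights use \code{PRPOS}/\code{PREND} weights inside CIs.
#' @slot digits decimal places used when serialising scores to INFO.
#'
#' @exportClass AggregationConfig
setClass("AggregationConfig",
    representation(operations = "character", topN = "integer",
                   useWeights = "logical", digits = "integer"))

AGG_OPS <- c("max", "sum", "mean", "topn")

setValidity("AggregationConfig", function(object) {
    msg <- character()
    if (!length(object@operations) ||
        !all(object@operations %in% AGG_OPS))
        msg <- c(msg, sprintf("operations must be a subset of {%s}",
                              paste(AGG_OPS, collapse = ", ")))
    if ("topn" %in% object@operations &&
        (!length(object@topN) || any(object@topN < 1L)))
        msg <- c(msg, "topN must be non-empty positive integers")
    if (length(msg)) msg else TRUE
})

#' Per-variant impact scores
#'
#' Final score per operation plus the per-interval breakdown for one
#' variant. The final score for an operation is the maximum over that
#' operation's interval scores; when no interval contains a scorable base
#' the variant is flagged missing and serialised with the -1 sentinel.
#'
#' @slot variantIds the record id(s) the scores apply to.
#' @slot perOperation named numeric, INFO key -> final score.
#' @slot perInterval data.frame with columns \code{op}, \code{label},
#'   \code{transcript}, \code{score} (NA when the interval had no scorable
#'   base).
#' @slot missing TRUE when no scorable base existed in any interval.
#'
#' @exportClass VariantScoreSet
setClass("VariantScoreSet",
    representation(variantIds = "character", perOperation = "numeric",
                   perInterval = "data.frame", missing = "logical"))

setValidity("VariantScoreSet", function(object) {
    msg <- character()
    if (!object@missing && length(object@perOperation)) {
        pi <- object@perInterval
        for (key in names(object@perOperation)) {
            sc <- pi$score[pi$op == key]
            if (any(!is.na(sc)) &&
                abs(object@perOperation[[key]] - max(sc, na.rm = TRUE)) >
                    1e-9 * max(1, abs(object@perOperation[[key]])))
                msg <- c(msg, sprintf(
                    "final %s score is not the max over its intervals", key))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Classification thresholds
#'
#' Percentile cutoffs defining the pathogenic/benign score (or length)
#' classes and the allele-frequency cutoffs defining rare/common.
#'
#' @slot pathogenicPercentile scores at or above this empirical percentile
#'   are pathogenic (default 0.90).
#' @slot benignPercentile scores below this percentile are benign (0.50).
#' @slot rareAF variants with AF strictly below this are rare (0.01).
#' @slot commonAF variants with AF at or above this are common (0.05).
#'
#' @exportClass ClassThresholds
setClass("ClassThresholds",
    representation(pathogenicPercentile = "numeric",
                   benignPercentile = "numeric",
                   rareAF = "numeric", commonAF = "numeric"))

setValidity("ClassThresholds", function(object) {
    ok <- object@benignPercentile > 0 &&
        object@benignPercentile < object@pathogenicPercentile &&
        object@pathogenicPercentile < 1 &&
        object@rareAF > 0 && object@rareAF <= object@commonAF &&
        object@commonAF < 1
    if (ok) TRUE else
        "need 0 < benign < pathogenic < 1 and 0 < rareAF <= commonAF < 1"
})
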