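#' Construct a Breakend
#'
#' @param chrom contig name.
#' @param pos 1-based most likely breakpoint position.
#' @param ciLo,ciHi signed CI offsets relative to \code{pos}
#'   (\code{ciLo <= 0 <= ciHi}); default 0,0 is a point breakpoint.
#' @param prob optional per-base breakpoint probability vector of length
#'   \code{ciHi - ciLo + 1}.
#' @return a \linkS4class{Breakend}.
#' @export
breakend <- function(chrom, pos, ciLo = 0L, ciHi = 0L, prob = numeric()) {
    new("Breakend", chrom = as.character(chrom), pos = as.integer(pos),
        ciLo = as.integer(ciLo), ciHi = as.integer(ciHi),
        prob = as.numeric(prob))
}

#' Construct a StructuralVariant
#'
#' @param ids record identifier(s).
#' @param svtype one of DEL, DUP, CNV, INV, INS, MEI, BND.
#' @param left,right breakends (\code{right} may be NULL for unmated BND).
#' @param mateId partner BND record id, if any.
#' @param alleleFreq allele frequency in [0, 1], if known.
#' @param svLength variant length in bp, if defined.
#' @return a \linkS4class{StructuralVariant}.
#' @export
structuralVariant <- function(ids, svtype, left, right = NULL,
                              mateId = character(), alleleFreq = numeric(),
                              svLength = NA_integer_) {
    new("StructuralVariant", ids = as.character(ids), svtype = svtype,
        left = left, right = right, mateId = as.character(mateId),
        alleleFreq = as.numeric(alleleFreq),
        svLength = as.integer(svLength))
}

#' @rdname structuralVariant
#' @param x a \code{StructuralVariant}.
#' @export
svId <- function(x) x@ids

#' @rdname structuralVariant
#' @export
svType <- function(x) x@svtype

#' @rdname structuralVariant
#' @export
svLength <- function(x) x@svLength

#' @rdname structuralVariant
#' @export
alleleFreq <- function(x) if (length(x@alleleFreq)) x@alleleFreq else NA_real_

#' @rdname structuralVariant
#' @export
leftBreakend <- function(x) x@left

#' @rdname structuralVariant
#' @export
rightBreakend <- function(x) x@right

#' Accessors for SVCallset
#'
#' @param x an \linkS4class{SVCallset}.
#' @return \code{variants()} the list of \linkS4class{StructuralVariant};
#'   \code{contigLengths()} the named contig-length vector.
#' @export
variants <- function(x) x@variants

#' @rdname variants
#' @export
contigLengths <- function(x) x@contigLengths

#' Accessors for VariantScoreSet
#'
#' @param x a \linkS4class{VariantScoreSet}.
#' @return \code{variantIds()} the record ids; \code{perOperation()} the
#'   named final-score vector; \code{perInterval()} the per-interval
#'   breakdown data.frame; \code{isMissing()} the missing flag.
#' @export
variantIds <- function(x) x@variantIds

#' @rdname variantIds
#' @export
perOperation <- function(x) x@perOperation

#' @rdname variantIds
#' @export
perInterval <- function(x) x@perInterval

#' @rdname variantIds
#' @export
isMissing <- function(x) x@missing

#' Aggregation configuration
#'
#' @param operations summary operations to compute; any of \code{"max"},
#'   \code{"sum"}, \code{"mean"}, \code{"topn"}.
#' @param topN the N values for the top-N mean (one INFO key per value).
#' @param useWeights apply breakpoint-probability weights inside CIs when
#'   the callset provides PRPOS/PREND.
#' @param digits decimal places for INFO serialisation.
#' @return an \linkS4class{AggregationConfig}.
#' @export
aggregationConfig <- function(operations = c("max", "sum", "mean", "topn"),
                              topN = c(10L, 100L), useWeights = TRUE,
                              digits = 1L) {
    new("AggregationConfig", operations = match.arg(operations, AGG_OPS,
                                                    several.ok = TRUE),
        topN = as.integer(topN), useWeights = isTRUE(useWeights),
        digits = as.integer(digits))
}

#' Classification thresholds
#'
#' @param pathogenicPercentile scores at/above this percentile are
#'   pathogenic.
#' @param benignPercentile scores below this percentile are benign.
#' @param rareAF AF strictly below this is rare.
#' @param commonAF AF at/above this is common.
#' @return a \linkS4class{ClassThresholds}.
#' @export
classThresholds <- function(pathogenicPercentile = 0.90,
                            benignPercentile = 0.50,
                            rareAF = 0.01, commonAF = 0.05) {
    new("ClassThresholds", pathogenicPercentile = pathogenicPercentile,
        benignPercentile = benignPercentile, rareAF = rareAF,
        commonAF = commonAF)
}

## INFO keys emitted per operation, in emission order
infoKeysFor <- function(config) {
    keys <- character()
    for (op in config@operations) {
        keys <- c(keys, switch(op,
            max = "SVSCOREMAX", sum = "SVSCORESUM", mean = "SVSCOREMEAN",
            topn = paste0("SVSCORETOP", config@topN)))
    }
    keys
}

setMethod("show", "Breakend", function(object) {
    cat(sprintf("Breakend %s:%d CI [%+d, %+d]%s\n", object@chrom,
                object@pos, object@ciLo, object@ciHi,
                if (length(object@prob)) " (weighted)" else ""))
})

setMethod("show", "StructuralVariant", function(object) {
    r <- if (is.null(object@right)) "unmated"
         else sprintf("%s:%d", object@right@chrom, object@right@pos)
    cat(sprintf("StructuralVariant %s [%s] %s:%d -- %s  AF=%s len=%s\n",
                paste(object@ids, collapse = "/"), object@svtype,
                object@left@chrom, object@left@pos, r,
                if (length(object@alleleFreq))
                    format(object@alleleFreq) else "NA",
                ifelse(is.na(object@svLength), "NA", object@svLength)))
})

setMethod("show", "SVCallset", function(object) {
    cat(sprintf(paste0("SVCallset: %d variants (%d records, %d retained",
                       " unscored), %d contigs\n"),
                length(object@variants), length(object@records),
                length(object@skipped), length(object@contigLengths)))
})

setMethod("show", "GeneIndex", function(object) {
    cat(sprintf("GeneIndex: %d transcripts, %d exons\n",
                length(object@transcripts), length(object@exons)))
})

setMethod("show", "ScoreTrack", function(object) {
    cat(sprintf("ScoreTrack: %s (%s)\n", object@path,
                if (object@preloaded) "preloaded" else "tabix"))
})

setMethod("show", "VariantScoreSet", function(object) {
    cat(sprintf("VariantScoreSet %s: %s\n",
                paste(object@variantIds, collapse = "/"),
                if (object@missing) "missing" else
                paste(names(object@perOperation),
                      format(object@perOperation), sep = "=",
                      collapse = " ")))
})
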