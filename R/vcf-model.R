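## Line-level VCF handling. The writer must reproduce every non-INFO byte of
## the input, so records are kept verbatim and INFO is edited as text.

readVcfLines <- function(path) {
    con <- if (grepl("\\.(gz|bgz)$", path)) gzfile(path, "rt")
           else file(path, "rt")
    on.exit(close(con))
    readLines(con)
}

## INFO string -> named character vector (flags get "")
parseInfoString <- function(info) {
    if (info == "." || info == "") return(structure(character(),
                                                    names = character()))
    parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
    eq <- regexpr("=", parts, fixed = TRUE)
    keys <- ifelse(eq > 0L, substr(parts, 1L, eq - 1L), parts)
    vals <- ifelse(eq > 0L, substr(parts, eq + 1L, nchar(parts)), "")
    names(vals) <- keys
    vals
}

infoField <- function(info, key) {
    if (key %in% names(info)) info[[key]] else NA_character_
}

## Fast constructors for the parser hot path: the parser validates fields
## inline (with record context in messages), so slot validity is skipped.
## Prototype objects are copied and slot-patched, which avoids the S4
## initialize/validity machinery per record.
.proto <- new.env(parent = emptyenv())

.newBreakend <- function(chrom, pos, ciLo = 0L, ciHi = 0L,
                         prob = numeric()) {
    x <- .proto$breakend
    if (is.null(x))
        x <- .proto$breakend <- new("Breakend", chrom = "N", pos = 1L,
                                    ciLo = 0L, ciHi = 0L, prob = numeric())
    x@chrom <- chrom; x@pos <- pos
    x@ciLo <- ciLo; x@ciHi <- ciHi
    x@prob <- prob
    x
}

.newSV <- function(ids, svtype, left, right = NULL, mateId = character(),
                   alleleFreq = numeric(), svLength = NA_integer_) {
    x <- .proto$sv
    if (is.null(x))
        x <- .proto$sv <- new("StructuralVariant", ids = "proto",
                              svtype = "DEL", left = .newBreakend("N", 1L),
                              right = NULL)
    x@ids <- ids; x@svtype <- svtype
    x@left <- left; x@right <- right
    x@mateId <- mateId
    x@alleleFreq <- alleleFreq
    x@svLength <- svLength
    x
}

.parseCI <- function(value) {
    if (is.na(value)) return(c(0L, 0L))
    v <- suppressWarnings(as.integer(strsplit(value, ",", fixed = TRUE)[[1L]]))
    if (length(v) != 2L || anyNA(v))
        stop("malformed confidence interval '", value, "'")
    v
}

.parseProb <- function(value, ciLo, ciHi, id, key) {
    if (is.na(value)) return(numeric())
    p <- suppressWarnings(as.numeric(strsplit(value, ",",
                                              fixed = TRUE)[[1L]]))
    width <- ciHi - ciLo + 1L
    if (anyNA(p) || length(p) != width)
        stop(sprintf("record '%s': %s has %d entries but the CI spans %d bases",
                     id, key, length(p), width))
    p
}

symbolicSvtype <- function(alt) {
    m <- regmatches(alt, regexec("^<([A-Za-z]+)(:[^>]*)?>$", alt))[[1L]]
    if (length(m)) toupper(m[2L]) else NA_character_
}

isBndAlt <- function(alt) grepl("\\[|\\]", alt)

#' Parse structural variants from a VCF
#'
#' Reads an SV callset in VCF (plain or gzipped) into typed
#' \linkS4class{StructuralVariant} records. \code{SVTYPE} in INFO takes
#' precedence over a symbolic ALT; BND records keep their \code{MATEID} for
#' later pairing with \code{\link{pairBndMates}}. Absent \code{CIPOS}/
#' \code{CIEND} default to a point breakpoint (0,0); \code{PRPOS}/
#' \code{PREND} probability vectors must match their CI width. \code{END}
#' (or a \code{SVLEN} fallback) populates the right breakend and the variant
#' length. Records with an unknown \code{SVTYPE} are skipped with a warning
#' and retained unscored in any written output. Multi-allelic records are
#' rejected; split them beforehand.
#'
#' @param path VCF file path.
#' @param afKey INFO key carrying the allele frequency (default "AF").
#' @return an \linkS4class{SVCallset}.
#' @export
parseSvVcf <- function(path, afKey = "AF") {
    lines <- readVcfLines(path)
    isHeader <- startsWith(lines, "#")
    if (any(!isHeader & seq_along(lines) < match(FALSE, isHeader)))
        stop("malformed VCF: header lines after data lines")
    header <- lines[isHeader]
    records <- lines[!isHeader]
    records <- records[nzchar(records)]

    ctg <- regmatches(header,
        regexec("^##contig=<ID=([^,>]+),.*length=([0-9]+)", header))
    ctg <- ctg[lengths(ctg) == 3L]
    contigLengths <- if (length(ctg))
        structure(as.numeric(vapply(ctg, `[`, "", 3L)),
                  names = vapply(ctg, `[`, "", 2L)) else numeric()

    vars <- vector("list", length(records))
    ids <- character(length(records))
    skipped <- character()
    for (i in seq_along(records)) {
        f <- strsplit(records[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 8L)
            stop(sprintf("record %d has %d fields; VCF needs at least 8",
                         i, length(f)))
        id <- if (f[3L] == ".") sprintf("rec%d", i) else f[3L]
        ids[i] <- id
        alt <- f[5L]
        if (grepl(",", alt, fixed = TRUE))
            stop(sprintf(paste0("record '%s' is multi-allelic; split it ",
                                "into one ALT per line before scoring"), id))
        info <- parseInfoString(f[8L])
        svtype <- infoField(info, "SVTYPE")
        if (is.na(svtype)) {
            svtype <- symbolicSvtype(alt)
            if (is.na(svtype) && isBndAlt(alt)) svtype <- "BND"
        }
        if (is.na(svtype) || !(svtype %in% SV_TYPES)) {
            warning(sprintf(
                "record '%s': unknown SVTYPE '%s'; retained unscored",
                id, if (is.na(svtype)) "." else svtype), call. = FALSE)
            skipped <- c(skipped, id)
            next
        }
        chrom <- f[1L]
        pos <- as.integer(f[2L])
        cipos <- .parseCI(infoField(info, "CIPOS"))
        if (cipos[1L] > 0L || cipos[2L] < 0L)
            stop(sprintf("record '%s': CIPOS offsets must straddle 0", id))
        prpos <- .parseProb(infoField(info, "PRPOS"), cipos[1L], cipos[2L],
                            id, "PRPOS")
        left <- .newBreakend(chrom, pos, cipos[1L], cipos[2L], prpos)

        endv <- suppressWarnings(as.integer(infoField(info, "END")))
        svlen <- suppressWarnings(as.integer(infoField(info, "SVLEN")))
        af <- suppressWarnings(as.numeric(infoField(info, afKey)))
        if (!is.na(af) && (af < 0 || af > 1))
            stop(sprintf("record '%s': allele frequency %s outside [0, 1]",
                         id, af))
        af <- if (is.na(af)) numeric() else af

        if (svtype == "BND") {
            mate <- infoField(info, "MATEID")
            vars[[i]] <- .newSV(id, "BND", left,
                mateId = if (is.na(mate)) character() else mate,
                alleleFreq = af)
            next
        }
        ciend <- .parseCI(infoField(info, "CIEND"))
        if (ciend[1L] > 0L || ciend[2L] < 0L)
            stop(sprintf("record '%s': CIEND offsets must straddle 0", id))
        prend <- .parseProb(infoField(info, "PREND"), ciend[1L], ciend[2L],
                            id, "PREND")
        if (svtype %in% c("INS", "MEI")) {
            rpos <- pos              # insertions are point events in ref coords
            len <- if (!is.na(svlen)) abs(svlen)
                   else if (!is.na(endv)) abs(endv - pos) else NA_integer_
        } else {
            rpos <- if (!is.na(endv)) endv
                    else if (!is.na(svlen)) pos + abs(svlen) else pos
            len <- if (!is.na(endv) || !is.na(svlen)) abs(rpos - pos)
                   else NA_integer_
        }
        if (svtype %in% c("DEL", "DUP", "CNV", "INV") && pos > rpos)
            stop(sprintf(
                "record '%s': left breakpoint %d after right breakpoint %d",
                id, pos, rpos))
        right <- .newBreakend(chrom, rpos, ciend[1L], ciend[2L], prend)
        vars[[i]] <- .newSV(id, svtype, left, right,
                            alleleFreq = af, svLength = len)
    }
    new("SVCallset", variants = Filter(Negate(is.null), vars),
        header = header, records = records, recordIds = ids,
        contigLengths = contigLengths, skipped = skipped)
}

#' Pair BND mates into single variants
#'
#' Merges reciprocal BND records (linked by \code{MATEID}) into one
#' \linkS4class{StructuralVariant} whose left breakend is the positionally
#' first of the pair; both record ids are retained so both VCF lines receive
#' identical scores. A BND whose mate is absent stays unmated (right
#' breakend NULL) with a warning.
#'
#' @param x an \linkS4class{SVCallset} or a list of
#'   \linkS4class{StructuralVariant}.
#' @return object of the same kind with BND pairs merged.
#' @export
pairBndMates <- function(x) {
    vars <- if (is(x, "SVCallset")) x@variants else x
    if (!length(vars)) return(x)
    firstId <- vapply(vars, function(v) v@ids[1L], "")
    byId <- setNames(seq_along(vars), firstId)
    merged <- vector("list", length(vars))
    consumed <- logical(length(vars))
    out <- list()
    for (i in seq_along(vars)) {
        if (consumed[i]) next
        v <- vars[[i]]
        if (v@svtype != "BND" || !length(v@mateId)) {
            out[[length(out) + 1L]] <- v
            next
        }
        j <- byId[v@mateId[1L]]
        if (is.na(j) || vars[[j]]@svtype != "BND") {
            warning(sprintf("BND '%s': mate '%s' not found; kept unmated",
                            v@ids[1L], v@mateId[1L]), call. = FALSE)
            out[[length(out) + 1L]] <- v
            next
        }
        m <- vars[[j]]
        consumed[c(i, j)] <- TRUE
        a <- v@left; b <- m@left
        swap <- (b@chrom < a@chrom) || (b@chrom == a@chrom && b@pos < a@pos)
        lft <- if (swap) b else a
        rgt <- if (swap) a else b
        af <- if (length(v@alleleFreq)) v@alleleFreq else m@alleleFreq
        out[[length(out) + 1L]] <- .newSV(
            c(v@ids[1L], m@ids[1L]), "BND", lft, rgt, alleleFreq = af)
    }
    if (is(x, "SVCallset")) {
        x@variants <- out
        x
    } else out
}

## Remove previously written score keys from an INFO string
stripScoreInfo <- function(info) {
    if (info == ".") return(".")
    parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
    keep <- !grepl("^(SVSCORE[A-Z0-9_]*)(=|$)", parts)
    if (!any(keep)) "." else paste(parts[keep], collapse = ";")
}

formatScore <- function(x, digits) {
    ifelse(is.na(x), "-1", formatC(x, format = "f", digits = digits))
}

scoreInfoHeaderLines <- function(keys, verbose) {
    desc <- c(SVSCOREMAX = "maximum per-base score over all intervals",
              SVSCORESUM = "summed per-base scores (max over intervals)",
              SVSCOREMEAN = "weighted mean per-base score (max over intervals)")
    lines <- vapply(keys, function(k) {
        d <- if (k %in% names(desc)) desc[[k]]
             else sprintf("weighted mean of the top %s per-base scores (max over intervals)",
                          sub("SVSCORETOP", "", k))
        sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, d)
    }, "")
    lines <- c(lines, paste0("##INFO=<ID=SVSCORE_MISSING,Number=0,",
        "Type=Flag,Description=\"No scorable base in any interval\">"))
    if (verbose)
        for (k in keys)
            lines <- c(lines, sprintf(paste0("##INFO=<ID=%s_%s,Number=1,",
                "Type=Float,Description=\"Per-interval breakdown: ",
                "%s over the %s interval(s)\">"),
                k, INTERVAL_LABELS, k, INTERVAL_LABELS))
    unname(lines)
}

#' Write a score-annotated VCF
#'
#' Reproduces the input VCF byte-identically apart from INFO: score keys
#' (\code{SVSCOREMAX}, \code{SVSCORESUM}, \code{SVSCOREMEAN},
#' \code{SVSCORETOP<N>}) are appended to each scored record, matching
#' \code{##INFO} header lines are added, and any score keys from a previous
#' run are replaced (re-annotation is idempotent). Records the engine could
#' not score carry the \code{-1} sentinel plus the \code{SVSCORE_MISSING}
#' flag; records skipped at parse time pass through untouched. Both lines of
#' a mated BND pair receive identical values. With \code{verboseIntervals}
#' the per-interval breakdown is added as one key per operation-label pair
#' (e.g. \code{SVSCOREMAX_LEFT}, \code{SVSCORETOP10_LTRUNC}), taking the
#' maximum across transcripts within a label.
#'
#' @param callset the \linkS4class{SVCallset} the scores were computed from.
#' @param scoreSets list of \linkS4class{VariantScoreSet}.
#' @param path output path (gzipped when it ends in .gz).
#' @param config the \linkS4class{AggregationConfig} used for scoring
#'   (controls key set and serialisation precision).
#' @param verboseIntervals also emit the per-interval breakdown under an
#'   \code{SVSCORE_INTERVALS} key.
#' @return \code{path}, invisibly.
#' @export
writeAnnotatedVcf <- function(callset, scoreSets, path,
                              config = aggregationConfig(),
                              verboseIntervals = FALSE) {
    stopifnot(is(callset, "SVCallset"))
    keys <- infoKeysFor(config)
    byId <- new.env(parent = emptyenv())
    for (s in scoreSets) {
        for (id in s@variantIds) {
            if (!(id %in% callset@recordIds))
                stop(sprintf(
                    "score set references id '%s' absent from the VCF", id))
            assign(id, s, envir = byId)
        }
    }
    header <- callset@header
    drop <- grepl("^##INFO=<ID=SVSCORE", header)
    header <- header[!drop]
    chromAt <- which(startsWith(header, "#CHROM"))[1L]
    if (is.na(chromAt)) chromAt <- length(header) + 1L
    header <- append(header, scoreInfoHeaderLines(keys, verboseIntervals),
                     after = chromAt - 1L)

    outRecords <- callset@records
    for (i in seq_along(outRecords)) {
        id <- callset@recordIds[i]
        if (!exists(id, envir = byId, inherits = FALSE)) next
        s <- get(id, envir = byId)
        f <- strsplit(outRecords[[i]], "\t", fixed = TRUE)[[1L]]
        info <- stripScoreInfo(f[8L])
        add <- if (s@missing)
            c(paste0(keys, "=-1"), "SVSCORE_MISSING")
        else
            paste0(keys, "=",
                   formatScore(s@perOperation[keys], config@digits))
        if (verboseIntervals && nrow(s@perInterval)) {
            pi <- s@perInterval
            pi <- pi[!is.na(pi$score), , drop = FALSE]
            if (nrow(pi)) {
                ## one key per (operation, label): max across transcripts
                grp <- paste(pi$op, pi$label, sep = "_")
                best <- vapply(split(pi$score, grp), max, 0)
                add <- c(add, paste0(names(best), "=",
                                     formatScore(best, config@digits)))
            }
        }
        f[8L] <- if (info == ".") paste(add, collapse = ";")
                 else paste(c(info, add), collapse = ";")
        outRecords[[i]] <- paste(f, collapse = "\t")
    }
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(c(header, outRecords), con)
    invisible(path)
}
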