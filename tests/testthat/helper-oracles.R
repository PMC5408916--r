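## Shared fixtures (generated once per session) and independent oracles.
## Oracles are deliberately naive loop/scan implementations, kept separate
## from the package's code paths.

.cache <- new.env(parent = emptyenv())

sharedFixtures <- function() {
    if (!is.null(.cache$fx)) return(.cache$fx)
    dir <- file.path(tempdir(), "svimpact-shared-fixtures")
    fx <- generateFixtures(fixtureSpec(), dir)
    fx$index <- loadGeneAnnotation(fx$annotation)
    fx$tabixTrack <- scoreTrack(fx$track)
    fx$memTrack <- scoreTrack(fx$trackTsv, preload = TRUE)
    .cache$fx <- fx
    fx
}

## raw rows of the shared score track (chrom, pos, score), no reduction
sharedTrackRows <- function() {
    if (!is.null(.cache$rows)) return(.cache$rows)
    fx <- sharedFixtures()
    tab <- utils::read.table(fx$trackTsv, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    .cache$rows <- data.frame(chrom = tab[[1L]], pos = tab[[2L]],
                              score = tab[[6L]])
    .cache$rows
}

## brute-force per-position fetch: scan every row, reduce by max
bruteFetch <- function(rows, chrom, start, end) {
    hit <- rows[rows$chrom == chrom & rows$pos >= start & rows$pos <= end,
                , drop = FALSE]
    if (!nrow(hit)) return(data.frame(pos = integer(), score = numeric()))
    ps <- sort(unique(hit$pos))
    sc <- vapply(ps, function(p) max(hit$score[hit$pos == p]), 0)
    data.frame(pos = ps, score = sc)
}

## brute-force aggregation: explicit loops, no vectorised shortcuts
bruteAggregate <- function(scores, weights, op, n = NULL) {
    if (length(scores) == 0L) return(NA_real_)
    if (is.null(weights)) weights <- rep(1, length(scores))
    if (op == "max") {
        m <- scores[1L]
        for (s in scores) if (s > m) m <- s
        return(m)
    }
    if (op == "sum") {
        acc <- 0
        for (s in scores) acc <- acc + s
        return(acc)
    }
    if (op == "topn") {
        keep <- integer()
        left <- seq_along(scores)
        while (length(keep) < min(n, length(scores))) {
            best <- left[1L]
            for (i in left) if (scores[i] > scores[best]) best <- i
            keep <- c(keep, best)
            left <- setdiff(left, best)
        }
        scores <- scores[keep]; weights <- weights[keep]
    }
    num <- 0; den <- 0
    for (i in seq_along(scores)) {
        num <- num + weights[i] * scores[i]
        den <- den + weights[i]
    }
    num / den
}

## brute-force transcript/exon overlap over a plain annotation data.frame
bruteTranscriptHits <- function(ann, chrom, start, end) {
    hits <- ann$name[ann$chrom == chrom & ann$txStart <= end &
                     start <= ann$txEnd]
    sort(hits)
}

bruteExonOverlap <- function(annExons, chrom, start, end) {
    any(annExons$chrom == chrom & annExons$start <= end &
        start <= annExons$end)
}

## independent refGene reader for the brute-force annotation oracle
readRefgeneRaw <- function(path) {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    ann <- data.frame(name = tab[[2L]], chrom = tab[[3L]],
                      strand = tab[[4L]], txStart = tab[[5L]] + 1L,
                      txEnd = tab[[6L]], stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
        s <- as.integer(strsplit(tab[[10L]][i], ",")[[1L]]) + 1L
        e <- as.integer(strsplit(tab[[11L]][i], ",")[[1L]])
        data.frame(chrom = tab[[3L]][i], start = s, end = e,
                   name = tab[[2L]][i], stringsAsFactors = FALSE)
    }))
    list(tx = ann, exons = exons)
}

## two-sided Fisher p by exhaustive hypergeometric enumeration over all
## tables with the observed margins (the textbook definition, with the
## standard 1+1e-7 tie tolerance)
hypergeomFisherP <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    lo <- max(0L, k - n); hi <- min(k, m)
    probs <- stats::dhyper(lo:hi, m, n, k)
    p0 <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
}

## one refGene flat-table row from 0-based half-open coordinates
mkRefgeneRow <- function(name, chrom, strand, txStart0, txEnd0,
                         exonStarts0, exonEnds0,
                         exonCount = length(exonStarts0)) {
    paste(c(0, name, chrom, strand, txStart0, txEnd0, txStart0, txEnd0,
            exonCount,
            paste0(paste(exonStarts0, collapse = ","), ","),
            paste0(paste(exonEnds0, collapse = ","), ","),
            0, name, "cmpl", "cmpl",
            paste0(paste(rep(-1, length(exonStarts0)), collapse = ","),
                   ",")), collapse = "\t")
}

## write a minimal SV VCF from record lines
writeTestVcf <- function(records, path,
                         contigs = c(chrT1 = 50000L, chrT2 = 30000L)) {
    header <- c("##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                as.integer(contigs)),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
        "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"c\">",
        "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"c\">",
        "##INFO=<ID=PRPOS,Number=.,Type=Float,Description=\"p\">",
        "##INFO=<ID=PREND,Number=.,Type=Float,Description=\"p\">",
        "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
        "##INFO=<ID=AF,Number=1,Type=Float,Description=\"a\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(header, records), path)
    path
}

## write a small bgzipped+indexed score track from (chrom, pos, score)
## rows in the minimal 3-column dialect
writeTestTrack <- function(chrom, pos, score, dir = tempfile("trk")) {
    dir.create(dir, showWarnings = FALSE)
    path <- file.path(dir, "mini.tsv")
    writeLines(c("#chrom\tpos\tscore",
                 sprintf("%s\t%d\t%s", chrom, as.integer(pos),
                         format(score, trim = TRUE))), path)
    bgz <- Rsamtools::bgzip(path, dest = paste0(path, ".bgz"),
                            overwrite = TRUE)
    Rsamtools::indexTabix(bgz, seq = 1L, start = 2L, end = 2L,
                          comment = "#")
    bgz
}

## a plain DEL variant for interval tests
mkDel <- function(pos = 100L, end = 200L, ciLo = -10L, ciHi = 5L,
                  ceLo = -5L, ceHi = 10L, svtype = "DEL",
                  chrom = "chrT1", prob = numeric(), eprob = numeric()) {
    structuralVariant("v1", svtype,
        breakend(chrom, pos, ciLo, ciHi, prob),
        breakend(chrom, end, ceLo, ceHi, eprob),
        svLength = abs(end - pos))
}
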