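#' Synthetic fixture specification
#'
#' Parameters of the deterministic generator that emulates the three inputs
#' of the pipeline at desk scale: a per-base score track, a refGene-style
#' annotation and an SV callset. Spike regions carry elevated scores;
#' variants overlapping a spike are coupled to rare allele frequency with
#' probability \code{enrichment} (otherwise they draw from the same
#' background AF mixture as every other variant, so \code{enrichment = 0}
#' is an exact null with no AF-score association).
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param contigs named vector of contig lengths (bp).
#' @param nVariants number of variants (a mated BND pair counts once).
#' @param svtypeMix named proportions over DEL, DUP, CNV, INV, INS, MEI,
#'   BND (must sum to 1).
#' @param ciMax maximum CI half-width in bp (offsets drawn from 0..ciMax).
#' @param probShape breakpoint probability shape inside CIs:
#'   \code{"triangular"} (peaked at the most likely position) or
#'   \code{"uniform"}.
#' @param bgShape,bgScale gamma parameters of the phred-like background
#'   score distribution (defaults shape 2, scale 3: mean 6).
#' @param spikeRegions data.frame(chrom, start, end) of elevated-score
#'   regions; defaults cover ~14\% of the genome.
#' @param spikeOffset score elevation inside spike regions (phred units).
#' @param enrichment probability that a spike-overlapping variant is forced
#'   to rare AF.
#' @param afBackground background AF-class mixture (rare, intermediate,
#'   common proportions).
#' @param svLengthRange SV length range in bp.
#' @param multiAlleleFrac fraction of track positions carrying a second
#'   alternate-allele row (exercises multi-allele reduction).
#' @return a list of class \code{FixtureSpec}.
#' @export
fixtureSpec <- function(seed = 42L,
                        contigs = c(chrT1 = 50000L, chrT2 = 30000L),
                        nVariants = 200L,
                        svtypeMix = c(DEL = 0.30, DUP = 0.20, CNV = 0.05,
                                      INV = 0.15, INS = 0.15, MEI = 0.05,
                                      BND = 0.10),
                        ciMax = 10L,
                        probShape = c("triangular", "uniform"),
                        bgShape = 2, bgScale = 3,
                        spikeRegions = NULL,
                        spikeOffset = 20,
                        enrichment = 0.9,
                        afBackground = c(rare = 0.25, intermediate = 0.15,
                                         common = 0.60),
                        svLengthRange = c(50L, 800L),
                        multiAlleleFrac = 0.05) {
    probShape <- match.arg(probShape)
    if (is.null(spikeRegions))
        spikeRegions <- data.frame(
            chrom = c("chrT1", "chrT1", "chrT2"),
            start = c(5000L, 20000L, 10000L),
            end = c(9000L, 24000L, 13000L),
            stringsAsFactors = FALSE)
    if (abs(sum(svtypeMix) - 1) > 1e-6)
        stop("svtypeMix proportions must sum to 1")
    if (!all(names(svtypeMix) %in% SV_TYPES))
        stop("svtypeMix names must be SV types")
    for (i in seq_len(nrow(spikeRegions))) {
        ch <- spikeRegions$chrom[i]
        if (!(ch %in% names(contigs)) ||
            spikeRegions$start[i] < 1 ||
            spikeRegions$end[i] > contigs[[ch]])
            stop("spike region ", i, " outside contig bounds")
    }
    structure(list(seed = as.integer(seed), contigs = contigs,
                   nVariants = as.integer(nVariants),
                   svtypeMix = svtypeMix, ciMax = as.integer(ciMax),
                   probShape = probShape, bgShape = bgShape,
                   bgScale = bgScale, spikeRegions = spikeRegions,
                   spikeOffset = spikeOffset, enrichment = enrichment,
                   afBackground = afBackground,
                   svLengthRange = as.integer(svLengthRange),
                   multiAlleleFrac = multiAlleleFrac),
              class = "FixtureSpec")
}

BASES <- c("A", "C", "G", "T")

#' Generate the synthetic score track
#'
#' One CADD-dialect row per base per contig (Chrom, Pos, Ref, Alt,
#' RawScore, PHRED), background scores from the configured gamma
#' distribution, spike regions elevated by \code{spikeOffset}, and a
#' fraction of positions duplicated with a second alternate allele. The
#' plain TSV is kept alongside the bgzipped, tabix-indexed copy. Identical
#' seeds give byte-identical files.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @return named list with \code{tsv}, \code{bgz} and \code{index} paths.
#' @export
generateScoreTrack <- function(spec, dir) {
    set.seed(spec$seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, "scores.tsv")
    out <- "#Chrom\tPos\tRef\tAlt\tRawScore\tPHRED"
    for (ch in names(spec$contigs)) {
        len <- as.integer(spec$contigs[[ch]])
        sc <- stats::rgamma(len, shape = spec$bgShape, scale = spec$bgScale)
        spk <- spec$spikeRegions[spec$spikeRegions$chrom == ch, ,
                                 drop = FALSE]
        for (i in seq_len(nrow(spk)))
            sc[spk$start[i]:spk$end[i]] <-
                sc[spk$start[i]:spk$end[i]] + spec$spikeOffset
        ref <- sample(BASES, len, replace = TRUE)
        altOf <- function(r) BASES[(match(r, BASES) - 1L +
            sample(1:3, length(r), replace = TRUE)) %% 4L + 1L]
        alt <- altOf(ref)
        nSec <- floor(len * spec$multiAlleleFrac)
        secPos <- sort(sample.int(len, nSec))
        secSc <- pmax(0, sc[secPos] + stats::runif(nSec, -3, 3))
        secAlt <- altOf(ref[secPos])
        pos <- c(seq_len(len), secPos)
        score <- c(sc, secSc)
        refAll <- c(ref, ref[secPos])
        altAll <- c(alt, secAlt)
        ord <- order(pos)       # stable: primary row precedes its duplicate
        out <- c(out, sprintf("%s\t%d\t%s\t%s\t%.4f\t%.3f",
                              ch, pos[ord], refAll[ord], altAll[ord],
                              score[ord] / 10 - 1, score[ord]))
    }
    writeLines(out, path)
    bgz <- Rsamtools::bgzip(path, dest = paste0(path, ".bgz"),
                            overwrite = TRUE)
    idx <- Rsamtools::indexTabix(bgz, seq = 1L, start = 2L, end = 2L,
                                 comment = "#")
    list(tsv = path, bgz = bgz, index = idx)
}

#' Generate the synthetic gene annotation
#'
#' Non-overlapping transcripts with 2-10 exons each, on both strands, laid
#' out left to right along each contig, written as a UCSC refGene-style
#' flat table (0-based half-open coordinates). Deterministic under the
#' spec's seed.
#'
#' @inheritParams generateScoreTrack
#' @return the annotation file path.
#' @export
generateAnnotation <- function(spec, dir) {
    set.seed(spec$seed + 1L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, "genes.refgene.txt")
    rows <- character()
    txi <- 0L
    for (ch in names(spec$contigs)) {
        len <- as.integer(spec$contigs[[ch]])
        cursor <- 1000L
        repeat {
            gap <- sample(500:2500, 1L)
            txLen <- sample(1000:4000, 1L)
            s <- cursor + gap
            e <- s + txLen - 1L
            if (e > len - 1000L) break
            txi <- txi + 1L
            strand <- sample(c("+", "-"), 1L)
            k <- sample(2:10, 1L)
            bnd <- as.integer(floor(seq(s, e + 1L, length.out = k + 1L)))
            es <- integer(k); ee <- integer(k)
            for (j in seq_len(k)) {
                chunkLen <- bnd[j + 1L] - bnd[j]
                elen <- sample(40:min(250L, chunkLen), 1L)
                es[j] <- bnd[j] + sample(0:(chunkLen - elen), 1L)
                ee[j] <- es[j] + elen - 1L
            }
            name <- sprintf("TX%03d", txi)
            rows <- c(rows, paste(c(
                0L, name, ch, strand, s - 1L, e, s - 1L, e, k,
                paste0(paste(es - 1L, collapse = ","), ","),
                paste0(paste(ee, collapse = ","), ","),
                0L, sprintf("GENE%03d", txi), "cmpl", "cmpl",
                paste0(paste(rep(-1L, k), collapse = ","), ",")),
                collapse = "\t"))
            cursor <- e
        }
    }
    writeLines(rows, path)
    path
}

.probVectorString <- function(lo, hi, shape) {
    off <- lo:hi
    p <- if (shape == "uniform") rep(1, length(off))
         else 1 - abs(off) / (max(abs(off)) + 1)
    p <- p / sum(p)
    paste(sprintf("%.10g", p), collapse = ",")
}

.drawAF <- function(class) {
    switch(class,
        rare = stats::runif(1, 5e-4, 9e-3),
        intermediate = stats::runif(1, 0.012, 0.045),
        common = stats::runif(1, 0.05, 0.5))
}

#' Generate the synthetic SV callset
#'
#' Valid VCF 4.2 with SVTYPE, END/SVLEN, CIPOS/CIEND, PRPOS/PREND
#' (normalised to sum 1) and AF per record; BND variants are emitted as
#' reciprocal mate pairs with MATEID. A variant whose affected interval
#' overlaps a spike region is forced to rare AF with probability
#' \code{enrichment}; otherwise (and for all other variants) its AF class
#' is drawn from the background mixture.
#'
#' @inheritParams generateScoreTrack
#' @return the VCF file path.
#' @export
generateSvVcf <- function(spec, dir) {
    set.seed(spec$seed + 2L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(dir, "variants.vcf")
    contigs <- spec$contigs
    cw <- as.numeric(contigs) / sum(as.numeric(contigs))
    spikes <- spec$spikeRegions
    overlapsSpike <- function(ch, s, e) {
        any(spikes$chrom == ch & spikes$start <= e & s <= spikes$end)
    }
    afFor <- function(hit) {
        if (hit && stats::runif(1) < spec$enrichment) return(.drawAF("rare"))
        cls <- sample(names(spec$afBackground), 1L,
                      prob = spec$afBackground)
        .drawAF(cls)
    }
    drawCI <- function() c(-sample(0:spec$ciMax, 1L),
                           sample(0:spec$ciMax, 1L))
    types <- sample(names(spec$svtypeMix), spec$nVariants, replace = TRUE,
                    prob = spec$svtypeMix)
    recs <- character()
    vi <- 0L
    for (ty in types) {
        vi <- vi + 1L
        id <- sprintf("SV%05d", vi)
        if (ty == "BND") {
            chA <- sample(names(contigs), 1L, prob = cw)
            chB <- sample(names(contigs), 1L, prob = cw)
            posA <- sample(200:(contigs[[chA]] - 200L), 1L)
            posB <- sample(200:(contigs[[chB]] - 200L), 1L)
            ciA <- drawCI(); ciB <- drawCI()
            prA <- .probVectorString(ciA[1L], ciA[2L], spec$probShape)
            prB <- .probVectorString(ciB[1L], ciB[2L], spec$probShape)
            hit <- overlapsSpike(chA, posA + ciA[1L], posA + ciA[2L]) ||
                   overlapsSpike(chB, posB + ciB[1L], posB + ciB[2L])
            af <- sprintf("%.4f", afFor(hit))
            recs <- c(recs,
                sprintf(paste0("%s\t%d\t%s_1\tN\tN[%s:%d[\t.\tPASS\t",
                               "SVTYPE=BND;MATEID=%s_2;CIPOS=%d,%d;",
                               "PRPOS=%s;AF=%s"),
                        chA, posA, id, chB, posB, id,
                        ciA[1L], ciA[2L], prA, af),
                sprintf(paste0("%s\t%d\t%s_2\tN\t]%s:%d]N\t.\tPASS\t",
                               "SVTYPE=BND;MATEID=%s_1;CIPOS=%d,%d;",
                               "PRPOS=%s;AF=%s"),
                        chB, posB, id, chA, posA, id,
                        ciB[1L], ciB[2L], prB, af))
            next
        }
        ch <- sample(names(contigs), 1L, prob = cw)
        len <- sample(spec$svLengthRange[1L]:spec$svLengthRange[2L], 1L)
        pos <- sample(200:(contigs[[ch]] - len - 200L), 1L)
        endp <- pos + len
        cip <- drawCI(); cie <- drawCI()
        prp <- .probVectorString(cip[1L], cip[2L], spec$probShape)
        pre <- .probVectorString(cie[1L], cie[2L], spec$probShape)
        hit <- if (ty %in% c("INS", "MEI"))
            overlapsSpike(ch, pos + cip[1L], pos + cip[2L])
        else overlapsSpike(ch, pos, endp)
        af <- sprintf("%.4f", afFor(hit))
        info <- if (ty %in% c("INS", "MEI"))
            sprintf(paste0("SVTYPE=%s;SVLEN=%d;CIPOS=%d,%d;CIEND=%d,%d;",
                           "PRPOS=%s;PREND=%s;AF=%s"),
                    ty, len, cip[1L], cip[2L], cie[1L], cie[2L],
                    prp, pre, af)
        else
            sprintf(paste0("SVTYPE=%s;END=%d;SVLEN=%d;CIPOS=%d,%d;",
                           "CIEND=%d,%d;PRPOS=%s;PREND=%s;AF=%s"),
                    ty, endp, len, cip[1L], cip[2L], cie[1L], cie[2L],
                    prp, pre, af)
        recs <- c(recs, sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                                ch, pos, id, ty, info))
    }
    header <- c("##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                as.integer(contigs)),
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
        "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
        paste0("##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=",
               "\"CI around POS\">"),
        paste0("##INFO=<ID=CIEND,Number=2,Type=Integer,Description=",
               "\"CI around END\">"),
        paste0("##INFO=<ID=PRPOS,Number=.,Type=Float,Description=",
               "\"Breakpoint probabilities around POS\">"),
        paste0("##INFO=<ID=PREND,Number=.,Type=Float,Description=",
               "\"Breakpoint probabilities around END\">"),
        paste0("##INFO=<ID=MATEID,Number=1,Type=String,Description=",
               "\"Mate breakend id\">"),
        paste0("##INFO=<ID=AF,Number=1,Type=Float,Description=",
               "\"Allele frequency\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(header, recs), path)
    path
}

#' Generate a complete, mutually consistent fixture set
#'
#' Runs the three generators with the spec's seed into one directory:
#' score track (plain + bgzipped + indexed), refGene-style annotation, and
#' SV callset sharing the same contigs.
#'
#' @inheritParams generateScoreTrack
#' @return named list with \code{track} (bgz), \code{trackTsv},
#'   \code{trackIndex}, \code{annotation}, \code{vcf} paths and the
#'   \code{spec}.
#' @export
generateFixtures <- function(spec, dir) {
    tr <- generateScoreTrack(spec, dir)
    ann <- generateAnnotation(spec, dir)
    vcf <- generateSvVcf(spec, dir)
    list(track = tr$bgz, trackTsv = tr$tsv, trackIndex = tr$index,
         annotation = ann, vcf = vcf, spec = spec)
}
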