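test_that("SV records map onto typed variants with CI defaults", {
    vcf <- writeTestVcf(c(
        "chrT1\t100\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200;CIPOS=-10,5;CIEND=-5,10",
        "chrT1\t300\tdel2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=400",
        "chrT1\t500\tdel3\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600;CIPOS=-2,2;PRPOS=0.1,0.2,0.4,0.2,0.1",
        "chrT1\t700\tmix\tN\t<DUP>\t.\tPASS\tSVTYPE=DEL;END=800",
        "chrT1\t900\tins1\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=60"),
        tempfile(fileext = ".vcf"))
    cs <- parseSvVcf(vcf)
    v <- variants(cs)
    expect_length(v, 5L)

    d1 <- v[[1L]]
    expect_identical(svType(d1), "DEL")
    expect_identical(leftBreakend(d1)@pos, 100L)
    expect_identical(leftBreakend(d1)@ciLo, -10L)
    expect_identical(leftBreakend(d1)@ciHi, 5L)
    expect_identical(rightBreakend(d1)@pos, 200L)
    expect_identical(rightBreakend(d1)@ciLo, -5L)
    expect_identical(rightBreakend(d1)@ciHi, 10L)
    expect_identical(svLength(d1), 100L)

    ## absent CIPOS -> point breakpoint
    expect_identical(leftBreakend(v[[2L]])@ciLo, 0L)
    expect_identical(leftBreakend(v[[2L]])@ciHi, 0L)

    ## PRPOS of length ciHi - ciLo + 1 accepted
    expect_length(leftBreakend(v[[3L]])@prob, 5L)

    ## INFO SVTYPE wins over the symbolic ALT
    expect_identical(svType(v[[4L]]), "DEL")

    ## insertion: both breakends at the insertion site, SVLEN kept
    expect_identical(rightBreakend(v[[5L]])@pos, 900L)
    expect_identical(svLength(v[[5L]]), 60L)

    ## contig lengths picked up from the header
    expect_identical(contigLengths(cs),
                     c(chrT1 = 50000, chrT2 = 30000))
})

test_that("malformed records produce record-level errors or warnings", {
    badProb <- writeTestVcf(
        "chrT1\t100\tp1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200;CIPOS=-2,2;PRPOS=0.5,0.5",
        tempfile(fileext = ".vcf"))
    expect_error(parseSvVcf(badProb), "p1.*PRPOS.*2 entries.*5 bases")

    multi <- writeTestVcf(
        "chrT1\t100\tm1\tN\t<DEL>,<DUP>\t.\tPASS\tSVTYPE=DEL;END=200",
        tempfile(fileext = ".vcf"))
    expect_error(parseSvVcf(multi), "multi-allelic")

    unk <- writeTestVcf(c(
        "chrT1\t100\tu1\tN\t<WEIRD>\t.\tPASS\tSVTYPE=WEIRD;END=200",
        "chrT1\t300\tok1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=400"),
        tempfile(fileext = ".vcf"))
    expect_warning(cs <- parseSvVcf(unk), "u1.*unknown SVTYPE")
    expect_length(variants(cs), 1L)
    expect_identical(cs@skipped, "u1")
    ## the skipped record is retained in output, untouched
    out <- tempfile(fileext = ".vcf")
    writeAnnotatedVcf(cs, list(), out)
    reread <- readLines(out)
    expect_true(any(grepl("^chrT1\t100\tu1\t", reread)))
})

test_that("BND mates pair reciprocally and survive unmated", {
    vcf <- writeTestVcf(c(
        "chrT2\t900\tbndB\tN\t]chrT1:500]N\t.\tPASS\tSVTYPE=BND;MATEID=bndA",
        "chrT1\t500\tbndA\tN\tN[chrT2:900[\t.\tPASS\tSVTYPE=BND;MATEID=bndB;CIPOS=-3,3",
        "chrT1\t700\tlone\tN\tN[chrT2:100[\t.\tPASS\tSVTYPE=BND;MATEID=ghost"),
        tempfile(fileext = ".vcf"))
    expect_warning(cs <- pairBndMates(parseSvVcf(vcf)),
                   "lone.*ghost.*unmated")
    v <- variants(cs)
    expect_length(v, 2L)
    mated <- v[[1L]]
    expect_setequal(svId(mated), c("bndA", "bndB"))
    ## left breakend is the positionally first (chrT1 before chrT2)
    expect_identical(leftBreakend(mated)@chrom, "chrT1")
    expect_identical(leftBreakend(mated)@pos, 500L)
    expect_identical(rightBreakend(mated)@chrom, "chrT2")
    expect_null(rightBreakend(v[[2L]]))
    ## empty input is the identity
    expect_identical(pairBndMates(list()), list())
})

test_that("annotation writing round-trips non-INFO bytes and is idempotent", {
    fx <- sharedFixtures()
    cs <- suppressWarnings(parseSvVcf(fx$vcf))
    out <- tempfile(fileext = ".vcf")
    ## zero score sets: records must be byte-identical
    writeAnnotatedVcf(cs, list(), out)
    rereadRecords <- grep("^#", readLines(out), value = TRUE,
                          invert = TRUE)
    expect_identical(rereadRecords, cs@records)

    ## scored output: every record gains the keys; BND mates agree
    res <- scoreCallset(fx$vcf, fx$memTrack, fx$index, out)
    lines <- grep("^#", readLines(out), value = TRUE, invert = TRUE)
    expect_true(all(grepl("SVSCOREMAX=", lines)))
    byId <- function(id) grep(paste0("\t", id, "\t"), lines, value = TRUE)
    mated <- Filter(function(v) length(svId(v)) == 2L,
                    variants(res$callset))
    ex <- mated[[1L]]
    s1 <- sub(".*SVSCOREMAX=([-0-9.]+).*", "\\1", byId(svId(ex)[1L]))
    s2 <- sub(".*SVSCOREMAX=([-0-9.]+).*", "\\1", byId(svId(ex)[2L]))
    expect_identical(s1, s2)

    ## re-scoring the annotated VCF replaces the keys, nothing else
    out2 <- tempfile(fileext = ".vcf")
    scoreCallset(out, fx$memTrack, fx$index, out2)
    expect_identical(readLines(out2), readLines(out))

    ## non-INFO fields unchanged relative to the original input
    orig <- do.call(rbind, strsplit(cs@records, "\t"))[, 1:7]
    ann <- do.call(rbind, strsplit(lines, "\t"))[, 1:7]
    expect_identical(ann, orig)
})

test_that("score serialisation uses the sentinel and rejects foreign ids", {
    vcf <- writeTestVcf(
        "chrT1\t100\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=150",
        tempfile(fileext = ".vcf"))
    cs <- parseSvVcf(vcf)
    cfg <- aggregationConfig("max")
    good <- new("VariantScoreSet", variantIds = "d1",
                perOperation = c(SVSCOREMAX = 12.5),
                perInterval = data.frame(op = "SVSCOREMAX",
                    label = "LEFT", transcript = NA_character_,
                    score = 12.5, stringsAsFactors = FALSE),
                missing = FALSE)
    out <- tempfile(fileext = ".vcf")
    writeAnnotatedVcf(cs, list(good), out, cfg)
    expect_match(grep("^chrT1", readLines(out), value = TRUE),
                 "SVSCOREMAX=12.5", fixed = TRUE)

    missing <- new("VariantScoreSet", variantIds = "d1",
                   perOperation = c(SVSCOREMAX = NA_real_),
                   perInterval = data.frame(),
                   missing = TRUE)
    writeAnnotatedVcf(cs, list(missing), out, cfg)
    line <- grep("^chrT1", readLines(out), value = TRUE)
    expect_match(line, "SVSCOREMAX=-1", fixed = TRUE)
    expect_match(line, "SVSCORE_MISSING")

    stray <- new("VariantScoreSet", variantIds = "nope",
                 perOperation = c(SVSCOREMAX = 1),
                 perInterval = data.frame(), missing = FALSE)
    expect_error(writeAnnotatedVcf(cs, list(stray), out, cfg),
                 "nope.*absent")
})

test_that("INFO parsing agrees with VariantAnnotation on the fixture VCF", {
    skip_if_not_installed("VariantAnnotation")
    fx <- sharedFixtures()
    cs <- suppressWarnings(parseSvVcf(fx$vcf))
    va <- VariantAnnotation::readVcf(fx$vcf)
    info <- VariantAnnotation::info(va)
    ids <- rownames(info)
    ours <- setNames(variants(cs),
                     vapply(variants(cs), function(v) svId(v)[1L], ""))
    spanTy <- ids[info$SVTYPE %in% c("DEL", "DUP", "CNV", "INV")]
    expect_identical(
        vapply(ours[spanTy], function(v) rightBreakend(v)@pos, 0L),
        setNames(as.integer(info[spanTy, "END"]), spanTy))
    afTheirs <- as.numeric(unlist(info[spanTy, "AF"]))
    afOurs <- unname(vapply(ours[spanTy], alleleFreq, 0))
    expect_equal(afOurs, afTheirs, tolerance = 1e-6)
})
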