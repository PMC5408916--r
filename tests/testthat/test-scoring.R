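test_that("the final score per operation is the max over interval scores", {
    ## craft a track with known blocks: LEFT CI [90,105] scores 3,
    ## RIGHT CI [195,210] scores 7.5, SPAN [100,200] background 5
    pos <- 90:210
    sc <- rep(5, length(pos))
    sc[pos <= 99] <- 3
    sc[pos >= 201] <- 7.5
    bgz <- writeTestTrack(rep("chrT1", length(pos)), pos, sc)
    tr <- scoreTrack(bgz)
    del <- mkDel()
    ss <- scoreVariant(del, tr, config = aggregationConfig("max"))
    expect_false(isMissing(ss))
    pi <- perInterval(ss)
    expect_equal(pi$score[pi$label == "LEFT"], 5)    # CI reaches 105
    expect_equal(pi$score[pi$label == "RIGHT"], 7.5)
    expect_equal(pi$score[pi$label == "SPAN"], 5)    # span stops at 200
    expect_equal(unname(perOperation(ss)["SVSCOREMAX"]),
                 max(pi$score))
})

test_that("constant tracks collapse operations; unscored regions flag missing", {
    pos <- 1:300
    bgz <- writeTestTrack(rep("chrT1", 300), pos, rep(2.5, 300))
    tr <- scoreTrack(bgz)
    del <- mkDel()
    ss <- scoreVariant(del, tr)
    po <- perOperation(ss)
    expect_equal(unname(po["SVSCOREMAX"]), 2.5)
    expect_equal(unname(po["SVSCOREMEAN"]), 2.5)
    expect_equal(unname(po["SVSCORETOP10"]), 2.5)
    expect_equal(unname(po["SVSCORETOP100"]), 2.5)
    ## widest interval is SPAN [100,200]: 101 scored bases
    expect_equal(unname(po["SVSCORESUM"]), 2.5 * 101)

    far <- mkDel(pos = 1000L, end = 1100L)
    ss2 <- scoreVariant(far, tr)
    expect_true(isMissing(ss2))
    expect_true(all(is.na(perOperation(ss2))))
})

test_that("scoreVariant equals the fetch+aggregate composition", {
    fx <- sharedFixtures()
    vs <- variants(pairBndMates(suppressWarnings(parseSvVcf(fx$vcf))))
    cfg <- aggregationConfig()
    set.seed(3)
    for (v in vs[sample.int(length(vs), 20L)]) {
        ss <- scoreVariant(v, fx$tabixTrack, fx$index, cfg)
        gr <- resolveIntervals(v, fx$index)
        pi <- perInterval(ss)
        for (i in seq_along(gr)) {
            f <- fetchScores(fx$tabixTrack,
                             as.character(GenomicRanges::seqnames(gr))[i],
                             GenomicRanges::start(gr)[i],
                             GenomicRanges::end(gr)[i])
            w <- as.numeric(S4Vectors::mcols(gr)$weights[[i]])
            if (length(w))
                w <- w[f$pos - GenomicRanges::start(gr)[i] + 1L]
            else w <- NULL
            expected <- aggregateScores(f$score, w, "topn", 10L)
            got <- pi$score[pi$op == "SVSCORETOP10"][i]
            if (is.na(expected)) expect_true(is.na(got))
            else expect_equal(got, expected, tolerance = 1e-12)
        }
    }
})

test_that("verbose output exposes the per-interval breakdown keys", {
    fx <- sharedFixtures()
    out <- tempfile(fileext = ".vcf")
    res <- scoreCallset(fx$vcf, fx$memTrack, fx$index, out,
                        aggregationConfig("max"),
                        verboseIntervals = TRUE)
    lines <- readLines(out)
    recs <- grep("^#", lines, invert = TRUE, value = TRUE)
    expect_true(all(grepl("SVSCOREMAX_LEFT=", recs)))
    expect_true(any(grepl("SVSCOREMAX_SPAN=", recs)))
    expect_true(any(grepl("^##INFO=<ID=SVSCOREMAX_LTRUNC,", lines)))
    ## the breakdown is consistent with the reported maximum
    del <- grep("SVTYPE=DEL", recs, value = TRUE)[1L]
    g <- function(k) as.numeric(sub(paste0(".*", k, "=([-0-9.]+).*"),
                                    "\\1", del))
    expect_equal(g("SVSCOREMAX"),
                 max(g("SVSCOREMAX_LEFT"), g("SVSCOREMAX_RIGHT"),
                     g("SVSCOREMAX_SPAN"),
                     if (grepl("SVSCOREMAX_LTRUNC", del))
                         g("SVSCOREMAX_LTRUNC"),
                     if (grepl("SVSCOREMAX_RTRUNC", del))
                         g("SVSCOREMAX_RTRUNC")))
})

test_that("callset scoring is complete, idempotent and summarised", {
    fx <- sharedFixtures()
    out <- tempfile(fileext = ".vcf")
    res <- scoreCallset(fx$vcf, fx$memTrack, fx$index, out)
    s <- res$summary
    expect_identical(s$n_variants, 200L)
    expect_identical(s$n_scored + s$n_missing, s$n_variants)
    lines <- grep("^#", readLines(out), invert = TRUE, value = TRUE)
    expect_identical(length(lines), s$n_records)
    expect_true(all(grepl("SVSCOREMAX=", lines)))

    ## empty VCF
    empty <- writeTestVcf(character(), tempfile(fileext = ".vcf"))
    out2 <- tempfile(fileext = ".vcf")
    res2 <- scoreCallset(empty, fx$memTrack, fx$index, out2)
    expect_identical(res2$summary$n_variants, 0L)
    expect_identical(res2$summary$n_scored, 0L)
})
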