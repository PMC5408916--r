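test_that("nearest-rank percentile classes on 1..100 are fixed by the rule", {
    cls <- classifyByScore(1:100)
    ## P90 = 90 (rank ceil(0.9*100)), P50 = 50: "at or above" keeps ties
    expect_identical(sum(cls == "pathogenic"), 11L)
    expect_identical(sum(cls == "benign"), 49L)
    expect_identical(sum(cls == "intermediate"), 40L)

    ## missing entries are excluded from percentiles and classed unscored
    withNA <- classifyByScore(c(1:100, NA, NA))
    expect_identical(sum(withNA == "unscored"), 2L)
    expect_identical(sum(withNA == "pathogenic"), 11L)

    ## degenerate distribution: everything is at or above P90
    expect_true(all(classifyByScore(rep(3, 20)) == "pathogenic"))

    expect_error(classifyByScore(1:9), "fewer than 10")
})

test_that("AF classes apply the rare/common boundaries exactly", {
    got <- classifyByAF(c(0.0099, 0.05, 0.03, 0, NA, 0.01, 0.049999))
    expect_identical(got, c("rare", "common", "intermediate_af", "rare",
                            "missing", "intermediate_af",
                            "intermediate_af"))
})

test_that("odds ratios follow the closed form with Fisher p-values", {
    r <- oddsRatio(c(10, 10, 10, 10))
    expect_equal(r$or, 1)
    expect_equal(r$p, 1)
    expect_false(r$corrected)

    expect_equal(oddsRatio(c(20, 5, 10, 10))$or, 4)
    expect_equal(oddsRatio(c(1, 1, 1, 1))$p, 1)

    z <- oddsRatio(c(5, 0, 3, 4))
    expect_true(z$corrected)
    expect_equal(z$or, (5.5 * 4.5) / (0.5 * 3.5))
    expect_true(z$ci95[1L] < z$or && z$or < z$ci95[2L])

    expect_error(oddsRatio(c(0, 0, 5, 5)), "margin.*zero")
})

test_that("length classifier shares the percentile rule; BNDs are unusable", {
    svs <- lapply(1:100, function(i) mkDel(pos = 1000L,
                                           end = 1000L + i))
    cls <- lengthClassifier(svs)
    expect_identical(sum(cls == "pathogenic"), 11L)
    expect_identical(sum(cls == "benign"), 49L)

    bnds <- lapply(1:12, function(i)
        structuralVariant(paste0("b", i), "BND",
                          breakend("chrT1", 100L + i)))
    expect_error(lengthClassifier(bnds), "fewer than 10")
    ## one DEL among BNDs is still below the stability guard
    expect_error(lengthClassifier(c(bnds, list(mkDel()))), "fewer than 10")
})

test_that("exon-overlap classifier needs exon (not just transcript) contact", {
    rg <- tempfile(fileext = ".txt")
    writeLines(mkRefgeneRow("T", "chrT1", "+", 999, 5000,
                            c(999, 3999), c(1200, 5000)), rg)
    idx <- loadGeneAnnotation(rg)
    spanning <- mkDel(pos = 900L, end = 2000L, ciLo = 0L, ciHi = 0L,
                      ceLo = 0L, ceHi = 0L)
    intronic <- mkDel(pos = 1300L, end = 1400L, ciLo = 0L, ciHi = 0L,
                      ceLo = 0L, ceHi = 0L)
    intergenic <- mkDel(pos = 10000L, end = 11000L, svtype = "INV")
    got <- exonOverlapClassifier(list(spanning, intronic, intergenic), idx)
    expect_identical(got, c("pathogenic", "benign", "benign"))
})

test_that("the AF spectrum conserves counts and drops intermediates into the 2x2", {
    score <- c("pathogenic", "pathogenic", "benign", "intermediate",
               "unscored", "benign")
    af <- c("rare", "common", "common", "rare", "rare", "missing")
    sp <- afSpectrum(score, af)
    expect_identical(sum(sp$spectrum), 4L)   # defined score AND af only
    expect_identical(unname(sp$contingency),
                     c(1L, 1L, 0L, 1L))
    expect_error(afSpectrum(score, af[-1]), "length")
})

test_that("shuffling AF labels against score classes centres log OR at zero", {
    fx <- sharedFixtures()
    out <- tempfile(fileext = ".vcf")
    scoreCallset(fx$vcf, fx$memTrack, fx$index, out,
                 aggregationConfig("topn", topN = 10L))
    ev <- evaluateScoredVcf(out)
    cls <- ev$classes
    set.seed(99)
    logs <- replicate(200, {
        shuf <- sample(cls$afClass)
        ct <- afSpectrum(cls$scoreClass, shuf)$contingency
        ct <- ct + 0.5
        log((ct[1L] * ct[4L]) / (ct[2L] * ct[3L]))
    })
    se <- stats::sd(logs) / sqrt(length(logs))
    expect_lt(abs(mean(logs)), 3 * se)
})
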