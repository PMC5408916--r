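labelsOf <- function(gr) S4Vectors::mcols(gr)$label

test_that("type-aware interval rules: LEFT/RIGHT always, SPAN only for CNV types", {
    del <- mkDel()
    gr <- resolveIntervals(del)
    expect_identical(labelsOf(gr), c("LEFT", "RIGHT", "SPAN"))
    expect_identical(GenomicRanges::start(gr), c(90L, 195L, 100L))
    expect_identical(GenomicRanges::end(gr), c(105L, 210L, 200L))

    inv <- mkDel(svtype = "INV")
    expect_identical(labelsOf(resolveIntervals(inv)), c("LEFT", "RIGHT"))

    dup <- mkDel(svtype = "DUP")
    expect_identical(labelsOf(resolveIntervals(dup)),
                     c("LEFT", "RIGHT", "SPAN"))

    bnd <- structuralVariant("b1", "BND",
                             breakend("chrT1", 500L, -3L, 3L))
    gr <- resolveIntervals(bnd)
    expect_identical(labelsOf(gr), "LEFT")
    expect_identical(GenomicRanges::start(gr), 497L)
    expect_identical(GenomicRanges::end(gr), 503L)
})

test_that("truncation intervals follow strand and strict containment", {
    rg <- tempfile(fileext = ".txt")
    writeLines(c(
        mkRefgeneRow("PLUS", "chrT1", "+", 999, 3000, 999, 3000),
        mkRefgeneRow("MINUS", "chrT1", "-", 999, 3000, 999, 3000)), rg)
    idx <- loadGeneAnnotation(rg)

    del <- mkDel(pos = 1500L, end = 5000L, ciLo = 0L, ciHi = 0L,
                 ceLo = 0L, ceHi = 0L)
    tr <- resolveTruncationIntervals(del, idx)
    expect_identical(labelsOf(tr), c("LTRUNC", "LTRUNC"))
    expect_identical(S4Vectors::mcols(tr)$transcript, c("MINUS", "PLUS"))
    m <- tr[S4Vectors::mcols(tr)$transcript == "MINUS"]
    p <- tr[S4Vectors::mcols(tr)$transcript == "PLUS"]
    expect_identical(c(GenomicRanges::start(p), GenomicRanges::end(p)),
                     c(1500L, 3000L))
    expect_identical(c(GenomicRanges::start(m), GenomicRanges::end(m)),
                     c(1000L, 1500L))

    ## DUP never truncates, whatever it overlaps
    dup <- mkDel(pos = 1500L, end = 5000L, svtype = "DUP")
    expect_length(resolveTruncationIntervals(dup, idx), 0L)

    ## breakend exactly at txStart is not strictly inside
    edge <- mkDel(pos = 1000L, end = 5000L, ciLo = 0L, ciHi = 0L)
    trE <- resolveTruncationIntervals(edge, idx)
    expect_length(trE, 0L)

    ## right breakend inside -> RTRUNC
    del2 <- mkDel(pos = 10L, end = 2000L, ciLo = 0L, ciHi = 0L,
                  ceLo = 0L, ceHi = 0L)
    tr2 <- resolveTruncationIntervals(del2, idx)
    expect_identical(unique(labelsOf(tr2)), "RTRUNC")

    ## point-event insertion: one truncation per transcript, not two
    ins <- structuralVariant("i1", "INS",
                             breakend("chrT1", 1500L),
                             breakend("chrT1", 1500L))
    trI <- resolveTruncationIntervals(ins, idx)
    expect_identical(labelsOf(trI), c("LTRUNC", "LTRUNC"))
})

test_that("weights ride on CI intervals only and survive clamping", {
    prob <- c(0.1, 0.2, 0.4, 0.2, 0.1)
    del <- mkDel(pos = 100L, end = 200L, ciLo = -2L, ciHi = 2L,
                 ceLo = -1L, ceHi = 1L, prob = prob)
    gr <- resolveIntervals(del)
    w <- S4Vectors::mcols(gr)$weights
    expect_equal(as.numeric(w[[1L]]), prob)
    expect_length(w[[2L]], 0L)   # no PREND given
    expect_length(w[[3L]], 0L)   # SPAN never weighted

    ## unweighted mode drops them
    grU <- resolveIntervals(del, useWeights = FALSE)
    expect_length(S4Vectors::mcols(grU)$weights[[1L]], 0L)

    ## clamping to contig bounds trims interval and weights together
    del2 <- mkDel(pos = 2L, end = 50L, ciLo = -3L, ciHi = 1L,
                  prob = c(1, 2, 3, 4, 5))
    gr2 <- resolveIntervals(del2, contigLengths = c(chrT1 = 45))
    left <- gr2[S4Vectors::mcols(gr2)$label == "LEFT"]
    expect_identical(GenomicRanges::start(left), 1L)
    ## CI spans positions -1..3; clamping drops the out-of-contig head
    expect_equal(as.numeric(S4Vectors::mcols(left)$weights[[1L]]),
                 c(3, 4, 5))
    right <- gr2[S4Vectors::mcols(gr2)$label == "RIGHT"]
    expect_identical(GenomicRanges::end(right), 45L)
})

test_that("interval resolution is deterministic and ordered", {
    fx <- sharedFixtures()
    vs <- variants(pairBndMates(suppressWarnings(parseSvVcf(fx$vcf))))
    for (v in vs[seq_len(25L)]) {
        a <- resolveIntervals(v, fx$index)
        b <- resolveIntervals(v, fx$index)
        expect_identical(as.data.frame(a), as.data.frame(b))
        labs <- labelsOf(a)
        core <- labs[labs %in% c("LEFT", "RIGHT", "SPAN")]
        expect_identical(core,
                         intersect(c("LEFT", "RIGHT", "SPAN"), core))
    }
})

test_that("exon-restricted truncation clips to downstream exonic bases", {
    rg <- tempfile(fileext = ".txt")
    writeLines(mkRefgeneRow("T", "chrT1", "+", 999, 3000,
                            c(999, 1999, 2799), c(1200, 2200, 3000)), rg)
    idx <- loadGeneAnnotation(rg)
    del <- mkDel(pos = 1500L, end = 5000L, ciLo = 0L, ciHi = 0L)
    tr <- resolveTruncationIntervals(del, idx,
                                     exonRestrictedTruncation = TRUE)
    ## downstream of 1500 on '+': exons [2000,2200] and [2800,3000]
    expect_identical(GenomicRanges::start(tr), c(2000L, 2800L))
    expect_identical(GenomicRanges::end(tr), c(2200L, 3000L))
    expect_identical(unique(labelsOf(tr)), "LTRUNC")

    full <- resolveTruncationIntervals(del, idx)
    expect_identical(GenomicRanges::start(full), 1500L)
    expect_identical(GenomicRanges::end(full), 3000L)
})
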