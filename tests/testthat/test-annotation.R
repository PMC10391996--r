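test_that("location categories follow the 50%-overlap rule with precedence", {
    len <- 10000
    gene <- GRanges("chr1", IRanges(2000, 3000), strand = "+",
                    gene_id = "g1", seqlengths = c(chr1 = len))
    ## wholly inside the [500, 1999] promoter window
    p1 <- GRanges("chr1", IRanges(1001, 1200), peak_id = "p1",
                  seqlengths = c(chr1 = len))
    expect_equal(annotatePeakLocations(p1, gene)$location, "promoter")
    ## 99 of 200 bp in the promoter window (49.5% < 50%) and nothing else
    p2 <- GRanges("chr1", IRanges(399, 598), peak_id = "p2",
                  seqlengths = c(chr1 = len))
    expect_equal(annotatePeakLocations(p2, gene)$location, "intergenic")
    ## unknown chromosome errors with the offending id
    pBad <- GRanges("chrX", IRanges(1, 100), peak_id = "bad")
    expect_error(annotatePeakLocations(pBad, gene), "bad")
})

test_that("random instances match the per-base location oracle exactly", {
    for (seed in c(101, 202)) {
        inst <- randomInstance(seed)
        got <- annotatePeakLocations(inst$peaks, inst$genes)$location
        want <- oracleLocations(start(inst$peaks), end(inst$peaks),
                                start(inst$genes), end(inst$genes),
                                as.character(strand(inst$genes)), inst$len)
        expect_identical(got, unname(want))
        ## the categories partition the peak set
        expect_equal(sum(table(got)), length(inst$peaks))
    }
})

test_that("teDHS flagging is boundary-inclusive at 30% and oracle-exact", {
    len <- 1000
    peak <- GRanges("chr1", IRanges(101, 200), peak_id = "p",
                    seqlengths = c(chr1 = len))
    te30 <- GRanges("chr1", IRanges(171, 200), seqlengths = c(chr1 = len))
    te29 <- GRanges("chr1", IRanges(172, 200), seqlengths = c(chr1 = len))
    expect_true(flagTeDHS(peak, te30)[["p"]])
    expect_false(flagTeDHS(peak, te29)[["p"]])

    inst <- randomInstance(303, nPeaks = 1000)
    got <- unname(flagTeDHS(inst$peaks, inst$tes))
    want <- oracleTeFraction(start(inst$peaks), end(inst$peaks),
                             start(inst$tes), end(inst$tes), inst$len) >= 0.3
    expect_identical(got, want)
    ## monotone: growing the TE track never clears a flag
    more <- c(inst$tes, GRanges("chr1", IRanges(5000, 7000),
                                seqlengths = c(chr1 = inst$len)))
    got2 <- unname(flagTeDHS(inst$peaks, more))
    expect_true(all(got2[got]))
})

test_that("nearest-gene distances match gap arithmetic and the exhaustive scan", {
    len <- 1000
    sl <- c(chr1 = len)
    genes <- GRanges("chr1", IRanges(c(150, 300), c(400, 400)),
                     gene_id = c("gA", "gB"), seqlengths = sl)
    peak <- GRanges("chr1", IRanges(100, 200), peak_id = "p", seqlengths = sl)
    nd <- nearestGeneDistance(peak, genes[1])
    expect_equal(nd$distance, 0)
    nd <- nearestGeneDistance(peak, genes[2])
    expect_equal(nd$distance, 99)   # gap bases between [100,200] and [300,400]

    inst <- randomInstance(404, nPeaks = 200)
    got <- nearestGeneDistance(inst$peaks, inst$genes)
    want <- oracleNearest(start(inst$peaks), end(inst$peaks),
                          start(inst$genes), end(inst$genes),
                          inst$genes$gene_id)
    expect_identical(got$nearest_gene, unname(want[, "gene"]))
    expect_identical(got$distance, as.numeric(want[, "distance"]))

    ## peaks on a geneless chromosome get an NA sentinel, with a message
    sl2 <- c(chr1 = len, chr2 = len)
    p2 <- GRanges(c("chr1", "chr2"), IRanges(c(100, 100), c(200, 200)),
                  peak_id = c("a", "b"), seqlengths = sl2)
    g2 <- GRanges("chr1", IRanges(300, 400), gene_id = "g", seqlengths = sl2)
    expect_message(nd2 <- nearestGeneDistance(p2, g2), "undefined")
    expect_true(is.na(nd2$distance[2]))
})

test_that("1-Mb region partition applies the 2x coverage rule", {
    sl <- c(chr1 = 1e6)
    mkCov <- function(frac) {
        n <- round(frac * 10)
        GRanges("chr1", IRanges(seq(1, by = 1e5, length.out = n),
                                width = 1e5), seqlengths = sl)
    }
    r <- partitionRegions(mkCov(0.6), shift(mkCov(0.1), 50), sl)
    expect_equal(r$label, "gene_rich")
    r <- partitionRegions(mkCov(0.2), shift(mkCov(0.2), 50), sl)
    expect_equal(r$label, "balanced")
    ## window larger than the chromosome -> single window spanning it
    r <- partitionRegions(mkCov(0.2), mkCov(0.1), c(chr1 = 5e5),
                          windowSize = 1e6)
    expect_length(r, 1)
    expect_equal(width(r), 5e5)
    expect_error(partitionRegions(mkCov(0.2), mkCov(0.1), sl, windowSize = 0),
                 "parameter error")
})

test_that("simulator region labels are recovered from the emitted intervals", {
    sim <- defaultSim()
    got <- partitionRegions(sim@genes, sim@tes, seqlengths(sim@genes))
    truth <- sim@truth$regionLabels
    expect_equal(length(got), length(truth))
    expect_gte(mean(got$label == truth$label), 0.9)
})

test_that("window signal conserves totals and matches recomputed ratios", {
    sl <- c(chr1 = 10500)
    x <- GRanges("chr1", IRanges(c(100, 4900, 9000), width = c(200, 300, 1400)),
                 seqlengths = sl)
    x$score <- c(10, 20, 30)
    w <- windowSignal(x, sl, 5000)
    expect_length(w, 3)
    expect_equal(width(w), c(5000, 5000, 500))
    expect_equal(sum(w$signal), 60)
    ## interval straddling a boundary is split pro rata
    expect_equal(w$signal[1], 10 + 20 * (5000 - 4900 + 1) / 300)
    ## fold-change track equals the element-wise ratio of recomputed sums
    y <- x; y$score <- c(5, 5, 60)
    wy <- windowSignal(y, sl, 5000)
    fc <- w$signal / wy$signal
    manual <- vapply(seq_len(3), function(i) {
        ws <- start(w)[i]; we <- end(w)[i]
        num <- sum(x$score * pmax(0, pmin(end(x), we) - pmax(start(x), ws) + 1) / width(x))
        den <- sum(y$score * pmax(0, pmin(end(y), we) - pmax(start(y), ws) + 1) / width(y))
        num / den
    }, numeric(1))
    expect_equal(fc, manual, tolerance = 1e-12)
    expect_error(windowSignal(x, sl, -1), "parameter error")
})
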