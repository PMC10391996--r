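test_that("95th-quantile normalization is bounded, idempotent, order-preserving", {
    ## all-zero column untouched
    m <- cbind(a = rep(0, 20), b = seq(0, 19))
    n <- normalize95(m)
    expect_equal(n[, "a"], rep(0, 20))
    expect_true(all(n >= 0 & n <= 1))
    ## q95 = 10: value 5 -> 0.5, value 20 -> 1 (clipped)
    col <- c(rep(1, 90), rep(10, 9), 20, 5)
    q <- quantile(col, 0.95, names = FALSE)
    n2 <- normalize95(matrix(col, ncol = 1))
    expect_equal(n2[length(col)], 5 / q)
    expect_equal(n2[100], 1)   # 20 clips at 1
    ## idempotent when the column q95 is already 1
    m3 <- matrix(c(seq(0, 0.9, length.out = 19), 1, 1), ncol = 1)
    stopifnot(quantile(m3, 0.95, names = FALSE) == 1)
    expect_equal(normalize95(m3), m3)
    ## order within a column preserved up to clipping
    o <- order(m[, "b"])
    expect_true(all(diff(n[o, "b"]) >= 0))
    expect_error(normalize95(matrix(-1)), "non-negative")
})

test_that("k-means recovers well-separated planted groups deterministically", {
    withr::with_seed(4, {
        centers <- matrix(c(0, 0, 5, 5, 0, 5), 3, 2, byrow = TRUE)
        m <- centers[rep(1:3, each = 30), ] + matrix(rnorm(180, 0, 0.3), 90)
        rownames(m) <- paste0("g", 1:90)
    })
    km <- kmeansProfiles(m, k = 3, seed = 1)
    expect_gte(adjustedRand(km$labels, rep(1:3, each = 30)), 0.99)
    ## duplicate rows land together
    m2 <- rbind(m, dup = m[1, ])
    km2 <- kmeansProfiles(m2, k = 3, seed = 1)
    expect_equal(unname(km2$labels["dup"]), unname(km2$labels["g1"]))
    ## determinism
    km3 <- kmeansProfiles(m, k = 3, seed = 1)
    expect_identical(km$labels, km3$labels)
    expect_error(kmeansProfiles(m, k = 100), "exceeds")
})

test_that("rangeability flags minor-magnitude centroids by the either-rule", {
    r <- rangeability(rep(0.5, 12))
    expect_equal(r$expression_range, 0)
    expect_true(r$flagged)
    cent <- c(seq(0, 0.4, length.out = 6), seq(0.5, 0.54, length.out = 6))
    r2 <- rangeability(cent)
    expect_equal(r2$expression_range, 0.4)
    expect_equal(r2$accessibility_range, 0.04, tolerance = 1e-12)
    expect_true(r2$flagged)   # accessibility < 0.05 suffices
    r3 <- rangeability(c(seq(0, 0.4, length.out = 6),
                         seq(0, 0.3, length.out = 6)))
    expect_false(r3$flagged)
})

test_that("region enrichment equals exact hypergeometric enumeration", {
    ## all 20 cluster genes in te_rich, genome 10% te_rich
    region <- setNames(rep(c("te_rich", "gene_rich"), c(20, 180)),
                       paste0("g", 1:200))
    cl <- setNames(rep(c(1L, 2L), c(20, 180)), paste0("g", 1:200))
    r <- regionEnrichment(cl, region)
    row <- r[r$cluster == 1 & r$region == "te_rich", ]
    want <- sum(vapply(20, function(j)
        choose(20, j) * choose(180, 20 - j), numeric(1))) / choose(200, 20)
    expect_equal(row$pvalue, want, tolerance = 1e-10)
    expect_equal(row$fold, (20 / 20) / (20 / 200))
    ## genome-matching composition: fold 1, unremarkable p
    withr::with_seed(17, {
        region2 <- setNames(sample(rep(c("a", "b"), each = 100)),
                            paste0("g", 1:200))
    })
    cl2 <- setNames(rep(1:2, 100), paste0("g", 1:200))
    r2 <- regionEnrichment(cl2, region2)
    expect_true(all(r2$pvalue >= 0.01))
})

test_that("profile clustering separates the planted expression programs", {
    cfg <- simConfig(seed = 31, nChromosomes = 2L, chromosomeLength = 2e6,
                     nGenes = 300L, nTes = 200L, nPeaks = 150L,
                     nPlantedLinks = 0L, nModules = 0L, nTfs = 1L,
                     targetsPerTf = 1L,
                     ovuleHighFraction = 1 / 3,
                     elongationHighFraction = 1 / 3,
                     baseMeanRange = c(180, 220))
    sim <- simulateFiberDataset(cfg)
    labels <- sim@truth$clusterLabels
    labeled <- names(labels)[!is.na(labels)]
    prof <- normalize95(stageMeanProfiles(sim@expression)[labeled, ])
    km <- kmeansProfiles(prof, k = 3, seed = 7)
    expect_gte(adjustedRand(km$labels, labels[labeled]), 0.99)
    ## the planted ovule-high program is enriched in TE-rich regions
    tss <- GRanges(seqnames(sim@genes),
                   IRanges(ifelse(as.character(strand(sim@genes)) == "-",
                                  end(sim@genes), start(sim@genes)),
                           width = 1))
    regions <- sim@truth$regionLabels
    ov <- findOverlaps(tss, regions)
    regionByGene <- setNames(regions$label[subjectHits(ov)],
                             sim@genes$gene_id[queryHits(ov)])
    enr <- regionEnrichment(km$labels, regionByGene[labeled])
    ovCluster <- km$labels[[names(which(labels == "ovule_high"))[1]]]
    row <- enr[enr$cluster == ovCluster & enr$region == "te_rich", ]
    expect_lt(row$pvalue, 0.01)
    expect_gt(row$fold, 1)
})
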