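test_that("configuration validity rejects impossible designs", {
    expect_error(simConfig(chromosomeLength = 5e5), "1e6")
    expect_error(simConfig(linkEffect = 1.2), "0, 1")
    expect_error(simConfig(stages = c(0, 3, 8), ovuleStages = c(0, 3)),
                 "elongation")
    expect_error(simConfig(teDhsFraction = 0.7, promoterPeakFraction = 0.5),
                 "exceed")
    expect_error(simConfig(nGenes = 0), "positive")
})

test_that("the genome emits exactly the requested features, non-overlapping genes", {
    cfg <- smallConfig()
    g <- simulateGenome(cfg)
    expect_length(g$genes, cfg@nGenes)
    expect_length(g$tes, cfg@nTes)
    ## genes never overlap, even across strands (slot construction)
    expect_equal(sum(width(reduce(g$genes, ignore.strand = TRUE))),
                 sum(width(g$genes)))
    ## sequences are uppercase ACGT only
    af <- alphabetFrequency(g$sequences[[1]])
    expect_equal(sum(af[c("A", "C", "G", "T")]), sum(af))
    ## sizing error when the genome cannot hold the genes
    expect_error(simulateGenome(simConfig(nGenes = 5000L,
                                          chromosomeLength = 1e6)),
                 "sizing error")
})

test_that("identical configurations reproduce byte-identical outputs", {
    cfg <- smallConfig()
    d1 <- file.path(tempdir(), "simA")
    d2 <- file.path(tempdir(), "simB")
    p1 <- writeSimulation(simulateFiberDataset(cfg), d1)
    p2 <- writeSimulation(simulateFiberDataset(cfg), d2)
    h1 <- tools::md5sum(unname(p1))
    h2 <- tools::md5sum(unname(p2))
    expect_equal(unname(h1), unname(h2))
})

test_that("TE-rich windows really are TE-dominated (coverage recount)", {
    sim <- defaultSim()
    regions <- sim@truth$regionLabels
    expect_equal(sum(regions$label == "te_rich"),
                 round(0.3 * length(regions)))
    for (i in which(regions$label == "te_rich")) {
        ws <- start(regions)[i]; we <- end(regions)[i]
        chrom <- as.character(seqnames(regions))[i]
        te <- sim@tes[as.character(seqnames(sim@tes)) == chrom]
        gn <- sim@genes[as.character(seqnames(sim@genes)) == chrom]
        teCov <- oracleCoveredBases(start(te), end(te), ws, we)
        gnCov <- oracleCoveredBases(start(gn), end(gn), ws, we)
        expect_gt(teCov, gnCov)
    }
})

test_that("peak construction honors the teDHS and promoter placement rules", {
    sim <- smallSim()
    ## per-chromosome merged-coverage recount of each peak's TE overlap
    frac <- vapply(seq_along(sim@peaks), function(i) {
        chrom <- as.character(seqnames(sim@peaks))[i]
        te <- sim@tes[as.character(seqnames(sim@tes)) == chrom]
        w <- width(sim@peaks)[i]
        cov <- oracleCoveredBases(start(te), end(te),
                                  start(sim@peaks)[i], end(sim@peaks)[i])
        cov / w
    }, numeric(1))
    expect_true(all(frac[sim@peaks$te_dhs] >= 0.3))
    expect_true(all(frac[!sim@peaks$te_dhs] < 0.3))
    ## promoter peaks sit wholly inside a 1.5-kb upstream window
    prom <- suppressWarnings(GenomicRanges::trim(
        promoters(sim@genes, upstream = 1500, downstream = 0)))
    inProm <- overlapsAny(sim@peaks[sim@peaks$type == "promoter"], prom,
                          type = "within")
    expect_true(all(inProm))
})

test_that("replicate peak interval counts follow stages x replicates", {
    cfg <- simConfig(seed = 3, nChromosomes = 1L, chromosomeLength = 2e6,
                     nGenes = 50L, nTes = 60L, nPeaks = 200L,
                     docrFraction = 0, peakDropout = 0,
                     nPlantedLinks = 0L, nModules = 0L, nTfs = 1L,
                     targetsPerTf = 1L, ovuleHighFraction = 0.1,
                     elongationHighFraction = 0.1)
    ## one edge peak carries a non-constitutive pattern sometimes; force all
    peaks <- simulatePeaks(simulateGenome(cfg), cfg)
    perStage <- table(peaks$replicates$stage, peaks$replicates$replicate)
    total <- length(peaks$replicates)
    presentPerStage <- vapply(cfg@stages, function(s)
        sum(vapply(peaks$stagePresence, function(p) s %in% p, logical(1))),
        numeric(1))
    expect_equal(total, sum(presentPerStage) * cfg@accReplicates)
    ## with every peak constitutive this is exactly nPeaks * 6 * 2
    if (all(presentPerStage == cfg@nPeaks))
        expect_equal(total, 200L * 6L * 2L)
})

test_that("counts are NB with the configured moments and planted correlations", {
    ## noiseless limit: latent stage-mean correlation is exactly +/- 1
    cfg <- smallConfig(linkEffect = 1, nbDispersion = 0)
    sim <- simulateFiberDataset(cfg)
    links <- sim@truth$links
    for (i in seq_len(nrow(links))) {
        r <- cor(sim@truth$accLatentMeans[links$peak_id[i], ],
                 sim@truth$exprLatentMeans[links$gene_id[i], ])
        expect_equal(r, links$sign[i] * 1, tolerance = 1e-9)
    }
    m <- countsMatrix(sim@expression)
    expect_true(all(m >= 0) && all(m == round(m)))

    ## Monte-Carlo moment check: var ~= mu + 0.1 mu^2 across null features
    cfgNull <- simConfig(seed = 7, nChromosomes = 2L,
                         chromosomeLength = 2.5e6, nGenes = 800L,
                         nTes = 50L, nPeaks = 50L, nbDispersion = 0.1,
                         nPlantedLinks = 0L, nModules = 0L, nTfs = 1L,
                         targetsPerTf = 1L, ovuleHighFraction = 0,
                         elongationHighFraction = 0, flatCv = 0,
                         depthVariation = 0, docrFraction = 0)
    genome <- simulateGenome(cfgNull)
    peaks <- simulatePeaks(genome, cfgNull)
    counts <- simulateCounts(genome, peaks, cfgNull)
    m <- countsMatrix(counts$expression)
    keep <- genome$genes$class == "flat"
    m <- m[keep, , drop = FALSE]
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    alphaHat <- sum((v - mu) * mu^2) / sum(mu^4)
    expect_lt(abs(alphaHat - 0.1), 0.012)
})

test_that("motif models are proper PWMs and consensi are planted verbatim", {
    sim <- smallSim()
    for (m in sim@motifs) {
        expect_equal(unname(colSums(m@matrix)), rep(1, motifLength(m)),
                     tolerance = 1e-9)
    }
    edges <- sim@truth$edges
    hits <- sim@truth$plantedHits
    expect_equal(length(hits), nrow(edges))
    for (i in seq_along(hits)) {
        chrom <- as.character(seqnames(hits))[i]
        found <- as.character(subseq(sim@sequences[[chrom]],
                                     start(hits)[i], end(hits)[i]))
        tf <- sim@motifTfMap$tf_gene[sim@motifTfMap$motif_id == hits$motif_id[i]]
        cons <- motifConsensus(sim@motifs[[hits$motif_id[i]]])
        expect_equal(found, cons)
    }
    ## scanning the emitted sequences recovers >= 95% of planted occurrences
    peakSeqs <- lapply(seq_along(sim@peaks), function(i) {
        chrom <- as.character(seqnames(sim@peaks))[i]
        as.character(subseq(sim@sequences[[chrom]], start(sim@peaks)[i],
                            end(sim@peaks)[i]))
    })
    names(peakSeqs) <- sim@peaks$peak_id
    found <- scanSequences(peakSeqs, sim@motifs)
    recovered <- vapply(seq_along(hits), function(i) {
        pid <- hits$peak_id[i]
        offset <- start(sim@peaks)[match(pid, sim@peaks$peak_id)] - 1L
        any(as.character(seqnames(found)) == pid &
            found$motif_id == hits$motif_id[i] &
            start(found) + offset == start(hits)[i])
    }, logical(1))
    expect_gte(mean(recovered), 0.95)
})
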