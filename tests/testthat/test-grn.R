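toyNetworkParts <- function() {
    sl <- c(chr1 = 50000)
    genes <- GRanges("chr1", IRanges(c(10000, 30000), width = 1000),
                     strand = c("+", "+"), gene_id = c("g1", "g2"),
                     seqlengths = sl)
    ## peak wholly inside g1's promoter window [8500, 9999]
    peaks <- GRanges("chr1", IRanges(c(9000, 7000), width = c(300, 400)),
                     peak_id = c("pkProm", "pkFar"), seqlengths = sl)
    hits <- GRanges("chr1", IRanges(c(9100, 7100), width = 8), strand = "+",
                    motif_id = c("m1", "m1"), seqlengths = sl)
    list(sl = sl, genes = genes, peaks = peaks, hits = hits,
         presence = list(pkProm = c(0, 8), pkFar = c(0, 3, 8, 12, 15, 18)),
         map = data.frame(motif_id = "m1", tf_gene = "tfA"))
}

test_that("DNase edges require promoter-window DHSs containing a mapped hit", {
    tp <- toyNetworkParts()
    net <- buildDnaseNetwork(tp$hits, tp$peaks, tp$presence, tp$genes, tp$map)
    ## pkProm yields tfA -> g1 at its presence stages; pkFar (2 kb upstream
    ## beyond the window) yields nothing
    expect_equal(sort(unique(net$stage)), c(0, 8))
    expect_equal(unique(net$tf), "tfA")
    expect_equal(unique(net$target), "g1")
    expect_false("pkFar" %in% net$peak_id)
    ## a motif mapped to two TFs fans out to two edges
    map2 <- data.frame(motif_id = c("m1", "m1"), tf_gene = c("tfA", "tfB"))
    net2 <- buildDnaseNetwork(tp$hits, tp$peaks, tp$presence, tp$genes, map2)
    expect_setequal(unique(net2$tf), c("tfA", "tfB"))
    ## unmapped motifs are ignored but counted
    net3 <- buildDnaseNetwork(tp$hits, tp$peaks, tp$presence, tp$genes,
                              data.frame(motif_id = "mX", tf_gene = "tfX"))
    expect_equal(nrow(net3), 0)
    expect_equal(attr(net3, "unmappedHits"), 2)
})

test_that("the merge is exactly the DNase/co-expression intersection", {
    dnase <- data.frame(
        tf = c("tfA", "tfA", "tfB"), target = c("g1", "g2", "g1"),
        stage = c(0, 8, 12), peak_id = "pk", motif_id = "m1")
    coexpr <- data.frame(gene_a = c("g1", "g2"), gene_b = c("tfA", "zz"),
                         pcc = c(0.9, 0.5), rank_ab = 1L, rank_ba = 1L,
                         mr = 1, sign = c("+", "+"))
    merged <- mergeNetworks(dnase, coexpr)
    expect_equal(nrow(merged), 1)
    expect_equal(merged$tf, "tfA")
    expect_equal(merged$target, "g1")
    expect_equal(merged$sign, "+")
    ## brute-force set intersection on pairs
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    dnPairs <- unique(paste(dnase$tf, dnase$target))
    coPairs <- pairKey(coexpr$gene_a, coexpr$gene_b)
    wantN <- sum(vapply(strsplit(dnPairs, " "), function(p)
        pairKey(p[1], p[2]) %in% coPairs, logical(1)))
    expect_equal(nrow(merged), wantN)
    ## positive-sign-only mode drops negative support
    coexprNeg <- coexpr; coexprNeg$sign <- c("-", "+")
    expect_equal(nrow(mergeNetworks(dnase, coexprNeg,
                                    requirePositive = TRUE)), 0)
})

test_that("edge stage categories follow ordered first-match rules", {
    expect_equal(classifyEdgeStage(0), "ovule")
    expect_equal(classifyEdgeStage(c(0, 3)), "ovule")
    expect_equal(classifyEdgeStage(8), "early_elongation")
    expect_equal(classifyEdgeStage(c(0, 8)), "early_elongation")
    expect_equal(classifyEdgeStage(c(0, 12)), "fiber_and_ovule")
    expect_equal(classifyEdgeStage(c(8, 15)), "fiber")
    expect_equal(classifyEdgeStage(c(12, 18)), "late_elongation")
    expect_equal(classifyEdgeStage("0;3;8;12"), "fiber_and_ovule")
    expect_error(classifyEdgeStage(numeric()), "empty")
    ## total on every non-empty subset of the six stages
    stages <- c(0, 3, 8, 12, 15, 18)
    labels <- c("ovule", "fiber_and_ovule", "fiber", "early_elongation",
                "late_elongation", "other")
    for (mask in 1:63) {
        s <- stages[as.logical(bitwAnd(mask, 2^(0:5)))]
        expect_true(classifyEdgeStage(s) %in% labels)
    }
})

test_that("degrees and hubs count distinct partners with stated tie-breaks", {
    edges <- data.frame(tf = c("A", "A", "A", "B", "C"),
                        target = c("x", "y", "z", "A", "x"))
    dh <- degreeAndHubs(edges, k = 2)
    degA <- dh$degrees[dh$degrees$id == "A", ]
    expect_equal(degA$out_degree, 3)
    expect_equal(degA$in_degree, 1)
    expect_equal(dh$hubs$id[1], "A")
    ## zero out-degree nodes never precede positive ones
    expect_true(all(diff(dh$degrees$out_degree) <= 0))
    expect_error(degreeAndHubs(edges[0, ]), "empty")
})

test_that("TF activity scores standardize motif-DHS accessibility per stage", {
    m <- matrix(rep(c(10L, 10L, 10L, 10L, 10L, 10L), each = 2), 2, 6,
                byrow = FALSE)
    m <- rbind(m, m)
    rownames(m) <- paste0("pk", 1:4)
    acc <- StageCounts(m, stage = rep(c(0, 3, 8), each = 2),
                       replicate = rep(1:2, 3))
    ht <- data.frame(peak_id = c("pk1", "pk2"), motif_id = "m1")
    map <- data.frame(motif_id = "m1", tf_gene = "tfA")
    z <- tfActivityScore("tfA", acc, ht, map)
    expect_equal(unname(z), rep(0, 3))
    ## doubled accessibility at one stage -> unique maximum there
    m2 <- m; m2[c(1, 2), 5:6] <- 40L
    acc2 <- StageCounts(m2, stage = rep(c(0, 3, 8), each = 2),
                        replicate = rep(1:2, 3))
    z2 <- tfActivityScore("tfA", acc2, ht, map)
    expect_equal(names(which.max(z2)), "8")
    ## no motif-bearing DHS -> NA sentinel with message
    expect_message(z3 <- tfActivityScore("tfB", acc, ht, map), "undefined")
    expect_true(all(is.na(z3)))
})

test_that("planted regulatory edges survive the full network pipeline", {
    sim <- smallSim()
    peakSeqs <- lapply(seq_along(sim@peaks), function(i) {
        chrom <- as.character(seqnames(sim@peaks))[i]
        as.character(subseq(sim@sequences[[chrom]], start(sim@peaks)[i],
                            end(sim@peaks)[i]))
    })
    names(peakSeqs) <- sim@peaks$peak_id
    local <- scanSequences(peakSeqs, sim@motifs)
    idx <- match(as.character(seqnames(local)), sim@peaks$peak_id)
    hits <- GRanges(seqnames(sim@peaks)[idx],
                    IRanges(start(sim@peaks)[idx] + start(local) - 1L,
                            width = width(local)),
                    strand = strand(local),
                    motif_id = local$motif_id,
                    seqlengths = seqlengths(sim@peaks))
    dnase <- buildDnaseNetwork(hits, sim@peaks, sim@truth$stagePresence,
                               sim@genes, sim@motifTfMap)
    p <- pccMatrix(sim@expression)
    net <- buildCoexpressionNetwork(mutualRank(p), p)
    merged <- mergeNetworks(dnase, net)
    truthKey <- paste(sim@truth$edges$tf_gene, sim@truth$edges$target_gene)
    gotKey <- paste(merged$tf, merged$target)
    expect_gte(mean(truthKey %in% gotKey), 0.8)
    ## final network pairs are a subset of DNase pairs with coexpr support
    dnKey <- paste(dnase$tf, dnase$target)
    coKey <- paste(pmin(net$gene_a, net$gene_b),
                   pmax(net$gene_a, net$gene_b))
    expect_true(all(gotKey %in% dnKey))
    expect_true(all(paste(pmin(merged$tf, merged$target),
                          pmax(merged$tf, merged$target)) %in% coKey))
    ## recovered stage sets equal the planted presence patterns
    m <- merge(merged, sim@truth$edges,
               by.x = c("tf", "target"), by.y = c("tf_gene", "target_gene"))
    expect_true(all(m$stages.x == m$stages.y))
})
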