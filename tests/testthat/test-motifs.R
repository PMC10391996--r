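uniformMotif <- function(L = 6, id = "u") {
    motifModel(id, matrix(0.25, 4, L), pseudocount = 0)
}

strongMotif <- function(consensus, id = "s", p = 0.91, pseudocount = 0.01) {
    bases <- c("A", "C", "G", "T")
    L <- nchar(consensus)
    m <- matrix((1 - p) / 3, 4, L, dimnames = list(bases, NULL))
    m[cbind(match(strsplit(consensus, "")[[1]], bases), seq_len(L))] <- p
    motifModel(id, m, pseudocount = pseudocount)
}

test_that("log-odds scores equal the hand formula", {
    ## certain base, uniform background, no pseudocount -> +2 bits
    m <- motifModel("m", cbind(c(1, 0, 0, 0), matrix(0.25, 4, 4)),
                    pseudocount = 0)
    lo <- buildLogOdds(m)
    expect_equal(unname(lo["A", 1]), 2)
    expect_equal(unname(lo[, 2]), rep(0, 4))
    ## random PWM vs element-wise formula
    withr::with_seed(8, {
        p <- matrix(rexp(4 * 7), 4)
        p <- sweep(p, 2, colSums(p), "/")
    })
    m <- motifModel("r", p, pseudocount = 0.05, background = c(.3, .2, .2, .3))
    lo <- buildLogOdds(m)
    want <- log2((p + 0.05 * c(.3, .2, .2, .3)) /
                 (1.05 * c(.3, .2, .2, .3)))
    expect_equal(unname(lo), unname(want), tolerance = 1e-12)
    mBad <- m; mBad@background <- c(0, 0.5, 0.25, 0.25)
    expect_error(buildLogOdds(mBad), "parameter error")
})

test_that("DP score p-values equal exhaustive enumeration over all words", {
    withr::with_seed(12, {
        p <- matrix(rexp(4 * 5), 4)
        p <- sweep(p, 2, colSums(p), "/")
    })
    m <- motifModel("e", p, pseudocount = 0.01,
                    background = c(0.3, 0.2, 0.2, 0.3))
    grain <- 1e-3
    ilo <- round(buildLogOdds(m) / grain)
    words <- as.matrix(expand.grid(rep(list(1:4), 5)))
    scores <- rowSums(matrix(ilo[cbind(as.vector(words),
                                       rep(1:5, each = nrow(words)))],
                             nrow(words)))
    probs <- apply(words, 1, function(w) prod(c(0.3, 0.2, 0.2, 0.3)[w]))
    dist <- motifScoreDistribution(m, grain)
    for (s in sort(unique(scores))) {
        want <- sum(probs[scores >= s])
        got <- scorePvalue(m, s * grain, dist = dist)
        expect_equal(got, want, tolerance = 1e-12)
    }
    ## extremes
    expect_equal(scorePvalue(m, min(scores) * grain - 1), 1)
    expect_equal(scorePvalue(m, max(scores) * grain + 1), 0)
    ## monotone non-increasing in score
    grid <- seq(min(scores), max(scores)) * grain
    expect_true(all(diff(scorePvalue(m, grid, dist = dist)) <= 1e-15))
})

test_that("scanning finds embedded consensi and is strand-symmetric", {
    ## the minimum achievable p-value is 4^-L, so an L=8 motif is needed for
    ## hits to clear the 1e-4 default threshold
    m <- strongMotif("ACGTACGT")
    withr::with_seed(3, {
        seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                     collapse = "")
    })
    seq <- paste0(substr(seq, 1, 9), "ACGTACGT", substr(seq, 18, 60))
    hits <- scanSequence(seq, m)
    expect_true(any(hits$start == 10 & hits$strand == "+"))
    ## reverse complement: mirrored coordinates, same scores
    rc <- as.character(reverseComplement(DNAString(seq)))
    hitsRc <- scanSequence(rc, m)
    n <- nchar(seq)
    mirrored <- data.frame(start = n - hitsRc$end + 1,
                           end = n - hitsRc$start + 1,
                           strand = ifelse(hitsRc$strand == "+", "-", "+"),
                           score = hitsRc$score)
    o1 <- order(hits$start, hits$strand)
    o2 <- order(mirrored$start, mirrored$strand)
    expect_equal(hits$start[o1], mirrored$start[o2])
    expect_equal(hits$strand[o1], mirrored$strand[o2])
    expect_equal(hits$score[o1], mirrored$score[o2])
    ## windows containing N are skipped; short sequences yield nothing
    expect_equal(nrow(scanSequence("ACGTNACG", m)), 0)
    expect_equal(nrow(scanSequence("ACG", m)), 0)
})

test_that("hit sets equal brute-force window scoring at the threshold", {
    m <- strongMotif("GATTAC", p = 0.7)
    withr::with_seed(21, {
        seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                     collapse = "")
    })
    grain <- 1e-3
    dist <- motifScoreDistribution(m, grain)
    got <- scanSequence(seq, m, pThreshold = 0.02, grain = grain)
    ilo <- round(buildLogOdds(m) / grain)
    iloRc <- ilo[4:1, 6:1]
    codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
    want <- list()
    for (i in seq_len(nchar(seq) - 5)) {
        w <- codes[i:(i + 5)]
        for (strand in c("+", "-")) {
            mat <- if (strand == "+") ilo else iloRc
            s <- sum(mat[cbind(w, 1:6)])
            if (scorePvalue(m, s * grain, dist = dist) <= 0.02)
                want[[length(want) + 1]] <- data.frame(
                    start = i, strand = strand, score = s * grain)
        }
    }
    want <- do.call(rbind, want)
    expect_gt(nrow(want), 0)
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
})

test_that("hits are assigned to peaks only by full containment", {
    sl <- c(chr1 = 1000)
    peaks <- GRanges("chr1", IRanges(91, 200), peak_id = "pk",
                     seqlengths = sl)
    hits <- GRanges("chr1", IRanges(c(101, 96, 191), width = 10),
                    strand = "+", motif_id = "m", seqlengths = sl)
    got <- assignHitsToPeaks(hits, peaks)
    ## [101,110] inside; [96,105] inside [91,200]; [191,200] touches the end
    expect_equal(nrow(got), 3)
    hits2 <- GRanges("chr1", IRanges(c(85, 195), width = 10), strand = "+",
                     motif_id = "m", seqlengths = sl)
    expect_equal(nrow(assignHitsToPeaks(hits2, peaks)), 0)

    ## random instance vs brute-force containment
    inst <- randomInstance(31, nPeaks = 100)
    withr::with_seed(32, {
        hs <- sample.int(inst$len - 12, 300)
    })
    hr <- GRanges("chr1", IRanges(hs, width = 8), strand = "+",
                  motif_id = "m", seqlengths = c(chr1 = inst$len))
    got <- assignHitsToPeaks(hr, inst$peaks)
    want <- 0L
    for (i in seq_along(hr)) for (j in seq_along(inst$peaks))
        if (start(hr)[i] >= start(inst$peaks)[j] &&
            end(hr)[i] <= end(inst$peaks)[j]) want <- want + 1L
    expect_equal(nrow(got), want)
})

test_that("hypergeometric enrichment matches exact combinatorial counts", {
    ## N=10, K=5, n=5, k=5 -> 1/C(10,5)
    universe <- paste0("p", 1:10)
    fg <- paste0("p", 1:5)
    hitTable <- data.frame(peak_id = paste0("p", 1:5), motif_id = "m")
    r <- hypergeometricEnrichment(fg, universe, hitTable)
    expect_equal(r$pvalue, 1 / choose(10, 5), tolerance = 1e-12)
    expect_equal(r$k, 5); expect_equal(r$K, 5)
    expect_equal(r$fold, 2)
    ## k = 0 -> p = 1
    r0 <- hypergeometricEnrichment(paste0("p", 6:10), universe, hitTable)
    expect_equal(r0$pvalue, 1)
    expect_error(hypergeometricEnrichment(character(), universe, hitTable),
                 "empty foreground")
    ## random small instances vs pmf enumeration
    withr::with_seed(14, {
        for (rep in 1:20) {
            N <- sample(8:25, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
            uni <- paste0("q", seq_len(N))
            fgIds <- sample(uni, n)
            withHit <- sample(uni, K)
            ht <- data.frame(peak_id = withHit,
                             motif_id = rep("m", K))
            if (!K) ht <- data.frame(peak_id = "none_such", motif_id = "m")
            r <- hypergeometricEnrichment(fgIds, uni, ht)
            k <- r$k
            want <- sum(vapply(k:n, function(j)
                choose(r$K, j) * choose(N - r$K, n - j), numeric(1))) /
                choose(N, n)
            if (k > r$K) want <- 0
            expect_equal(r$pvalue, min(1, want), tolerance = 1e-10)
        }
    })
})

test_that("the teDHS enrichment ratio averages folds per compartment", {
    expect_equal(teEnrichmentRatio(rep(1.5, 6), rep(1.5, 6)), 1)
    expect_equal(teEnrichmentRatio(rep(2, 6), rep(1, 6)), 2)
    expect_message(r <- teEnrichmentRatio(c(2, 2), c(0, 0)), "undefined")
    expect_true(is.na(r))
})
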