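suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

## A small, fast configuration exercising every planted structure.
smallConfig <- function(...) {
    simConfig(seed = 11, nChromosomes = 2L, chromosomeLength = 1e6,
              nGenes = 60L, nTes = 100L, nPeaks = 100L,
              nPlantedLinks = 10L, nModules = 5L, moduleSize = 3L,
              nTfs = 3L, targetsPerTf = 2L,
              ovuleHighFraction = 0.2, elongationHighFraction = 0.2, ...)
}

## Memoised fixtures (built once per test run).
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}
smallSim <- function() fixture("smallSim",
    function() simulateFiberDataset(smallConfig()))
defaultSim <- function() fixture("defaultSim",
    function() simulateFiberDataset(simConfig(seed = 1)))

## ---------------------------------------------------------------------------
## Independent brute-force oracles (no package internals)
## ---------------------------------------------------------------------------

## Logical per-base mask of a set of [start, end] 1-based intervals.
baseMask <- function(starts, ends, len) {
    m <- logical(len)
    for (i in seq_along(starts)) {
        s <- max(1L, starts[i]); e <- min(len, ends[i])
        if (s <= e) m[s:e] <- TRUE
    }
    m
}

## Per-base location oracle: promoter/genic/downstream >= minOverlap of the
## peak, precedence promoter > genic > downstream, else intergenic.
oracleLocations <- function(peakStart, peakEnd, geneStart, geneEnd,
                            geneStrand, len, promoterWidth = 1500,
                            downstreamWidth = 1500, minOverlap = 0.5) {
    promS <- ifelse(geneStrand == "+", geneStart - promoterWidth, geneEnd + 1)
    promE <- ifelse(geneStrand == "+", geneStart - 1, geneEnd + promoterWidth)
    downS <- ifelse(geneStrand == "+", geneEnd + 1, geneStart - downstreamWidth)
    downE <- ifelse(geneStrand == "+", geneEnd + downstreamWidth, geneStart - 1)
    masks <- list(promoter = baseMask(promS, promE, len),
                  genic = baseMask(geneStart, geneEnd, len),
                  downstream = baseMask(downS, downE, len))
    vapply(seq_along(peakStart), function(i) {
        span <- peakStart[i]:peakEnd[i]
        w <- length(span)
        for (cls in c("promoter", "genic", "downstream"))
            if (sum(masks[[cls]][span]) >= minOverlap * w) return(cls)
        "intergenic"
    }, character(1))
}

## Per-base TE-coverage fraction oracle.
oracleTeFraction <- function(peakStart, peakEnd, teStart, teEnd, len) {
    m <- baseMask(teStart, teEnd, len)
    vapply(seq_along(peakStart), function(i) {
        span <- peakStart[i]:peakEnd[i]
        sum(m[span]) / length(span)
    }, numeric(1))
}

## Exhaustive nearest-gene oracle (gap bp; ties -> smaller gene start).
oracleNearest <- function(peakStart, peakEnd, geneStart, geneEnd, geneIds) {
    t(vapply(seq_along(peakStart), function(i) {
        gaps <- vapply(seq_along(geneStart), function(j) {
            if (peakEnd[i] >= geneStart[j] && peakStart[i] <= geneEnd[j]) 0
            else if (peakStart[i] > geneEnd[j]) peakStart[i] - geneEnd[j] - 1
            else geneStart[j] - peakEnd[i] - 1
        }, numeric(1))
        best <- which(gaps == min(gaps))
        best <- best[which.min(geneStart[best])]
        c(gene = geneIds[best], distance = min(gaps))
    }, c(gene = "", distance = "")))
}

## Merged total covered bases of [s, e] intervals intersected with a window.
oracleCoveredBases <- function(starts, ends, winStart, winEnd) {
    s <- pmax(starts, winStart); e <- pmin(ends, winEnd)
    keep <- s <= e
    if (!any(keep)) return(0L)
    o <- order(s[keep]); s <- s[keep][o]; e <- e[keep][o]
    tot <- 0L; cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
        if (s[i] > ce + 1) { tot <- tot + ce - cs + 1L; cs <- s[i]; ce <- e[i] }
        else ce <- max(ce, e[i])
    }
    tot + ce - cs + 1L
}

## Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    expected <- ai * bj / choose(n, 2)
    (sumij - expected) / ((ai + bj) / 2 - expected)
}

## Random toy annotation instance on a short chromosome.
randomInstance <- function(seed, len = 10000, nGenes = 50, nPeaks = 500,
                           nTes = 60) {
    withr::with_seed(seed, {
        gw <- sample(100:1000, nGenes, replace = TRUE)
        gs <- sample.int(len - max(gw), nGenes, replace = TRUE)
        pw <- sample(20:300, nPeaks, replace = TRUE)
        ps <- sample.int(len - max(pw), nPeaks, replace = TRUE)
        tw <- sample(30:500, nTes, replace = TRUE)
        ts <- sample.int(len - max(tw), nTes, replace = TRUE)
        list(
            len = len,
            genes = GRanges("chr1", IRanges(gs, width = gw),
                            strand = sample(c("+", "-"), nGenes, TRUE),
                            gene_id = sprintf("g%03d", seq_len(nGenes)),
                            seqlengths = c(chr1 = len)),
            peaks = GRanges("chr1", IRanges(ps, width = pw),
                            peak_id = sprintf("p%03d", seq_len(nPeaks)),
                            seqlengths = c(chr1 = len)),
            tes = GRanges("chr1", IRanges(ts, width = tw),
                          seqlengths = c(chr1 = len)))
    })
}
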