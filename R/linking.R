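## Correlation-based peak-to-gene linking: 50-kb candidate pairs, observed
## stage-profile Pearson correlation, pooled random-peak empirical null,
## z-score with a one-sided test, and the four-way DOCR classification.

#' Enumerate candidate peak-gene pairs within a distance window
#'
#' A pair is emitted iff the peak interval lies within \code{window} bp of
#' the gene body (overlap counts as distance 0; the 50,000-bp boundary is
#' inclusive).
#'
#' @param peaks,genes GRanges with \code{peak_id} / \code{gene_id}.
#' @param window maximum gap in bp (default 50000).
#' @return data.frame with \code{peak_id}, \code{gene_id}, \code{distance}
#'   (gap bp, 0 when overlapping), and \code{signed_distance} (peak midpoint
#'   minus TSS, strand-agnostic genome orientation).
#' @export
enumerateCandidatePairs <- function(peaks, genes, window = 5e4) {
    hits <- findOverlaps(peaks, genes, maxgap = window, ignore.strand = TRUE)
    p <- peaks[queryHits(hits)]
    g <- genes[subjectHits(hits)]
    d <- distance(p, g, ignore.strand = TRUE)
    mid <- floor((start(p) + end(p)) / 2)
    data.frame(peak_id = .peakIds(p), gene_id = g$gene_id,
               distance = as.numeric(d),
               signed_distance = mid - tssPositions(g),
               stringsAsFactors = FALSE)
}

#' Pearson correlation of two stage profiles
#'
#' Profiles are size-factor-normalized counts averaged over replicates per
#' stage (see [stageMeanProfiles()]); a constant profile makes the
#' correlation undefined and returns \code{NA}.
#'
#' @param peakProfile,geneProfile numeric stage profiles of equal length.
#' @return Pearson r in \[-1, 1\], or NA for a constant profile.
#' @export
stageProfileCorrelation <- function(peakProfile, geneProfile) {
    if (sd(peakProfile) == 0 || sd(geneProfile) == 0) {
        message("constant stage profile: correlation undefined, pair skipped")
        return(NA_real_)
    }
    cor(peakProfile, geneProfile)
}

#' Build the pooled empirical null for link correlations
#'
#' Samples \code{n} random peaks from the eligible pool (peaks within 50 kb
#' of any gene body) -- without replacement, or with replacement when the
#' pool is smaller than \code{n} -- and pools the Pearson correlations of
#' each sampled peak's stage profile against every gene's. The pool mean
#' (expected.mean) and standard deviation (expected.std) standardize
#' observed correlations.
#'
#' @param peakProfiles,geneProfiles feature x stage matrices
#'   ([stageMeanProfiles()]).
#' @param n number of random peaks (default 10000).
#' @param seed sampling seed.
#' @return A [NullModel-class].
#' @export
buildEmpiricalNull <- function(peakProfiles, geneProfiles, n = 10000L,
                               seed = 1L) {
    if (nrow(geneProfiles) < 2)
        stop("null-model error: need >= 2 genes")
    nPool <- nrow(peakProfiles)
    idx <- withr::with_seed(as.integer(seed),
        sample.int(nPool, n, replace = nPool < n))
    keepP <- apply(peakProfiles[idx, , drop = FALSE], 1, sd) > 0
    keepG <- apply(geneProfiles, 1, sd) > 0
    rs <- cor(t(peakProfiles[idx[keepP], , drop = FALSE]),
              t(geneProfiles[keepG, , drop = FALSE]))
    rs <- as.numeric(rs)
    if (!length(rs) || sd(rs) == 0)
        stop("null-model error: degenerate correlation pool ",
             "(expected.std = 0)")
    new("NullModel", mean = mean(rs), sd = sd(rs), n = as.integer(n),
        poolSize = length(rs), sample = head(rs, 10000L),
        seed = as.integer(seed))
}

#' z-score link test against the empirical null
#'
#' \code{z = (observed - expected.mean) / expected.std}, with a one-sided
#' upper-tail normal p-value. In the default \code{twoDirection} mode the
#' same one-sided test is applied symmetrically to the mirrored deviation,
#' so repressive (negative-r) links can also reach significance; set
#' \code{twoDirection = FALSE} for the strict positive-direction test.
#'
#' @param observed observed Pearson r (vectorized).
#' @param null A [NullModel-class].
#' @param twoDirection admit negative-direction links (default TRUE).
#' @param alpha significance threshold on p (default 0.05).
#' @return data.frame with \code{observed}, \code{z}, \code{pvalue},
#'   \code{significant}, \code{sign}.
#' @export
zLinkTest <- function(observed, null, twoDirection = TRUE, alpha = 0.05) {
    z <- (observed - null@mean) / null@sd
    p <- if (twoDirection) pnorm(abs(z), lower.tail = FALSE)
         else pnorm(z, lower.tail = FALSE)
    data.frame(observed = observed, z = z, pvalue = p,
               significant = !is.na(p) & p < alpha,
               sign = ifelse(observed >= 0, "+", "-"),
               stringsAsFactors = FALSE)
}

#' Link peaks to genes via the empirical-null correlation test
#'
#' Convenience wrapper: enumerates candidate pairs, computes observed
#' stage-profile correlations, builds (or reuses) the empirical null from
#' the supplied eligible peak pool, and applies [zLinkTest()].
#'
#' @param pairs data.frame from [enumerateCandidatePairs()].
#' @param peakProfiles,geneProfiles stage-mean profile matrices.
#' @param null optional precomputed [NullModel-class]; built from
#'   \code{peakProfiles} when NULL.
#' @param nRandom,seed empirical-null parameters.
#' @param twoDirection,alpha test parameters (see [zLinkTest()]).
#' @return data.frame of per-pair link results (pairs with a constant
#'   profile are dropped with a message).
#' @export
linkPeaksToGenes <- function(pairs, peakProfiles, geneProfiles, null = NULL,
                             nRandom = 10000L, seed = 1L,
                             twoDirection = TRUE, alpha = 0.05) {
    if (is.null(null))
        null <- buildEmpiricalNull(peakProfiles, geneProfiles, n = nRandom,
                                   seed = seed)
    ps <- peakProfiles[pairs$peak_id, , drop = FALSE]
    gs <- geneProfiles[pairs$gene_id, , drop = FALSE]
    ok <- apply(ps, 1, sd) > 0 & apply(gs, 1, sd) > 0
    if (any(!ok))
        message(sum(!ok), " pair(s) with constant profiles skipped")
    r <- rep(NA_real_, nrow(pairs))
    r[ok] <- vapply(which(ok), function(i) cor(ps[i, ], gs[i, ]), numeric(1))
    res <- cbind(pairs[ok, , drop = FALSE],
                 zLinkTest(r[ok], null, twoDirection, alpha))
    rownames(res) <- NULL
    attr(res, "null") <- null
    res
}

#' Classify significant links into the four DOCR groups
#'
#' Combines the accessibility direction of the DOCR and the expression
#' direction of the linked gene: down/down = ovule_activating,
#' down/up = ovule_repressing, up/up = elongation_activating,
#' up/down = elongation_repressing. Links with an \code{ns} direction on
#' either side are left \code{unclassified}.
#'
#' @param links data.frame with \code{peak_id}, \code{gene_id} (significant
#'   links).
#' @param docrCalls,degCalls data.frames from [callDifferentialSet()].
#' @return \code{links} with a \code{group} column.
#' @export
classifyDocrGroups <- function(links, docrCalls, degCalls) {
    dStat <- setNames(docrCalls$status, docrCalls$feature)
    gStat <- setNames(degCalls$status, degCalls$feature)
    d <- dStat[links$peak_id]
    g <- gStat[links$gene_id]
    group <- rep("unclassified", nrow(links))
    group[d == "down" & g == "down"] <- "ovule_activating"
    group[d == "down" & g == "up"] <- "ovule_repressing"
    group[d == "up" & g == "up"] <- "elongation_activating"
    group[d == "up" & g == "down"] <- "elongation_repressing"
    links$group <- group
    links
}
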