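## Size-factor normalization, a simplified negative-binomial Wald test, and
## the two-stage-consistency DEG/DOCR decision rules.

#' Median-of-ratios size factors
#'
#' Per-sample factors are the median across features of the ratio of the
#' sample's counts to the geometric-mean pseudo-reference; features
#' containing any zero are excluded from the reference.
#'
#' @param x A [StageCounts-class] or a counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2)
#' computeSizeFactors(m)   # ratio 2 between the samples
#' @export
computeSizeFactors <- function(x) {
    m <- if (is(x, "StageCounts")) countsMatrix(x) else as.matrix(x)
    allPos <- rowSums(m == 0) == 0
    if (!any(allPos))
        stop("normalization error: no feature has all-positive counts")
    ref <- exp(rowMeans(log(m[allPos, , drop = FALSE])))
    sf <- apply(m[allPos, , drop = FALSE] / ref, 2, stats::median)
    setNames(sf, colnames(m))
}

#' Size-factor-normalized counts
#'
#' @param x A [StageCounts-class] or counts matrix.
#' @param sizeFactors optional precomputed factors.
#' @return Matrix of normalized counts.
#' @export
normalizedCounts <- function(x, sizeFactors = NULL) {
    m <- if (is(x, "StageCounts")) countsMatrix(x) else as.matrix(x)
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(m)
    sweep(m, 2, sizeFactors, "/")
}

#' Per-stage replicate means of normalized counts
#'
#' The common axis for peak-gene correlation: size-factor-normalized counts
#' averaged over replicates within each stage.
#'
#' @param x A [StageCounts-class].
#' @param sizeFactors optional precomputed factors.
#' @return features x stages matrix, stages in increasing order.
#' @export
stageMeanProfiles <- function(x, sizeFactors = NULL) {
    norm <- normalizedCounts(x, sizeFactors)
    stages <- stageLevels(x)
    out <- vapply(stages, function(s)
        rowMeans(norm[, sampleStages(x) == s, drop = FALSE]),
        numeric(nrow(norm)))
    colnames(out) <- stages
    out
}

#' Simplified negative-binomial Wald test between two stages
#'
#' A per-feature NB model with method-of-moments dispersion (floored at
#' 1e-8): normalized group means feed a Wald statistic on the log2 fold
#' change (pseudocount 1), with a t reference on the pooled replicate
#' degrees of freedom. This is a deliberately simple differential caller;
#' the decision thresholds applied downstream, not the caller's internals,
#' are the analysis contract.
#'
#' @param x A [StageCounts-class].
#' @param stageA numerator stage (e.g. an elongation stage).
#' @param stageB denominator/baseline stage (e.g. 0 DPA).
#' @param sizeFactors optional precomputed factors.
#' @return data.frame with \code{feature}, \code{baseMean}, \code{log2FC}
#'   (A vs B), \code{stat}, \code{pvalue}, \code{padj} (BH over all tested
#'   features).
#' @export
nbWaldTest <- function(x, stageA, stageB, sizeFactors = NULL) {
    st <- sampleStages(x)
    if (!stageA %in% st || !stageB %in% st)
        stop("comparison error: stage ", setdiff(c(stageA, stageB), st)[1],
             " absent from sample metadata")
    norm <- normalizedCounts(x, sizeFactors)
    a <- norm[, st == stageA, drop = FALSE]
    b <- norm[, st == stageB, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    if (na + nb < 4)
        stop("comparison error: need >= 2 samples per stage")
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    ## pooled method-of-moments dispersion alpha: var = mu + alpha mu^2
    pooledVar <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    mbar <- (ma + mb) / 2
    alpha <- pmax((pooledVar - mbar) / pmax(mbar, 1e-8)^2, 1e-8)
    lfc <- log2((ma + 1) / (mb + 1))
    seA2 <- (ma + alpha * ma^2) / na
    seB2 <- (mb + alpha * mb^2) / nb
    seLfc <- sqrt(seA2 / (ma + 1)^2 + seB2 / (mb + 1)^2) / log(2)
    stat <- ifelse(seLfc > 0, lfc / seLfc, 0)
    pvalue <- 2 * pt(-abs(stat), df = na + nb - 2)
    data.frame(feature = rownames(norm), baseMean = mbar, log2FC = lfc,
               stat = stat, pvalue = pvalue,
               padj = p.adjust(pvalue, method = "BH"),
               stringsAsFactors = FALSE)
}

#' Call the differential set under the two-stage consistency rule
#'
#' Combines per-comparison results (each elongation stage vs the 0-DPA
#' baseline) into final feature calls. DEGs use BH-adjusted p < 0.01, DOCRs
#' raw p < 0.05 (a \code{adjusted} switch is provided); both require
#' |log2FC| > 1. A feature is \code{up} (elongation-specific) or \code{down}
#' (ovule-specific) only when at least \code{minComparisons} (default 2)
#' comparisons pass with the same direction; mixed-direction significance
#' yields \code{ns}.
#'
#' @param results named list of [nbWaldTest()] data.frames, one per
#'   elongation-vs-baseline comparison.
#' @param kind \code{"DEG"} or \code{"DOCR"} (sets the p-value convention).
#' @param pThreshold significance threshold (default: 0.01 adjusted for DEG,
#'   0.05 raw for DOCR).
#' @param lfcThreshold |log2FC| threshold (default 1, exclusive).
#' @param adjusted use BH-adjusted p-values (default TRUE for DEG, FALSE for
#'   DOCR).
#' @param minComparisons minimum consistent significant comparisons
#'   (default 2).
#' @return data.frame with \code{feature}, \code{status} (up/down/ns),
#'   \code{n_significant_comparisons}.
#' @export
callDifferentialSet <- function(results, kind = c("DEG", "DOCR"),
                                pThreshold = NULL, lfcThreshold = 1,
                                adjusted = NULL, minComparisons = 2L) {
    kind <- match.arg(kind)
    if (length(results) < minComparisons)
        stop("configuration error: need >= ", minComparisons,
             " elongation comparisons, got ", length(results))
    if (is.null(adjusted)) adjusted <- kind == "DEG"
    if (is.null(pThreshold)) pThreshold <- if (kind == "DEG") 0.01 else 0.05
    features <- results[[1]]$feature
    sig <- vapply(results, function(r) {
        stopifnot(identical(r$feature, features))
        p <- if (adjusted) r$padj else r$pvalue
        ifelse(p < pThreshold & abs(r$log2FC) > lfcThreshold,
               sign(r$log2FC), 0)
    }, numeric(length(features)))
    if (!is.matrix(sig)) sig <- matrix(sig, nrow = length(features))
    nUp <- rowSums(sig > 0)
    nDown <- rowSums(sig < 0)
    status <- ifelse(nUp >= minComparisons & nDown == 0, "up",
              ifelse(nDown >= minComparisons & nUp == 0, "down", "ns"))
    data.frame(feature = features, status = status,
               n_significant_comparisons = pmax(nUp, nDown),
               stringsAsFactors = FALSE)
}
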