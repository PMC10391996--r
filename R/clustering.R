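## Joint k-means clustering of expression and promoter-accessibility stage
## profiles: 95th-quantile column normalization, k-means++ seeding,
## rangeability filtering, and genome-region enrichment of clusters.

#' Normalize a profile matrix to \[0, 1\] by column 95th percentiles
#'
#' Each column is divided by its 95th percentile and clipped at 1; all-zero
#' columns are left untouched. Idempotent on a matrix whose column 95th
#' percentiles are already 1.
#'
#' @param m non-negative numeric matrix (genes x profile columns).
#' @return matrix with values in \[0, 1\].
#' @export
normalize95 <- function(m) {
    m <- as.matrix(m)
    if (any(m < 0)) stop("normalize95 expects non-negative values")
    for (j in seq_len(ncol(m))) {
        q <- quantile(m[, j], 0.95, names = FALSE)
        if (q > 0) m[, j] <- pmin(m[, j] / q, 1)
    }
    m
}

#' Assemble the joint expression / promoter-accessibility profile matrix
#'
#' Six expression stage values followed by six promoter-accessibility stage
#' values per gene. Promoter accessibility is the mean stage profile over
#' DHSs overlapping the gene's 1.5-kb promoter window (by at least half of
#' the DHS length), 0 when the gene has none.
#'
#' @param expression A [StageCounts-class].
#' @param accessibility A [StageCounts-class] over the DHS catalog.
#' @param peaks GRanges DHS catalog with \code{peak_id}.
#' @param genes GRanges with \code{gene_id}.
#' @param promoterWidth promoter window (default 1500).
#' @param minOverlap minimum overlapping fraction of the DHS (default 0.5).
#' @return genes x (2 * stages) matrix; columns "expr_<stage>" then
#'   "acc_<stage>".
#' @export
profileMatrix <- function(expression, accessibility, peaks, genes,
                          promoterWidth = 1500, minOverlap = 0.5) {
    ep <- stageMeanProfiles(expression)
    ap <- stageMeanProfiles(accessibility)
    prom <- suppressWarnings(trim(promoters(genes, upstream = promoterWidth,
                                            downstream = 0)))
    ov <- findOverlaps(peaks, prom, ignore.strand = TRUE)
    ovBases <- width(pintersect(peaks[queryHits(ov)], prom[subjectHits(ov)],
                                ignore.strand = TRUE))
    keep <- ovBases >= minOverlap * width(peaks)[queryHits(ov)]
    byGene <- split(.peakIds(peaks)[queryHits(ov)[keep]],
                    genes$gene_id[subjectHits(ov)[keep]])
    acc <- matrix(0, nrow(ep), ncol(ap),
                  dimnames = list(rownames(ep), colnames(ap)))
    for (g in intersect(names(byGene), rownames(acc))) {
        ids <- intersect(byGene[[g]], rownames(ap))
        if (length(ids))
            acc[g, ] <- colMeans(ap[ids, , drop = FALSE])
    }
    out <- cbind(ep, acc)
    colnames(out) <- c(paste0("expr_", colnames(ep)),
                       paste0("acc_", colnames(ap)))
    out
}

## k-means++ seeding: spread initial centers by squared-distance sampling.
.kmeansPlusPlusCenters <- function(m, k) {
    n <- nrow(m)
    centers <- matrix(NA_real_, k, ncol(m))
    idx <- sample.int(n, 1)
    centers[1, ] <- m[idx, ]
    d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
    for (i in seq_len(k - 1)) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx <- sample.int(n, 1, prob = prob)
        centers[i + 1, ] <- m[idx, ]
        nd2 <- rowSums((m - matrix(centers[i + 1, ], n, ncol(m),
                                   byrow = TRUE))^2)
        d2 <- pmin(d2, nd2)
    }
    centers
}

#' k-means clustering of stage profiles
#'
#' Euclidean k-means (Lloyd iterations, 300 max) with k-means++
#' initialization and \code{nstart} restarts, keeping the lowest total
#' within-cluster sum of squares. Deterministic given \code{seed}. Cluster
#' numbering is arbitrary; compare labelings with label-invariant scores
#' such as the adjusted Rand index.
#'
#' @param m profile matrix (rows = genes).
#' @param k number of clusters (default 13).
#' @param seed RNG seed.
#' @param nstart restarts (default 10).
#' @param iterMax maximum Lloyd iterations (default 300).
#' @return list with \code{labels} (named integer vector), \code{centers},
#'   \code{totWithinSS}.
#' @export
kmeansProfiles <- function(m, k = 13, seed = 1L, nstart = 10L,
                           iterMax = 300L) {
    m <- as.matrix(m)
    if (k > nrow(m)) stop("k exceeds the number of genes")
    withr::with_seed(as.integer(seed), {
        best <- NULL
        for (i in seq_len(nstart)) {
            centers <- .kmeansPlusPlusCenters(m, k)
            ## k-means++ may duplicate rows when data has few distinct
            ## points; nudge duplicates to keep stats::kmeans happy
            dup <- duplicated(round(centers, 12))
            if (any(dup))
                centers[dup, ] <- centers[dup, ] +
                    matrix(rnorm(sum(dup) * ncol(m), 0, 1e-8),
                           sum(dup), ncol(m))
            fit <- suppressWarnings(
                kmeans(m, centers = centers, iter.max = iterMax,
                       algorithm = "Lloyd"))
            if (is.null(best) || fit$tot.withinss < best$tot.withinss)
                best <- fit
        }
        list(labels = setNames(best$cluster, rownames(m)),
             centers = best$centers, totWithinSS = best$tot.withinss)
    })
}

#' Rangeability of a cluster centroid
#'
#' The max - min range over the stage values, computed separately for the
#' expression half and the accessibility half of the (normalized) centroid;
#' the cluster is flagged as a minor-magnitude ("rangeability < threshold")
#' cluster when either range falls below the threshold.
#'
#' @param centroid numeric centroid over concatenated expr/acc columns.
#' @param nExpr number of leading expression columns (default half).
#' @param threshold flagging threshold (default 0.05).
#' @return list with \code{expression_range}, \code{accessibility_range},
#'   \code{flagged}.
#' @export
rangeability <- function(centroid, nExpr = length(centroid) %/% 2,
                         threshold = 0.05) {
    e <- centroid[seq_len(nExpr)]
    a <- centroid[-seq_len(nExpr)]
    er <- max(e) - min(e)
    ar <- if (length(a)) max(a) - min(a) else NA_real_
    list(expression_range = er, accessibility_range = ar,
         flagged = er < threshold || (is.finite(ar) && ar < threshold))
}

#' Genome-region enrichment of gene clusters
#'
#' For each cluster and each region class (gene_rich / te_rich / balanced),
#' the upper-tail hypergeometric p-value of the cluster's count of genes in
#' that class against the genome-wide composition, with fold enrichment
#' \code{(k/n)/(K/N)}. Empty clusters are skipped; an empty region class
#' yields an NA fold.
#'
#' @param clusterLabels named integer vector (gene -> cluster).
#' @param regionByGene named character vector (gene -> region label, e.g.
#'   via the gene's TSS window).
#' @return data.frame with \code{cluster}, \code{region}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{fold}, \code{pvalue}.
#' @export
regionEnrichment <- function(clusterLabels, regionByGene) {
    genes <- intersect(names(clusterLabels), names(regionByGene))
    cl <- clusterLabels[genes]
    rg <- regionByGene[genes]
    N <- length(genes)
    rows <- list()
    for (c in sort(unique(cl))) {
        inC <- rg[cl == c]
        n <- length(inC)
        if (!n) next
        for (r in sort(unique(rg))) {
            K <- sum(rg == r)
            k <- sum(inC == r)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = c, region = r, k = k, n = n, K = K, N = N,
                fold = if (K > 0) (k / n) / (K / N) else NA_real_,
                pvalue = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
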