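## Mutual-rank co-expression network: Pearson correlation matrix, directed
## rank matrices, the MR statistic, and the Rank<3 / MR<50 signed network.

#' Pearson correlation matrix over all samples
#'
#' Correlates every gene pair across all samples (e.g. the 36 = 6 stages x 6
#' replicates expression samples). Constant-expression genes are excluded
#' (logged via a message).
#'
#' @param x A [StageCounts-class] or a genes x samples matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pccMatrix <- function(x) {
    m <- if (is(x, "StageCounts")) countsMatrix(x) else as.matrix(x)
    if (ncol(m) < 3) stop("need >= 3 samples for correlation")
    constant <- apply(m, 1, sd) == 0
    if (any(constant))
        message(sum(constant), " constant-expression gene(s) excluded: ",
                paste(head(rownames(m)[constant], 5), collapse = ", "))
    cor(t(m[!constant, , drop = FALSE]))
}

#' Directed correlation ranks and the mutual-rank matrix
#'
#' \code{rankAB[i, j]} is the position of gene j when gene i's partners are
#' sorted by decreasing |PCC| (self excluded; ties broken by gene-id order);
#' \code{MR = sqrt(rankAB * rankBA)} is symmetric. Ranking by absolute PCC
#' (the default) lets strong negative co-expression reach low ranks; set
#' \code{absolute = FALSE} for signed-descending ranking.
#'
#' @param pcc symmetric correlation matrix (from [pccMatrix()]).
#' @param absolute rank by |PCC| (default TRUE).
#' @return list with integer matrices \code{rank} (rank[i, j] = rank of j
#'   among i's partners) and numeric \code{mr}.
#' @export
mutualRank <- function(pcc, absolute = TRUE) {
    n <- nrow(pcc)
    ids <- rownames(pcc)
    key <- if (absolute) -abs(pcc) else -pcc
    rk <- matrix(NA_integer_, n, n, dimnames = dimnames(pcc))
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        ord <- others[order(key[i, others], ids[others])]
        rk[i, ord] <- seq_len(n - 1L)
    }
    mr <- sqrt(rk * t(rk))
    list(rank = rk, mr = mr)
}

#' Build the signed mutual-rank co-expression network
#'
#' An undirected edge A--B is retained iff the better single-direction rank
#' satisfies \code{min(rankAB, rankBA) < rankMax} (default 3) and
#' \code{MR < mrMax} (default 50). The edge sign is the sign of the PCC.
#'
#' @param mr result of [mutualRank()].
#' @param pcc the correlation matrix the ranks were computed from.
#' @param rankMax single-direction rank threshold (exclusive, default 3).
#' @param mrMax mutual-rank threshold (exclusive, default 50).
#' @return data.frame of deduplicated edges (gene_a < gene_b) with
#'   \code{pcc}, \code{rank_ab}, \code{rank_ba}, \code{mr}, \code{sign}.
#' @export
buildCoexpressionNetwork <- function(mr, pcc, rankMax = 3, mrMax = 50) {
    ids <- rownames(pcc)
    keep <- which(upper.tri(pcc) &
                  pmin(mr$rank, t(mr$rank)) < rankMax &
                  mr$mr < mrMax, arr.ind = TRUE)
    if (!nrow(keep))
        return(data.frame(gene_a = character(), gene_b = character(),
                          pcc = numeric(), rank_ab = integer(),
                          rank_ba = integer(), mr = numeric(),
                          sign = character(), stringsAsFactors = FALSE))
    i <- keep[, 1]; j <- keep[, 2]
    out <- data.frame(
        gene_a = ids[i], gene_b = ids[j],
        pcc = pcc[keep],
        rank_ab = mr$rank[keep],
        rank_ba = mr$rank[cbind(j, i)],
        mr = mr$mr[keep],
        sign = ifelse(pcc[keep] > 0, "+", "-"),
        stringsAsFactors = FALSE)
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
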