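## Replicate reproducibility: 5-kb window correlation, pseudo-replicate
## splits, and a simplified rescue ratio. The reproducibility rule here is a
## deliberately simple >= 50%-reciprocal-overlap criterion, NOT an IDR
## implementation; reports name it accordingly.

#' Pearson correlation between replicate window-count vectors
#'
#' @param w1,w2 numeric window counts on the same window grid.
#' @param dropZero drop windows that are zero in both replicates
#'   (default FALSE: retained).
#' @param normalize depth-normalize each vector to counts per million
#'   (default TRUE).
#' @return Pearson r.
#' @export
replicateCorrelation <- function(w1, w2, dropZero = FALSE, normalize = TRUE) {
    if (length(w1) != length(w2))
        stop("replicates must share the window grid")
    if (dropZero) {
        keep <- w1 > 0 | w2 > 0
        w1 <- w1[keep]; w2 <- w2[keep]
    }
    if (length(w1) < 3) stop("need >= 3 windows for correlation")
    if (normalize) {
        w1 <- w1 / sum(w1) * 1e6
        w2 <- w2 / sum(w2) * 1e6
    }
    cor(w1, w2)
}

#' Split a pooled item set into two pseudo-replicates
#'
#' Each item is assigned to exactly one half. With \code{balanced = TRUE}
#' (default) the halves differ in size by at most one, and when the pool
#' carries item identities (a GRanges \code{peak_id} column) the split is
#' additionally stratified by identity, so the two measurement copies of the
#' same underlying peak land in opposite halves -- the peak-level analogue
#' of splitting the merged reads in half, where each half retains support
#' for essentially every peak. Deterministic given \code{seed}.
#'
#' @param pool a vector, or a GRanges, of pooled items (e.g. the
#'   concatenation of both replicates' peak lists).
#' @param seed RNG seed.
#' @param balanced enforce the size-balance (and identity-stratification)
#'   guarantee (default TRUE; otherwise an independent fair coin per item).
#' @return list of two halves of the same class as \code{pool}.
#' @export
pseudoReplicates <- function(pool, seed = 1L, balanced = TRUE) {
    n <- length(pool)
    if (!n) stop("empty pool")
    ids <- if (is(pool, "GRanges") && !is.null(pool$peak_id)) pool$peak_id
           else NULL
    half <- withr::with_seed(as.integer(seed), {
        if (balanced && !is.null(ids)) {
            assign <- integer(n)
            sizes <- c(0L, 0L)
            for (grp in split(seq_len(n), ids)) {
                if (length(grp) > 1) grp <- sample(grp)
                ## alternate within the group so copies of one item always
                ## land in opposite halves
                h0 <- if (sizes[1] < sizes[2]) 1L
                      else if (sizes[2] < sizes[1]) 2L
                      else sample(1:2, 1)
                for (j in seq_along(grp)) {
                    h <- if (j %% 2 == 1L) h0 else 3L - h0
                    assign[grp[j]] <- h
                    sizes[h] <- sizes[h] + 1L
                }
            }
            which(assign == 1L)
        } else if (balanced) {
            perm <- sample.int(n)
            perm[seq_len(n %/% 2 + n %% 2)]
        } else {
            which(runif(n) < 0.5)
        }
    })
    inFirst <- seq_len(n) %in% half
    list(pool[inFirst], pool[!inFirst])
}

#' Simplified rescue ratio between true and pseudo replicates
#'
#' A peak is "reproducible" iff it overlaps a peak of its sibling list by at
#' least \code{minOverlap} of its own length. Nt and Np are the reproducible
#' counts summed over both true-replicate lists and both pseudo-replicate
#' lists respectively; the ratio is min(Nt, Np) / max(Nt, Np). This
#' reciprocal-overlap rule is a labelled simplification standing in for
#' IDR-thresholded peak counting.
#'
#' @param trueReps list of two GRanges (true replicates).
#' @param pseudoReps list of two GRanges (pooled pseudo-replicates).
#' @param minOverlap minimum overlapping fraction of the peak (default 0.5).
#' @return list with \code{Nt}, \code{Np}, \code{ratio} (NA with a message
#'   when either pair has no reproducible peak), and
#'   \code{method = "reciprocal_overlap_0.5"}.
#' @export
rescueRatio <- function(trueReps, pseudoReps, minOverlap = 0.5) {
    stopifnot(length(trueReps) == 2, length(pseudoReps) == 2)
    reproducible <- function(a, b) {
        sum(overlapBases(a, b) / width(a) >= minOverlap)
    }
    Nt <- reproducible(trueReps[[1]], trueReps[[2]]) +
          reproducible(trueReps[[2]], trueReps[[1]])
    Np <- reproducible(pseudoReps[[1]], pseudoReps[[2]]) +
          reproducible(pseudoReps[[2]], pseudoReps[[1]])
    if (Nt == 0 || Np == 0) {
        message("rescue ratio undefined: no reproducible peaks in a pair")
        ratio <- NA_real_
    } else ratio <- min(Nt, Np) / max(Nt, Np)
    list(Nt = Nt, Np = Np, ratio = ratio,
         method = sprintf("reciprocal_overlap_%.2g", minOverlap))
}

#' Replicate QC report for a simulated (or real) staged peak dataset
#'
#' For each stage: the 5-kb window accessibility correlation between the two
#' replicates, and the simplified rescue ratio computed from the replicate
#' peak lists and a seeded pseudo-replicate split of their union.
#'
#' @param replicatePeaks GRanges with \code{stage} and \code{replicate}.
#' @param accessibility A [StageCounts-class] whose samples match the
#'   replicate structure; per-peak counts are spread over peak intervals to
#'   form the window signal.
#' @param seqlens named chromosome lengths.
#' @param windowSize QC window (default 5000).
#' @param seed seed for the pseudo-replicate split.
#' @return data.frame with \code{stage}, \code{replicate_r},
#'   \code{rescue_ratio}, \code{Nt}, \code{Np}.
#' @export
qcReport <- function(replicatePeaks, accessibility, seqlens,
                     windowSize = 5000, seed = 1L) {
    counts <- countsMatrix(accessibility)
    st <- sampleStages(accessibility)
    reps <- SummarizedExperiment::colData(accessibility)$replicate
    rows <- list()
    for (s in stageLevels(accessibility)) {
        peaks1 <- replicatePeaks[replicatePeaks$stage == s &
                                 replicatePeaks$replicate == 1]
        peaks2 <- replicatePeaks[replicatePeaks$stage == s &
                                 replicatePeaks$replicate == 2]
        sig <- function(peaks, col) {
            peaks$score <- counts[peaks$peak_id, col]
            windowSignal(peaks, seqlens, windowSize)$signal
        }
        col1 <- which(st == s & reps == 1)[1]
        col2 <- which(st == s & reps == 2)[1]
        r <- replicateCorrelation(sig(peaks1, col1), sig(peaks2, col2))
        pool <- c(peaks1, peaks2)
        halves <- pseudoReplicates(pool, seed = seed + match(s, stageLevels(accessibility)))
        rr <- rescueRatio(list(peaks1, peaks2), halves)
        rows[[length(rows) + 1L]] <- data.frame(
            stage = s, replicate_r = r, rescue_ratio = rr$ratio,
            Nt = rr$Nt, Np = rr$Np, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
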