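## PWM log-odds scanning with exact score p-values (dynamic programming over
## discretized scores), hit-to-peak assignment by full containment, and
## hypergeometric motif enrichment.

#' Log-odds score matrix of a motif (bits)
#'
#' Entry \eqn{\log_2((p + pc \cdot b) / ((1 + pc) \cdot b))} for probability
#' \code{p}, pseudocount \code{pc}, and background frequency \code{b};
#' finite everywhere for a positive background.
#'
#' @param motif A [MotifModel-class].
#' @return 4 x L numeric matrix in bits (rows A, C, G, T).
#' @export
buildLogOdds <- function(motif) {
    b <- motif@background
    if (any(b <= 0))
        stop("parameter error: background frequencies must be positive")
    pc <- motif@pseudocount
    log2((motif@matrix + pc * b) / ((1 + pc) * b))
}

## Integer-discretized log-odds at the stated grain (bits).
.discretizeLogOdds <- function(motif, grain = 1e-3) {
    round(buildLogOdds(motif) / grain)
}

#' Exact score distribution of a motif under the background
#'
#' Dynamic programming over scores discretized to \code{grain} bits: the
#' exact probability, under the background model, of each achievable total
#' score of a random word of motif length. p-values computed from this
#' distribution agree with exhaustive enumeration over all 4^L words at the
#' discretization grain.
#'
#' @param motif A [MotifModel-class].
#' @param grain score discretization in bits (default 1e-3).
#' @return A list with \code{grain}, \code{imin} (integer score of the first
#'   pmf cell), \code{pmf}, and \code{tail} (upper-tail probabilities,
#'   \code{tail\[i\] = P(score >= imin + i - 1)}).
#' @export
motifScoreDistribution <- function(motif, grain = 1e-3) {
    ilo <- .discretizeLogOdds(motif, grain)
    b <- motif@background
    ## DP over positions; the pmf support is tracked relative to curMin
    pmf <- 1
    curMin <- 0L
    for (j in seq_len(ncol(ilo))) {
        colVals <- ilo[, j]
        newMin <- curMin + min(colVals)
        newMax <- curMin + length(pmf) - 1L + max(colVals)
        new <- numeric(newMax - newMin + 1L)
        for (base in 1:4) {
            sh <- (curMin + colVals[base]) - newMin
            idx <- seq_along(pmf) + sh
            new[idx] <- new[idx] + pmf * b[base]
        }
        pmf <- new
        curMin <- newMin
    }
    tail <- rev(cumsum(rev(pmf)))
    list(grain = grain, imin = curMin, pmf = pmf, tail = tail)
}

#' Upper-tail p-value of a motif score
#'
#' \code{P(random word score >= score)} under the background model, from the
#' exact discretized distribution: monotone non-increasing in score, 1 at or
#' below the minimum achievable score, 0 above the maximum.
#'
#' @param motif A [MotifModel-class].
#' @param score score(s) in bits.
#' @param grain discretization (default 1e-3).
#' @param dist optional precomputed [motifScoreDistribution()].
#' @return numeric p-value(s).
#' @export
scorePvalue <- function(motif, score, grain = 1e-3, dist = NULL) {
    if (is.null(dist)) dist <- motifScoreDistribution(motif, grain)
    iscore <- round(score / dist$grain)
    idx <- iscore - dist$imin + 1
    vapply(idx, function(i) {
        if (i <= 1) 1
        else if (i > length(dist$tail)) 0
        else dist$tail[i]
    }, numeric(1))
}

## Map sequence characters to base codes 1..4 (NA for anything else).
.baseCodes <- function(seqChar) {
    match(strsplit(toupper(seqChar), "")[[1]], c("A", "C", "G", "T"))
}

## Score every window of coded sequence with an integer score matrix.
.scanCodes <- function(codes, ilo) {
    L <- ncol(ilo)
    W <- length(codes) - L + 1L
    if (W < 1L) return(integer(0))
    s <- integer(W)
    na <- logical(W)
    for (j in seq_len(L)) {
        cj <- codes[j:(j + W - 1L)]
        bad <- is.na(cj)
        na <- na | bad
        cj[bad] <- 1L
        s <- s + ilo[cbind(cj, j)]
    }
    s[na] <- NA_integer_
    s
}

#' Scan a sequence for motif occurrences on both strands
#'
#' Reports a hit at every position, on either strand, whose log-odds score
#' has an exact p-value at or below \code{pThreshold}. Reverse-strand scores
#' are computed on the reverse complement; coordinates are reported on the
#' forward strand (1-based). Windows containing non-ACGT characters are
#' skipped; sequences shorter than the motif yield an empty result.
#'
#' @param sequence character or DNAString.
#' @param motif A [MotifModel-class].
#' @param pThreshold score p-value threshold (default 1e-4, the convention
#'   of standard scanners' defaults).
#' @param grain score discretization in bits.
#' @param dist optional precomputed [motifScoreDistribution()] (reused
#'   across sequences for speed).
#' @return data.frame with \code{start}, \code{end}, \code{strand},
#'   \code{score} (bits), \code{pvalue}.
#' @export
scanSequence <- function(sequence, motif, pThreshold = 1e-4, grain = 1e-3,
                         dist = NULL) {
    seqChar <- as.character(sequence)
    codes <- .baseCodes(seqChar)
    ilo <- .discretizeLogOdds(motif, grain)
    L <- ncol(ilo)
    if (is.null(dist)) dist <- motifScoreDistribution(motif, grain)
    ## reverse complement of the matrix: complement rows, reverse columns
    iloRc <- ilo[4:1, L:1, drop = FALSE]
    rownames(iloRc) <- rownames(ilo)
    rows <- list()
    for (strand in c("+", "-")) {
        s <- .scanCodes(codes, if (strand == "+") ilo else iloRc)
        if (!length(s)) next
        p <- scorePvalue(motif, s[!is.na(s)] * grain, dist = dist)
        keepPos <- which(!is.na(s))[p <= pThreshold]
        if (!length(keepPos)) next
        rows[[strand]] <- data.frame(
            start = keepPos, end = keepPos + L - 1L, strand = strand,
            score = s[keepPos] * grain,
            pvalue = scorePvalue(motif, s[keepPos] * grain, dist = dist),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          pvalue = numeric(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of sequences with a set of motifs
#'
#' @param sequences named DNAStringSet (or named character vector); names
#'   become seqnames of the returned hits.
#' @param motifs list of [MotifModel-class].
#' @param pThreshold,grain see [scanSequence()].
#' @param seqlengths optional named lengths for the returned GRanges.
#' @return GRanges of hits with \code{motif_id}, \code{score},
#'   \code{pvalue}.
#' @export
scanSequences <- function(sequences, motifs, pThreshold = 1e-4,
                          grain = 1e-3, seqlengths = NULL) {
    rows <- list()
    for (m in motifs) {
        dist <- motifScoreDistribution(m, grain)
        for (nm in names(sequences)) {
            h <- scanSequence(sequences[[nm]], m, pThreshold, grain, dist)
            if (!nrow(h)) next
            g <- GRanges(nm, IRanges(h$start, h$end), strand = h$strand)
            g$motif_id <- m@id
            g$score <- h$score
            g$pvalue <- h$pvalue
            rows[[length(rows) + 1L]] <- g
        }
    }
    out <- if (length(rows)) suppressWarnings(do.call(c, rows)) else GRanges()
    if (!is.null(seqlengths)) {
        out <- GRanges(as.character(seqnames(out)),
                       IRanges(start(out), end(out)),
                       strand = strand(out), seqlengths = seqlengths,
                       motif_id = out$motif_id, score = out$score,
                       pvalue = out$pvalue)
    }
    out
}

#' Assign motif hits to peaks by full containment
#'
#' A hit is assigned to a peak iff 100\% of the hit interval lies within the
#' peak interval.
#'
#' @param hits GRanges of motif hits (with \code{motif_id}).
#' @param peaks GRanges with \code{peak_id}.
#' @return data.frame with \code{peak_id}, \code{motif_id}, \code{hit_start},
#'   \code{hit_end}, \code{strand}, and \code{score} when present.
#' @export
assignHitsToPeaks <- function(hits, peaks) {
    ov <- findOverlaps(hits, peaks, type = "within", ignore.strand = TRUE)
    h <- hits[queryHits(ov)]
    data.frame(peak_id = .peakIds(peaks)[subjectHits(ov)],
               motif_id = if (!is.null(h$motif_id)) h$motif_id
                          else rep(NA_character_, length(h)),
               hit_start = start(h), hit_end = end(h),
               strand = as.character(strand(h)),
               score = if (!is.null(h$score)) h$score
                       else rep(NA_real_, length(h)),
               stringsAsFactors = FALSE)
}

#' Hypergeometric motif enrichment over peaks
#'
#' For each motif: \code{k} foreground peaks with at least one hit, drawn in
#' \code{n = |foreground|} draws from \code{N = |universe|} peaks of which
#' \code{K} carry a hit; upper-tail hypergeometric p-value and fold
#' enrichment \code{(k/n)/(K/N)}. Significant at p < 0.001.
#'
#' @param foregroundIds character vector of foreground peak ids (must be a
#'   subset of the universe).
#' @param universeIds character vector of all peak ids (the background).
#' @param hitTable data.frame with \code{peak_id}, \code{motif_id} (e.g.
#'   from [assignHitsToPeaks()]).
#' @param pThreshold significance threshold (default 0.001).
#' @return data.frame with \code{motif_id}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{fold}, \code{pvalue}, \code{significant}.
#' @export
hypergeometricEnrichment <- function(foregroundIds, universeIds, hitTable,
                                     pThreshold = 0.001) {
    if (!length(foregroundIds))
        stop("enrichment error: empty foreground peak set")
    if (!all(foregroundIds %in% universeIds))
        stop("enrichment error: foreground must be a subset of the universe")
    N <- length(universeIds)
    n <- length(foregroundIds)
    motifIds <- sort(unique(hitTable$motif_id))
    rows <- lapply(motifIds, function(m) {
        withHit <- unique(hitTable$peak_id[hitTable$motif_id == m])
        K <- sum(universeIds %in% withHit)
        k <- sum(foregroundIds %in% withHit)
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(motif_id = m, k = k, n = n, K = K, N = N,
                   fold = if (K > 0) (k / n) / (K / N) else NA_real_,
                   pvalue = p, significant = p < pThreshold,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' teDHS / non-teDHS enrichment ratio of a motif
#'
#' The ratio of the mean fold-enrichment of the motif in teDHSs across
#' stages to the mean fold-enrichment in non-teDHSs across the same stages.
#' A zero or undefined denominator yields \code{NA} (logged).
#'
#' @param teFolds,nonTeFolds per-stage fold enrichments of one motif.
#' @return scalar ratio, or NA.
#' @export
teEnrichmentRatio <- function(teFolds, nonTeFolds) {
    num <- mean(teFolds, na.rm = TRUE)
    den <- mean(nonTeFolds, na.rm = TRUE)
    if (!is.finite(den) || den == 0) {
        message("te-enrichment ratio undefined (zero/empty denominator)")
        return(NA_real_)
    }
    num / den
}
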