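#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- findOverlaps pintersect reduce promoters flank resize shift
#'   tileGenome distance seqinfo granges trim
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors DataFrame queryHits subjectHits Rle
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement replaceAt
#'   subseq writeXStringSet readDNAStringSet
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlengths<- keepSeqlevels
NULL

## Fan a single global seed out to named, component-isolated child seeds.
childSeeds <- function(seed, components) {
    withr::with_seed(as.integer(seed), {
        s <- sample.int(.Machine$integer.max - 1L, length(components))
    })
    names(s) <- components
    s
}

## Standardize a vector to sample mean 0 and sample sd 1.
standardizeProfile <- function(x) {
    s <- sd(x)
    if (s == 0) stop("cannot standardize a constant profile")
    (x - mean(x)) / s
}

## A standardized noise vector exactly orthogonal (sample covariance 0) to u,
## so that rho * u + sqrt(1 - rho^2) * orth has sample correlation rho with u
## exactly.
orthogonalNoise <- function(u) {
    k <- length(u)
    repeat {
        e <- rnorm(k)
        e <- e - mean(e)
        e <- e - sum(e * u) / sum(u * u) * u
        if (sd(e) > 1e-8) break
    }
    e / sd(e)
}

## Mix a standardized profile with orthogonal noise at exact correlation rho.
correlatedProfile <- function(u, rho) {
    if (abs(rho) >= 1) return(sign(rho) * u)
    rho * u + sqrt(1 - rho^2) * orthogonalNoise(u)
}

## Draw NB (or Poisson in the zero-dispersion limit) counts around mu.
rcounts <- function(n, mu, dispersion) {
    if (dispersion <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

## Extract sequences for ranges from an in-memory chromosome set.
extractSequences <- function(sequences, gr) {
    stopifnot(all(as.character(seqnames(gr)) %in% names(sequences)))
    out <- DNAStringSet(vapply(seq_along(gr), function(i) {
        chrom <- as.character(seqnames(gr))[i]
        as.character(subseq(sequences[[chrom]], start(gr)[i], end(gr)[i]))
    }, character(1)))
    names(out) <- if (!is.null(gr$peak_id)) gr$peak_id else as.character(seq_along(gr))
    out
}

## Transcription start sites, strand-aware (start on +, end on -).
tssPositions <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

## Zero-padded identifiers.
padIds <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))

## Total bases of each query covered by the (internally merged) subject set.
overlapBases <- function(query, subject) {
    subject <- reduce(subject, ignore.strand = TRUE)
    hits <- findOverlaps(query, subject, ignore.strand = TRUE)
    ov <- width(pintersect(query[queryHits(hits)], subject[subjectHits(hits)],
                           ignore.strand = TRUE))
    out <- numeric(length(query))
    if (length(hits)) {
        agg <- tapply(ov, queryHits(hits), sum)
        out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
}

## Drop seqinfo so feature tracks can be intersected with windows tiled from
## an externally supplied (possibly differing) seqlengths vector.
.stripSeqinfo <- function(x, score = NULL) {
    out <- GRanges(as.character(seqnames(x)),
                   IRanges(start(x), end(x)))
    if (!is.null(score)) out$score <- score
    out
}
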