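## Peak annotation rules: genomic-location categories, teDHS flagging,
## nearest-gene distances, 1-Mb region partition, windowed signal profiles.

#' Annotate peaks by genomic location relative to gene models
#'
#' Assigns each peak exactly one of \code{promoter}, \code{genic},
#' \code{downstream}, or \code{intergenic}. A category is eligible only when
#' at least \code{minOverlap} (default 50\%) of the peak's length overlaps
#' that feature class: the 1.5-kb strand-aware window upstream of the TSS
#' (promoter), the gene body (genic), or the 1.5-kb window downstream of the
#' TTS (downstream). When several classes pass, precedence is
#' promoter > genic > downstream; otherwise the peak is intergenic.
#'
#' @param peaks GRanges of peaks (a \code{peak_id} metadata column is used
#'   for ids when present).
#' @param genes GRanges of gene models with strand and a \code{gene_id}
#'   column.
#' @param promoterWidth,downstreamWidth window sizes in bp (default 1500).
#' @param minOverlap minimum fraction of the peak covered by a feature class
#'   (default 0.5).
#' @return A data.frame with \code{peak_id} and \code{location}.
#' @export
annotatePeakLocations <- function(peaks, genes, promoterWidth = 1500,
                                  downstreamWidth = 1500, minOverlap = 0.5) {
    .checkChromosomes(peaks, genes)
    prom <- suppressWarnings(trim(promoters(genes, upstream = promoterWidth,
                                            downstream = 0)))
    down <- suppressWarnings(trim(flank(genes, width = downstreamWidth,
                                        start = FALSE)))
    fracs <- cbind(
        promoter = overlapBases(peaks, prom) / width(peaks),
        genic = overlapBases(peaks, genes) / width(peaks),
        downstream = overlapBases(peaks, down) / width(peaks))
    location <- rep("intergenic", length(peaks))
    for (cls in c("downstream", "genic", "promoter"))
        location[fracs[, cls] >= minOverlap] <- cls
    data.frame(peak_id = .peakIds(peaks), location = location,
               stringsAsFactors = FALSE)
}

.peakIds <- function(peaks) {
    if (!is.null(peaks$peak_id)) peaks$peak_id
    else as.character(seq_along(peaks))
}

.checkChromosomes <- function(peaks, features) {
    bad <- !as.character(seqnames(peaks)) %in%
        unique(as.character(seqnames(features)))
    if (any(bad))
        stop("annotation error: peaks on chromosomes absent from the ",
             "annotation: ", paste(head(.peakIds(peaks)[bad], 5),
                                   collapse = ", "))
}

#' Flag TE-derived DHSs
#'
#' A peak is a teDHS when the total bases covered by the (merged) TE track
#' reach at least \code{minOverlap} (default 30\%) of the peak's length.
#'
#' @param peaks,tes GRanges.
#' @param minOverlap minimum covered fraction of the peak (default 0.3,
#'   boundary inclusive).
#' @return Named logical vector, one flag per peak.
#' @export
flagTeDHS <- function(peaks, tes, minOverlap = 0.3) {
    frac <- overlapBases(peaks, tes) / width(peaks)
    setNames(frac >= minOverlap, .peakIds(peaks))
}

#' Nearest gene and distance for each peak
#'
#' Distance is 0 when the peak overlaps a gene body, otherwise the minimal
#' gap in bp between interval ends. Ties are broken by the smaller gene
#' start. Peaks on chromosomes with no gene receive an \code{NA} distance
#' (logged via a message).
#'
#' @param peaks,genes GRanges; genes carry \code{gene_id}.
#' @return data.frame with \code{peak_id}, \code{nearest_gene},
#'   \code{distance}.
#' @export
nearestGeneDistance <- function(peaks, genes) {
    ids <- .peakIds(peaks)
    out <- data.frame(peak_id = ids, nearest_gene = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    geneChrom <- as.character(seqnames(genes))
    for (chrom in unique(as.character(seqnames(peaks)))) {
        pIdx <- which(as.character(seqnames(peaks)) == chrom)
        gIdx <- which(geneChrom == chrom)
        if (!length(gIdx)) next
        ps <- start(peaks)[pIdx]; pe <- end(peaks)[pIdx]
        gs <- start(genes)[gIdx]; ge <- end(genes)[gIdx]
        ## gap matrix (0 when overlapping), peaks x genes
        gap <- pmax(outer(ps, ge, "-") - 1,
                    outer(pe, gs, function(p, g) g - p) - 1, 0)
        ord <- order(gs)                     # tie-break: smaller gene start
        gap <- gap[, ord, drop = FALSE]
        best <- apply(gap, 1, which.min)
        out$nearest_gene[pIdx] <- genes$gene_id[gIdx[ord[best]]]
        out$distance[pIdx] <- gap[cbind(seq_along(pIdx), best)]
    }
    if (anyNA(out$distance))
        message(sum(is.na(out$distance)),
                " peak(s) on chromosomes without genes: distance undefined")
    out
}

#' Partition the genome into gene-rich / TE-rich / balanced 1-Mb regions
#'
#' Per non-overlapping window, the gene-covered fraction \code{g} and
#' TE-covered fraction \code{t} are computed from the merged tracks; a
#' window is \code{gene_rich} when \code{g >= ratio * t}, \code{te_rich}
#' when \code{t >= ratio * g}, otherwise \code{balanced}. Windows empty of
#' both tracks are \code{balanced}. The final window on a chromosome may be
#' short; a window larger than the chromosome degrades to a single window
#' spanning it.
#'
#' @param genes,tes GRanges.
#' @param seqlens named chromosome lengths.
#' @param windowSize window size in bp (default 1e6).
#' @param ratio coverage-ratio threshold (default 2).
#' @return GRanges of windows with \code{gene_fraction}, \code{te_fraction},
#'   and \code{label}.
#' @export
partitionRegions <- function(genes, tes, seqlens, windowSize = 1e6,
                             ratio = 2) {
    if (windowSize <= 0) stop("parameter error: windowSize must be > 0")
    windows <- tileGenome(seqlens, tilewidth = min(windowSize, sum(seqlens)),
                          cut.last.tile.in.chrom = TRUE)
    g <- overlapBases(windows, .stripSeqinfo(genes)) / width(windows)
    t <- overlapBases(windows, .stripSeqinfo(tes)) / width(windows)
    label <- ifelse(g == 0 & t == 0, "balanced",
             ifelse(g >= ratio * t, "gene_rich",
             ifelse(t >= ratio * g, "te_rich", "balanced")))
    windows$gene_fraction <- g
    windows$te_fraction <- t
    windows$label <- label
    windows
}

#' Windowed signal totals along the genome
#'
#' Sums interval signal into non-overlapping windows (5 kb, 100 kb, 1 Mb,
#' ...). Each interval's \code{score} (default 1) is attributed to windows
#' proportionally to the overlapping bases, so window totals conserve the
#' input sum exactly. The last window per chromosome may be short.
#'
#' @param x GRanges, optionally with a numeric \code{score} column.
#' @param seqlens named chromosome lengths.
#' @param windowSize window size in bp.
#' @param perMillion divide totals by \code{sum(score)/1e6} (signal per
#'   million) when \code{TRUE}.
#' @return GRanges of windows with a \code{signal} column.
#' @export
windowSignal <- function(x, seqlens, windowSize, perMillion = FALSE) {
    if (windowSize <= 0) stop("parameter error: windowSize must be > 0")
    windows <- tileGenome(seqlens, tilewidth = min(windowSize, sum(seqlens)),
                          cut.last.tile.in.chrom = TRUE)
    score <- if (!is.null(x$score)) as.numeric(x$score) else rep(1, length(x))
    x <- .stripSeqinfo(x, score = score)
    hits <- findOverlaps(x, windows, ignore.strand = TRUE)
    ov <- width(pintersect(x[queryHits(hits)], windows[subjectHits(hits)],
                           ignore.strand = TRUE))
    contrib <- score[queryHits(hits)] * ov / width(x)[queryHits(hits)]
    signal <- numeric(length(windows))
    if (length(hits)) {
        agg <- tapply(contrib, subjectHits(hits), sum)
        signal[as.integer(names(agg))] <- as.numeric(agg)
    }
    if (perMillion) signal <- signal / (sum(score) / 1e6)
    windows$signal <- signal
    windows
}
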