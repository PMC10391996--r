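## TF regulatory network: per-stage motif-DHS-promoter edges, merge with the
## co-expression network, edge stage categories, degree/hub statistics, and
## a documented substitute TF-activity score.

#' Build the per-stage DNase (motif-in-promoter-DHS) network
#'
#' An edge TF -> target exists at stage s iff some DHS present at s overlaps
#' the target's 1500-bp strand-aware upstream window by at least 50\% of the
#' DHS's length and fully contains a hit of a motif mapped to the TF. Every
#' TF mapped to a shared motif receives the edge (fan-out). Hits of motifs
#' with no TF mapping are ignored (counted via attribute).
#'
#' @param hits GRanges of motif hits (genome coordinates, \code{motif_id}).
#' @param peaks GRanges DHS catalog with \code{peak_id}.
#' @param stagePresence named list: peak id -> stages at which the DHS is
#'   present.
#' @param genes GRanges with \code{gene_id} and strand.
#' @param motifTfMap data.frame with \code{motif_id}, \code{tf_gene}.
#' @param promoterWidth upstream window in bp (default 1500).
#' @param minOverlap minimum overlapping fraction of the DHS (default 0.5).
#' @return data.frame of per-stage directed edges: \code{tf}, \code{target},
#'   \code{stage}, \code{peak_id}, \code{motif_id}.
#' @export
buildDnaseNetwork <- function(hits, peaks, stagePresence, genes, motifTfMap,
                              promoterWidth = 1500, minOverlap = 0.5) {
    prom <- suppressWarnings(trim(promoters(genes, upstream = promoterWidth,
                                            downstream = 0)))
    ## DHSs overlapping a promoter window by >= minOverlap of DHS length
    ov <- findOverlaps(peaks, prom, ignore.strand = TRUE)
    ovBases <- width(pintersect(peaks[queryHits(ov)], prom[subjectHits(ov)],
                                ignore.strand = TRUE))
    keep <- ovBases >= minOverlap * width(peaks)[queryHits(ov)]
    dhsGene <- data.frame(peak_id = .peakIds(peaks)[queryHits(ov)[keep]],
                          gene_id = genes$gene_id[subjectHits(ov)[keep]],
                          stringsAsFactors = FALSE)
    hitTable <- assignHitsToPeaks(hits, peaks)
    unmapped <- sum(!hitTable$motif_id %in% motifTfMap$motif_id)
    hitTable <- merge(hitTable, motifTfMap, by = "motif_id")
    joined <- merge(dhsGene, hitTable, by = "peak_id")
    rows <- list()
    for (i in seq_len(nrow(joined))) {
        stages <- stagePresence[[joined$peak_id[i]]]
        if (is.null(stages) || !length(stages)) next
        rows[[length(rows) + 1L]] <- data.frame(
            tf = joined$tf_gene[i], target = joined$gene_id[i],
            stage = stages, peak_id = joined$peak_id[i],
            motif_id = joined$motif_id[i], stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) unique(do.call(rbind, rows))
           else data.frame(tf = character(), target = character(),
                           stage = numeric(), peak_id = character(),
                           motif_id = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "unmappedHits") <- unmapped
    out
}

#' Merge the DNase network with the co-expression network
#'
#' A TF -> target edge is retained iff it exists in the DNase network at
#' one or more stages and the (tf, target) pair is an edge of the co-expression
#' network; the sign is copied from co-expression.
#'
#' @param dnaseEdges data.frame from [buildDnaseNetwork()].
#' @param coexprEdges data.frame from [buildCoexpressionNetwork()].
#' @param requirePositive retain only positively co-expressed pairs
#'   (default FALSE: both signs accepted).
#' @return data.frame of final regulatory edges: \code{tf}, \code{target},
#'   \code{stages} (";"-joined, ascending), \code{sign},
#'   \code{coexpression_supported} (all TRUE by construction),
#'   \code{peak_ids}, \code{motif_ids}.
#' @export
mergeNetworks <- function(dnaseEdges, coexprEdges, requirePositive = FALSE) {
    if (!nrow(dnaseEdges))
        return(data.frame(tf = character(), target = character(),
                          stages = character(), sign = character(),
                          coexpression_supported = logical(),
                          peak_ids = character(), motif_ids = character(),
                          stringsAsFactors = FALSE))
    pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    co <- coexprEdges
    if (requirePositive) co <- co[co$sign == "+", , drop = FALSE]
    coKey <- pairKey(co$gene_a, co$gene_b)
    coSign <- setNames(co$sign, coKey)
    key <- paste(dnaseEdges$tf, dnaseEdges$target, sep = "->")
    rows <- lapply(split(dnaseEdges, key), function(d) {
        pk <- pairKey(d$tf[1], d$target[1])
        if (!pk %in% coKey) return(NULL)
        data.frame(tf = d$tf[1], target = d$target[1],
                   stages = paste(sort(unique(d$stage)), collapse = ";"),
                   sign = unname(coSign[pk]),
                   coexpression_supported = TRUE,
                   peak_ids = paste(sort(unique(d$peak_id)), collapse = ";"),
                   motif_ids = paste(sort(unique(d$motif_id)), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(tf = character(), target = character(),
                          stages = character(), sign = character(),
                          coexpression_supported = logical(),
                          peak_ids = character(), motif_ids = character(),
                          stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out[order(out$tf, out$target), , drop = FALSE]
}

#' Classify an edge's stage-presence set into a developmental category
#'
#' Ordered first-match evaluation of the five categories: (1) \code{ovule}
#' (connected only at ovule stages, 0/3 DPA); (2) \code{fiber_and_ovule}
#' (>= 1 ovule stage and >= 1 late-elongation stage, 12/15/18 DPA);
#' (3) \code{fiber} (8 DPA and >= 1 late stage); (4) \code{early_elongation}
#' (8 DPA present, no late stage); (5) \code{late_elongation} (only late
#' stages); anything else falls into \code{other}.
#'
#' @param stagesPresent numeric vector (or ";"-joined string) of stages.
#' @param ovule ovule stage labels (default 0, 3).
#' @param early the early elongation stage (default 8).
#' @param late late elongation stages (default 12, 15, 18).
#' @return category string.
#' @export
classifyEdgeStage <- function(stagesPresent, ovule = c(0, 3), early = 8,
                              late = c(12, 15, 18)) {
    if (is.character(stagesPresent))
        stagesPresent <- as.numeric(strsplit(stagesPresent, ";")[[1]])
    s <- unique(stagesPresent)
    if (!length(s)) stop("empty stage set")
    if (all(s %in% ovule)) return("ovule")
    if (any(s %in% ovule) && any(s %in% late)) return("fiber_and_ovule")
    if (early %in% s && any(s %in% late)) return("fiber")
    if (early %in% s && !any(s %in% late)) return("early_elongation")
    if (all(s %in% late)) return("late_elongation")
    "other"
}

#' Degree statistics and hub TFs of the final network
#'
#' Out-degree counts distinct targets, in-degree distinct regulators; hubs
#' are the top-k nodes by out-degree (tie-break: total degree, then id).
#' Degree-based hub ranking is a deliberate, simple substitute for
#' module-centrality tooling.
#'
#' @param edges data.frame with \code{tf}, \code{target}.
#' @param k number of hubs to report (default 10).
#' @return list with \code{degrees} (data.frame id/out_degree/in_degree/
#'   total_degree) and \code{hubs} (top-k slice).
#' @export
degreeAndHubs <- function(edges, k = 10) {
    if (!nrow(edges)) stop("empty network")
    ids <- sort(unique(c(edges$tf, edges$target)))
    outDeg <- vapply(ids, function(i)
        length(unique(edges$target[edges$tf == i])), integer(1))
    inDeg <- vapply(ids, function(i)
        length(unique(edges$tf[edges$target == i])), integer(1))
    deg <- data.frame(id = ids, out_degree = outDeg, in_degree = inDeg,
                      total_degree = outDeg + inDeg,
                      stringsAsFactors = FALSE)
    deg <- deg[order(-deg$out_degree, -deg$total_degree, deg$id), ]
    rownames(deg) <- NULL
    list(degrees = deg, hubs = head(deg, k))
}

#' Per-stage TF activity score (substitute definition)
#'
#' The raw score at a stage is the mean size-factor-normalized accessibility
#' over the DHSs containing a hit of the TF's motif; scores are reported
#' z-standardized across stages. This is the package's own summary of a
#' TF's open-chromatin footprint over development (no standard definition
#' exists for this quantity).
#'
#' @param tf TF gene id.
#' @param accessibility A [StageCounts-class] of DHS accessibility.
#' @param hitTable data.frame with \code{peak_id}, \code{motif_id}.
#' @param motifTfMap data.frame with \code{motif_id}, \code{tf_gene}.
#' @return named numeric vector of standardized per-stage scores, or NA
#'   vector when the TF has no motif-bearing DHS.
#' @export
tfActivityScore <- function(tf, accessibility, hitTable, motifTfMap) {
    motifs <- motifTfMap$motif_id[motifTfMap$tf_gene == tf]
    dhs <- unique(hitTable$peak_id[hitTable$motif_id %in% motifs])
    profiles <- stageMeanProfiles(accessibility)
    dhs <- intersect(dhs, rownames(profiles))
    stages <- colnames(profiles)
    if (!length(dhs)) {
        message("TF ", tf, " has no motif-bearing DHS: activity undefined")
        return(setNames(rep(NA_real_, length(stages)), stages))
    }
    raw <- colMeans(profiles[dhs, , drop = FALSE])
    s <- sd(raw)
    z <- if (s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
    setNames(z, stages)
}

#' Export a regulatory network as GraphML
#'
#' @param edges data.frame from [mergeNetworks()].
#' @param path output file.
#' @return invisibly, the igraph object written.
#' @export
writeNetworkGraphML <- function(edges, path) {
    g <- igraph::graph_from_data_frame(
        edges[, c("tf", "target", setdiff(colnames(edges), c("tf", "target")))],
        directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
    invisible(g)
}
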