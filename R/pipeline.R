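## End-to-end orchestration: simulate -> annotate -> differential -> link ->
## motifs -> coexpress -> network -> cluster -> qc, with per-stage caching,
## structured logging, and a manifest of every artifact.

#' Read a pipeline configuration from YAML
#'
#' The YAML may carry a \code{simulate} block (arguments to [simConfig()])
#' and per-module override blocks (\code{link}, \code{cluster}, \code{qc},
#' \code{motifs}).
#'
#' @param path YAML file.
#' @return list with \code{config} ([SimConfig-class]) and \code{options}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    simArgs <- if (!is.null(y$simulate)) y$simulate else list()
    config <- do.call(simConfig, simArgs)
    list(config = config,
         options = y[setdiff(names(y), "simulate")])
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes every stage in dependency order, writes standard-format outputs
#' under \code{outdir}, and records a manifest (file md5 hashes, parameters,
#' seed). Reruns with an identical configuration are byte-identical for all
#' deterministic outputs. With \code{resume = TRUE}, stages whose cached
#' result exists under \code{outdir/cache} are reloaded instead of
#' recomputed, so deleting one stage's cache regenerates only that stage and
#' everything downstream of it.
#'
#' @param config A [SimConfig-class] (or result of [readPipelineConfig()]).
#' @param outdir output directory.
#' @param seed optional override of \code{config@seed}.
#' @param resume reuse cached stage results when present (default FALSE).
#' @param options named list of per-module overrides: \code{link} (window,
#'   nRandom, twoDirection, alpha), \code{cluster} (k), \code{qc}
#'   (windowSize), \code{motifs} (pThreshold).
#' @return invisibly, a list with every stage's result and the manifest.
#' @export
runPipeline <- function(config = simConfig(), outdir, seed = NULL,
                        resume = FALSE, options = list()) {
    if (is.list(config) && !is.null(config$config)) {
        options <- utils::modifyList(config$options %||% list(), options)
        config <- config$config
    }
    if (!is.null(seed)) config@seed <- as.integer(seed)
    validObject(config)
    opt <- function(module, name, default) {
        v <- options[[module]][[name]]
        if (is.null(v)) default else v
    }
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    cacheDir <- file.path(outdir, "cache")
    dir.create(cacheDir, showWarnings = FALSE)
    manifest <- list(package = "fibergrn", seed = config@seed,
                     parameters = .configAsList(config), stages = list())
    results <- list()
    computed <- character()
    upstreamChanged <- FALSE

    runStage <- function(name, compute) {
        cache <- file.path(cacheDir, paste0(name, ".rds"))
        t0 <- Sys.time()
        if (resume && !upstreamChanged && file.exists(cache)) {
            message(sprintf("[%s] loaded from cache", name))
            res <- readRDS(cache)
        } else {
            res <- tryCatch(compute(), error = function(e)
                stop("pipeline halted at stage '", name, "': ",
                     conditionMessage(e), call. = FALSE))
            saveRDS(res, cache)
            computed <<- c(computed, name)
            upstreamChanged <<- TRUE
            message(sprintf("[%s] computed in %.1fs", name,
                            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
        }
        results[[name]] <<- res
        res
    }
    stageFiles <- function(name, files) {
        manifest$stages[[name]] <<- list(
            computed = name %in% computed,
            files = as.list(setNames(unname(tools::md5sum(files)),
                                     basename(files))))
    }

    ## -- simulate ----------------------------------------------------------
    sim <- runStage("simulate", function() simulateFiberDataset(config))
    simDir <- file.path(outdir, "simulate")
    paths <- writeSimulation(sim, simDir)
    stageFiles("simulate", paths)
    seqlens <- seqlengths(sim@genes)
    stages <- config@stages
    baseline <- sort(config@ovuleStages)[1]
    elong <- elongationStages(config)

    ## -- annotate ----------------------------------------------------------
    ann <- runStage("annotate", function() {
        loc <- annotatePeakLocations(sim@peaks, sim@genes)
        loc$te_dhs <- unname(flagTeDHS(sim@peaks, sim@tes))
        nd <- nearestGeneDistance(sim@peaks, sim@genes)
        loc$nearest_gene <- nd$nearest_gene
        loc$distance <- nd$distance
        regions <- partitionRegions(sim@genes, sim@tes, seqlens)
        list(annotation = loc, regions = regions)
    })
    annDir <- file.path(outdir, "annotate")
    dir.create(annDir, showWarnings = FALSE)
    annPaths <- c(file.path(annDir, "peak_annotation.tsv"),
                  file.path(annDir, "regions.tsv"))
    write.table(ann$annotation, annPaths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(.regionsAsDf(ann$regions), annPaths[2], sep = "\t",
                quote = FALSE, row.names = FALSE)
    stageFiles("annotate", annPaths)

    ## -- differential ------------------------------------------------------
    diffRes <- runStage("differential", function() {
        docrTests <- lapply(elong, function(s)
            nbWaldTest(sim@accessibility, s, baseline))
        names(docrTests) <- paste0("docr_", elong)
        degTests <- lapply(elong, function(s)
            nbWaldTest(sim@expression, s, baseline))
        names(degTests) <- paste0("deg_", elong)
        list(docrTests = docrTests, degTests = degTests,
             docr = callDifferentialSet(docrTests, "DOCR"),
             deg = callDifferentialSet(degTests, "DEG"))
    })
    diffDir <- file.path(outdir, "differential")
    dir.create(diffDir, showWarnings = FALSE)
    diffPaths <- c(file.path(diffDir, "docr_calls.tsv"),
                   file.path(diffDir, "deg_calls.tsv"))
    write.table(diffRes$docr, diffPaths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(diffRes$deg, diffPaths[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    stageFiles("differential", diffPaths)

    ## -- link --------------------------------------------------------------
    linkRes <- runStage("link", function() {
        peakProf <- stageMeanProfiles(sim@accessibility)
        geneProf <- stageMeanProfiles(sim@expression)
        docrIds <- diffRes$docr$feature[diffRes$docr$status != "ns"]
        degIds <- diffRes$deg$feature[diffRes$deg$status != "ns"]
        window <- opt("link", "window", 5e4)
        eligible <- unique(enumerateCandidatePairs(
            sim@peaks, sim@genes, window)$peak_id)
        null <- buildEmpiricalNull(peakProf[eligible, , drop = FALSE],
                                   geneProf,
                                   n = opt("link", "nRandom", 10000L),
                                   seed = config@seed + 1L)
        pairs <- enumerateCandidatePairs(
            sim@peaks[sim@peaks$peak_id %in% docrIds],
            sim@genes[sim@genes$gene_id %in% degIds], window)
        links <- if (nrow(pairs)) {
            l <- linkPeaksToGenes(pairs, peakProf, geneProf, null = null,
                                  twoDirection = opt("link", "twoDirection", TRUE),
                                  alpha = opt("link", "alpha", 0.05))
            classifyDocrGroups(l[l$significant, , drop = FALSE],
                               diffRes$docr, diffRes$deg)
        } else cbind(pairs, group = character(0))
        list(null = null, pairs = pairs, links = links)
    })
    linkDir <- file.path(outdir, "link")
    dir.create(linkDir, showWarnings = FALSE)
    linkPaths <- c(file.path(linkDir, "links.tsv"),
                   file.path(linkDir, "null_model.json"))
    write.table(linkRes$links, linkPaths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(expected.mean = linkRes$null@mean,
                              expected.std = linkRes$null@sd,
                              n_random_peaks = linkRes$null@n,
                              pool_size = linkRes$null@poolSize,
                              n_stage_points = length(stages),
                              seed = linkRes$null@seed),
                         linkPaths[2], auto_unbox = TRUE, digits = NA)
    stageFiles("link", linkPaths)

    ## -- motifs ------------------------------------------------------------
    motifRes <- runStage("motifs", function() {
        peakSeqs <- extractSequences(sim@sequences, sim@peaks)
        hitsLocal <- scanSequences(peakSeqs, sim@motifs,
                                   pThreshold = opt("motifs", "pThreshold", 1e-4))
        hits <- .liftPeakHits(hitsLocal, sim@peaks, seqlens)
        hitTable <- assignHitsToPeaks(hits, sim@peaks)
        ## per-stage teDHS vs non-teDHS enrichment
        presence <- sim@truth$stagePresence
        enrich <- list()
        for (s in stages) {
            present <- sim@peaks$peak_id[vapply(
                presence[sim@peaks$peak_id], function(p) s %in% p,
                logical(1))]
            teIds <- intersect(present,
                               sim@peaks$peak_id[sim@peaks$te_dhs])
            nonTe <- setdiff(present, teIds)
            if (!length(teIds) || !length(nonTe)) next
            te <- hypergeometricEnrichment(teIds, present, hitTable)
            nt <- hypergeometricEnrichment(nonTe, present, hitTable)
            te$compartment <- "teDHS"; nt$compartment <- "non_teDHS"
            te$stage <- s; nt$stage <- s
            enrich[[as.character(s)]] <- rbind(te, nt)
        }
        enrichment <- do.call(rbind, enrich)
        rownames(enrichment) <- NULL
        ratios <- vapply(sort(unique(enrichment$motif_id)), function(m) {
            e <- enrichment[enrichment$motif_id == m, ]
            teEnrichmentRatio(e$fold[e$compartment == "teDHS"],
                              e$fold[e$compartment == "non_teDHS"])
        }, numeric(1))
        list(hits = hits, hitTable = hitTable, enrichment = enrichment,
             teRatios = ratios)
    })
    motifDir <- file.path(outdir, "motifs")
    dir.create(motifDir, showWarnings = FALSE)
    motifPaths <- c(file.path(motifDir, "motif_hits.gff3"),
                    file.path(motifDir, "enrichment.tsv"),
                    file.path(motifDir, "te_enrichment_ratio.tsv"))
    .writeHitsGff3(motifRes$hits, motifPaths[1])
    write.table(motifRes$enrichment, motifPaths[2], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(motif_id = names(motifRes$teRatios),
                           te_ratio = unname(motifRes$teRatios)),
                motifPaths[3], sep = "\t", quote = FALSE, row.names = FALSE)
    stageFiles("motifs", motifPaths)

    ## -- coexpress ---------------------------------------------------------
    coexRes <- runStage("coexpress", function() {
        pcc <- pccMatrix(sim@expression)
        mr <- mutualRank(pcc)
        list(pcc = pcc, mr = mr,
             edges = buildCoexpressionNetwork(mr, pcc))
    })
    coexDir <- file.path(outdir, "coexpress")
    dir.create(coexDir, showWarnings = FALSE)
    coexPath <- file.path(coexDir, "coexpression_edges.tsv")
    write.table(coexRes$edges, coexPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    stageFiles("coexpress", coexPath)

    ## -- network -----------------------------------------------------------
    netRes <- runStage("network", function() {
        dnase <- buildDnaseNetwork(motifRes$hits, sim@peaks,
                                   sim@truth$stagePresence, sim@genes,
                                   sim@motifTfMap)
        merged <- mergeNetworks(dnase, coexRes$edges)
        if (nrow(merged))
            merged$stage_category <- vapply(
                merged$stages, classifyEdgeStage, character(1),
                ovule = config@ovuleStages, early = elong[1],
                late = elong[-1])
        hubs <- if (nrow(merged)) degreeAndHubs(merged) else NULL
        activity <- lapply(setNames(nm = unique(sim@motifTfMap$tf_gene)),
                           function(tf) tfActivityScore(
                               tf, sim@accessibility, motifRes$hitTable,
                               sim@motifTfMap))
        list(dnase = dnase, merged = merged, hubs = hubs,
             activity = do.call(rbind, activity))
    })
    netDir <- file.path(outdir, "network")
    dir.create(netDir, showWarnings = FALSE)
    netPaths <- c(file.path(netDir, "regulatory_network.tsv"),
                  file.path(netDir, "regulatory_network.graphml"),
                  file.path(netDir, "hubs.tsv"),
                  file.path(netDir, "tf_activity.tsv"))
    write.table(netRes$merged, netPaths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (nrow(netRes$merged)) writeNetworkGraphML(netRes$merged, netPaths[2])
    else writeLines("<graphml/>", netPaths[2])
    if (!is.null(netRes$hubs))
        write.table(netRes$hubs$hubs, netPaths[3], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    else writeLines("id\tout_degree\tin_degree\ttotal_degree", netPaths[3])
    write.table(data.frame(tf = rownames(netRes$activity),
                           netRes$activity, check.names = FALSE),
                netPaths[4], sep = "\t", quote = FALSE, row.names = FALSE)
    stageFiles("network", netPaths)

    ## -- cluster -----------------------------------------------------------
    clustRes <- runStage("cluster", function() {
        pm <- profileMatrix(sim@expression, sim@accessibility, sim@peaks,
                            sim@genes)
        norm <- normalize95(pm)
        k <- min(opt("cluster", "k", 13L), nrow(norm))
        km <- kmeansProfiles(norm, k = k, seed = config@seed + 2L)
        ranges <- lapply(seq_len(k), function(i)
            rangeability(km$centers[i, ], nExpr = length(stages)))
        tss <- GRanges(seqnames(sim@genes),
                       IRanges(tssPositions(sim@genes), width = 1))
        ov <- findOverlaps(tss, ann$regions)
        regionByGene <- setNames(
            ann$regions$label[subjectHits(ov)],
            sim@genes$gene_id[queryHits(ov)])
        enrich <- regionEnrichment(km$labels, regionByGene)
        list(profiles = norm, kmeans = km, rangeability = ranges,
             regionEnrichment = enrich, regionByGene = regionByGene)
    })
    clustDir <- file.path(outdir, "cluster")
    dir.create(clustDir, showWarnings = FALSE)
    clustPaths <- c(file.path(clustDir, "cluster_labels.tsv"),
                    file.path(clustDir, "centroids.tsv"),
                    file.path(clustDir, "region_enrichment.tsv"))
    write.table(data.frame(gene_id = names(clustRes$kmeans$labels),
                           cluster = unname(clustRes$kmeans$labels)),
                clustPaths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(cluster = seq_len(nrow(clustRes$kmeans$centers)),
                           clustRes$kmeans$centers, check.names = FALSE),
                clustPaths[2], sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(clustRes$regionEnrichment, clustPaths[3], sep = "\t",
                quote = FALSE, row.names = FALSE)
    stageFiles("cluster", clustPaths)

    ## -- qc ----------------------------------------------------------------
    qcRes <- runStage("qc", function() {
        if (config@accReplicates < 2) {
            message("qc skipped: fewer than 2 accessibility replicates")
            return(data.frame())
        }
        qcReport(sim@peakReplicates, sim@accessibility, seqlens,
                 windowSize = opt("qc", "windowSize", 5000),
                 seed = config@seed + 3L)
    })
    qcDir <- file.path(outdir, "qc")
    dir.create(qcDir, showWarnings = FALSE)
    qcPath <- file.path(qcDir, "qc_report.json")
    jsonlite::write_json(list(method = "reciprocal_overlap_0.5 (simplified; not IDR)",
                              per_stage = qcRes),
                         qcPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageFiles("qc", qcPath)

    manifest$stages <- manifest$stages[c("simulate", "annotate",
                                         "differential", "link", "motifs",
                                         "coexpress", "network", "cluster",
                                         "qc")]
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$manifest <- manifest
    invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configAsList <- function(config) {
    out <- lapply(slotNames(config), function(s) slot(config, s))
    names(out) <- slotNames(config)
    out
}

.regionsAsDf <- function(regions) {
    data.frame(chrom = as.character(seqnames(regions)),
               start = start(regions) - 1L, end = end(regions),
               gene_fraction = regions$gene_fraction,
               te_fraction = regions$te_fraction,
               label = regions$label, stringsAsFactors = FALSE)
}

## Lift peak-local motif hits to genome coordinates.
.liftPeakHits <- function(hitsLocal, peaks, seqlens) {
    if (!length(hitsLocal)) return(GRanges(seqlengths = seqlens))
    idx <- match(as.character(seqnames(hitsLocal)), peaks$peak_id)
    GRanges(seqnames(peaks)[idx],
            IRanges(start(peaks)[idx] + start(hitsLocal) - 1L,
                    start(peaks)[idx] + end(hitsLocal) - 1L),
            strand = strand(hitsLocal), seqlengths = seqlens,
            motif_id = hitsLocal$motif_id, score = hitsLocal$score,
            pvalue = hitsLocal$pvalue)
}

.writeHitsGff3 <- function(hits, path) {
    out <- granges(hits)
    out$type <- "TF_binding_site"
    out$source <- "fibergrn"
    out$ID <- paste0("hit", seq_along(hits))
    out$Name <- hits$motif_id
    out$score <- hits$score
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}
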