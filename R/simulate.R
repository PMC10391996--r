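## Synthetic staged ovule/fiber dataset generator.
##
## The generator plants every structure the downstream analysis is meant to
## recover -- TE-derived DHSs, stage-specific (differentially open) peaks,
## peak-gene links with a controlled latent stage-profile correlation,
## co-expression modules, archetypal 4-fold ovule-high / elongation-high
## expression programs, and TF->target edges realised as consensus motif
## occurrences written into promoter DHSs -- and emits the ground truth
## alongside the data.

#' Generate the toy genome: gene models, TEs, sequences, region labels
#'
#' Chromosomes are partitioned into 1-Mb windows designated gene-rich,
#' TE-rich, or balanced; genes and TEs are allocated to windows at densities
#' that realise those labels (TE coverage at least twice gene coverage in
#' TE-rich windows, and conversely). Genes are placed on a non-overlapping
#' slot grid, so gene models never overlap, on either strand. Sequences are
#' uniform-random uppercase ACGT. Deterministic given \code{config@seed}.
#'
#' @param config A [SimConfig-class].
#' @return A list with \code{sequences} (DNAStringSet), \code{genes} and
#'   \code{tes} (GRanges), \code{regions} (GRanges of 1-Mb windows with a
#'   \code{label} column), and \code{tfAssignments} (data.frame of planted
#'   TF -> target pairings).
#' @export
simulateGenome <- function(config) {
    validObject(config)
    seed <- childSeeds(config@seed, "genome")[["genome"]]
    withr::with_seed(seed, .simulateGenome(config))
}

.simulateGenome <- function(config) {
    chromLen <- config@chromosomeLength
    chroms <- paste0("chr", seq_len(config@nChromosomes))
    seqlens <- setNames(rep(chromLen, config@nChromosomes), chroms)

    ## 1-Mb windows and their planted labels
    winStarts <- seq(1, chromLen, by = 1e6)
    windows <- GRanges(rep(chroms, each = length(winStarts)),
                       IRanges(rep(winStarts, config@nChromosomes),
                               width = pmin(1e6, chromLen - rep(winStarts, config@nChromosomes) + 1)))
    nWin <- length(windows)
    nTeRich <- round(config@teRichFraction * nWin)
    nGeneRich <- round(0.5 * (nWin - nTeRich))
    labels <- rep("balanced", nWin)
    idx <- sample.int(nWin)
    labels[idx[seq_len(nTeRich)]] <- "te_rich"
    labels[idx[nTeRich + seq_len(nGeneRich)]] <- "gene_rich"
    windows$label <- labels

    ## gene allocation: slot grid guarantees non-overlap
    slotWidth <- 5000L
    slotsPerWin <- floor(width(windows) / slotWidth)
    geneWeight <- c(gene_rich = 3, balanced = 2, te_rich = 0.8)[labels]
    if (sum(slotsPerWin) < config@nGenes)
        stop("sizing error: chromosomes too short to place ", config@nGenes,
             " genes (capacity ", sum(slotsPerWin), ")")
    nPerWin <- .allocateCounts(config@nGenes, geneWeight, slotsPerWin)

    geneRows <- vector("list", nWin)
    for (i in seq_len(nWin)) {
        n <- nPerWin[i]
        if (n == 0L) next
        slots <- sort(sample.int(slotsPerWin[i], n))
        w <- sample(2000:4500, n, replace = TRUE)
        slotStart <- start(windows)[i] + (slots - 1L) * slotWidth
        offset <- floor(runif(n) * (slotWidth - w))
        geneRows[[i]] <- data.frame(
            chrom = as.character(seqnames(windows))[i],
            start = slotStart + offset, width = w,
            strand = sample(c("+", "-"), n, replace = TRUE),
            window = i)
    }
    geneDf <- do.call(rbind, geneRows)
    geneDf <- geneDf[order(geneDf$chrom, geneDf$start), ]
    genes <- GRanges(geneDf$chrom, IRanges(geneDf$start, width = geneDf$width),
                     strand = geneDf$strand, seqlengths = seqlens)
    genes$gene_id <- padIds("gene", nrow(geneDf))
    genes$window <- geneDf$window

    ## TE allocation
    teWeight <- c(gene_rich = 1, balanced = 3.3, te_rich = 12)[labels]
    tePerWin <- .allocateCounts(config@nTes, teWeight, rep(Inf, nWin))
    teRows <- vector("list", nWin)
    for (i in seq_len(nWin)) {
        n <- tePerWin[i]
        if (n == 0L) next
        w <- sample(500:3000, n, replace = TRUE)
        maxStart <- pmax(start(windows)[i], end(windows)[i] - w + 1L)
        s <- start(windows)[i] +
            floor(runif(n) * pmax(1, end(windows)[i] - w - start(windows)[i] + 1))
        teRows[[i]] <- data.frame(chrom = as.character(seqnames(windows))[i],
                                  start = pmin(s, maxStart), width = w)
    }
    teDf <- do.call(rbind, teRows)
    teDf <- teDf[order(teDf$chrom, teDf$start), ]
    tes <- GRanges(teDf$chrom, IRanges(teDf$start, width = teDf$width),
                   strand = "*", seqlengths = seqlens)
    tes$te_id <- padIds("te", nrow(teDf))

    ## gene roles: archetypes biased by region, TF regulons, modules, flat
    genes$class <- .assignGeneClasses(genes, windows$label, config)

    tfGenes <- genes$gene_id[genes$class == "tf"]
    targetGenes <- genes$gene_id[genes$class == "target"]
    tfAssignments <- data.frame(
        tf_gene = rep(tfGenes, each = config@targetsPerTf),
        target_gene = sample(targetGenes),
        stringsAsFactors = FALSE)

    ## module memberships (TF regulons are their own tight expression groups)
    genes$module <- NA_integer_
    moduleGenes <- genes$gene_id[genes$class == "module"]
    if (length(moduleGenes))
        genes$module[match(moduleGenes, genes$gene_id)] <-
            rep(seq_len(config@nModules), each = config@moduleSize)

    ## sequences
    sequences <- DNAStringSet(vapply(chroms, function(ch)
        paste(sample(c("A", "C", "G", "T"), chromLen, replace = TRUE),
              collapse = ""), character(1)))
    names(sequences) <- chroms

    list(sequences = sequences, genes = genes, tes = tes, regions = windows,
         tfAssignments = tfAssignments, seqlengths = seqlens)
}

## Largest-remainder allocation of n items to bins by weight, within capacity.
.allocateCounts <- function(n, weights, capacity) {
    raw <- n * weights / sum(weights)
    alloc <- pmin(floor(raw), capacity)
    while (sum(alloc) < n) {
        spare <- capacity - alloc
        frac <- ifelse(spare > 0, raw - floor(raw) + weights / sum(weights), -Inf)
        i <- which.max(frac)
        if (!is.finite(frac[i]))
            stop("sizing error: total capacity insufficient")
        alloc[i] <- alloc[i] + 1L
        raw[i] <- alloc[i]          # consumed its remainder
    }
    as.integer(alloc)
}

.assignGeneClasses <- function(genes, windowLabels, config) {
    n <- length(genes)
    nOv <- round(config@ovuleHighFraction * n)
    nEl <- round(config@elongationHighFraction * n)
    nTf <- config@nTfs
    nTarget <- config@nTfs * config@targetsPerTf
    nMod <- config@nModules * config@moduleSize
    if (nOv + nEl + nTf + nTarget + nMod > n)
        stop("config error: gene role fractions exceed the number of genes")
    cls <- rep("flat", n)
    pool <- seq_len(n)
    inTeRich <- windowLabels[genes$window] == "te_rich"
    inGeneRich <- windowLabels[genes$window] == "gene_rich"
    pick <- function(pool, k, weight) {
        if (k == 0L) return(integer())
        sample(pool, k, prob = weight[pool])
    }
    ## ovule-high genes concentrate in TE-rich regions (and conversely),
    ## emulating the observed coupling between pericentromeric accessibility
    ## and ovule-stage expression
    ov <- pick(pool, nOv, ifelse(inTeRich, 6, 1))
    pool <- setdiff(pool, ov)
    el <- pick(pool, nEl, ifelse(inGeneRich, 6, 1))
    pool <- setdiff(pool, el)
    ## TF regulons prefer TE-sparse neighbourhoods so target promoters can
    ## host TE-clear DHSs
    tf <- pick(pool, nTf, ifelse(inTeRich, 1, 6))
    pool <- setdiff(pool, tf)
    tg <- pick(pool, nTarget, ifelse(inTeRich, 1, 6))
    pool <- setdiff(pool, tg)
    md <- if (nMod) sample(pool, nMod) else integer()
    cls[ov] <- "ovule_high"; cls[el] <- "elongation_high"
    cls[tf] <- "tf"; cls[tg] <- "target"; cls[md] <- "module"
    cls
}

#' Generate the DHS catalog and per-stage/per-replicate peak sets
#'
#' A configurable fraction of catalog peaks is placed to overlap a
#' transposable element by at least 30\% of peak length (flagged
#' \code{te_dhs}); a disjoint fraction is placed wholly within 1.5-kb
#' promoter windows; planted-link peaks are placed within 50 kb of their
#' partner gene; planted-edge peaks sit wholly within their target's promoter
#' window. All non-TE peaks are rejection-sampled to keep their TE overlap
#' below 30\%. Stage-specific presence patterns make a \code{docrFraction} of
#' peaks differentially open; replicate peak sets are jittered, thinned
#' copies of the per-stage consensus.
#'
#' @param genome result of [simulateGenome()].
#' @param config the same [SimConfig-class].
#' @return A list with \code{catalog} (GRanges with \code{peak_id},
#'   \code{type}, \code{te_dhs}, link/edge annotations and a \code{presence}
#'   string), \code{replicates} (GRanges with \code{stage} and
#'   \code{replicate}), and \code{stagePresence} (named list of stage
#'   vectors).
#' @export
simulatePeaks <- function(genome, config) {
    seed <- childSeeds(config@seed, "peaks")[["peaks"]]
    withr::with_seed(seed, .simulatePeaks(genome, config))
}

.simulatePeaks <- function(genome, config) {
    nTe <- round(config@teDhsFraction * config@nPeaks)
    nProm <- round(config@promoterPeakFraction * config@nPeaks)
    nLink <- config@nPlantedLinks
    nEdge <- config@plantedEdgeCount
    nBg <- config@nPeaks - nTe - nProm - nLink - nEdge
    if (nBg < 0)
        stop("config error: peak fraction sums exceed 1 ",
             "(TE + promoter + link + edge peaks exceed nPeaks)")
    seqlens <- genome$seqlengths
    mergedTe <- reduce(genome$tes, ignore.strand = TRUE)
    teFrac <- function(gr) overlapBases(gr, mergedTe) / width(gr)

    rejectionPlace <- function(n, proposal) {
        ## draw candidate peaks until their TE overlap stays below 30%
        out <- NULL
        tries <- 0L
        while ((is.null(out) || length(out) < n) && tries < 200L) {
            need <- n - if (is.null(out)) 0L else length(out)
            cand <- proposal(need)
            keep <- cand[teFrac(cand) < 0.3]
            out <- if (is.null(out)) keep else c(out, keep)
            tries <- tries + 1L
        }
        if (length(out) < n)
            stop("sizing error: could not place ", n,
                 " peaks clear of the TE track")
        out[seq_len(n)]
    }

    uniformPeaks <- function(n) {
        w <- sample(150:500, n, replace = TRUE)
        chrom <- sample(names(seqlens), n, replace = TRUE)
        s <- 1L + floor(runif(n) * (seqlens[chrom] - w))
        GRanges(chrom, IRanges(s, width = w), seqlengths = seqlens)
    }

    ## TE-derived peaks: overlap a TE by construction (>= 35% of length)
    tePeaks <- local({
        if (nTe == 0L) return(GRanges(seqlengths = seqlens))
        teIdx <- sample.int(length(genome$tes), nTe, replace = TRUE)
        te <- genome$tes[teIdx]
        w <- sample(150:500, nTe, replace = TRUE)
        inside <- runif(nTe) < 0.7 & width(te) >= w
        s <- integer(nTe)
        insideMax <- pmax(start(te), end(te) - w + 1L)
        s[inside] <- start(te)[inside] +
            floor(runif(sum(inside)) * pmax(1, insideMax - start(te) + 1)[inside])
        ov <- ceiling(runif(nTe, 0.35, 0.9) * w)
        ov <- pmin(ov, width(te))
        right <- runif(nTe) < 0.5
        s[!inside & right] <- (end(te) - ov + 1L)[!inside & right]
        s[!inside & !right] <- (start(te) + ov - w)[!inside & !right]
        s <- pmax(1L, pmin(s, as.integer(seqlens[as.character(seqnames(te))]) - w + 1L))
        GRanges(seqnames(te), IRanges(s, width = w), seqlengths = seqlens)
    })

    promWindows <- suppressWarnings(
        GenomicRanges::trim(promoters(genome$genes, upstream = 1500, downstream = 0)))
    placeInPromoter <- function(geneIdx, wmin, wmax) {
        win <- promWindows[geneIdx]
        w <- sample(wmin:wmax, length(geneIdx), replace = TRUE)
        w <- pmin(w, width(win))
        s <- start(win) + floor(runif(length(geneIdx)) * (width(win) - w + 1))
        GRanges(seqnames(win), IRanges(s, width = w), seqlengths = seqlens)
    }

    targetIds <- genome$tfAssignments$target_gene
    nonTarget <- which(!genome$genes$gene_id %in% targetIds)

    promPeaks <- rejectionPlace(nProm, function(n)
        placeInPromoter(sample(nonTarget, n, replace = TRUE), 150L, 400L))
    ## promoter peak -> which gene's promoter it sits in is implicit; keep it
    promPeaks$host_gene <- NA_character_

    edgePeaks <- if (nEdge) {
        gidx <- match(targetIds, genome$genes$gene_id)
        ## placed one at a time so the peak-to-target pairing is preserved
        p <- local({
            out <- vector("list", nEdge)
            for (i in seq_len(nEdge)) {
                for (try in 1:100) {
                    cand <- placeInPromoter(gidx[i], 250L, 400L)
                    out[[i]] <- cand   # accept TE-overlapping as last resort
                    if (teFrac(cand) < 0.3) break
                }
            }
            do.call(c, out)
        })
        p$host_gene <- targetIds
        p
    } else GRanges(seqlengths = seqlens)

    ## planted-link peaks: within 50 kb of a structured (archetype) gene
    archetype <- which(genome$genes$class %in% c("ovule_high", "elongation_high"))
    if (nLink > 0L && length(archetype) == 0L)
        stop("config error: planted links require archetype genes")
    linkGenes <- if (nLink) sample(archetype, nLink, replace = TRUE) else integer()
    linkPeaks <- if (nLink) {
        out <- vector("list", nLink)
        for (i in seq_len(nLink)) {
            g <- genome$genes[linkGenes[i]]
            for (try in 1:200) {
                w <- sample(150:500, 1)
                gap <- sample(500:45000, 1)
                upstream <- runif(1) < 0.5
                s <- if (upstream) start(g) - gap - w else end(g) + gap
                if (s < 1 || s + w - 1 > seqlens[[as.character(seqnames(g))]]) next
                cand <- GRanges(seqnames(g), IRanges(s, width = w),
                                seqlengths = seqlens)
                if (teFrac(cand) < 0.3) { out[[i]] <- cand; break }
            }
            if (is.null(out[[i]]))
                stop("sizing error: could not place link peak near gene ",
                     g$gene_id)
        }
        do.call(c, out)
    } else GRanges(seqlengths = seqlens)

    bgPeaks <- if (nBg) rejectionPlace(nBg, uniformPeaks)
               else GRanges(seqlengths = seqlens)

    catalog <- c(granges(tePeaks), granges(promPeaks), granges(edgePeaks),
                 granges(linkPeaks), granges(bgPeaks))
    catalog$peak_id <- padIds("peak", length(catalog))
    catalog$type <- rep(c("te", "promoter", "edge", "link", "background"),
                        c(nTe, nProm, nEdge, nLink, nBg))
    ## the flag always reflects the emitted TE track (TE-type peaks overlap
    ## >= 35% by construction; other types are rejection-sampled below 30%,
    ## except edge peaks pinned to TE-covered promoters)
    catalog$te_dhs <- teFrac(catalog) >= 0.3
    catalog$link_gene <- NA_character_
    if (nLink)
        catalog$link_gene[catalog$type == "link"] <-
            genome$genes$gene_id[linkGenes]
    catalog$link_sign <- NA_integer_
    if (nLink)
        catalog$link_sign[catalog$type == "link"] <-
            ifelse(runif(nLink) < config@linkPositiveFraction, 1L, -1L)
    catalog$target_gene <- NA_character_
    if (nEdge) catalog$target_gene[catalog$type == "edge"] <- targetIds

    ## stage presence: constitutive unless differentially open by design
    stages <- config@stages
    elong <- elongationStages(config)
    presence <- rep(list(stages), length(catalog))
    eligible <- which(catalog$type %in% c("te", "promoter", "background"))
    nDocr <- min(round(config@docrFraction * config@nPeaks), length(eligible))
    docrIdx <- sample(eligible, nDocr,
                      prob = ifelse(catalog$type[eligible] == "te", 3, 1))
    for (i in docrIdx) {
        ovuleType <- if (catalog$type[i] == "te") runif(1) < 0.8 else runif(1) < 0.3
        presence[[i]] <- if (ovuleType) config@ovuleStages
        else if (length(elong) <= 2L || runif(1) < 0.6) elong
        else sort(sample(elong, length(elong) - 1L))
    }
    ## edge peaks carry the planted stage set of their regulatory edge
    edgeIdx <- which(catalog$type == "edge")
    patterns <- list(stages, config@ovuleStages, elong,
                     if (length(elong) > 1) elong[-1] else elong, elong[1])
    for (i in edgeIdx)
        presence[[i]] <- sort(patterns[[sample.int(5, 1, prob = c(.5, .125, .125, .125, .125))]])
    catalog$presence <- vapply(presence, paste, character(1), collapse = ";")

    ## jittered replicate copies of the per-stage consensus
    repRows <- list()
    for (s in stages) {
        present <- which(vapply(presence, function(p) s %in% p, logical(1)))
        for (r in seq_len(config@accReplicates)) {
            keep <- present[runif(length(present)) >= config@peakDropout]
            p <- catalog[keep]
            shift <- round(rnorm(length(p), 0, config@peakJitterSd))
            ns <- pmax(1L, pmin(start(p) + shift,
                as.integer(seqlens[as.character(seqnames(p))]) - width(p) + 1L))
            jit <- GRanges(seqnames(p), IRanges(ns, width = width(p)),
                           seqlengths = seqlens)
            jit$peak_id <- p$peak_id
            jit$stage <- s
            jit$replicate <- r
            repRows[[length(repRows) + 1L]] <- jit
        }
    }
    replicates <- do.call(c, repRows)

    names(presence) <- catalog$peak_id
    list(catalog = catalog, replicates = replicates, stagePresence = presence)
}

#' Generate accessibility and expression counts with planted structure
#'
#' Latent per-stage means are built as \code{base * (1 + cv * w)} where
#' \code{w} is a standardized stage profile: archetype genes get 4-fold
#' ovule-high or elongation-high programs, module and TF-regulon genes share
#' profiles at a controlled correlation, and each planted link forces the
#' peak's standardized latent profile to have sample correlation exactly
#' \code{sign * linkEffect} with its partner gene's. Counts are negative
#' binomial around \code{mu * depth} with variance \eqn{\mu + \alpha\mu^2}
#' (Poisson when \code{nbDispersion = 0}).
#'
#' @param genome result of [simulateGenome()].
#' @param peaks result of [simulatePeaks()].
#' @param config the same [SimConfig-class].
#' @return A list with \code{accessibility} and \code{expression}
#'   ([StageCounts-class]) and a \code{truth} list (links, modules, cluster
#'   labels, latent stage-mean matrices, depth factors).
#' @export
simulateCounts <- function(genome, peaks, config) {
    if (config@nbDispersion < 0)
        stop("parameter error: nb_dispersion must be >= 0")
    seed <- childSeeds(config@seed, "counts")[["counts"]]
    withr::with_seed(seed, .simulateCounts(genome, peaks, config))
}

.simulateCounts <- function(genome, peaks, config) {
    stages <- config@stages
    k <- length(stages)
    ovule <- stages %in% config@ovuleStages
    genes <- genome$genes
    nG <- length(genes)

    baseG <- runif(nG, config@baseMeanRange[1], config@baseMeanRange[2])
    exprMu <- matrix(0, nG, k, dimnames = list(genes$gene_id, stages))

    tfShared <- list()
    for (tf in unique(genome$tfAssignments$tf_gene))
        tfShared[[tf]] <- standardizeProfile(rnorm(k))
    modShared <- lapply(seq_len(max(1L, config@nModules)),
                        function(i) standardizeProfile(rnorm(k)))

    tfOf <- setNames(genome$tfAssignments$tf_gene,
                     genome$tfAssignments$target_gene)
    for (i in seq_len(nG)) {
        cls <- genes$class[i]
        mu <- switch(cls,
            ovule_high = baseG[i] * ifelse(ovule, 1, 0.25) *
                pmax(0.02, 1 + config@archetypeJitter * rnorm(k)),
            elongation_high = baseG[i] * ifelse(ovule, 0.25, 1) *
                pmax(0.02, 1 + config@archetypeJitter * rnorm(k)),
            module = {
                w <- correlatedProfile(modShared[[genes$module[i]]],
                                       config@moduleEffect)
                baseG[i] * pmax(0.02, 1 + config@stageCv * w)
            },
            tf = {
                w <- correlatedProfile(tfShared[[genes$gene_id[i]]], 0.97)
                baseG[i] * pmax(0.02, 1 + config@stageCv * w)
            },
            target = {
                w <- correlatedProfile(tfShared[[tfOf[[genes$gene_id[i]]]]], 0.97)
                baseG[i] * pmax(0.02, 1 + config@stageCv * w)
            },
            flat = baseG[i] * pmax(0.02, 1 + config@flatCv *
                                       standardizeProfile(rnorm(k))))
        exprMu[i, ] <- mu
    }

    catalog <- peaks$catalog
    nP <- length(catalog)
    baseP <- runif(nP, config@baseMeanRange[1], config@baseMeanRange[2])
    accMu <- matrix(0, nP, k, dimnames = list(catalog$peak_id, stages))
    linkCv <- 0.35   # keeps 1 + linkCv*w positive for any standardized 6-vector
    for (i in seq_len(nP)) {
        if (catalog$type[i] == "link") {
            u <- standardizeProfile(exprMu[catalog$link_gene[i], ])
            w <- catalog$link_sign[i] * correlatedProfile(u, config@linkEffect)
            accMu[i, ] <- baseP[i] * pmax(0.02, 1 + linkCv * w)
        } else {
            pres <- stages %in% peaks$stagePresence[[catalog$peak_id[i]]]
            lvl <- ifelse(pres, 1, 0.15)
            accMu[i, ] <- pmax(0.5, baseP[i] * lvl *
                                   pmax(0.02, 1 + 0.15 * rnorm(k)))
        }
    }

    ## Genes of one co-expression group (module or TF regulon) share a
    ## per-sample biological factor: real co-expressed genes covary at the
    ## replicate level too, not only through their 6-point stage profile.
    drawAssay <- function(mu, reps, groups = NULL, groupSd = 0.3) {
        nSamp <- k * reps
        depth <- runif(nSamp, 1 - config@depthVariation,
                       1 + config@depthVariation)
        groupIds <- unique(groups[!is.na(groups)])
        h <- if (length(groupIds))
            matrix(rnorm(length(groupIds) * nSamp), length(groupIds),
                   nSamp, dimnames = list(groupIds, NULL))
        counts <- matrix(0L, nrow(mu), nSamp)
        stage <- rep(stages, each = reps)
        replicate <- rep(seq_len(reps), k)
        for (j in seq_len(nSamp)) {
            sIdx <- match(stage[j], stages)
            muj <- mu[, sIdx] * depth[j]
            if (length(groupIds)) {
                gi <- which(!is.na(groups))
                muj[gi] <- muj[gi] * pmax(0.05, 1 + groupSd * h[groups[gi], j])
            }
            counts[, j] <- rcounts(nrow(mu), muj, config@nbDispersion)
        }
        dimnames(counts) <- list(rownames(mu), paste0(stage, "_", replicate))
        names(depth) <- colnames(counts)
        list(sc = StageCounts(counts, stage, replicate), depth = depth)
    }

    coexprGroup <- rep(NA_character_, nG)
    coexprGroup[genes$class == "module"] <- paste0("m", genes$module[genes$class == "module"])
    coexprGroup[genes$class == "tf"] <- paste0("r", genes$gene_id[genes$class == "tf"])
    coexprGroup[genes$class == "target"] <-
        paste0("r", unname(tfOf[genes$gene_id[genes$class == "target"]]))

    acc <- drawAssay(accMu, config@accReplicates)
    expr <- drawAssay(exprMu, config@exprReplicates, groups = coexprGroup)

    linkIdx <- which(catalog$type == "link")
    links <- data.frame(
        peak_id = catalog$peak_id[linkIdx],
        gene_id = catalog$link_gene[linkIdx],
        sign = catalog$link_sign[linkIdx],
        effect = rep(config@linkEffect, length(linkIdx)),
        stringsAsFactors = FALSE)

    modules <- data.frame(gene_id = genes$gene_id[!is.na(genes$module)],
                          module = genes$module[!is.na(genes$module)],
                          stringsAsFactors = FALSE)

    clusterLabels <- setNames(
        ifelse(genes$class %in% c("ovule_high", "elongation_high", "flat"),
               genes$class, NA_character_),
        genes$gene_id)

    list(accessibility = acc$sc, expression = expr$sc,
         truth = list(links = links, modules = modules,
                      clusterLabels = clusterLabels,
                      accLatentMeans = accMu, exprLatentMeans = exprMu,
                      accDepthFactors = acc$depth,
                      exprDepthFactors = expr$depth))
}

#' Generate TF motifs and plant consensus occurrences in promoter DHSs
#'
#' Each TF receives an information-rich PWM (dominant base probability 0.85);
#' for every planted TF -> target edge, the TF's consensus is written into
#' the target's promoter DHS (which lies wholly within the 1500-bp upstream
#' window), so the full scan -> containment -> promoter-overlap -> merge
#' pipeline can recover the edge.
#'
#' @param genome result of [simulateGenome()].
#' @param peaks result of [simulatePeaks()].
#' @param config the same [SimConfig-class].
#' @return A list with \code{motifs} (list of [MotifModel-class]),
#'   \code{motifTfMap} (data.frame motif_id/tf_gene), \code{plantedHits}
#'   (GRanges of inserted occurrences), and \code{sequences} (chromosome set
#'   with the insertions applied).
#' @export
simulateMotifs <- function(genome, peaks, config) {
    seed <- childSeeds(config@seed, "motifs")[["motifs"]]
    withr::with_seed(seed, .simulateMotifs(genome, peaks, config))
}

.simulateMotifs <- function(genome, peaks, config) {
    L <- config@motifLength
    catalog <- peaks$catalog
    edgeIdx <- which(catalog$type == "edge")
    if (length(edgeIdx) && L > min(width(catalog[edgeIdx])))
        stop("config error: motif_length exceeds the smallest promoter DHS")

    tfs <- unique(genome$tfAssignments$tf_gene)
    bases <- c("A", "C", "G", "T")
    consensi <- character(0)
    motifs <- list()
    for (i in seq_along(tfs)) {
        repeat {
            cons <- paste(sample(bases, L, replace = TRUE), collapse = "")
            if (!cons %in% consensi) break
        }
        consensi <- c(consensi, cons)
        m <- matrix(0.05, 4, L, dimnames = list(bases, NULL))
        hit <- match(strsplit(cons, "")[[1]], bases)
        m[cbind(hit, seq_len(L))] <- 0.85
        motifs[[i]] <- motifModel(sprintf("motif%02d", i), m)
    }
    names(motifs) <- vapply(motifs, function(m) m@id, character(1))
    motifTfMap <- data.frame(motif_id = names(motifs), tf_gene = tfs,
                             stringsAsFactors = FALSE)

    ## write each TF's consensus into its targets' promoter DHSs
    sequences <- genome$sequences
    hitRows <- list()
    tfOfTarget <- setNames(genome$tfAssignments$tf_gene,
                           genome$tfAssignments$target_gene)
    for (i in edgeIdx) {
        target <- catalog$target_gene[i]
        tf <- tfOfTarget[[target]]
        cons <- consensi[match(tf, tfs)]
        at <- start(catalog)[i] + floor((width(catalog)[i] - L) / 2)
        chrom <- as.character(seqnames(catalog))[i]
        sequences[[chrom]] <- replaceAt(sequences[[chrom]],
                                        IRanges(at, width = L), cons)
        g <- GRanges(chrom, IRanges(at, width = L), strand = "+",
                     seqlengths = genome$seqlengths)
        g$motif_id <- names(motifs)[match(tf, tfs)]
        g$peak_id <- catalog$peak_id[i]
        hitRows[[length(hitRows) + 1L]] <- g
    }
    plantedHits <- if (length(hitRows)) do.call(c, hitRows)
                   else GRanges(seqlengths = genome$seqlengths)

    list(motifs = motifs, motifTfMap = motifTfMap,
         plantedHits = plantedHits, sequences = sequences)
}

#' Simulate a complete staged ovule/fiber dataset
#'
#' Runs the genome, peak, count, and motif generators in order and assembles
#' a [FiberSim-class] object carrying the data and the full ground truth.
#' Byte-identical outputs are guaranteed for identical configurations
#' (a single global seed fans out to per-component child seeds).
#'
#' @param config A [SimConfig-class]; see [simConfig()].
#' @return A [FiberSim-class] object.
#' @examples
#' sim <- simulateFiberDataset(simConfig(seed = 1, nGenes = 60, nPeaks = 80,
#'     nPlantedLinks = 5, nModules = 4, nTfs = 2, nTes = 80))
#' sim
#' @export
simulateFiberDataset <- function(config = simConfig()) {
    genome <- simulateGenome(config)
    peaks <- simulatePeaks(genome, config)
    counts <- simulateCounts(genome, peaks, config)
    motifs <- simulateMotifs(genome, peaks, config)

    catalog <- peaks$catalog
    edgeIdx <- which(catalog$type == "edge")
    tfOfTarget <- setNames(genome$tfAssignments$tf_gene,
                           genome$tfAssignments$target_gene)
    edges <- if (length(edgeIdx)) data.frame(
        tf_gene = unname(tfOfTarget[catalog$target_gene[edgeIdx]]),
        target_gene = catalog$target_gene[edgeIdx],
        peak_id = catalog$peak_id[edgeIdx],
        stages = catalog$presence[edgeIdx],
        stringsAsFactors = FALSE)
    else data.frame(tf_gene = character(), target_gene = character(),
                    peak_id = character(), stages = character())

    truth <- counts$truth
    truth$teDhsFlags <- setNames(catalog$te_dhs, catalog$peak_id)
    truth$edges <- edges
    truth$regionLabels <- genome$regions
    truth$stagePresence <- peaks$stagePresence
    truth$plantedHits <- motifs$plantedHits
    truth$geneClass <- setNames(genome$genes$class, genome$genes$gene_id)

    new("FiberSim", config = config,
        genes = genome$genes, tes = genome$tes,
        sequences = motifs$sequences,
        peaks = catalog, peakReplicates = peaks$replicates,
        accessibility = counts$accessibility, expression = counts$expression,
        motifs = motifs$motifs, motifTfMap = motifs$motifTfMap,
        truth = truth)
}
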