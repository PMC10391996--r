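#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom stats cor rnbinom rpois runif rnorm sd quantile pnorm pt phyper
#'   p.adjust kmeans setNames
#' @importFrom utils head write.table read.table
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the staged ovule/fiber synthetic dataset
#'
#' Holds every tunable of the synthetic-data generator: genome geometry,
#' stage/replicate design, negative-binomial noise, and the planted structure
#' (teDHSs, peak-gene links, co-expression modules, TF->target motif edges)
#' whose ground truth is used to score the downstream analysis.
#'
#' @slot seed integer; global seed fanned out to per-component child seeds.
#' @slot nChromosomes,chromosomeLength genome geometry (bp).
#' @slot nGenes,nTes feature counts.
#' @slot teRichFraction fraction of 1-Mb windows designated TE-rich.
#' @slot stages numeric stage labels in days post anthesis (DPA).
#' @slot ovuleStages subset of \code{stages} treated as the ovule phase;
#'   the remainder is the fiber elongation phase.
#' @slot accReplicates,exprReplicates replicates per stage for the
#'   accessibility and expression assays.
#' @slot nbDispersion negative-binomial dispersion alpha (variance
#'   \eqn{\mu + \alpha\mu^2}).
#' @slot nPeaks number of consensus peaks in the DHS catalog.
#' @slot teDhsFraction fraction of peaks placed to overlap a TE by >= 30\%.
#' @slot promoterPeakFraction fraction of peaks placed wholly inside 1.5-kb
#'   promoter windows.
#' @slot docrFraction fraction of peaks given stage-specific presence
#'   (differentially open).
#' @slot nPlantedLinks,linkEffect,linkPositiveFraction planted peak-gene links:
#'   count, latent stage-profile correlation magnitude in \[0, 1\], and the
#'   fraction with positive sign.
#' @slot nModules,moduleSize,moduleEffect planted co-expression modules.
#' @slot ovuleHighFraction,elongationHighFraction fractions of genes given the
#'   4-fold ovule-high / elongation-high archetype profiles.
#' @slot nTfs,targetsPerTf,motifLength,plantedEdgeCount planted TF regulon
#'   structure (each TF's consensus motif is written into a promoter DHS of
#'   each target, and TF/targets are made co-expressed).
#' @slot stageCv,flatCv coefficient of variation of latent stage means for
#'   structured and unstructured ("flat") features.
#' @slot archetypeJitter per-stage multiplicative jitter of the archetype
#'   fold profiles (diversifies individual genes' programs).
#' @slot baseMeanRange range of per-feature base means.
#' @slot depthVariation half-width of the per-sample depth factor band
#'   (factors drawn uniformly from 1 +/- depthVariation).
#' @slot peakJitterSd,peakDropout replicate peak jitter (bp, normal sd) and
#'   per-replicate peak dropout probability.
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    nChromosomes = "integer",
    chromosomeLength = "numeric",
    nGenes = "integer",
    nTes = "integer",
    teRichFraction = "numeric",
    stages = "numeric",
    ovuleStages = "numeric",
    accReplicates = "integer",
    exprReplicates = "integer",
    nbDispersion = "numeric",
    nPeaks = "integer",
    teDhsFraction = "numeric",
    promoterPeakFraction = "numeric",
    docrFraction = "numeric",
    nPlantedLinks = "integer",
    linkEffect = "numeric",
    linkPositiveFraction = "numeric",
    nModules = "integer",
    moduleSize = "integer",
    moduleEffect = "numeric",
    ovuleHighFraction = "numeric",
    elongationHighFraction = "numeric",
    nTfs = "integer",
    targetsPerTf = "integer",
    motifLength = "integer",
    plantedEdgeCount = "integer",
    stageCv = "numeric",
    flatCv = "numeric",
    archetypeJitter = "numeric",
    baseMeanRange = "numeric",
    depthVariation = "numeric",
    peakJitterSd = "numeric",
    peakDropout = "numeric"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    pos <- c(nChromosomes = object@nChromosomes, nGenes = object@nGenes,
             nTes = object@nTes, accReplicates = object@accReplicates,
             exprReplicates = object@exprReplicates, nPeaks = object@nPeaks)
    if (any(pos <= 0L))
        msg <- c(msg, sprintf("counts must be positive (%s)",
                              paste(names(pos)[pos <= 0L], collapse = ", ")))
    if (object@chromosomeLength < 1e6)
        msg <- c(msg, "chromosomeLength must be >= 1e6 bp")
    if (object@linkEffect < 0 || object@linkEffect > 1)
        msg <- c(msg, "linkEffect must lie in [0, 1]")
    if (object@nbDispersion < 0)
        msg <- c(msg, "nbDispersion must be >= 0")
    if (length(object@ovuleStages) < 2)
        msg <- c(msg, "need >= 2 ovule stages")
    if (length(setdiff(object@stages, object@ovuleStages)) < 2)
        msg <- c(msg, "need >= 2 elongation stages")
    if (!all(object@ovuleStages %in% object@stages))
        msg <- c(msg, "ovuleStages must be a subset of stages")
    if (anyDuplicated(object@stages))
        msg <- c(msg, "stages must be unique")
    frac <- object@teDhsFraction + object@promoterPeakFraction
    if (frac > 1)
        msg <- c(msg, "teDhsFraction + promoterPeakFraction exceed 1")
    if (object@motifLength > 1500L)
        msg <- c(msg, "motifLength exceeds the 1500-bp promoter window")
    if (object@plantedEdgeCount != object@nTfs * object@targetsPerTf)
        msg <- c(msg, "plantedEdgeCount must equal nTfs * targetsPerTf")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults emulate the six-stage cotton ovule/fiber design: stages 0 and 3
#' DPA are ovules, 8/12/15/18 DPA are elongating fibers, accessibility has two
#' replicates per stage and expression six.
#'
#' @param seed integer global seed.
#' @param nChromosomes,chromosomeLength toy genome geometry.
#' @param nGenes,nTes numbers of gene models and transposable elements.
#' @param teRichFraction fraction of 1-Mb windows made TE-rich.
#' @param stages,ovuleStages stage labels (DPA) and the ovule subset.
#' @param accReplicates,exprReplicates replicates per stage.
#' @param nbDispersion NB dispersion alpha; 0 gives the Poisson limit.
#' @param nPeaks DHS catalog size.
#' @param teDhsFraction,promoterPeakFraction,docrFraction peak composition.
#' @param nPlantedLinks,linkEffect,linkPositiveFraction planted link design.
#' @param nModules,moduleSize,moduleEffect planted co-expression modules.
#' @param ovuleHighFraction,elongationHighFraction archetype gene fractions.
#' @param nTfs,targetsPerTf,motifLength planted TF regulon design.
#' @param stageCv,flatCv latent stage-profile coefficients of variation.
#' @param archetypeJitter per-stage multiplicative jitter (sd) applied to the
#'   archetype 4-fold programs; real stage programs differ gene to gene, so
#'   the default keeps within-class profiles correlated but not collinear
#'   while preserving the planted phase contrast.
#' @param baseMeanRange per-feature base mean range.
#' @param depthVariation per-sample depth factor half-width.
#' @param peakJitterSd,peakDropout replicate peak jitter and dropout.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 100, nPeaks = 200)
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 2L, chromosomeLength = 5e6,
                      nGenes = 300L, nTes = 500L, teRichFraction = 0.3,
                      stages = c(0, 3, 8, 12, 15, 18),
                      ovuleStages = c(0, 3),
                      accReplicates = 2L, exprReplicates = 6L,
                      nbDispersion = 0.05,
                      nPeaks = 600L,
                      teDhsFraction = 0.3, promoterPeakFraction = 0.25,
                      docrFraction = 0.3,
                      nPlantedLinks = 100L, linkEffect = 0.95,
                      linkPositiveFraction = 0.7,
                      nModules = 30L, moduleSize = 3L, moduleEffect = 0.95,
                      ovuleHighFraction = 0.2, elongationHighFraction = 0.2,
                      nTfs = 10L, targetsPerTf = 2L, motifLength = 8L,
                      stageCv = 0.35, flatCv = 0.05,
                      archetypeJitter = 0.25,
                      baseMeanRange = c(50, 500), depthVariation = 0.3,
                      peakJitterSd = 20, peakDropout = 0.03) {
    new("SimConfig",
        seed = as.integer(seed),
        nChromosomes = as.integer(nChromosomes),
        chromosomeLength = as.numeric(chromosomeLength),
        nGenes = as.integer(nGenes), nTes = as.integer(nTes),
        teRichFraction = teRichFraction,
        stages = as.numeric(stages), ovuleStages = as.numeric(ovuleStages),
        accReplicates = as.integer(accReplicates),
        exprReplicates = as.integer(exprReplicates),
        nbDispersion = nbDispersion,
        nPeaks = as.integer(nPeaks),
        teDhsFraction = teDhsFraction,
        promoterPeakFraction = promoterPeakFraction,
        docrFraction = docrFraction,
        nPlantedLinks = as.integer(nPlantedLinks),
        linkEffect = linkEffect,
        linkPositiveFraction = linkPositiveFraction,
        nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
        moduleEffect = moduleEffect,
        ovuleHighFraction = ovuleHighFraction,
        elongationHighFraction = elongationHighFraction,
        nTfs = as.integer(nTfs), targetsPerTf = as.integer(targetsPerTf),
        motifLength = as.integer(motifLength),
        plantedEdgeCount = as.integer(nTfs) * as.integer(targetsPerTf),
        stageCv = stageCv, flatCv = flatCv,
        archetypeJitter = archetypeJitter,
        baseMeanRange = as.numeric(baseMeanRange),
        depthVariation = depthVariation,
        peakJitterSd = peakJitterSd, peakDropout = peakDropout)
}

#' @describeIn simConfig Elongation (non-ovule) stages of a configuration.
#' @param config A [SimConfig-class].
#' @export
elongationStages <- function(config) {
    setdiff(config@stages, config@ovuleStages)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat(sprintf("  genome   : %d chromosome(s) x %.3g bp\n",
                object@nChromosomes, object@chromosomeLength))
    cat(sprintf("  features : %d genes, %d TEs, %d peaks\n",
                object@nGenes, object@nTes, object@nPeaks))
    cat(sprintf("  stages   : %s DPA (ovule: %s)\n",
                paste(object@stages, collapse = ", "),
                paste(object@ovuleStages, collapse = ", ")))
    cat(sprintf("  design   : %d acc reps, %d expr reps, NB dispersion %.3g\n",
                object@accReplicates, object@exprReplicates,
                object@nbDispersion))
    cat(sprintf("  planted  : %d links (effect %.2f), %d modules, %d TF edges\n",
                object@nPlantedLinks, object@linkEffect, object@nModules,
                object@plantedEdgeCount))
    cat(sprintf("  seed     : %d\n", object@seed))
})

## ---------------------------------------------------------------------------
## StageCounts
## ---------------------------------------------------------------------------

#' Count matrix with stage/replicate metadata
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' validity guarantees the contract shared by the accessibility and
#' expression assays: a non-negative integer \code{counts} assay and
#' \code{stage}/\code{replicate} columns in \code{colData}.
#'
#' @export
setClass("StageCounts", contains = "SummarizedExperiment")

setValidity("StageCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0))
        msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m)))
        msg <- c(msg, "counts must be integral")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("stage", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'stage' and 'replicate'")
    else if (any(table(cd$stage) < 1))
        msg <- c(msg, "every stage needs >= 1 replicate")
    if (length(msg)) msg else TRUE
})

#' Build a StageCounts object
#'
#' @param counts feature x sample matrix of non-negative integers; sample
#'   names default to \code{"<stage>_<replicate>"}.
#' @param stage,replicate per-sample metadata vectors.
#' @return A [StageCounts-class] object.
#' @examples
#' m <- matrix(rpois(12, 10), 2, dimnames = list(c("a", "b"), NULL))
#' sc <- StageCounts(m, stage = rep(c(0, 3, 8), each = 2), replicate = rep(1:2, 3))
#' @export
StageCounts <- function(counts, stage, replicate) {
    counts <- as.matrix(counts)
    stopifnot(length(stage) == ncol(counts),
              length(replicate) == ncol(counts))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0(stage, "_", replicate)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("f", seq_len(nrow(counts)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(stage = as.numeric(stage),
                                       replicate = as.integer(replicate)))
    new("StageCounts", se)
}

#' @describeIn StageCounts Raw count matrix.
#' @param x A [StageCounts-class].
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn StageCounts Per-sample stage labels.
#' @export
sampleStages <- function(x) SummarizedExperiment::colData(x)$stage

#' @describeIn StageCounts Ordered unique stage labels.
#' @export
stageLevels <- function(x) sort(unique(sampleStages(x)))

setMethod("show", "StageCounts", function(object) {
    cat(sprintf("StageCounts: %d features x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(sampleStages(object))
    cat(sprintf("  stages: %s (replicates: %s)\n",
                paste(names(tab), collapse = ", "),
                paste(as.integer(tab), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## MotifModel
## ---------------------------------------------------------------------------

#' Position weight matrix motif model
#'
#' A per-position nucleotide probability model over ACGT, with the pseudocount
#' and background used to form log-odds scores.
#'
#' @slot id motif identifier.
#' @slot matrix 4 x L probability matrix with rownames A, C, G, T; columns
#'   sum to 1.
#' @slot pseudocount pseudocount applied when forming log-odds.
#' @slot background background nucleotide frequencies (sums to 1).
#' @export
setClass("MotifModel", representation(
    id = "character", matrix = "matrix",
    pseudocount = "numeric", background = "numeric"))

setValidity("MotifModel", function(object) {
    msg <- character()
    m <- object@matrix
    if (!identical(rownames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "matrix rownames must be A, C, G, T")
    if (ncol(m) < 4)
        msg <- c(msg, "motif length must be >= 4")
    if (any(abs(colSums(m) - 1) > 1e-6))
        msg <- c(msg, "matrix columns must sum to 1")
    if (any(m < 0))
        msg <- c(msg, "matrix entries must be non-negative")
    if (abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must sum to 1")
    if (length(object@background) != 4)
        msg <- c(msg, "background must have 4 entries")
    if (length(msg)) msg else TRUE
})

#' Construct a motif model
#'
#' @param id motif identifier.
#' @param matrix 4 x L probability matrix (rows A, C, G, T).
#' @param pseudocount pseudocount for log-odds (default 0.01).
#' @param background background frequencies (default uniform).
#' @return A [MotifModel-class].
#' @examples
#' m <- motifModel("m1", matrix(0.25, 4, 6, dimnames = list(c("A","C","G","T"), NULL)))
#' @export
motifModel <- function(id, matrix, pseudocount = 0.01,
                       background = rep(0.25, 4)) {
    rownames(matrix) <- c("A", "C", "G", "T")
    new("MotifModel", id = id, matrix = matrix,
        pseudocount = pseudocount, background = as.numeric(background))
}

#' @describeIn motifModel Motif length (bp).
#' @param motif A [MotifModel-class].
#' @export
motifLength <- function(motif) ncol(motif@matrix)

#' @describeIn motifModel Consensus sequence (per-column argmax base).
#' @export
motifConsensus <- function(motif) {
    paste(rownames(motif@matrix)[apply(motif@matrix, 2, which.max)],
          collapse = "")
}

setMethod("show", "MotifModel", function(object) {
    cat(sprintf("MotifModel '%s': length %d, consensus %s\n",
                object@id, motifLength(object), motifConsensus(object)))
})

## ---------------------------------------------------------------------------
## NullModel
## ---------------------------------------------------------------------------

#' Empirical null for peak-gene link correlations
#'
#' Pooled Pearson correlations of randomly sampled peaks against every gene;
#' the mean and standard deviation of the pool standardize observed link
#' correlations into z-scores.
#'
#' @slot mean,sd pool mean (expected.mean) and standard deviation
#'   (expected.std).
#' @slot n number of random peaks sampled.
#' @slot poolSize number of correlations pooled.
#' @slot sample a bounded subsample of the pool kept for inspection.
#' @slot seed the sampling seed.
#' @export
setClass("NullModel", representation(
    mean = "numeric", sd = "numeric", n = "integer",
    poolSize = "integer", sample = "numeric", seed = "integer"))

setValidity("NullModel", function(object) {
    msg <- character()
    if (object@sd <= 0) msg <- c(msg, "expected.std must be > 0")
    if (object@mean < -1 || object@mean > 1)
        msg <- c(msg, "expected.mean must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NullModel", function(object) {
    cat(sprintf(
        "NullModel: %d random peaks, %d pooled correlations\n  expected.mean = %.4f, expected.std = %.4f (seed %d)\n",
        object@n, object@poolSize, object@mean, object@sd, object@seed))
})

## ---------------------------------------------------------------------------
## FiberSim
## ---------------------------------------------------------------------------

#' A complete synthetic staged ovule/fiber dataset
#'
#' Produced by [simulateFiberDataset()]; bundles the toy genome, annotations,
#' DHS catalog with per-stage/per-replicate peak sets, count matrices, motif
#' models, and the ground truth needed to score every downstream stage.
#'
#' @slot config the generating [SimConfig-class].
#' @slot genes,tes [GenomicRanges::GRanges] gene models (with \code{gene_id},
#'   strand) and TE intervals.
#' @slot sequences [Biostrings::DNAStringSet] chromosome sequences.
#' @slot peaks GRanges DHS catalog with mcols \code{peak_id}, \code{type},
#'   \code{te_dhs}, and a \code{stages} CharacterList-style presence string.
#' @slot peakReplicates GRanges of jittered per-stage/per-replicate intervals.
#' @slot accessibility,expression [StageCounts-class] assays.
#' @slot motifs list of [MotifModel-class].
#' @slot motifTfMap data.frame mapping motif ids to TF gene ids.
#' @slot truth list of ground-truth tables (teDhsFlags, links, edges,
#'   modules, clusterLabels, regionLabels, latent means, depth factors).
#' @export
setClass("FiberSim", representation(
    config = "SimConfig",
    genes = "GRanges", tes = "GRanges",
    sequences = "DNAStringSet",
    peaks = "GRanges", peakReplicates = "GRanges",
    accessibility = "StageCounts", expression = "StageCounts",
    motifs = "list", motifTfMap = "data.frame",
    truth = "list"))

setMethod("show", "FiberSim", function(object) {
    cat("FiberSim synthetic dataset\n")
    cat(sprintf("  genome     : %d chromosome(s), %s bp total\n",
                length(object@sequences),
                format(sum(Biostrings::width(object@sequences)),
                       big.mark = ",")))
    cat(sprintf("  annotation : %d genes, %d TEs\n",
                length(object@genes), length(object@tes)))
    cat(sprintf("  peaks      : %d catalog DHSs (%d teDHS), %d replicate intervals\n",
                length(object@peaks), sum(object@peaks$te_dhs),
                length(object@peakReplicates)))
    cat(sprintf("  counts     : accessibility %d x %d, expression %d x %d\n",
                nrow(object@accessibility), ncol(object@accessibility),
                nrow(object@expression), ncol(object@expression)))
    cat(sprintf("  planted    : %d links, %d TF edges, %d motifs\n",
                nrow(object@truth$links), nrow(object@truth$edges),
                length(object@motifs)))
})
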