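## Readers and writers for the standard interchange formats. Interval and
## sequence formats go through rtracklayer / Biostrings (BED is 0-based
## half-open on disk, 1-based closed in memory); counts and annotation
## tables are plain TSV; motifs use MEME-minimal text; ground truth is JSON.

#' Write a peak/interval set as BED6
#'
#' @param gr GRanges; \code{peak_id}/\code{te_id}/\code{gene_id} (first
#'   found) becomes the name column, score defaults to 0.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
    out <- granges(gr)
    nm <- gr$peak_id
    if (is.null(nm)) nm <- gr$te_id
    if (is.null(nm)) nm <- gr$gene_id
    if (is.null(nm)) nm <- as.character(seq_along(gr))
    out$name <- nm
    out$score <- if (!is.null(gr$score)) gr$score else 0
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read a BED file as GRanges
#'
#' @param path BED file; the name column is exposed as \code{peak_id}.
#' @return GRanges.
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(gr$name)) gr$peak_id <- gr$name
    gr
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with \code{gene_id}.
#' @param path output file.
#' @export
writeGenesGff3 <- function(genes, path) {
    out <- granges(genes)
    out$type <- "gene"
    out$ID <- genes$gene_id
    out$source <- "fibergrn"
    rtracklayer::export(out, path, format = "GFF3")
    invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file.
#' @return GRanges of type-"gene" records with \code{gene_id}.
#' @export
readGenesGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    gr$gene_id <- gr$ID
    gr
}

#' Write a StageCounts assay as TSV (plus sample metadata sidecar)
#'
#' The first column is the feature id; sample columns are named
#' \code{<stage>_<replicate>}.
#'
#' @param x A [StageCounts-class].
#' @param path counts TSV path; metadata is written to
#'   \code{<path>.samples.tsv}.
#' @export
writeCountsTsv <- function(x, path) {
    m <- countsMatrix(x)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- data.frame(sample_id = colnames(m), cd)
    write.table(cd, paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a counts TSV (with sidecar metadata) as StageCounts
#'
#' @param path counts TSV written by [writeCountsTsv()]; stage/replicate are
#'   taken from \code{<path>.samples.tsv} when present, otherwise parsed
#'   from \code{<stage>_<replicate>} column names.
#' @return A [StageCounts-class].
#' @export
readCountsTsv <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    side <- paste0(path, ".samples.tsv")
    if (file.exists(side)) {
        cd <- read.table(side, header = TRUE, sep = "\t")
        StageCounts(m, stage = cd$stage, replicate = cd$replicate)
    } else {
        parts <- strsplit(colnames(m), "_")
        StageCounts(m,
                    stage = as.numeric(vapply(parts, `[`, "", 1)),
                    replicate = as.integer(vapply(parts, `[`, "", 2)))
    }
}

#' Write motifs in MEME-minimal format
#'
#' @param motifs list of [MotifModel-class].
#' @param path output file.
#' @export
writeMemeMotifs <- function(motifs, path) {
    con <- file(path, "w")
    on.exit(close(con))
    bg <- motifs[[1]]@background
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f",
                         bg[1], bg[2], bg[3], bg[4]), ""), con)
    for (m in motifs) {
        writeLines(sprintf("MOTIF %s", m@id), con)
        writeLines(sprintf(
            "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            motifLength(m)), con)
        for (j in seq_len(motifLength(m)))
            writeLines(paste(sprintf("%.6f", m@matrix[, j]), collapse = "  "),
                       con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read motifs from MEME-minimal format
#'
#' @param path MEME-minimal text file.
#' @param pseudocount pseudocount to attach (default 0.01).
#' @return named list of [MotifModel-class].
#' @export
readMemeMotifs <- function(path, pseudocount = 0.01) {
    lines <- readLines(path)
    bg <- rep(0.25, 4)
    bgIdx <- grep("^Background letter frequencies", lines)
    if (length(bgIdx)) {
        tok <- strsplit(trimws(lines[bgIdx[1] + 1]), "\\s+")[[1]]
        bg <- as.numeric(tok[c(2, 4, 6, 8)])
    }
    out <- list()
    i <- 1
    while (i <= length(lines)) {
        if (grepl("^MOTIF ", lines[i])) {
            id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
            j <- i + 1
            while (j <= length(lines) &&
                   !grepl("^letter-probability matrix", lines[j])) j <- j + 1
            w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
            rows <- vapply(lines[(j + 1):(j + w)], function(l)
                as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4))
            ## renormalize columns: fixed-precision text truncates slightly
            rows <- sweep(rows, 2, colSums(rows), "/")
            dimnames(rows) <- NULL
            out[[id]] <- motifModel(id, rows, pseudocount = pseudocount,
                                    background = bg)
            i <- j + w
        }
        i <- i + 1
    }
    out
}

#' Write a simulated dataset to disk in standard formats
#'
#' Genes as GFF3, TEs and the peak catalog as BED6, per-stage/replicate
#' peaks as BED6, chromosome sequences as FASTA, counts as TSV, motifs as
#' MEME-minimal text, and the ground truth as JSON.
#'
#' @param sim A [FiberSim-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        genes = file.path(dir, "genes.gff3"),
        tes = file.path(dir, "tes.bed"),
        peaks = file.path(dir, "peaks.bed"),
        replicate_peaks = file.path(dir, "replicate_peaks.bed"),
        sequences = file.path(dir, "genome.fa"),
        accessibility = file.path(dir, "accessibility_counts.tsv"),
        expression = file.path(dir, "expression_counts.tsv"),
        motifs = file.path(dir, "motifs.meme"),
        motif_tf_map = file.path(dir, "motif_tf_map.tsv"),
        ground_truth = file.path(dir, "ground_truth.json"))
    writeGenesGff3(sim@genes, paths["genes"])
    writeBed(sim@tes, paths["tes"])
    writeBed(sim@peaks, paths["peaks"])
    repPeaks <- sim@peakReplicates
    repPeaks$peak_id <- paste(repPeaks$peak_id, repPeaks$stage,
                              repPeaks$replicate, sep = "|")
    writeBed(repPeaks, paths["replicate_peaks"])
    writeXStringSet(sim@sequences, paths["sequences"])
    writeCountsTsv(sim@accessibility, paths["accessibility"])
    writeCountsTsv(sim@expression, paths["expression"])
    writeMemeMotifs(sim@motifs, paths["motifs"])
    write.table(sim@motifTfMap, paths["motif_tf_map"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- sim@truth
    truthJson <- list(
        te_dhs_flags = as.list(truth$teDhsFlags),
        links = truth$links,
        edges = truth$edges,
        modules = truth$modules,
        cluster_labels = as.list(truth$clusterLabels[!is.na(truth$clusterLabels)]),
        region_labels = data.frame(
            chrom = as.character(seqnames(truth$regionLabels)),
            start = start(truth$regionLabels) - 1L,
            end = end(truth$regionLabels),
            label = truth$regionLabels$label),
        stage_presence = truth$stagePresence)
    jsonlite::write_json(truthJson, paths["ground_truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
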