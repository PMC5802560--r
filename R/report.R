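#' @include AllClasses.R pair_score.R
NULL

#' ClusteredMatrix: a hierarchically clustered, reordered matrix
#'
#' @slot values the input matrix reordered to the clustering leaf orders
#'   (a pure permutation of the input values).
#' @slot rowOrder,colOrder leaf orders (permutations of the input labels).
#' @slot distance,linkage parameters used.
#' @export
setClass("ClusteredMatrix",
         representation(values = "matrix", rowOrder = "character",
                        colOrder = "character", distance = "character",
                        linkage = "character"))

.leafOrder <- function(m, distance, linkage) {
    if (nrow(m) == 1L) return(rownames(m))
    d <- switch(distance,
                euclidean = stats::dist(m),
                correlation = stats::as.dist(1 - stats::cor(t(m))))
    hc <- stats::hclust(d, method = linkage)
    rownames(m)[hc$order]
}

#' Hierarchically cluster a matrix for heat-map display
#'
#' Agglomerative clustering of rows and columns with a deterministic leaf
#' order: rows and columns are first sorted lexicographically by label, so
#' the result does not depend on input order, and equal rows (zero
#' distance) end up adjacent.  Only the orderings and the reordered value
#' matrix are produced; rendering is left to the caller (e.g. pheatmap
#' with \code{cluster_rows = FALSE}).
#'
#' @param m numeric matrix with complete dimnames, at least 2 x 2, no
#'   missing values.
#' @param distance \code{"euclidean"} or \code{"correlation"}.
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return A \linkS4class{ClusteredMatrix}.
#' @export
clusterHeatmap <- function(m, distance = c("euclidean", "correlation"),
                           linkage = c("average", "complete")) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    m <- .checkedMatrix(m, "m")
    if (nrow(m) < 2L || ncol(m) < 2L)
        stop("clustering needs at least a 2 x 2 matrix")
    if (any(!is.finite(m))) stop("matrix contains NaN/Inf/NA entries")
    m <- m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
    ro <- .leafOrder(m, distance, linkage)
    co <- .leafOrder(t(m), distance, linkage)
    new("ClusteredMatrix", values = m[ro, co, drop = FALSE],
        rowOrder = ro, colOrder = co,
        distance = distance, linkage = linkage)
}

setMethod("show", "ClusteredMatrix", function(object) {
    cat(sprintf("ClusteredMatrix %d x %d (%s distance, %s linkage)\n",
                nrow(object@values), ncol(object@values),
                object@distance, object@linkage))
})

#' @rdname clusterHeatmap
#' @param x a \linkS4class{ClusteredMatrix}.
#' @param path output CSV; the reordered matrix is written with row labels
#'   in the first column.
#' @export
writeClusteredMatrix <- function(x, path) {
    stopifnot(is(x, "ClusteredMatrix"))
    df <- data.frame(id = rownames(x@values),
                     as.data.frame(x@values, check.names = FALSE),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a Circos-compatible link table
#'
#' Tab-separated \code{otu_id, brain_feature_id, s_combined}, mirroring
#' the content of a chord diagram of OTU to brain-ROI links.
#'
#' @param pairs data.frame of (selected) scored pairs.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writeCircosLinks <- function(pairs, path) {
    lines <- c("otu_id\tbrain_feature_id\ts_combined",
               sprintf("%s\t%s\t%s", pairs$otu_id, pairs$brain_feature_id,
                       .fmtNum(pairs$s_combined)))
    writeLines(lines, path)
    invisible(path)
}

#' Write a run manifest
#'
#' Records the seed and all analysis parameters, the MD5 digests of the
#' input files, and the output file list, so a rerun with an equal
#' manifest (timestamp aside) is byte-identical.
#'
#' @param config named list of run parameters (seed, ntree, pseudocount,
#'   top-k, folds, repeats, pairs-k, threshold, ...).
#' @param inputs character vector of input file paths (digested).
#' @param outputs character vector of output file paths; all must exist.
#' @param path manifest JSON path.
#' @return Invisibly, the path.
#' @export
writeManifest <- function(config, inputs, outputs, path) {
    missing <- outputs[!file.exists(outputs)]
    if (length(missing))
        stop("missing output file(s): ", paste(missing, collapse = ", "))
    digests <- if (length(inputs)) {
        as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                basename(inputs)))
    } else list()
    manifest <- list(config = config,
                     input_md5 = digests,
                     outputs = sort(basename(outputs)),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Run the full gut-brain association pipeline
#'
#' Glue over the package's stages: log2-transform the OTU table, z-scale
#' the brain table, align on common samples; classify diet from each table
#' (whole-data feature selection + LOOCV, plus nested CV); regress every
#' brain feature on the OTUs; score all pairs with the rank-product
#' scheme; select the top pairs, apply the combined-score threshold, and
#' write all tabular outputs plus a manifest under \code{outDir}.
#'
#' @param otu \linkS4class{OtuTable} (relative scale).
#' @param brain \linkS4class{BrainFeatureTable} (raw scale).
#' @param diet named factor of diet labels.
#' @param outDir output directory (created if needed).
#' @param ntreeClass trees for diet classification (study design: 16000).
#' @param ntreeReg trees for per-feature regression (study design: 4000).
#' @param topK features selected per table for diet prediction (default 9).
#' @param pairsK number of top pairs retained (default 27).
#' @param threshold combined-score cutoff for called links (default 0.84).
#' @param folds,repeats nested-CV layout (default 5, 3).
#' @param pseudocount log2 pseudocount (default 1e-6).
#' @param seed integer seed driving every stochastic stage.
#' @param inputs optional character vector of input files to digest into
#'   the manifest.
#' @return Invisibly, a list with the principal in-memory results:
#'   \code{otuSelection}, \code{brainSelection} (from [selectThenLoocv()]),
#'   \code{otuNested}, \code{brainNested} (\linkS4class{CvReport}),
#'   \code{pairs}, \code{topPairs}, \code{calledPairs} (data.frames), and
#'   \code{paths} of the files written.
#' @export
runPipeline <- function(otu, brain, diet, outDir,
                        ntreeClass = 16000L, ntreeReg = 4000L,
                        topK = 9L, pairsK = 27L, threshold = 0.84,
                        folds = 5L, repeats = 3L, pseudocount = 1e-6,
                        seed = 1L, inputs = character(0)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    al <- alignCohort(otu, brain, diet)
    otuX <- otuMatrix(log2Transform(al$otu, pseudocount))
    brainX <- brainMatrix(zScale(al$brain))
    y <- al$diet

    cfgC <- forestConfig(ntree = ntreeClass, seed = .subSeed(seed, 1L))
    cfgR <- forestConfig(ntree = ntreeReg, seed = .subSeed(seed, 2L))

    otuSel <- selectThenLoocv(otuX, y, topK, cfgC)
    brainSel <- selectThenLoocv(brainX, y, topK, cfgC)
    otuNested <- nestedCv(otuX, y, topK, cfgC, folds, repeats)
    brainNested <- nestedCv(brainX, y, topK, cfgC, folds, repeats)

    regImps <- regressBrainOnOtus(otuX, brainX, cfgR)
    pairs <- scoreAllPairs(otuSel$importance, brainSel$importance, regImps)
    topPairs <- selectTopPairs(pairs, min(pairsK, nrow(pairs)))
    called <- applyThreshold(pairs, threshold)

    paths <- c(
        otu_importance = file.path(outDir, "importances_otu.csv"),
        brain_importance = file.path(outDir, "importances_brain.csv"),
        confusion_otu = file.path(outDir, "confusion_otu.csv"),
        confusion_brain = file.path(outDir, "confusion_brain.csv"),
        cv_report = file.path(outDir, "cv_report.json"),
        pairs = file.path(outDir, "pairs.csv"),
        circos = file.path(outDir, "circos_links.tsv"),
        heatmap_otu = file.path(outDir, "heatmap_otu.csv"),
        heatmap_brain = file.path(outDir, "heatmap_brain.csv"),
        pairs_heatmap = file.path(outDir, "pairs_heatmap.csv"))

    writeImportance(otuSel$importance, paths[["otu_importance"]])
    writeImportance(brainSel$importance, paths[["brain_importance"]])
    utils::write.csv(cvConfusion(otuSel$report), paths[["confusion_otu"]])
    utils::write.csv(cvConfusion(brainSel$report),
                     paths[["confusion_brain"]])
    jsonlite::write_json(list(
        otu = .cvAsList(otuSel$report), brain = .cvAsList(brainSel$report),
        otu_nested = .cvAsList(otuNested),
        brain_nested = .cvAsList(brainNested)),
        paths[["cv_report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)

    pairsOut <- pairs
    key <- paste(pairs$otu_id, pairs$brain_feature_id)
    pairsOut$selected_flag <- as.integer(
        key %in% paste(topPairs$otu_id, topPairs$brain_feature_id))
    utils::write.csv(pairsOut, paths[["pairs"]], row.names = FALSE,
                     quote = FALSE)
    writeCircosLinks(topPairs, paths[["circos"]])

    writeClusteredMatrix(
        clusterHeatmap(otuX[, otuSel$selected, drop = FALSE]),
        paths[["heatmap_otu"]])
    writeClusteredMatrix(
        clusterHeatmap(brainX[, brainSel$selected, drop = FALSE]),
        paths[["heatmap_brain"]])
    scoreMat <- matrix(pairs$s_combined,
                       nrow = length(unique(pairs$otu_id)),
                       dimnames = list(sort(unique(pairs$otu_id)),
                                       sort(unique(pairs$brain_feature_id))))
    scoreMat[cbind(match(pairs$otu_id, rownames(scoreMat)),
                   match(pairs$brain_feature_id, colnames(scoreMat)))] <-
        pairs$s_combined
    writeClusteredMatrix(clusterHeatmap(scoreMat),
                         paths[["pairs_heatmap"]])

    manifestPath <- file.path(outDir, "manifest.json")
    writeManifest(list(seed = seed, ntree_class = ntreeClass,
                       ntree_reg = ntreeReg, top_k = topK,
                       pairs_k = pairsK, threshold = threshold,
                       folds = folds, repeats = repeats,
                       pseudocount = pseudocount),
                  inputs, unname(paths), manifestPath)
    paths <- c(paths, manifest = manifestPath)

    invisible(list(otuSelection = otuSel, brainSelection = brainSel,
                   otuNested = otuNested, brainNested = brainNested,
                   pairs = pairs, topPairs = topPairs,
                   calledPairs = called, paths = paths))
}

.cvAsList <- function(rep) {
    out <- list(method = rep@method, accuracy = rep@accuracy)
    if (length(rep@foldAccuracies)) {
        out$fold_accuracies <- rep@foldAccuracies
        out$mean <- mean(rep@foldAccuracies)
        out$sd <- rep@accuracySd
        out$ci95_half_width <- rep@ciHalfWidth
    }
    out
}
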