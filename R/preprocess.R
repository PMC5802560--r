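#' @include AllClasses.R
NULL

#' Read cohort tables from disk
#'
#' Readers for the dialects written by [writeCohort()].  In strict mode
#' (the default) the OTU reader rejects missing values and samples whose
#' relative abundances do not sum to 1 within \code{1e-6}.
#'
#' @param path file path.
#' @param strict reject NA values and, for relative-scale OTU tables,
#'   sample rows not summing to 1 within \code{1e-6}.
#' @param scale declared scale of the values on disk.
#' @return [readOtuTable()]: an \linkS4class{OtuTable};
#'   [readBrainTable()]: a \linkS4class{BrainFeatureTable};
#'   [readDietLabels()]: a named factor; [readCohort()]: a list of the
#'   three.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
readOtuTable <- function(path, strict = TRUE,
                         scale = c("relative", "log2")) {
    scale <- match.arg(scale)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1] != "sample_id")
        stop("OTU table must have 'sample_id' as its first column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    storage.mode(m) <- "double"
    if (strict) {
        if (anyNA(m)) stop("OTU table contains missing values")
        if (scale == "relative") {
            rs <- rowSums(m)
            bad <- abs(rs - 1) > 1e-6
            if (any(bad))
                stop("sample(s) not summing to 1 within 1e-6: ",
                     paste(utils::head(rownames(m)[bad], 3L),
                           collapse = ", "))
        }
    }
    OtuTable(t(m), scale = scale)
}

#' @rdname cohort-io
#' @export
readBrainTable <- function(path, strict = TRUE,
                           scale = c("raw", "zscaled")) {
    scale <- match.arg(scale)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "roi", "metric", "value")
    if (!all(need %in% colnames(df)))
        stop("brain table must have columns sample_id, roi, metric, value")
    if (strict && anyNA(df$value))
        stop("brain table contains missing values")
    if (!all(df$metric %in% DTI_METRICS))
        stop("unknown diffusion metric(s): ",
             paste(setdiff(unique(df$metric), DTI_METRICS), collapse = ", "))
    fid <- paste0(df$roi, "_", df$metric)
    samples <- sort(unique(df$sample_id))
    feats <- unique(fid)
    m <- matrix(NA_real_, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
    m[cbind(match(fid, feats), match(df$sample_id, samples))] <- df$value
    if (anyNA(m))
        stop("brain table is not a complete sample x feature grid")
    lut <- !duplicated(fid)
    BrainFeatureTable(m, scale = scale,
                      roi = df$roi[lut], metric = df$metric[lut])
}

#' @rdname cohort-io
#' @export
readDietLabels <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "diet") %in% colnames(df)))
        stop("labels file must have columns sample_id, diet")
    DietLabels(stats::setNames(df$diet, df$sample_id))
}

#' @rdname cohort-io
#' @export
readCohort <- function(path, strict = TRUE) {
    list(otu = readOtuTable(file.path(path, "otu.tsv"), strict = strict),
         brain = readBrainTable(file.path(path, "brain.csv"),
                                strict = strict),
         diet = readDietLabels(file.path(path, "labels.csv")))
}

#' Log2-transform relative abundances
#'
#' Applies \code{log2(value + pseudocount)} entrywise.  The pseudocount
#' guards the zeros that are ubiquitous in OTU tables; the default 1e-6 is
#' of the order of the smallest relative abundance detectable at typical
#' 16S sequencing depth.  The transform is strictly monotone per entry, so
#' the ordering of any two abundances is preserved.
#'
#' @param table an \linkS4class{OtuTable} on the relative scale.
#' @param pseudocount positive offset added before taking logs.  May be 0
#'   only when the table has no zero entries.
#' @return An \linkS4class{OtuTable} with \code{scale = "log2"}.
#' @export
log2Transform <- function(table, pseudocount = 1e-6) {
    stopifnot(is(table, "OtuTable"))
    if (abundanceScale(table) != "relative")
        stop("table is already log2-scaled; refusing to transform twice")
    if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
        is.na(pseudocount) || pseudocount < 0)
        stop("pseudocount must be a nonnegative number")
    a <- assay(table, "abundance")
    if (pseudocount == 0 && any(a == 0))
        stop("pseudocount 0 with zero abundances present: log2 undefined")
    out <- table
    SummarizedExperiment::assay(out, "abundance") <- log2(a + pseudocount)
    metadata(out)$scale <- "log2"
    metadata(out)$pseudocount <- pseudocount
    validObject(out)
    out
}

#' z-scale brain features across samples
#'
#' Centers each feature and divides by its sample standard deviation
#' (\eqn{n-1} denominator).  Constant features are mapped to all zeros with
#' a warning: zero-variance features are uninformative, not malformed.
#'
#' @param table a \linkS4class{BrainFeatureTable} on the raw scale with at
#'   least two samples.
#' @return A \linkS4class{BrainFeatureTable} with \code{scale = "zscaled"}.
#' @export
zScale <- function(table) {
    stopifnot(is(table, "BrainFeatureTable"))
    if (brainScale(table) != "raw")
        stop("table is already z-scaled; refusing to scale twice")
    v <- assay(table, "value")
    if (ncol(v) < 2L)
        stop("z-scaling needs at least two samples")
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    const <- sdv == 0
    if (any(const)) {
        warning(sum(const), " constant feature(s) mapped to all zeros: ",
                paste(utils::head(rownames(v)[const], 3L), collapse = ", "))
        sdv[const] <- 1
    }
    z <- (v - mu) / sdv
    out <- table
    SummarizedExperiment::assay(out, "value") <- z
    metadata(out)$scale <- "zscaled"
    validObject(out)
    out
}

#' Align the cohort tables on their common samples
#'
#' Restricts the OTU table, brain table and diet labels to the samples
#' present in all three, in lexicographic sample_id order, so downstream
#' joins are deterministic regardless of file order.
#'
#' @param otu an \linkS4class{OtuTable}.
#' @param brain a \linkS4class{BrainFeatureTable}.
#' @param diet named factor of diet labels.
#' @return A list \code{otu}, \code{brain}, \code{diet}, plus
#'   \code{dropped}: character vector of sample ids present in at least
#'   one input but not all three.
#' @export
alignCohort <- function(otu, brain, diet) {
    ids <- list(sampleIds(otu), sampleIds(brain), names(diet))
    common <- sort(Reduce(intersect, ids))
    if (length(common) == 0L)
        stop("no samples shared by the OTU table, brain table and labels")
    dropped <- sort(setdiff(unique(unlist(ids)), common))
    diet2 <- diet[common]
    diet2 <- droplevels(diet2)
    list(otu = otu[, common], brain = brain[, common],
         diet = diet2, dropped = dropped)
}
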