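#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

DIET_LEVELS_DEFAULT <- c("A", "B", "C", "D")
DTI_METRICS <- c("fa", "rd", "ad", "tr")

#' OtuTable: OTU abundance container
#'
#' A \linkS4class{SummarizedExperiment} holding an OTU feature table with
#' OTUs in rows and samples in columns.  The single assay \code{"abundance"}
#' holds relative abundances in \eqn{[0,1]} or their log2 transform; which of
#' the two is recorded in \code{metadata(x)$scale} (\code{"relative"} or
#' \code{"log2"}).  The scale flag gates the transform operations so that,
#' e.g., a table cannot be log2-transformed twice.
#'
#' @seealso [OtuTable()], [log2Transform()], [otuMatrix()]
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

#' BrainFeatureTable: diffusion-tensor ROI feature container
#'
#' A \linkS4class{SummarizedExperiment} with one row per brain feature,
#' a feature being a (region of interest, diffusion metric) pair where the
#' metric is one of \code{fa} (fractional anisotropy), \code{rd} (radial
#' diffusivity), \code{ad} (axial diffusivity) or \code{tr} (trace, i.e.
#' mean diffusivity times three).  Columns are samples.  The assay
#' \code{"value"} holds per-ROI mean metric values, raw or z-scaled across
#' samples (\code{metadata(x)$scale} is \code{"raw"} or \code{"zscaled"});
#' \code{rowData} carries the \code{roi} and \code{metric} columns.
#'
#' @seealso [BrainFeatureTable()], [zScale()], [brainMatrix()]
#' @export
setClass("BrainFeatureTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "abundance"))
        msg <- c(msg, "assay must be named 'abundance'")
    sc <- metadata(object)$scale
    if (!is.character(sc) || length(sc) != 1L ||
        !sc %in% c("relative", "log2"))
        msg <- c(msg, "metadata(x)$scale must be 'relative' or 'log2'")
    a <- assay(object)
    if (anyNA(a))
        msg <- c(msg, "abundance matrix contains missing values")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate OTU identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (identical(sc, "relative") && !anyNA(a) && length(a) &&
        (min(a) < 0 || max(a) > 1))
        msg <- c(msg, "relative abundances must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setValidity("BrainFeatureTable", function(object) {
    msg <- character()
    if (!identical(SummarizedExperiment::assayNames(object), "value"))
        msg <- c(msg, "assay must be named 'value'")
    sc <- metadata(object)$scale
    if (!is.character(sc) || length(sc) != 1L ||
        !sc %in% c("raw", "zscaled"))
        msg <- c(msg, "metadata(x)$scale must be 'raw' or 'zscaled'")
    rd <- rowData(object)
    if (!all(c("roi", "metric") %in% colnames(rd))) {
        msg <- c(msg, "rowData must carry 'roi' and 'metric'")
    } else if (!all(rd$metric %in% DTI_METRICS)) {
        msg <- c(msg, sprintf("metrics must be in {%s}",
                              paste(DTI_METRICS, collapse = ", ")))
    }
    if (anyNA(assay(object)))
        msg <- c(msg, "value matrix contains missing values")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
})

#' Construct an OtuTable
#'
#' @param abundance numeric matrix, OTUs in rows and samples in columns,
#'   with complete dimnames.  Use [otuMatrix()] to get back the transposed
#'   samples-by-OTUs view used for model fitting.
#' @param scale \code{"relative"} (values in \eqn{[0,1]}) or \code{"log2"}.
#' @param taxonomy optional character vector of taxonomy strings, one per
#'   OTU (recycled into \code{rowData}).
#' @return An \linkS4class{OtuTable}.
#' @examples
#' m <- matrix(c(.6, .4, .3, .7), 2, dimnames = list(c("OTU1","OTU2"),
#'                                                   c("s1","s2")))
#' OtuTable(m)
#' @export
OtuTable <- function(abundance, scale = c("relative", "log2"),
                     taxonomy = NULL) {
    scale <- match.arg(scale)
    abundance <- .checkedMatrix(abundance, "abundance")
    rd <- if (is.null(taxonomy)) {
        DataFrame(row.names = rownames(abundance))
    } else {
        if (length(taxonomy) != nrow(abundance))
            stop("taxonomy must have one entry per OTU")
        DataFrame(taxonomy = taxonomy, row.names = rownames(abundance))
    }
    se <- SummarizedExperiment(assays = list(abundance = abundance),
                               rowData = rd,
                               metadata = list(scale = scale))
    new("OtuTable", se)
}

#' Construct a BrainFeatureTable
#'
#' Feature identifiers are formed as \code{<roi>_<metric>}.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#'   Row names must be \code{<roi>_<metric>} with metric one of
#'   \code{fa, rd, ad, tr}; alternatively supply \code{roi} and
#'   \code{metric} vectors explicitly.
#' @param scale \code{"raw"} or \code{"zscaled"}.
#' @param roi,metric optional character vectors (one entry per row)
#'   overriding the parse of the row names.
#' @return A \linkS4class{BrainFeatureTable}.
#' @export
BrainFeatureTable <- function(values, scale = c("raw", "zscaled"),
                              roi = NULL, metric = NULL) {
    scale <- match.arg(scale)
    values <- .checkedMatrix(values, "values")
    if (is.null(roi) || is.null(metric)) {
        parsed <- .parseFeatureIds(rownames(values))
        roi <- parsed$roi
        metric <- parsed$metric
    }
    se <- SummarizedExperiment(
        assays = list(value = values),
        rowData = DataFrame(roi = roi, metric = metric,
                            row.names = rownames(values)),
        metadata = list(scale = scale))
    new("BrainFeatureTable", se)
}

.checkedMatrix <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m))
        stop(what, " must be a numeric matrix")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop(what, " must have complete dimnames")
    m
}

.parseFeatureIds <- function(ids) {
    metric <- sub("^.*_", "", ids)
    roi <- sub("_[^_]*$", "", ids)
    bad <- !metric %in% DTI_METRICS
    if (any(bad))
        stop("cannot parse metric from feature id(s): ",
             paste(utils::head(ids[bad], 3L), collapse = ", "),
             " (expected '<roi>_<fa|rd|ad|tr>')")
    list(roi = roi, metric = metric)
}

#' Validate diet labels
#'
#' Diet labels are a named factor: names are sample identifiers, levels the
#' ordered diet classes (default \code{A, B, C, D}).
#'
#' @param x named character or factor of diet assignments.
#' @param levels ordered class labels; defaults to the levels present
#'   (sorted) or \code{A,B,C,D} when \code{x} uses exactly those.
#' @return A named factor.
#' @export
DietLabels <- function(x, levels = NULL) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("diet labels must be uniquely named by sample_id")
    if (anyNA(x)) stop("diet labels contain missing values")
    if (is.null(levels))
        levels <- sort(unique(as.character(x)))
    y <- factor(as.character(x), levels = levels)
    if (anyNA(y)) stop("diet label outside declared class set")
    names(y) <- names(x)
    y
}

# ---- forest configuration ---------------------------------------------------

#' ForestConfig: random-forest fitting parameters
#'
#' @slot ntree number of trees.
#' @slot mtry features tried per split: a count, or one of the rules
#'   \code{"sqrt_p"} / \code{"p_over_3"} resolved against the number of
#'   features at fit time (the classification and regression defaults of
#'   the randomForest package).
#' @slot seed integer seed; identical configuration implies identical fits
#'   and importances.
#' @slot importanceScaled if TRUE, permutation importances are divided by
#'   their standard error across trees; default FALSE (raw mean decrease).
#' @export
setClass("ForestConfig",
         representation(ntree = "integer", mtry = "ANY", seed = "integer",
                        importanceScaled = "logical"))

setValidity("ForestConfig", function(object) {
    msg <- character()
    if (object@ntree < 1L) msg <- c(msg, "ntree must be >= 1")
    m <- object@mtry
    ok <- (is.character(m) && length(m) == 1L &&
           m %in% c("sqrt_p", "p_over_3", "mode_default")) ||
          (is.numeric(m) && length(m) == 1L && m >= 1)
    if (!ok)
        msg <- c(msg, "mtry must be a count >= 1, 'sqrt_p' or 'p_over_3'")
    if (length(msg)) msg else TRUE
})

#' Create a ForestConfig
#'
#' @param ntree number of trees (>= 1).  The diet classifiers in the
#'   original study design use 16000 and the per-region regressions 4000;
#'   smaller values are adequate for simulation work.
#' @param mtry count, or \code{"sqrt_p"} / \code{"p_over_3"}; \code{NULL}
#'   picks the mode default at fit time (\code{sqrt_p} for classification,
#'   \code{p_over_3} for regression).
#' @param seed integer driving all randomness of the fit.
#' @param importanceScaled divide mean importance by its standard error
#'   across trees (FALSE: raw mean decrease).
#' @return A \linkS4class{ForestConfig}.
#' @export
forestConfig <- function(ntree = 500L, mtry = NULL, seed = 1L,
                         importanceScaled = FALSE) {
    if (is.null(mtry)) mtry <- "mode_default"
    new("ForestConfig", ntree = as.integer(ntree), mtry = mtry,
        seed = as.integer(seed),
        importanceScaled = isTRUE(importanceScaled))
}

.resolveMtry <- function(mtry, p, mode) {
    if (identical(mtry, "mode_default"))
        mtry <- if (mode == "classification") "sqrt_p" else "p_over_3"
    if (is.character(mtry)) {
        m <- switch(mtry, sqrt_p = floor(sqrt(p)), p_over_3 = floor(p / 3))
    } else m <- floor(mtry)
    max(1L, min(as.integer(m), p))
}

# ---- importance -------------------------------------------------------------

#' ImportanceTable: per-feature permutation importance
#'
#' Out-of-bag permutation importances from a random-forest fit:
#' MeanDecreaseAccuracy in classification mode, \%IncMSE in regression
#' mode.  Ranks are dense with ties broken stably by feature identifier.
#'
#' @slot importance named numeric vector, one finite value per feature.
#' @slot mode \code{"classification"} or \code{"regression"}.
#' @export
setClass("ImportanceTable",
         representation(importance = "numeric", mode = "character"))

setValidity("ImportanceTable", function(object) {
    msg <- character()
    if (is.null(names(object@importance)) ||
        anyDuplicated(names(object@importance)))
        msg <- c(msg, "importance must be uniquely named by feature")
    if (!all(is.finite(object@importance)))
        msg <- c(msg, "importance values must be finite")
    if (!object@mode %in% c("classification", "regression"))
        msg <- c(msg, "mode must be 'classification' or 'regression'")
    if (length(msg)) msg else TRUE
})

ImportanceTable <- function(importance, mode) {
    new("ImportanceTable", importance = importance, mode = mode)
}

#' ForestFit: a fitted forest with its importance table
#'
#' @slot model the underlying \code{randomForest} fit.
#' @slot importance an \linkS4class{ImportanceTable}.
#' @slot mode \code{"classification"} or \code{"regression"}.
#' @export
setClass("ForestFit",
         representation(model = "ANY", importance = "ImportanceTable",
                        mode = "character"))

# ---- cross-validation report ------------------------------------------------

#' CvReport: cross-validation results
#'
#' @slot predictions data.frame with columns \code{sample_id},
#'   \code{truth}, \code{predicted} and, for repeated CV, \code{repeat_id}
#'   and \code{fold}.
#' @slot confusion true-class by predicted-class count matrix.
#' @slot accuracy pooled accuracy (trace over grand total).
#' @slot foldAccuracies per repeat-fold accuracies (length 0 for LOOCV).
#' @slot accuracySd sample standard deviation of the fold accuracies.
#' @slot ciHalfWidth 95\% normal-approximation half-width.
#' @slot method label of the procedure that produced the report.
#' @export
setClass("CvReport",
         representation(predictions = "data.frame", confusion = "matrix",
                        accuracy = "numeric", foldAccuracies = "numeric",
                        accuracySd = "numeric", ciHalfWidth = "numeric",
                        method = "character"))

setValidity("CvReport", function(object) {
    msg <- character()
    tot <- sum(object@confusion)
    if (tot != nrow(object@predictions))
        msg <- c(msg, "confusion grand total must equal evaluated samples")
    acc <- sum(diag(object@confusion)) / tot
    if (abs(acc - object@accuracy) > 1e-12)
        msg <- c(msg, "accuracy must equal trace / grand total")
    if (object@accuracy < 0 || object@accuracy > 1)
        msg <- c(msg, "accuracy must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

# ---- synthetic cohort design ------------------------------------------------

#' CohortDesign: parameters of the synthetic cohort generator
#'
#' The defaults mirror the study design the package emulates: 20 animals,
#' four diets with five animals each, nine diet-discriminative OTUs among
#' 100, and diffusion-tensor features carrying effects of linked OTUs.
#'
#' @slot nPerDiet animals per diet class.
#' @slot diets ordered diet class labels.
#' @slot nOtus number of OTU features.
#' @slot nBrainFeatures number of (ROI, metric) brain features.
#' @slot nSignalOtus number of diet-discriminative OTUs.
#' @slot otuEffectSize separation of diet-specific mean log2 abundances,
#'   in units of the within-diet standard deviation.
#' @slot nLinkedPairs number of planted OTU-to-brain associations.
#' @slot linkStrength coefficient of the standardized OTU value in the
#'   linked brain feature's mean.
#' @slot noiseSd residual standard deviation of brain features.
#' @slot pairedSampling emit a pre-diet baseline sample per animal.
#' @slot seed integer seed.
#' @export
setClass("CohortDesign",
         representation(nPerDiet = "integer", diets = "character",
                        nOtus = "integer", nBrainFeatures = "integer",
                        nSignalOtus = "integer", otuEffectSize = "numeric",
                        nLinkedPairs = "integer", linkStrength = "numeric",
                        noiseSd = "numeric", pairedSampling = "logical",
                        seed = "integer"))

setValidity("CohortDesign", function(object) {
    msg <- character()
    chkCount <- function(v, nm) {
        if (length(v) != 1L || is.na(v) || v < 1L)
            sprintf("%s must be a count >= 1", nm) else character()
    }
    msg <- c(msg,
             chkCount(object@nPerDiet, "nPerDiet"),
             chkCount(object@nOtus, "nOtus"),
             chkCount(object@nBrainFeatures, "nBrainFeatures"))
    if (length(object@diets) < 2L || anyDuplicated(object@diets))
        msg <- c(msg, "diets must be >= 2 distinct class labels")
    if (object@nSignalOtus < 0L || object@nSignalOtus > object@nOtus)
        msg <- c(msg, "nSignalOtus must lie in [0, nOtus]")
    if (object@nLinkedPairs < 0L ||
        object@nLinkedPairs >
            max(object@nSignalOtus, 0L) * object@nBrainFeatures)
        msg <- c(msg,
                 "nLinkedPairs must lie in [0, nSignalOtus * nBrainFeatures]")
    for (nm in c("otuEffectSize", "linkStrength", "noiseSd")) {
        v <- slot(object, nm)
        if (!is.finite(v) || v < 0)
            msg <- c(msg, sprintf("%s must be finite and >= 0", nm))
    }
    if (length(msg)) msg else TRUE
})
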