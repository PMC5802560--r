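#' @include AllClasses.R
NULL

#' Accessors for the cohort containers
#'
#' \code{otuMatrix} and \code{brainMatrix} return the samples-by-features
#' orientation used by the model-fitting functions; \code{sampleIds},
#' \code{featureIds}, and the scale flags expose identity and state without
#' touching slots.
#'
#' @param x an \linkS4class{OtuTable} or \linkS4class{BrainFeatureTable}.
#' @return \code{otuMatrix}/\code{brainMatrix}: numeric matrix with samples
#'   in rows; \code{sampleIds}/\code{featureIds}: character;
#'   \code{abundanceScale}/\code{brainScale}: length-1 character.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("otuMatrix", function(x) standardGeneric("otuMatrix"))

#' @rdname accessors
#' @export
setGeneric("brainMatrix", function(x) standardGeneric("brainMatrix"))

#' @rdname accessors
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' @rdname accessors
#' @export
setGeneric("brainScale", function(x) standardGeneric("brainScale"))

#' @rdname accessors
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' @rdname accessors
setMethod("featureIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname accessors
setMethod("otuMatrix", "OtuTable", function(x) t(assay(x, "abundance")))

#' @rdname accessors
setMethod("brainMatrix", "BrainFeatureTable", function(x) t(assay(x, "value")))

#' @rdname accessors
setMethod("abundanceScale", "OtuTable", function(x) metadata(x)$scale)

#' @rdname accessors
setMethod("brainScale", "BrainFeatureTable", function(x) metadata(x)$scale)

#' Accessors for fitted objects
#'
#' @param x a \linkS4class{ForestFit}, \linkS4class{ImportanceTable} or
#'   \linkS4class{CvReport}.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname fit-accessors
#' @export
setGeneric("forestModel", function(x) standardGeneric("forestModel"))

#' @rdname fit-accessors
#' @export
setGeneric("importanceValues", function(x) standardGeneric("importanceValues"))

#' @rdname fit-accessors
#' @export
setGeneric("importanceMode", function(x) standardGeneric("importanceMode"))

#' @rdname fit-accessors
setMethod("importanceTable", "ForestFit", function(x) x@importance)

#' @rdname fit-accessors
setMethod("forestModel", "ForestFit", function(x) x@model)

#' @rdname fit-accessors
setMethod("importanceValues", "ImportanceTable", function(x) x@importance)

#' @rdname fit-accessors
setMethod("importanceMode", "ImportanceTable", function(x) x@mode)

#' @rdname fit-accessors
#' @export
setGeneric("cvAccuracy", function(x) standardGeneric("cvAccuracy"))

#' @rdname fit-accessors
#' @export
setGeneric("cvConfusion", function(x) standardGeneric("cvConfusion"))

#' @rdname fit-accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname fit-accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))

#' @rdname fit-accessors
setMethod("cvAccuracy", "CvReport", function(x) x@accuracy)

#' @rdname fit-accessors
setMethod("cvConfusion", "CvReport", function(x) x@confusion)

#' @rdname fit-accessors
setMethod("cvPredictions", "CvReport", function(x) x@predictions)

#' @rdname fit-accessors
setMethod("foldAccuracies", "CvReport", function(x) x@foldAccuracies)

#' Export an importance table as a data.frame
#'
#' Rows are ordered by decreasing importance with ties broken by feature
#' identifier; \code{rank} is 1 for the most important feature.
#'
#' @param x an \linkS4class{ImportanceTable}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with \code{feature_id}, \code{importance},
#'   \code{rank}.
#' @export
as.data.frame.ImportanceTable <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    imp <- importanceValues(x)
    ord <- order(-imp, names(imp))
    data.frame(feature_id = names(imp)[ord],
               importance = unname(imp[ord]),
               rank = seq_along(imp),
               stringsAsFactors = FALSE)
}

setMethod("show", "ImportanceTable", function(object) {
    imp <- importanceValues(object)
    metric <- if (object@mode == "classification")
        "MeanDecreaseAccuracy" else "%IncMSE"
    cat(sprintf("ImportanceTable (%s, %s): %d features\n",
                object@mode, metric, length(imp)))
    print(utils::head(as.data.frame(object), 5L))
    if (length(imp) > 5L) cat("...\n")
})

setMethod("show", "ForestFit", function(object) {
    cat(sprintf("ForestFit (%s), ntree = %d\n", object@mode,
                object@model$ntree))
    show(object@importance)
})

setMethod("show", "CvReport", function(object) {
    cat(sprintf("CvReport [%s]: accuracy %.3f over %d samples\n",
                object@method, object@accuracy,
                nrow(object@predictions)))
    if (length(object@foldAccuracies)) {
        cat(sprintf("  fold accuracies: mean %.3f, sd %.3f, 95%% +/- %.3f\n",
                    mean(object@foldAccuracies), object@accuracySd,
                    object@ciHalfWidth))
    }
    cat("Confusion (true x predicted):\n")
    print(object@confusion)
})

setMethod("show", "CohortDesign", function(object) {
    cat(sprintf(paste0(
        "CohortDesign: %d diets x %d animals, %d OTUs (%d signal,",
        " effect %.2f sd), %d brain features, %d linked pairs",
        " (strength %.2f, noise sd %.2f)%s, seed %d\n"),
        length(object@diets), object@nPerDiet, object@nOtus,
        object@nSignalOtus, object@otuEffectSize, object@nBrainFeatures,
        object@nLinkedPairs, object@linkStrength, object@noiseSd,
        if (object@pairedSampling) ", paired pre-diet samples" else "",
        object@seed))
})

setMethod("show", "ForestConfig", function(object) {
    m <- object@mtry
    cat(sprintf("ForestConfig: ntree %d, mtry %s, seed %d, %s importance\n",
                object@ntree,
                if (is.numeric(m)) as.character(m) else m,
                object@seed,
                if (object@importanceScaled) "scaled" else "unscaled"))
})
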