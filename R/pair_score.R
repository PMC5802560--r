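#' @include AllClasses.R diet_predict.R
NULL

#' Rank-derived importance scores
#'
#' Converts an importance vector over \eqn{N} features into scores in
#' \eqn{\{1/N, 2/N, \ldots, 1\}}: the ascending rank of each feature's
#' importance divided by \eqn{N}, so the most important feature scores 1
#' and the least important \eqn{1/N}.  Ties receive the average of their
#' rank positions, which preserves the exact score sum \eqn{(N+1)/2}.
#' Negative importances (common for pure-noise features under permutation
#' importance) are ranked as-is; only the ordering matters.
#'
#' @param imp an \linkS4class{ImportanceTable} or a named numeric vector.
#' @return Named numeric vector of scores in \eqn{(0, 1]}.
#' @export
rankScore <- function(imp) {
    v <- if (is(imp, "ImportanceTable")) importanceValues(imp) else imp
    if (length(v) == 0L) stop("empty importance table")
    if (is.null(names(v))) stop("importances must be named by feature")
    if (anyNA(v)) stop("importance contains NaN/NA")
    r <- rank(v, ties.method = "average")
    stats::setNames(r / length(v), names(v))
}

#' Score all OTU x brain-feature pairs
#'
#' The rank-product scoring scheme: each pair (OTU \eqn{i}, brain feature
#' \eqn{j}) receives
#' \deqn{S_{combined}(i,j) = S(OTU_i) \cdot S(BrainM_j) \cdot S(OTU_i, BrainM_j)}
#' where \eqn{S(OTU_i)} ranks the OTU's MeanDecreaseAccuracy for predicting
#' diet over \eqn{N_{OTU}}, \eqn{S(BrainM_j)} ranks the brain feature's
#' MeanDecreaseAccuracy for predicting diet over \eqn{N_{BrainM}}, and
#' \eqn{S(OTU_i, BrainM_j)} ranks the OTU's \%IncMSE within the regression
#' of brain feature \eqn{j} on all OTUs, over \eqn{N_{OTU}}.  A pair scores
#' 1 exactly when it is top-ranked in all three lists.
#'
#' @param otuImp \linkS4class{ImportanceTable} of OTUs for diet
#'   classification.
#' @param brainImp \linkS4class{ImportanceTable} of brain features for
#'   diet classification.
#' @param regImps named list of \linkS4class{ImportanceTable}, one per
#'   brain feature (as from [regressBrainOnOtus()]), each over exactly the
#'   OTU universe of \code{otuImp}.
#' @return data.frame with one row per pair (\eqn{N_{OTU} \times
#'   N_{BrainM}} rows): \code{otu_id}, \code{brain_feature_id},
#'   \code{s_otu}, \code{s_brain}, \code{s_pair}, \code{s_combined},
#'   ordered by decreasing \code{s_combined} with ties broken by
#'   (\code{otu_id}, \code{brain_feature_id}).
#' @export
scoreAllPairs <- function(otuImp, brainImp, regImps) {
    sOtu <- rankScore(otuImp)
    sBrain <- rankScore(brainImp)
    otus <- names(sOtu)
    brains <- names(sBrain)
    if (!setequal(names(regImps), brains))
        stop("regression map does not cover the brain feature universe; ",
             "missing: ",
             paste(utils::head(setdiff(brains, names(regImps)), 3L),
                   collapse = ", "))
    sPair <- matrix(NA_real_, nrow = length(otus), ncol = length(brains),
                    dimnames = list(otus, brains))
    for (b in brains) {
        vi <- importanceValues(regImps[[b]])
        if (!setequal(names(vi), otus))
            stop("regression for '", b,
                 "' is not over the OTU universe of otuImp")
        sPair[, b] <- rankScore(vi)[otus]
    }
    df <- data.frame(
        otu_id = rep(otus, times = length(brains)),
        brain_feature_id = rep(brains, each = length(otus)),
        s_otu = rep(unname(sOtu), times = length(brains)),
        s_brain = rep(unname(sBrain), each = length(otus)),
        s_pair = as.vector(sPair),
        stringsAsFactors = FALSE)
    df$s_combined <- df$s_otu * df$s_brain * df$s_pair
    df <- df[order(-df$s_combined, df$otu_id, df$brain_feature_id), ]
    rownames(df) <- NULL
    df
}

#' Keep the top-ranked pairs
#'
#' @param pairs data.frame from [scoreAllPairs()] (already in the
#'   deterministic order).
#' @param k number of pairs to keep (default 27, the prefix used to build
#'   the downstream diet models).
#' @return The first \code{k} rows.
#' @export
selectTopPairs <- function(pairs, k = 27L) {
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
        stop("k must be a positive count")
    if (k > nrow(pairs)) stop("k exceeds the number of pairs")
    pairs[seq_len(k), , drop = FALSE]
}

#' Threshold pairs on the combined score
#'
#' @param pairs data.frame with an \code{s_combined} column.
#' @param cutoff retain pairs with \code{s_combined >= cutoff}; default
#'   0.84, the operating point used to call OTU to brain-ROI links.
#' @return The retained rows, order preserved (possibly empty).
#' @export
applyThreshold <- function(pairs, cutoff = 0.84) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
        cutoff < 0 || cutoff > 1)
        stop("cutoff must lie in [0, 1]")
    pairs[pairs$s_combined >= cutoff, , drop = FALSE]
}

#' Forward selection of pairs to a target LOOCV accuracy
#'
#' Adds pairs one at a time in decreasing \code{s_combined} order; after
#' each addition the diet-prediction LOOCV accuracy of the growing feature
#' set is evaluated and selection stops at the first prefix reaching
#' \code{targetAccuracy} (default 1, i.e. 100\%).  The feature set is the
#' union of the OTU columns, the brain columns, or both, per the
#' three-model scheme.
#'
#' @param pairs data.frame of scored pairs in selection order.
#' @param otuX samples x OTUs matrix (log2 scale).
#' @param brainX samples x brain-features matrix (z-scaled).
#' @param y factor of diet labels.
#' @param cfg a \linkS4class{ForestConfig}.
#' @param targetAccuracy stop once LOOCV accuracy reaches this value; must
#'   lie in \eqn{(0, 1]}.
#' @param model which columns the growing feature set uses:
#'   \code{"both"}, \code{"otu"} or \code{"brain"}.
#' @return A list: \code{selected} (the pair prefix), \code{report}
#'   (\linkS4class{CvReport} of the final prefix), \code{reached}
#'   (logical), \code{accuracies} (per-prefix LOOCV accuracies).
#' @export
forwardSelect <- function(pairs, otuX, brainX, y, cfg = forestConfig(),
                          targetAccuracy = 1.0,
                          model = c("both", "otu", "brain")) {
    model <- match.arg(model)
    if (!is.numeric(targetAccuracy) || length(targetAccuracy) != 1L ||
        is.na(targetAccuracy) || targetAccuracy <= 0 || targetAccuracy > 1)
        stop("targetAccuracy must lie in (0, 1]")
    if (nrow(pairs) == 0L) stop("no pairs to select from")
    accs <- numeric(0)
    report <- NULL
    for (i in seq_len(nrow(pairs))) {
        cols <- list()
        if (model %in% c("both", "otu"))
            cols$otu <- otuX[, unique(pairs$otu_id[seq_len(i)]),
                             drop = FALSE]
        if (model %in% c("both", "brain"))
            cols$brain <- brainX[, unique(pairs$brain_feature_id[seq_len(i)]),
                                 drop = FALSE]
        Xi <- do.call(cbind, unname(cols))
        report <- loocv(Xi, y, cfg)
        accs <- c(accs, cvAccuracy(report))
        if (cvAccuracy(report) >= targetAccuracy)
            return(list(selected = pairs[seq_len(i), , drop = FALSE],
                        report = report, reached = TRUE,
                        accuracies = accs))
    }
    list(selected = pairs, report = report, reached = FALSE,
         accuracies = accs)
}

#' Evaluate the three downstream diet models on the selected pairs
#'
#' Fits and LOOCV-evaluates the three forests built from a selected pair
#' set: OTU columns only, brain columns only, and both.
#'
#' @inheritParams forwardSelect
#' @return Named list of \linkS4class{CvReport} (\code{otu},
#'   \code{brain}, \code{both}).
#' @export
evaluatePairModels <- function(pairs, otuX, brainX, y,
                               cfg = forestConfig()) {
    ou <- unique(pairs$otu_id)
    bu <- unique(pairs$brain_feature_id)
    list(otu = loocv(otuX[, ou, drop = FALSE], y, cfg),
         brain = loocv(brainX[, bu, drop = FALSE], y, cfg),
         both = loocv(cbind(otuX[, ou, drop = FALSE],
                            brainX[, bu, drop = FALSE]), y, cfg))
}
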