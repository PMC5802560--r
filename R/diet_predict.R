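#' @include AllClasses.R forest_engine.R
NULL

.mkConfusion <- function(truth, predicted, levels) {
    table(true = factor(truth, levels = levels),
          predicted = factor(predicted, levels = levels))
}

.mkCvReport <- function(pred, levels, method, foldAcc = numeric(0),
                        seMode = FALSE) {
    conf <- .mkConfusion(pred$truth, pred$predicted, levels)
    conf <- unclass(conf)
    acc <- sum(diag(conf)) / sum(conf)
    sdv <- if (length(foldAcc) > 1L) stats::sd(foldAcc) else NA_real_
    hw <- if (is.na(sdv)) NA_real_ else
        1.96 * sdv / if (seMode) sqrt(length(foldAcc)) else 1
    new("CvReport", predictions = pred, confusion = conf, accuracy = acc,
        foldAccuracies = foldAcc, accuracySd = sdv, ciHalfWidth = hw,
        method = method)
}

#' Leave-one-out cross-validated diet classification
#'
#' For each sample, a forest is fit on the remaining \eqn{n-1} samples and
#' predicts the held-out one; the report assembles the confusion matrix
#' and pooled accuracy.  Per-fold seeds derive from \code{cfg@seed}.
#'
#' Note that when the feature columns of \code{X} were themselves selected
#' using all samples, LOOCV accuracy is optimistically biased; use
#' [nestedCv()] for an honest estimate that keeps selection inside the
#' resampling loop.
#'
#' @param X samples x features numeric matrix.
#' @param y factor of class labels aligned with rows of \code{X}.
#' @param cfg a \linkS4class{ForestConfig}; the study design uses
#'   \code{ntree = 16000} for diet classification.
#' @return A \linkS4class{CvReport}.
#' @export
loocv <- function(X, y, cfg = forestConfig()) {
    X <- .checkX(X)
    y <- factor(y)
    n <- nrow(X)
    if (n < 2L) stop("leave-one-out needs at least two samples")
    preds <- character(n)
    for (i in seq_len(n)) {
        yTrain <- droplevels(y[-i])
        if (nlevels(yTrain) < 2L)
            stop("training fold leaving out sample ", i,
                 " ('", rownames(X)[i], "') has a single class")
        cfgI <- cfg
        cfgI@seed <- .subSeed(cfg@seed, i)
        fit <- fitClassifier(X[-i, , drop = FALSE], yTrain, cfgI)
        preds[i] <- as.character(predictClasses(fit, X[i, , drop = FALSE]))
    }
    pred <- data.frame(sample_id = rownames(X), truth = as.character(y),
                       predicted = preds, stringsAsFactors = FALSE)
    .mkCvReport(pred, levels(y), "loocv")
}

#' Select the most important features
#'
#' Returns the \code{k} features with the largest importance; ties are
#' broken stably by feature identifier so the selection is deterministic.
#'
#' @param imp an \linkS4class{ImportanceTable}.
#' @param k number of features to keep (1..N).
#' @return Character vector of feature identifiers, most important first.
#' @export
selectTopFeatures <- function(imp, k) {
    stopifnot(is(imp, "ImportanceTable"))
    v <- importanceValues(imp)
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
        stop("k must be a positive count")
    if (k > length(v))
        stop("k exceeds the number of features (", length(v), ")")
    ord <- order(-v, names(v))
    names(v)[ord][seq_len(k)]
}

# Stratified fold assignment: per class, shuffle with the derived seed and
# deal round-robin, so a 4x5 design yields five folds of one animal per
# diet each.
.stratifiedFolds <- function(y, folds, seed) {
    assign <- integer(length(y))
    set.seed(seed)
    for (cl in levels(y)) {
        idx <- which(y == cl)
        if (length(idx) < folds)
            stop("stratification infeasible: class '", cl, "' has ",
                 length(idx), " samples for ", folds, " folds")
        idx <- idx[sample.int(length(idx))]
        assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
}

#' Repeated stratified nested cross-validation of feature selection
#'
#' Honest accuracy estimation for the select-then-classify procedure: in
#' each of \code{repeats} repetitions, samples are split into
#' diet-stratified folds; within every training split a forest is fit on
#' all features, the top \code{k} by permutation importance are selected,
#' and a forest restricted to them predicts the held-out fold.  Selection
#' happens strictly inside the loop, so no information from the test fold
#' leaks into the feature ranking.  The report carries the repeat-by-fold
#' accuracies, their mean and sample standard deviation, and a 95\%
#' normal-approximation interval half-width of \code{1.96 * sd} (set
#' \code{seMode = TRUE} for \code{1.96 * sd / sqrt(folds * repeats)}).
#'
#' @param X samples x features numeric matrix.
#' @param y factor of class labels.
#' @param k number of features selected inside each training split.
#' @param cfg a \linkS4class{ForestConfig}.
#' @param folds folds per repeat (default 5).
#' @param repeats repetitions (default 3).
#' @param seMode report the standard-error interval instead of the
#'   sample-sd interval.
#' @return A \linkS4class{CvReport}; \code{foldAccuracies(x)} has
#'   \code{folds * repeats} entries.
#' @export
nestedCv <- function(X, y, k, cfg = forestConfig(), folds = 5L,
                     repeats = 3L, seMode = FALSE) {
    X <- .checkX(X)
    y <- factor(y)
    if (k > ncol(X)) stop("k exceeds the number of features")
    predList <- list()
    foldAcc <- numeric(0)
    for (r in seq_len(repeats)) {
        assign <- .stratifiedFolds(y, folds, .subSeed(cfg@seed, 5000L + r))
        for (f in seq_len(folds)) {
            test <- which(assign == f)
            train <- which(assign != f)
            cfgRF <- cfg
            cfgRF@seed <- .subSeed(cfg@seed, 6000L + r * 100L + f)
            sel <- selectTopFeatures(
                importanceTable(fitClassifier(X[train, , drop = FALSE],
                                              droplevels(y[train]), cfgRF)),
                k)
            cfgRF2 <- cfg
            cfgRF2@seed <- .subSeed(cfg@seed, 7000L + r * 100L + f)
            fit <- fitClassifier(X[train, sel, drop = FALSE],
                                 droplevels(y[train]), cfgRF2)
            pr <- as.character(
                predictClasses(fit, X[test, sel, drop = FALSE]))
            foldAcc <- c(foldAcc, mean(pr == as.character(y[test])))
            predList[[length(predList) + 1L]] <- data.frame(
                sample_id = rownames(X)[test],
                truth = as.character(y[test]), predicted = pr,
                repeat_id = r, fold = f, stringsAsFactors = FALSE)
        }
    }
    pred <- do.call(rbind, predList)
    .mkCvReport(pred, levels(y),
                sprintf("nested %dx%d-fold stratified CV", repeats, folds),
                foldAcc, seMode)
}

#' LOOCV after whole-data feature selection
#'
#' The optimistic headline procedure: features are ranked by permutation
#' importance on \emph{all} samples, the top \code{k} are kept, and LOOCV
#' is run on the reduced matrix.  Because selection saw every sample, the
#' resulting accuracy overstates performance on future data; pair it with
#' [nestedCv()] for the honest figure.
#'
#' @param X samples x features numeric matrix.
#' @param y factor of class labels.
#' @param k number of features to select on the full data.
#' @param cfg a \linkS4class{ForestConfig}.
#' @return A list: \code{selected} (character), \code{report}
#'   (\linkS4class{CvReport}), \code{importance}
#'   (\linkS4class{ImportanceTable} from the whole-data fit).
#' @export
selectThenLoocv <- function(X, y, k, cfg = forestConfig()) {
    X <- .checkX(X)
    imp <- importanceTable(fitClassifier(X, y, cfg))
    sel <- selectTopFeatures(imp, k)
    rep <- loocv(X[, sel, drop = FALSE], y, cfg)
    list(selected = sel, report = rep, importance = imp)
}
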