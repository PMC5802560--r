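#' @include AllClasses.R
#' @importFrom randomForest randomForest importance
NULL

.checkX <- function(X) {
    if (!is.matrix(X) || !is.numeric(X))
        stop("X must be a numeric matrix (samples x features)")
    if (any(!is.finite(X)))
        stop("X contains NaN/Inf/NA values")
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
    X
}

.importanceFrom <- function(rf, mode, scaled, featureIds) {
    type1 <- randomForest::importance(rf, type = 1, scale = scaled)
    imp <- stats::setNames(as.numeric(type1[, 1]), rownames(type1))
    imp <- imp[featureIds]
    imp[!is.finite(imp)] <- 0  # zero-variance permutation contrast
    ImportanceTable(imp, mode)
}

#' Fit a random-forest diet classifier with permutation importance
#'
#' Fits a classification forest and extracts out-of-bag permutation
#' importance (MeanDecreaseAccuracy): for each feature, the decrease in a
#' tree's out-of-bag accuracy when that feature's values are permuted,
#' averaged over trees.  With \code{importanceScaled = FALSE} (default)
#' the raw mean decrease is reported; the scaled variant divides by the
#' standard error across trees.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y factor (or coercible) of class labels, aligned with the rows
#'   of \code{X}; at least two classes.
#' @param cfg a \linkS4class{ForestConfig}.
#' @return A \linkS4class{ForestFit}.
#' @seealso [fitRegressor()], [predictClasses()]
#' @export
fitClassifier <- function(X, y, cfg = forestConfig()) {
    X <- .checkX(X)
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2L)
        stop("classification needs at least two classes")
    if (length(y) != nrow(X))
        stop("y must align with the rows of X")
    set.seed(cfg@seed)
    rf <- randomForest::randomForest(
        x = X, y = y, ntree = cfg@ntree,
        mtry = .resolveMtry(cfg@mtry, ncol(X), "classification"),
        importance = TRUE, keep.forest = TRUE)
    new("ForestFit", model = rf,
        importance = .importanceFrom(rf, "classification",
                                     cfg@importanceScaled, colnames(X)),
        mode = "classification")
}

#' Fit a random-forest regressor with permutation importance
#'
#' Fits a regression forest and extracts \%IncMSE: the percent increase in
#' out-of-bag mean squared error when one feature is permuted, averaged
#' over trees.  Used to regress each z-scaled brain feature on the OTU
#' abundances.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y numeric response, finite, not constant.
#' @param cfg a \linkS4class{ForestConfig}.
#' @return A \linkS4class{ForestFit}.
#' @export
fitRegressor <- function(X, y, cfg = forestConfig()) {
    X <- .checkX(X)
    if (!is.numeric(y) || any(!is.finite(y)))
        stop("y must be finite numeric")
    if (length(y) != nrow(X))
        stop("y must align with the rows of X")
    if (stats::sd(y) == 0)
        stop("constant response: no out-of-bag MSE contrast")
    set.seed(cfg@seed)
    rf <- randomForest::randomForest(
        x = X, y = as.numeric(y), ntree = cfg@ntree,
        mtry = .resolveMtry(cfg@mtry, ncol(X), "regression"),
        importance = TRUE, keep.forest = TRUE)
    new("ForestFit", model = rf,
        importance = .importanceFrom(rf, "regression",
                                     cfg@importanceScaled, colnames(X)),
        mode = "regression")
}

#' Predict classes or responses for new samples
#'
#' @param fit a \linkS4class{ForestFit}.
#' @param newX numeric matrix with the same feature columns used at fit
#'   time.
#' @return Factor of predicted classes (classification) or numeric
#'   predictions (regression).
#' @export
predictClasses <- function(fit, newX) {
    stopifnot(is(fit, "ForestFit"))
    stats::predict(fit@model, newdata = newX)
}

#' Regress every brain feature on the OTU table
#'
#' Runs one random-forest regression per brain feature (z-scaled value on
#' all OTU log2 abundances) and collects the \%IncMSE importance tables,
#' the inputs of the pair-scoring stage.  Per-feature seeds are derived
#' deterministically from \code{cfg@seed}.
#'
#' @param otuX samples x OTUs numeric matrix (log2 scale).
#' @param brainX samples x brain-features numeric matrix (z-scaled).
#' @param cfg a \linkS4class{ForestConfig}; the study design uses
#'   \code{ntree = 4000} here.
#' @return Named list of \linkS4class{ImportanceTable}, one per brain
#'   feature, each over the full OTU universe.
#' @export
regressBrainOnOtus <- function(otuX, brainX, cfg = forestConfig(ntree = 4000L)) {
    otuX <- .checkX(otuX)
    brainX <- .checkX(brainX)
    if (nrow(otuX) != nrow(brainX))
        stop("otuX and brainX must have the same samples")
    res <- vector("list", ncol(brainX))
    names(res) <- colnames(brainX)
    for (j in seq_len(ncol(brainX))) {
        cfgJ <- cfg
        cfgJ@seed <- .subSeed(cfg@seed, 1000L + j)
        res[[j]] <- importanceTable(
            fitRegressor(otuX, brainX[, j], cfgJ))
    }
    res
}

#' Export importances to CSV
#'
#' @param imp an \linkS4class{ImportanceTable}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeImportance <- function(imp, path) {
    utils::write.csv(as.data.frame(imp), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}
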