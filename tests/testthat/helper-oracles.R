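# Independent oracles used by the property and acceptance tests.  These
# deliberately avoid the package's own code paths.

# Average-rank score computed per feature by direct counting: rank of x in v
# = (# strictly smaller) + (tied + 1) / 2, divided by N.
oracleRankScore <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
        (sum(v < v[i]) + (sum(v == v[i]) + 1) / 2) / n
    }, numeric(1)) |> stats::setNames(names(v))
}

# Exhaustive pair enumeration: loops over every (otu, brain) combination
# and multiplies the three counted-rank scores.
oraclePairScores <- function(otuImpVec, brainImpVec, regList) {
    sO <- oracleRankScore(otuImpVec)
    sB <- oracleRankScore(brainImpVec)
    out <- list()
    for (o in names(otuImpVec)) {
        for (b in names(brainImpVec)) {
            sP <- oracleRankScore(regList[[b]])[[o]]
            out[[length(out) + 1L]] <- data.frame(
                otu_id = o, brain_feature_id = b,
                s_combined = sO[[o]] * sB[[b]] * sP,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

# Direct OOB permutation importance: refits a forest with kept bag masks,
# then for each feature permutes its values among each tree's out-of-bag
# samples `nperm` times and measures the change in OOB accuracy (or MSE)
# from per-tree predictions.
oraclePermImportance <- function(X, y, ntree, seed, nperm = 1000L) {
    classification <- is.factor(y)
    set.seed(seed)
    rf <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                     keep.inbag = TRUE, keep.forest = TRUE)
    ind <- predict(rf, newdata = X, predict.all = TRUE)$individual
    imp <- numeric(ncol(X))
    names(imp) <- colnames(X)
    set.seed(seed + 1L)
    for (j in seq_len(ncol(X))) {
        deltas <- numeric(0)
        for (t in seq_len(ntree)) {
            oob <- which(rf$inbag[, t] == 0L)
            if (length(oob) < 2L) next
            base <- if (classification) {
                mean(ind[oob, t] == as.character(y[oob]))
            } else {
                mean((as.numeric(ind[oob, t]) - y[oob])^2)
            }
            # stack all permuted copies of the OOB rows for one predict call
            reps <- lapply(seq_len(nperm), function(r) {
                Xi <- X[oob, , drop = FALSE]
                Xi[, j] <- Xi[sample.int(length(oob)), j]
                Xi
            })
            stacked <- do.call(rbind, reps)
            pr <- predict(rf, newdata = stacked,
                          predict.all = TRUE)$individual[, t]
            prm <- matrix(pr, nrow = length(oob))
            if (classification) {
                permAcc <- colMeans(prm == as.character(y[oob]))
                deltas <- c(deltas, base - permAcc)       # decrease in accuracy
            } else {
                truth <- y[oob]
                permMse <- colMeans((apply(prm, 2, as.numeric) - truth)^2)
                deltas <- c(deltas, permMse - base)        # increase in MSE
            }
        }
        imp[j] <- mean(deltas)
    }
    imp
}

# Small helper: a toy cohort-like matrix pair for forward-selection tests.
toyDietMatrix <- function(n_per_class = 5, classes = c("A", "B", "C", "D"),
                          seed = 1) {
    set.seed(seed)
    y <- factor(rep(classes, each = n_per_class))
    n <- length(y)
    ids <- sprintf("s%02d", seq_len(n))
    X <- cbind(sep = as.numeric(y) * 3 + rnorm(n, sd = 0.2),
               noise1 = rnorm(n), noise2 = rnorm(n))
    rownames(X) <- ids
    names(y) <- ids
    list(X = X, y = y)
}
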