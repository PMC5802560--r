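# Planted-signal cohort for classification: one feature encodes the class
# exactly, the rest are noise.
plantedX <- function(seed, nNoise = 50, nPerClass = 5) {
    set.seed(seed)
    y <- factor(rep(c("A", "B", "C", "D"), each = nPerClass))
    X <- cbind(signal = as.numeric(y),
               matrix(rnorm(length(y) * nNoise), ncol = nNoise,
                      dimnames = list(NULL, sprintf("n%02d",
                                                    seq_len(nNoise)))))
    rownames(X) <- sprintf("s%02d", seq_along(y))
    list(X = X, y = y)
}

test_that("a class-encoding feature ranks first in permutation importance", {
    hits <- vapply(seq_len(20), function(s) {
        d <- plantedX(s)
        imp <- importanceTable(
            fitClassifier(d$X, d$y, forestConfig(ntree = 300L, seed = s)))
        as.data.frame(imp)$feature_id[1] == "signal"
    }, logical(1))
    expect_gte(sum(hits), 19L)
})

test_that("under a permuted response, importances are centred on zero", {
    nSeeds <- 50L
    d0 <- plantedX(999, nNoise = 5)
    imps <- vapply(seq_len(nSeeds), function(s) {
        set.seed(10000 + s)
        yPerm <- sample(d0$y)
        importanceValues(importanceTable(
            fitClassifier(d0$X, yPerm,
                          forestConfig(ntree = 150L, seed = s))))
    }, numeric(ncol(d0$X)))
    for (j in seq_len(nrow(imps))) {
        m <- mean(imps[j, ])
        half <- stats::qt(0.995, nSeeds - 1L) *
            stats::sd(imps[j, ]) / sqrt(nSeeds)
        expect_lt(abs(m), half + 1e-12)
    }
})

test_that("a linear driver dominates %IncMSE in regression mode", {
    hits <- vapply(seq_len(20), function(s) {
        set.seed(s)
        n <- 30
        X <- matrix(rnorm(n * 50), n,
                    dimnames = list(NULL, c("x1", sprintf("n%02d", 1:49))))
        y <- 3 * X[, "x1"] + rnorm(n, sd = 0.1)
        imp <- importanceTable(
            fitRegressor(X, y, forestConfig(ntree = 300L, seed = s)))
        as.data.frame(imp)$feature_id[1] == "x1"
    }, logical(1))
    expect_gte(sum(hits), 19L)

    # a feature independent of y has mean importance near zero
    nulls <- vapply(seq_len(50), function(s) {
        set.seed(100 + s)
        n <- 30
        X <- matrix(rnorm(n * 5), n,
                    dimnames = list(NULL, paste0("f", 1:5)))
        y <- 3 * X[, 1] + rnorm(n, sd = 0.1)
        importanceValues(importanceTable(
            fitRegressor(X, y, forestConfig(ntree = 150L, seed = s))))[["f5"]]
    }, numeric(1))
    half <- stats::qt(0.995, 49) * stats::sd(nulls) / sqrt(50)
    expect_lt(abs(mean(nulls)), half + 1e-12)
})

test_that("importance variance across seeds shrinks with more trees", {
    d <- plantedX(7, nNoise = 5)
    y <- 2 * d$X[, "signal"] + rnorm(nrow(d$X), sd = 0.5)
    impAt <- function(ntree) vapply(seq_len(25), function(s)
        importanceValues(importanceTable(
            fitRegressor(d$X, y,
                         forestConfig(ntree = ntree,
                                      seed = 200 + s))))[["signal"]],
        numeric(1))
    expect_gt(stats::var(impAt(1L)), stats::var(impAt(500L)))
})

test_that("fits and importances are seed-deterministic", {
    d <- plantedX(3, nNoise = 10)
    cfg <- forestConfig(ntree = 101L, seed = 42L)
    i1 <- importanceValues(importanceTable(fitClassifier(d$X, d$y, cfg)))
    i2 <- importanceValues(importanceTable(fitClassifier(d$X, d$y, cfg)))
    expect_identical(i1, i2)
    yr <- rnorm(nrow(d$X))
    r1 <- importanceValues(importanceTable(fitRegressor(d$X, yr, cfg)))
    r2 <- importanceValues(importanceTable(fitRegressor(d$X, yr, cfg)))
    expect_identical(r1, r2)
})

test_that("every sample is out-of-bag for some tree at practical ntree", {
    d <- plantedX(5, nNoise = 3)
    covered <- vapply(seq_len(60), function(s) {
        set.seed(s)
        rf <- randomForest::randomForest(x = d$X, y = d$y, ntree = 100L)
        all(rf$oob.times > 0L)
    }, logical(1))
    expect_gte(mean(covered), 0.99)
})

test_that("degenerate inputs are rejected", {
    d <- plantedX(1, nNoise = 3)
    expect_error(fitClassifier(d$X, factor(rep("A", nrow(d$X))),
                               forestConfig()), "two classes")
    Xbad <- d$X; Xbad[1, 1] <- NaN
    expect_error(fitClassifier(Xbad, d$y, forestConfig()), "NaN")
    expect_error(fitRegressor(d$X, rep(1, nrow(d$X)), forestConfig()),
                 "constant")
    expect_error(fitRegressor(d$X, c(rnorm(nrow(d$X) - 1), Inf),
                              forestConfig()), "finite")
})
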