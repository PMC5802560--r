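impT <- function(v, mode = "classification")
    gutBrainRank:::ImportanceTable(v, mode)

test_that("rank scores follow the rank-over-N construction", {
    expect_equal(rankScore(impT(c(a = 0.9, b = 0.2, c = 0.5))),
                 c(a = 1, b = 1 / 3, c = 2 / 3))
    expect_equal(rankScore(impT(c(solo = 42))), c(solo = 1))
    expect_equal(rankScore(impT(c(a = 0.5, b = 0.5))),
                 c(a = 0.75, b = 0.75))
    expect_error(rankScore(stats::setNames(c(1, NaN), c("a", "b"))), "NaN")
    expect_error(rankScore(numeric(0)), "empty")
})

test_that("rank scores conserve their sum under any tie configuration", {
    set.seed(11)
    for (i in 1:25) {
        n <- sample(2:40, 1)
        v <- sample(round(runif(n), sample(0:2, 1)))  # coarse => many ties
        names(v) <- paste0("f", seq_len(n))
        s <- rankScore(impT(v))
        expect_equal(sum(s), (n + 1) / 2)
        expect_gte(min(s), 1 / n)
        expect_lte(max(s), 1)
        # agreement with the independent counting oracle
        expect_equal(s, oracleRankScore(v))
    }
})

test_that("pair scoring multiplies the three rank scores and matches the toy", {
    otuImp <- impT(c(o1 = 5, o2 = 3, o3 = 1))
    brainImp <- impT(c(b1 = 2, b2 = 9))
    regs <- list(b1 = impT(c(o1 = 0.1, o2 = 0.7, o3 = 0.3), "regression"),
                 b2 = impT(c(o1 = 0.9, o2 = 0.2, o3 = 0.4), "regression"))
    pairs <- scoreAllPairs(otuImp, brainImp, regs)
    expect_equal(nrow(pairs), 6L)
    expect_equal(pairs$s_combined, pairs$s_otu * pairs$s_brain * pairs$s_pair)
    expect_true(all(diff(pairs$s_combined) <= 0))
    # hand-computed top pair: o1 top for diet (1), in b2 regression top (1),
    # b2 top brain feature (1) => s_combined = 1
    expect_identical(pairs$otu_id[1], "o1")
    expect_identical(pairs$brain_feature_id[1], "b2")
    expect_equal(pairs$s_combined[1], 1.0)
    # spot-check an interior pair: o2 (rank 2/3) x b1 (rank 1/2) x
    # o2 top in b1 regression (3/3)
    row <- pairs[pairs$otu_id == "o2" & pairs$brain_feature_id == "b1", ]
    expect_equal(row$s_combined, (2 / 3) * (1 / 2) * 1)

    # universe mismatches are named
    expect_error(scoreAllPairs(otuImp, brainImp, regs["b1"]), "missing")
    badRegs <- regs
    badRegs$b2 <- impT(c(o1 = 1, o2 = 2, oX = 3), "regression")
    expect_error(scoreAllPairs(otuImp, brainImp, badRegs), "b2")
})

test_that("pair scoring equals exhaustive enumeration on random toy instances", {
    set.seed(99)
    for (i in 1:10) {
        nO <- sample(2:5, 1); nB <- sample(2:4, 1)
        otus <- paste0("o", seq_len(nO)); brains <- paste0("b", seq_len(nB))
        ov <- stats::setNames(round(rnorm(nO), 1), otus)
        bv <- stats::setNames(round(rnorm(nB), 1), brains)
        rv <- lapply(stats::setNames(brains, brains), function(b)
            stats::setNames(round(rnorm(nO), 1), otus))
        pairs <- scoreAllPairs(impT(ov), impT(bv),
                               lapply(rv, impT, mode = "regression"))
        oracle <- oraclePairScores(ov, bv, rv)
        key <- function(d) paste(d$otu_id, d$brain_feature_id)
        expect_equal(pairs$s_combined[match(key(oracle), key(pairs))],
                     oracle$s_combined)
        # bounds and the top-in-all-three characterisation
        expect_true(all(pairs$s_combined > 0 & pairs$s_combined <= 1))
        expect_identical(pairs$s_combined == 1,
                         pairs$s_otu == 1 & pairs$s_brain == 1 &
                             pairs$s_pair == 1)
    }
})

test_that("improving any component rank never lowers the combined score", {
    set.seed(5)
    for (i in 1:50) {
        s <- runif(3); s2 <- s
        j <- sample(3, 1)
        s2[j] <- min(1, s[j] + runif(1))
        expect_gte(prod(s2), prod(s))
    }
})

test_that("top-pair selection and thresholding are faithful filters", {
    pairs <- data.frame(otu_id = paste0("o", 1:5),
                        brain_feature_id = "b1",
                        s_combined = c(1.0, 0.9, 0.84, 0.83, 0.2))
    expect_equal(nrow(selectTopPairs(pairs, 3)), 3L)
    expect_identical(selectTopPairs(pairs, nrow(pairs)), pairs)
    expect_error(selectTopPairs(pairs, 0), "positive")
    expect_error(selectTopPairs(pairs, 99), "exceeds")

    expect_equal(applyThreshold(pairs, 0.84)$otu_id,
                 c("o1", "o2", "o3"))
    expect_equal(nrow(applyThreshold(pairs, 0)), 5L)
    expect_equal(applyThreshold(pairs, 1.0)$otu_id, "o1")
    expect_error(applyThreshold(pairs, 1.5), "cutoff")
})

test_that("forward selection stops at the first prefix reaching the target", {
    d <- toyDietMatrix(seed = 31)
    otuX <- d$X
    colnames(otuX) <- c("oSep", "oN1", "oN2")
    brainX <- matrix(rnorm(nrow(d$X) * 2), ncol = 2,
                     dimnames = list(rownames(d$X), c("R1_fa", "R2_fa")))
    pairs <- data.frame(
        otu_id = c("oSep", "oN1", "oN2"),
        brain_feature_id = c("R1_fa", "R2_fa", "R1_fa"),
        s_combined = c(0.9, 0.5, 0.1), stringsAsFactors = FALSE)

    fs <- forwardSelect(pairs, otuX, brainX, d$y,
                        forestConfig(ntree = 150L, seed = 8L),
                        targetAccuracy = 1.0, model = "otu")
    expect_true(fs$reached)
    expect_equal(nrow(fs$selected), 1L)  # the separating OTU alone suffices
    expect_equal(cvAccuracy(fs$report), 1.0)

    # pure-noise pairs cannot reach 100%: all pairs consumed, flag unset
    noise <- pairs
    noiseX <- otuX
    set.seed(77)
    noiseX[, "oSep"] <- rnorm(nrow(noiseX))
    fs0 <- forwardSelect(noise, noiseX, brainX, d$y,
                         forestConfig(ntree = 100L, seed = 9L),
                         targetAccuracy = 1.0, model = "both")
    expect_false(fs0$reached)
    expect_equal(nrow(fs0$selected), nrow(noise))
    expect_length(fs0$accuracies, nrow(noise))

    expect_error(forwardSelect(pairs, otuX, brainX, d$y,
                               targetAccuracy = 0), "targetAccuracy")
})

test_that("the three downstream pair models evaluate coherently", {
    d <- toyDietMatrix(seed = 17)
    otuX <- d$X; colnames(otuX) <- c("oSep", "oN1", "oN2")
    brainX <- cbind(R1_fa = as.numeric(d$y) + rnorm(nrow(otuX), sd = 0.1),
                    R2_fa = rnorm(nrow(otuX)))
    rownames(brainX) <- rownames(otuX)
    pairs <- data.frame(otu_id = "oSep", brain_feature_id = "R1_fa",
                        s_combined = 1)
    reps <- evaluatePairModels(pairs, otuX, brainX, d$y,
                               forestConfig(ntree = 150L, seed = 2L))
    expect_named(reps, c("otu", "brain", "both"))
    for (r in reps) expect_gte(cvAccuracy(r), 0.9)
})
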