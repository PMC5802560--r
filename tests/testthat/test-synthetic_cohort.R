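test_that("generated cohorts are compositional, balanced and deterministic", {
    design <- cohortDesign(nPerDiet = 5L, nOtus = 100L, seed = 7L)
    co <- generateCohort(design)
    m <- otuMatrix(co$otu)

    expect_equal(dim(m), c(20L, 100L))
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
    expect_true(all(m >= 0))
    expect_equal(unname(table(co$diet)), rep(5L, 4L),
                 ignore_attr = TRUE)

    co2 <- generateCohort(cohortDesign(nPerDiet = 5L, nOtus = 100L,
                                       seed = 7L))
    expect_identical(otuMatrix(co2$otu), m)
    expect_identical(brainMatrix(co2$brain), brainMatrix(co$brain))
    expect_identical(co2$truth, co$truth)

    # ground truth is a subset of the generated universes
    expect_true(all(co$truth$signal_otu_ids %in% featureIds(co$otu)))
    expect_true(all(co$truth$linked_pairs$otu_id %in%
                        co$truth$signal_otu_ids))
    expect_true(all(co$truth$linked_pairs$brain_feature_id %in%
                        featureIds(co$brain)))
})

test_that("planted diet effect is calibrated to otuEffectSize in sd units", {
    diffs <- vapply(seq_len(200), function(s) {
        co <- generateCohort(cohortDesign(seed = s))
        lr <- log2(otuMatrix(co$otu))
        d <- co$truth$signal_otu_diet[["OTU001"]]
        mean(lr[co$diet == d, "OTU001"]) -
            mean(lr[co$diet != d, "OTU001"])
    }, numeric(1))
    effect <- 2  # default otuEffectSize, within-diet sd is 1
    expect_lt(abs(mean(diffs) - effect) / effect, 0.10)
})

test_that("with zero effect sizes, signal OTUs are indistinguishable from noise", {
    pvals <- vapply(seq_len(100), function(s) {
        co <- generateCohort(cohortDesign(seed = 5000L + s,
                                          otuEffectSize = 0,
                                          linkStrength = 0))
        lr <- log2(otuMatrix(co$otu))
        d <- co$truth$signal_otu_diet[["OTU001"]]
        stats::t.test(lr[co$diet == d, "OTU001"],
                      lr[co$diet != d, "OTU001"])$p.value
    }, numeric(1))
    expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("paired sampling emits pre-diet baselines without diet effect", {
    co <- generateCohort(cohortDesign(seed = 3L, pairedSampling = TRUE,
                                      otuEffectSize = 4))
    ids <- sampleIds(co$otu)
    expect_length(ids, 40L)
    pre <- grep("\\.pre$", ids, value = TRUE)
    expect_length(pre, 20L)
    m <- otuMatrix(co$otu)
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))

    # pre-diet samples share the weaning distribution: the planted OTU shows
    # no diet contrast before the diet starts, a strong one after
    lr <- log2(m)
    d <- co$truth$signal_otu_diet[["OTU001"]]
    post <- setdiff(ids, pre)
    dietOf <- co$diet
    contrast <- function(s) mean(lr[s[dietOf[s] == d], "OTU001"]) -
        mean(lr[s[dietOf[s] != d], "OTU001"])
    expect_gt(contrast(post), 2)
    expect_lt(abs(contrast(pre)), 1.5)
})

test_that("invalid designs are rejected with the field named", {
    expect_error(cohortDesign(nOtus = 0), "nOtus")
    expect_error(cohortDesign(nPerDiet = 2.5), "nPerDiet")
    expect_error(generateCohort(cohortDesign(nSignalOtus = 200,
                                             nOtus = 100)),
                 "nSignalOtus")
    expect_error(generateCohort(cohortDesign(otuEffectSize = -1)),
                 "otuEffectSize")
    expect_error(generateCohort(cohortDesign(nLinkedPairs = 1000,
                                             nSignalOtus = 2,
                                             nBrainFeatures = 4)),
                 "nLinkedPairs")
})

test_that("cohorts round-trip through disk losslessly and byte-identically", {
    co <- generateCohort(cohortDesign(seed = 11L, nOtus = 40L,
                                      nBrainFeatures = 8L))
    dir1 <- withr::local_tempdir()
    paths <- writeCohort(co, dir1)
    expect_true(all(file.exists(paths)))

    back <- readCohort(dir1)
    expect_equal(otuMatrix(back$otu), otuMatrix(co$otu), tolerance = 1e-12)
    expect_equal(brainMatrix(back$brain), brainMatrix(co$brain),
                 tolerance = 1e-12)
    expect_identical(as.character(back$diet[names(co$diet)]),
                     as.character(co$diet))

    # identical design => identical bytes on disk
    dir2 <- withr::local_tempdir()
    co2 <- generateCohort(cohortDesign(seed = 11L, nOtus = 40L,
                                       nBrainFeatures = 8L))
    paths2 <- writeCohort(co2, dir2)
    for (k in c("otu", "brain", "labels"))
        expect_identical(unname(tools::md5sum(paths[[k]])),
                         unname(tools::md5sum(paths2[[k]])))
})

test_that("degenerate cohorts and dialect violations are rejected at write", {
    co <- generateCohort(cohortDesign(seed = 2L, nOtus = 10L,
                                      nBrainFeatures = 4L))
    empty <- co
    empty$otu <- co$otu[, character(0)]
    expect_error(writeCohort(empty, withr::local_tempdir()), "empty")

    withTax <- co
    m <- SummarizedExperiment::assay(co$otu, "abundance")
    withTax$otu <- OtuTable(m, scale = "relative",
                            taxonomy = c("k__Bacteria;\tg__Bad",
                                         rep("k__Bacteria", 9)))
    expect_error(writeCohort(withTax, withr::local_tempdir()), "tab")
})
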