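#' @include AllClasses.R
NULL

# Deterministic sub-seed derivation: one user-facing seed drives every
# stream; offsets keep streams distinct while staying inside 32-bit range.
.subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) %% 1000003 + 1) * 1009 + offset) %% 2147483647L
}

#' Define a synthetic cohort design
#'
#' The defaults emulate the study design the package targets: 20 animals
#' (four diets, five animals each), 100 OTUs of which nine carry
#' diet-specific abundance shifts, and 40 diffusion-tensor features
#' (10 ROIs times the four metrics fa, rd, ad, tr) of which a few are
#' linearly linked to signal OTUs.  Signal OTUs are modelled as rarer taxa
#' that bloom under their assigned diet: their baseline log2 intensity sits
#' well below the bulk community so the compositional closure leaves the
#' planted log2 shift essentially intact for every other feature.
#'
#' @param nPerDiet animals per diet (default 5).
#' @param diets ordered class labels (default \code{A,B,C,D}).
#' @param nOtus number of OTUs (default 100).
#' @param nBrainFeatures number of (ROI, metric) features; a multiple of 4
#'   is laid out as ROIs times the metrics fa, rd, ad, tr (default 40).
#' @param nSignalOtus diet-discriminative OTUs (default 9).
#' @param otuEffectSize separation of per-diet mean log2 abundances in
#'   within-diet standard deviations (default 2).
#' @param nLinkedPairs planted OTU-to-brain-feature associations
#'   (default 5).
#' @param linkStrength coefficient of the standardized linked-OTU value in
#'   the brain feature mean (default 1).
#' @param noiseSd residual standard deviation of brain features
#'   (default 1).
#' @param pairedSampling also emit one pre-diet baseline fecal sample per
#'   animal, drawn from the common weaning distribution with no diet
#'   effect (default FALSE).
#' @param seed integer seed; identical designs generate identical cohorts.
#' @return A \linkS4class{CohortDesign}.
#' @export
cohortDesign <- function(nPerDiet = 5L, diets = DIET_LEVELS_DEFAULT,
                         nOtus = 100L, nBrainFeatures = 40L,
                         nSignalOtus = 9L, otuEffectSize = 2,
                         nLinkedPairs = 5L, linkStrength = 1,
                         noiseSd = 1, pairedSampling = FALSE, seed = 1L) {
    for (nm in c("nPerDiet", "nOtus", "nBrainFeatures", "nSignalOtus",
                 "nLinkedPairs", "seed")) {
        v <- get(nm)
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v))
            stop("invalid design field '", nm, "': must be a single integer")
    }
    new("CohortDesign",
        nPerDiet = as.integer(nPerDiet), diets = as.character(diets),
        nOtus = as.integer(nOtus),
        nBrainFeatures = as.integer(nBrainFeatures),
        nSignalOtus = as.integer(nSignalOtus),
        otuEffectSize = as.numeric(otuEffectSize),
        nLinkedPairs = as.integer(nLinkedPairs),
        linkStrength = as.numeric(linkStrength),
        noiseSd = as.numeric(noiseSd),
        pairedSampling = isTRUE(pairedSampling),
        seed = as.integer(seed))
}

# Within-diet sd of log2 intensities; the unit in which otuEffectSize is
# expressed.
.SIGMA_W <- 1

#' Generate a synthetic gut-brain cohort
#'
#' Draws per-OTU log-normal intensities (log2 scale) whose means shift by
#' \code{otuEffectSize} within-diet standard deviations in the diet
#' assigned to each signal OTU, closes each sample to the simplex, and
#' builds brain features as diet-independent baselines plus
#' \code{linkStrength} times the standardized log2 relative abundance of
#' each linked OTU plus Gaussian noise.  Returns the tables together with
#' the planted ground truth for parameter-recovery testing.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @return A list with elements \code{otu} (\linkS4class{OtuTable},
#'   relative scale), \code{brain} (\linkS4class{BrainFeatureTable}, raw
#'   scale), \code{diet} (named factor), and \code{truth} (list:
#'   \code{signal_otu_ids}, \code{signal_otu_diet}, \code{linked_pairs}
#'   data.frame, \code{per_diet_log2_means} matrix).
#' @examples
#' cohort <- generateCohort(cohortDesign(seed = 7))
#' dim(otuMatrix(cohort$otu))   # 20 x 100
#' @export
generateCohort <- function(design) {
    stopifnot(is(design, "CohortDesign"))
    validObject(design)
    diets <- design@diets
    nd <- length(diets)
    n <- design@nPerDiet * nd
    animalIds <- paste0(rep(diets, each = design@nPerDiet),
                        rep(seq_len(design@nPerDiet), times = nd))
    dietOfAnimal <- rep(diets, each = design@nPerDiet)

    otuIds <- sprintf("OTU%03d", seq_len(design@nOtus))
    sig <- seq_len(design@nSignalOtus)

    # per-OTU baseline log2 means: bulk community N(0, 2); signal OTUs are
    # rare at baseline so their diet-driven bloom barely moves the total
    set.seed(.subSeed(design@seed, 11L))
    baseMu <- stats::rnorm(design@nOtus, mean = 0, sd = 2)
    if (design@nSignalOtus > 0L)
        baseMu[sig] <- stats::rnorm(design@nSignalOtus, mean = -3, sd = 0.5)

    # per-diet mean matrix on log2 scale (diets x OTUs)
    mu <- matrix(rep(baseMu, each = nd), nrow = nd,
                 dimnames = list(diets, otuIds))
    sigDiet <- character(0)
    if (design@nSignalOtus > 0L) {
        sigDiet <- diets[((sig - 1L) %% nd) + 1L]  # round-robin assignment
        for (i in sig)
            mu[sigDiet[i], i] <- mu[sigDiet[i], i] +
                design@otuEffectSize * .SIGMA_W
    }

    drawSamples <- function(ids, dietMeans, seedOffset) {
        set.seed(.subSeed(design@seed, seedOffset))
        logI <- dietMeans + matrix(stats::rnorm(length(ids) * design@nOtus,
                                                sd = .SIGMA_W),
                                   nrow = length(ids))
        inten <- 2^logI
        rel <- inten / rowSums(inten)
        dimnames(rel) <- list(ids, otuIds)
        rel
    }

    postIds <- animalIds
    relPost <- drawSamples(postIds, mu[dietOfAnimal, , drop = FALSE], 23L)

    if (design@pairedSampling) {
        preIds <- paste0(animalIds, ".pre")
        relPre <- drawSamples(preIds,
                              matrix(rep(baseMu, each = n), nrow = n), 29L)
        rel <- rbind(relPost, relPre)
        sampleIdsAll <- c(postIds, preIds)
        dietAll <- c(dietOfAnimal, dietOfAnimal)
    } else {
        rel <- relPost
        sampleIdsAll <- postIds
        dietAll <- dietOfAnimal
    }
    diet <- DietLabels(stats::setNames(dietAll, sampleIdsAll),
                       levels = diets)

    # brain features: ROIs x metrics grid
    nroi <- ceiling(design@nBrainFeatures / length(DTI_METRICS))
    grid <- expand.grid(metric = DTI_METRICS,
                        roi = sprintf("ROI%02d", seq_len(nroi)),
                        stringsAsFactors = FALSE)
    grid <- grid[seq_len(design@nBrainFeatures), ]
    brainIds <- paste0(grid$roi, "_", grid$metric)

    # planted links: pair signal OTUs with brain features round-robin
    linked <- data.frame(otu_id = character(0), brain_feature_id = character(0),
                         link_strength = numeric(0))
    if (design@nLinkedPairs > 0L) {
        lo <- otuIds[((seq_len(design@nLinkedPairs) - 1L) %%
                      max(design@nSignalOtus, 1L)) + 1L]
        lb <- brainIds[((seq_len(design@nLinkedPairs) - 1L) %%
                        design@nBrainFeatures) + 1L]
        linked <- data.frame(otu_id = lo, brain_feature_id = lb,
                             link_strength = design@linkStrength,
                             stringsAsFactors = FALSE)
    }

    set.seed(.subSeed(design@seed, 37L))
    nAll <- length(sampleIdsAll)
    baselineFeat <- stats::rnorm(design@nBrainFeatures, 0, 1)
    brain <- matrix(rep(baselineFeat, each = nAll), nrow = nAll,
                    dimnames = list(sampleIdsAll, brainIds))
    logRel <- log2(rel)
    for (k in seq_len(nrow(linked))) {
        z <- as.numeric(scale(logRel[, linked$otu_id[k]]))
        brain[, linked$brain_feature_id[k]] <-
            brain[, linked$brain_feature_id[k]] +
            design@linkStrength * z
    }
    brain <- brain + matrix(stats::rnorm(nAll * design@nBrainFeatures,
                                         sd = design@noiseSd),
                            nrow = nAll)

    list(otu = OtuTable(t(rel), scale = "relative"),
         brain = BrainFeatureTable(t(brain), scale = "raw",
                                   roi = grid$roi, metric = grid$metric),
         diet = diet,
         truth = list(signal_otu_ids = otuIds[sig],
                      signal_otu_diet = stats::setNames(sigDiet, otuIds[sig]),
                      linked_pairs = linked,
                      per_diet_log2_means = mu))
}

.fmtNum <- function(x) sprintf("%.15g", x)

#' Write a cohort to disk
#'
#' Emits \code{otu.tsv} (wide TSV: \code{sample_id} then one column per
#' OTU), \code{brain.csv} (long CSV: \code{sample_id, roi, metric, value}),
#' \code{labels.csv} (\code{sample_id, diet}), \code{ground_truth.json},
#' and, when the OTU table carries taxonomy, \code{taxonomy.tsv}.  Numbers
#' are written with 15 significant digits so the files round-trip through
#' [readCohort()] losslessly well past 12 significant digits.
#'
#' @param cohort list as returned by [generateCohort()]; \code{truth} may
#'   be absent.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
writeCohort <- function(cohort, dir) {
    otu <- cohort$otu; brain <- cohort$brain; diet <- cohort$diet
    stopifnot(is(otu, "OtuTable"), is(brain, "BrainFeatureTable"))
    if (length(sampleIds(otu)) == 0L)
        stop("refusing to write an empty cohort (no samples)")
    if (!setequal(sampleIds(otu), sampleIds(brain)) ||
        !setequal(sampleIds(otu), names(diet)))
        stop("tables disagree on sample identifiers; align the cohort first")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

    paths <- c(otu = file.path(dir, "otu.tsv"),
               brain = file.path(dir, "brain.csv"),
               labels = file.path(dir, "labels.csv"))

    m <- otuMatrix(otu)
    header <- paste(c("sample_id", colnames(m)), collapse = "\t")
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
        character(1))
    writeLines(c(header, rows), paths[["otu"]])

    b <- brainMatrix(brain)
    rd <- rowData(brain)
    long <- data.frame(
        sample_id = rep(rownames(b), times = ncol(b)),
        roi = rep(rd$roi, each = nrow(b)),
        metric = rep(rd$metric, each = nrow(b)),
        value = .fmtNum(as.vector(b)),
        stringsAsFactors = FALSE)
    utils::write.csv(long, paths[["brain"]], row.names = FALSE, quote = FALSE)

    utils::write.csv(data.frame(sample_id = names(diet),
                                diet = as.character(diet)),
                     paths[["labels"]], row.names = FALSE, quote = FALSE)

    tax <- rowData(otu)$taxonomy
    if (!is.null(tax)) {
        if (any(grepl("[\t\n]", tax)))
            stop("taxonomy strings must not contain tabs or newlines ",
                 "(TSV dialect)")
        paths <- c(paths, taxonomy = file.path(dir, "taxonomy.tsv"))
        writeLines(c("otu_id\ttaxonomy",
                     paste(featureIds(otu), tax, sep = "\t")),
                   paths[["taxonomy"]])
    }
    if (!is.null(cohort$truth)) {
        paths <- c(paths, truth = file.path(dir, "ground_truth.json"))
        tr <- cohort$truth
        tr$per_diet_log2_means <- NULL  # matrices stay in-memory artifacts
        jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE,
                             digits = NA)
    }
    invisible(paths)
}
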