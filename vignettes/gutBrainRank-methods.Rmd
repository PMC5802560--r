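---
title: "Methods: rank-product association of gut OTUs with brain DTI features"
author: "gutBrainRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-product association of gut OTUs with brain DTI features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutBrainRank)
```

## The model and its assumptions

The package links two feature tables measured on the same subjects — an
OTU relative-abundance table from 16S sequencing and a table of per-ROI
means of the diffusion-tensor indices fa, rd, ad and tr — through a diet
intervention with four classes of five animals each. Three assumptions
underpin the pipeline:

* diet shifts the abundance of some OTUs (on the log2 scale of relative
  abundance);
* diet shifts some diffusion-tensor features;
* a subset of OTUs carry information about specific brain features over
  and above the shared diet effect, detectable by regressing the brain
  feature on all OTUs.

All three signals are quantified the same way: out-of-bag (OOB)
permutation importance from random forests — MeanDecreaseAccuracy for the
two diet classifiers, %IncMSE for the per-feature regressions. Permutation
importance is used rather than impurity importance because impurity-based
rankings are biased toward high-cardinality features and would change the
rank lists that everything downstream consumes.

### The rank-product score

Each importance list over $N$ features is converted to scores
$\{1/N, \dots, 1\}$: the ascending rank of the feature's importance
divided by $N$, so the most important feature scores 1 and the least
$1/N$; ties take the average of their rank positions, which preserves the
score sum $(N+1)/2$. For OTU $i$ and brain feature $j$,

$$S_{combined}(i,j) \;=\; \underbrace{\frac{\mathrm{Rank}\,
\mathrm{MDA}(Diet \mid OTU_i)}{N_{OTU}}}_{S(OTU_i)} \cdot
\underbrace{\frac{\mathrm{Rank}\,\mathrm{MDA}(Diet \mid
BrainM_j)}{N_{BrainM}}}_{S(BrainM_j)} \cdot
\underbrace{\frac{\mathrm{Rank}\,\%\mathrm{IncMSE}(BrainM_j \mid
OTU_i)}{N_{OTU}}}_{S(OTU_i,BrainM_j)}$$

$S_{combined} \in (0,1]$, equals 1 exactly for a pair top-ranked in all
three lists, and is monotone in each component. The third score is ranked
*within* each brain feature's regression (its denominator is $N_{OTU}$),
not jointly across regressions — the only reading consistent with that
denominator. Negative importances, common for noise features, are ranked
as-is: only order matters, and clipping would manufacture massive ties.

Pairs are ordered by $S_{combined}$ with ties broken by (otu\_id,
brain\_feature\_id); the top 27 feed three downstream diet classifiers
(OTU columns, brain columns, both), forward selection adds pairs until a
target LOOCV accuracy (default 100%) is reached, and links are called at
a combined-score threshold, default 0.84. The threshold is interpreted as
a cutoff on $S_{combined}$ — it is applied after the $S_{combined}$
ordering and lies inside that score's range — and is configurable.

## Two accuracy figures, deliberately

`selectThenLoocv()` reproduces the headline procedure: features are
ranked on *all* samples, the top $k$ (default 9) kept, and LOOCV run on
the reduced matrix. Because selection saw every sample, this figure is
optimistically biased. `nestedCv()` is the honest counterpart: 3 × 5-fold
cross-validation stratified by diet with the whole selection process
repeated inside every training split. Both are first-class outputs and
both are exercised by the tests; on moderate-signal synthetic cohorts the
nested estimate is, on average, no larger than the optimistic one — the
direction the two published-style figures differ in. The nested report's
95% interval is $1.96\,s$ with $s$ the sample sd of the 15 fold
accuracies; "± a few percent on 15 fold accuracies" reads most naturally
as the sample-sd interval, and the $1.96\,s/\sqrt{n}$ variant is exposed
via `seMode = TRUE` for the other reading.

Chance level for the balanced four-class design is 25%, the reference
point for all null simulations.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 1e-6 | added before log2; order of the smallest detectable relative abundance at typical 16S depth; 0 is allowed only for zero-free tables |
| `ntree` (classification) | 16000 in `runPipeline` | trees for the diet forests; simulations use 150–500, which already stabilises rankings at $n=20$ |
| `ntree` (regression) | 4000 in `runPipeline` | trees per brain-feature regression |
| `mtry` | `sqrt_p` / `p_over_3` | randomForest's classification / regression defaults, not overridden |
| `importanceScaled` | FALSE | raw mean decrease; the scaled (SE-normalised) variant is a sensitivity flag |
| `k` (top features) | 9 | features kept per table for diet prediction |
| `pairsK` | 27 | pairs retained for the downstream models |
| `threshold` | 0.84 | combined-score cutoff for called links |
| `folds`, `repeats` | 5, 3 | nested-CV layout; exact stratification for the 4 × 5 design |

## The synthetic generator

`generateCohort(cohortDesign(...))` emulates the target study design: 20
animals, four diets × five, one post-diet fecal sample each (optionally a
paired pre-diet baseline drawn from the common weaning distribution with
no diet effect). Per-OTU intensities are log-normal on the log2 scale
with within-diet sd 1; signal OTUs get a $+\mathrm{effect}\times sd$ mean
shift in their assigned diet (round-robin over diets) and are then closed
to the simplex with all other OTUs.

Two generator choices deserve explanation:

* **Signal OTUs are rare taxa.** Their baseline log2 mean is drawn from
  N(−3, 0.5) against a N(0, 2) bulk, so a diet-driven bloom barely moves
  the per-sample total and compositional closure leaves the planted log2
  contrast essentially intact (measured calibration bias < 1% at the
  default effect size 2; the test suite requires < 10% averaged over 200
  seeds).
* **Brain features have diet-independent baselines.** Diet reaches a
  brain feature only through its linked, diet-shifted OTUs
  ($\mathrm{linkStrength}\times$ standardized OTU log2 abundance plus
  N(0, noiseSd) residual). This keeps zero-effect designs genuinely null
  for both tables — a property the null-cohort tests rely on — while
  linked features still inherit a diet signal, as white matter would
  under a microbially mediated effect.

The generator does **not** emulate sequencing-depth noise (it produces
relative abundances directly, not counts), taxonomic correlation
structure, cage/litter/coprophagy effects, nonlinear or interaction
OTU–brain effects, or spatial correlation among ROIs. Passing
recovery tests therefore show the pipeline detects linear-Gaussian links
planted in compositional data at the study's sample size — not that real
diets behave this way.

The abundance model is log-normal-plus-closure rather than
Dirichlet-multinomial because the analysis consumes relative abundances
directly and depth noise is out of scope; brain linkage is linear-Gaussian
because that is the weakest structure the regression forests should
detect and keeps recovery tests interpretable.

## Numerical and determinism choices

* One user seed drives everything; sub-streams (per table, per LOOCV
  fold, per regression, per CV repeat) are derived arithmetically so
  callers never manage seed bookkeeping, and identical designs produce
  byte-identical files (numbers serialised at 15 significant digits).
* z-scaling uses the sample sd ($n-1$); constant brain features map to
  all-zero columns with a warning rather than an error — zero variance is
  uninformative, not malformed.
* Sample alignment sorts lexicographically by sample id; rank ties break
  stably by feature identifier; heat-map clustering (euclidean distance,
  average linkage by default — the conventions of the standard heat-map
  tooling) first sorts labels so leaf orders are independent of input
  order.
* Scale flags on the containers gate the transforms: double log2 or
  double z-scaling is an error, never silent.

## Problem sizes used by the test suite

Simulation-backed tests run at reduced forest sizes, chosen once as the
smallest that stabilise the tested statistic at $n = 20$: ntree 150–500
for classification, 150 for the per-feature regressions; 200 seeds for
generator calibration, 100 for the generator null, 25 for planted-pair
recovery (16 brain features, 3 planted links, effect 4, link strength
3 × noiseSd), 10 each for the null nested-CV and leakage-direction
checks. The whole suite completes in about a minute on one CPU.

## Known limitations

* With 20 samples, permutation importances are noisy; rank lists (and
  hence $S_{combined}$) are stable only for clearly separated features.
* The 0.84 threshold is an operating point, not a calibrated error rate;
  no null distribution of $S_{combined}$ is derived.
* The three-component score treats the rank lists as independent
  evidence; strongly correlated OTUs share rank mass and can displace
  each other from the top set.
* LOOCV after whole-data selection is reproduced on purpose as the
  optimistic headline procedure; any claim about generalisation should
  cite the nested figure instead.
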