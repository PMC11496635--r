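---
title: "FDR-controlled metabolite annotation for imaging MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDR-controlled metabolite annotation for imaging MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiannot)
```

## The annotation problem

Imaging mass spectrometry records a centroided spectrum — discrete
(m/z, intensity) peaks — at every pixel of a tissue section or other sample.
Annotating a dataset means deciding which molecular formulas from a database,
combined with plausible ionization adducts (+H, +Na, +K in positive mode),
are genuinely present. Because a molecular formula plus adduct predicts a
full isotope pattern and a spatially coherent set of ion images, presence can
be scored; because most database ions are absent, the decision must control
the false discovery rate (FDR).

`msiannot` implements a target-decoy annotation engine: every target ion
(formula x plausible adduct) competes against decoy ions formed from the same
formula and chemically implausible single-element adducts (+Sc, +W, ...). A
gradient-boosted pairwise ranking model scores ions from five features, a
single weighted target-decoy ranking converts scores to a continuous FDR, and
an F-beta-based reliability score selects the most trustworthy default FDR
threshold per dataset.

## The five ion features

For a candidate ion, the engine extracts the ion image of each of its first
`T = 4` theoretical isotopic peaks (every centroid within a closed +-3 ppm
window contributes; per-pixel intensities are summed, and the matched m/z per
pixel is the intensity-weighted mean of the matched centroids).

* **rho_spectral** — agreement between theoretical relative isotope
  intensities and the observed per-isotope total intensities: one minus half
  the L1 distance of the two L1-normalized vectors (total-variation
  agreement, in [0, 1]).
* **rho_spatial** — coherence of the isotope images: the mean over isotopes
  i >= 2 of the positive part of the Pearson correlation between image i and
  the principal image, weighted by theoretical relative intensity. Negative
  correlations are clipped to zero; missing isotopes contribute zero.
* **rho_chaos** — spatial informativeness of the principal image: the image
  is thresholded at 30 quantile-spaced levels of its nonzero intensities,
  and the score is one minus the mean ratio of 4-connected components to
  above-threshold pixels. Structured signal (few large patches) scores near
  1; salt-and-pepper noise scores near 0.
* **mz_error_abs** — `1 - |mean observed m/z - theoretical m/z|` of the
  principal isotope, with the observed mean intensity-weighted across
  pixels.
* **mz_error_rel** — one minus the absolute theoretical-intensity-weighted
  mean, over observed isotopes i >= 2, of the deviation of isotope i's m/z
  error from the principal isotope's m/z error. A mass-axis shift common to
  all isotopes cancels; inconsistent errors (typical of decoys matching
  noise) do not.

The three rho features are the constituents of the rule-based predecessor
score, Metabolite Signal Matching (`msm_score`), their equal-weight product.
Their exact formulas are not uniquely fixed in the literature; the
definitions above are this package's normative versions, isolated behind
single functions so alternates can be swapped.

Two unit conventions were genuinely open. The m/z-error features are
computed literally in m/z (Da) units by default; `mz_error_in_ppm = TRUE`
converts deviations to ppm first. Tree-based rankers are invariant to
monotone feature rescalings, so the choice does not affect rankings — only
the feature values reported. Missing-isotope policy: if the principal
isotope is never observed both error scores are 0 (absence of evidence must
not look like perfect mass accuracy); missing higher isotopes are excluded
from the weighted sums; if all higher isotopes are missing, `mz_error_rel`
is 0.

## Isotope patterns and decoy ions

Theoretical patterns are computed by element-wise convolution of natural
isotope abundances, aggregated into nominal-mass-shift bins, sorted by m/z,
truncated to the first `T` peaks and normalized to the most intense kept
peak (optional resolving-power merging is available). The electron mass is
included in m/z; charges are restricted to +-1. The bundled element table
carries full isotope distributions for the biochemically common elements;
exotic elements appearing only as decoy adducts carry their principal
isotope — a decoy ion's envelope is dominated by its molecule's own
C/H/N/O/S composition, so this simplification does not affect scoring
behaviour.

Decoy adducts are drawn without replacement from a configurable universe of
~70 implausible single-element adducts (`default_decoy_adducts()`, mirrored
as a text file in `extdata`; no canonical published list exists, so the
shipped universe is user-overridable via `read_adduct_list()`). The draw for
a formula is a function of (formula, master seed, universe) only — a named
RNG substream per formula — so the same decoy set is shared across all
target adducts of that formula and is stable when the corpus grows.

## FDR estimation

For one database and target adduct, targets and all sampled decoy ions are
merged into a single ranking by descending score (ties conservatively place
decoys first). With `T_i` targets and `D_i` decoys at or above rank `i` and
`S_D` decoy samplings per formula (default 20), the FDR at rank `i` is

    FDR_i = ((D_i + 1) / S_D) / ((T_i + 1) + (D_i + 1) / S_D)

— decoys weighted `1/S_D`, with a rule-of-succession pseudocount added to
both counts so the FDR is never exactly 0 (the minimum achievable value with
a clean top target at `S_D = 20` is 0.0244). The raw sequence is made
non-decreasing down the ranking by a reverse cumulative minimum (the
standard q-value-style monotonicity adjustment; the adjustment is named but
not specified in the source literature, and the reverse cummin is the
conventional choice). Annotations at threshold q are the target ions with
adjusted FDR <= q; decoys below the threshold are reported separately as
estimated false positives.

A known small-sample property, verified in the calibration tests: on very
short rankings (tens of formulas) the reverse-cummin adjustment's selection
effect can push the realized false discovery proportion at q = 0.2 slightly
above q. At realistic database sizes (hundreds of formulas) the estimator
is calibrated at 5, 10 and 20% within three binomial standard errors.

## The ranking model

A gradient-boosted decision-tree ensemble is trained with a pairwise
logistic ranking loss: within each training dataset, every (target, decoy)
pair is an ordered pair with the target as winner; no cross-dataset pairs
are formed. The backend is xgboost's `rank:pairwise` objective,
single-threaded and deterministic under a fixed seed; the contract is
backend-agnostic (gradient-boosted trees, pairwise logistic loss, >= the
requested iterations, deterministic under seed) and the default is 1000
iterations (tests and the bundled analyses use fewer on small corpora, where
the loss plateaus long before). Raw ensemble output is min-max scaled to
[0, 1] using bounds recorded over the training corpus's raw predictions —
a backend-independent proxy for leaf-value extremes, declared as such —
and out-of-bound predictions clip. The scaling is strictly monotone, so
rankings and hence FDR values are identical under raw and scaled scores.

Cross-validation is k-fold (default 5) over datasets, stratified by context
so each context keeps its relative size across folds; contexts with fewer
than k datasets go wholly to training with a warning. Ranking quality is
summarized by average precision (AP) per held-out dataset — the mean of
precision@k over target positions — and MAP, their unweighted mean.

Per-feature attribution uses TreeSHAP contributions; each ion's share per
feature is the absolute contribution normalized by the sum of absolute
contributions, and per-dataset aggregation is the median share.

## Reliability score and threshold selection

Treating targets as positives and decoys as negatives, the F-beta score
(beta = 0.5, weighting precision over recall, reflecting the 20:1
decoy-to-target imbalance) is computed at every observed adjusted-FDR cutoff.
Decoys are counted unweighted in the confusion matrix by default (a
`decoy_weighting` switch applies `1/S_D` weighting as a documented
alternative). For each default threshold (5, 10, 20, 50%), the reliability
score is the F-beta at the nearest observed cutoff relative to the curve
maximum, multiplied by the complement of the cutoff attaining that maximum;
argmin/argmax ties resolve toward smaller cutoffs. The selected optimal
threshold is the smallest among those attaining the maximum reliability
score. Candidate cutoffs are the observed adjusted-FDR values, not a fixed
grid.

## Quality control

Mistakenly submitted profile-mode data defeats target-decoy annotation
(decoy isotopes match peak shoulders). The overlap score measures, over the
50 pixels with the most nonzero peaks, the fraction of consecutive m/z gaps
inside the 3 ppm matching tolerance; datasets scoring above 0.5 are flagged.
The printed form of this score in the source literature compares an absolute
Da gap against a dimensionless ppm fraction and counts wide gaps — which
contradicts both the score's name and the exclusion direction — so the
package implements the evident intent (relative gap <= m * tol/1e6 counts as
overlap) by default and retains the literal variant behind `literal = TRUE`
for auditability.

A dataset is excluded when all (adduct, database) combinations yield fewer
than 10 annotations at FDR 20% (any adequate combination rescues it), when
the median per-pixel nonzero peak count exceeds 50,000, or when the overlap
score exceeds 0.5.

## Context classification and corpus selection

A dataset's context is the combination of polarity, ionization source, mass
analyzer, m/z class (max m/z <= 400: small molecules; min > 500: lipids;
otherwise both), sample type, and species, with species whose cumulative
frequency falls in the bottom 10% (inclusive at the boundary) grouped as
OTHER. Contexts are eligible for corpus selection with at least 45 datasets.
Selection within a context first takes one dataset from every
(project, group) combination — datasets without a project get a
(submitter, submission day) pseudo-label — then fills remaining slots from
combinations ranked lexicographically by (Shannon entropy of the
combination's submission-day composition, descending; relative size,
descending), drawing seeded random datasets from the top-ranked combinations
in turn. The entropy input is under-specified in the source literature; the
submission-day composition is this package's normative choice, as a proxy
for replicate heterogeneity (same-day submissions are likely replicates).
Test datasets are drawn first and removed from the pool before training
datasets, so the two are mutually exclusive. Alphabetical tie-breaks are
used wherever frequencies tie, for determinism.

## The synthetic-data generator

`generate_dataset()` emulates what the pipeline needs from real data and
nothing more: planted ions with `T = 4` isotopic peaks at theoretical m/z
jittered by Gaussian ppm noise (sd 0.5 ppm, well inside the 3 ppm window of
Orbitrap/FTICR acquisitions), per-ion smooth random blob intensity templates
(so rho_chaos is high for planted ions and low for scattered noise matches),
multiplicative log-normal per-pixel intensity noise (sd 0.1), uniform-random
noise peaks (30 per pixel by default, so decoys occasionally match noise —
required for non-degenerate FDR curves), a detector limit of detection at
0.3x the mean noise intensity (tying planted-ion detectability to the
signal-to-noise ratio, default 20, and producing realistic missing higher
isotopes; zero when generating noise-free data), and optional profile-mode
shoulders (each peak expanded into satellites spaced 0.8 ppm apart with
geometrically decaying intensity — sub-tolerance, so the QC overlap score
saturates). Defaults use a 32 x 32 grid and 15 of the 30 toy-database
molecules as +H ions. `generate_feature_corpus()` additionally draws
feature tables directly with a planted informativeness profile, isolating
the ranking model from the image simulation for controlled
importance-recovery experiments.

What the generator does **not** emulate: instrument-specific peak shapes and
mass-resolution decay, chemical noise with structured m/z distributions
(matrix clusters), correlated molecular co-localization, or real tissue
morphology. Passing tests therefore demonstrate the correctness and internal
calibration of the pipeline, not field performance on real acquisitions.

## Numerical choices and degenerate inputs

* ppm windows are closed, symmetric and relative; coincident centroids are
  merged on construction.
* Score ties in rankings break decoy-before-target, never understating FDR.
* Pearson correlations on constant images are undefined and contribute 0.
* `fbeta(0, 0) = 0` by convention; degenerate min-max bounds (max == min)
  predict 0.5 with a warning; all-zero SHAP rows get uniform shares with a
  flag.
* All randomness flows from one master seed through named substreams
  (`derive_seed`), so decoy sets, simulations, and fold assignments are
  reproducible independently of evaluation order; the whole
  simulate-qc-annotate-train-evaluate pipeline is byte-identical across
  reruns with the same master seed.
* Test-suite and bundled-script problem sizes (grids of 8x8 to 32x32, 10-30
  molecules, S_D of 5-20, corpora of 4-20 datasets, 20-200 boosting
  iterations) are chosen so planted effects are comfortably detectable while
  each analysis stays in the seconds-to-minutes range.

## Known limitations

* The shipped decoy universe is a reasonable stand-in, not a canonical list.
* Principal-isotope-only data for exotic decoy elements slightly idealizes
  decoy isotope envelopes.
* The rho formulas are normative reconstructions of the rule-based
  predecessor's scores, not bit-for-bit reimplementations.
* Continuous FDR values on very short rankings inherit the q-value
  selection bias described above.
* Headline corpus-scale results from the motivating study (median MAP gains
  on 1710 public datasets, LC-MS/MS validation rates) require those corpora
  and are out of scope; the package's own evaluation metrics reproduce the
  analysis machinery on synthetic data.

## A worked example

```{r example}
db <- toy_molecule_db()
cfg <- simulation_config(grid_shape = c(16, 16), n_planted_molecules = 8,
                         seed = 42)
sim <- generate_dataset(cfg)
apply_quality_filters(sim$dataset)

ann <- annotate_dataset(sim$dataset, db, s_d = 10, seed = 42)
count_annotations(ann, threshold = 0.10)
reliability_result(ann$rankings[["+H"]], s_d = 10)
```
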