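---
title: "Models and methods behind textrecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind textrecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(textrecal)
```

## The scientific problem

Text-based phonetic recalibration pairs a written syllable ('aba' or
'ada') with an ambiguous speech sound /a?a/ that sits midway on an
/aba/--/ada/ continuum. After a short audiovisual exposure block, the
listener's category boundary shifts toward the text: subsequent
auditory-only presentations of the same ambiguous sound are more often
categorized in agreement with the previously shown text. Pairing text with
*clear* sounds instead produces the opposite, repulsive shift (selective
adaptation). The neural counterpart of the perceptual shift is subtle: the
stimulus is acoustically identical across percepts, so the signature must
be read out from distributed multivoxel activity patterns rather than
regional mean amplitudes.

`textrecal` implements the complete analysis chain for such experiments —
behavioral psychometrics, single-trial hemodynamic response estimation,
multivoxel percept decoding, and task-dependent connectivity — together
with generators that synthesize behavioral and BOLD data with exactly the
structure those analyses assume. Because no public dataset accompanies the
paradigm, every quantitative guarantee of the package is *property-based*:
estimators are validated by closure against the generators (what is
planted is recovered), by calibration (chance and false-positive levels
are where theory puts them), and by power (stronger planted effects yield
stronger read-outs).

## Session designs

`build_fmri_design()` lays out 12 'aba' and 12 'ada' recalibration
exposure blocks over 3 runs (4 + 4 per run, seeded random order). A block
holds 8 audiovisual trials spaced one TR (2 s) apart, followed by 6
auditory post-test trials — the three middle continuum tokens, each twice,
in random order — presented slow event-related with inter-trial intervals
drawn uniformly from {6, 7, 8} TR (mean 14 s). The same jitter separates
the last exposure trial from the first post-test, and the post-tests from
the next block, so exposure and post-test responses are separable in the
design matrix and genuine baseline periods exist. All onsets lie on the TR
grid. Totals: 72 post-tests per exposure text.

`build_psychophysical_design()` adds the adaptation condition (text +
matching clear sound, represented as block labels — no audio is modelled)
with 8 blocks per condition and text, i.e. 16 blocks and 96 post-tests per
condition, and continuous 4--6 s jitter (mean 5 s). The field note that the
session has "16 blocks per condition" is parameterized as
`n_blocks_per_text` per condition-text pair (default 8), which keeps the
count arithmetic consistent for reduced designs.

## Behavioral model

Responses are binary (/aba/ = 1, /ada/ = 0) and modelled with a logistic
mixed model on difference-coded covariates:
Condition `C` (+0.5 recalibration, −0.5 adaptation), Exposure `E`
(+0.5 'aba' text, −0.5 'ada'), Sound `S` (+1, 0, −1 for the three
continuum tokens, positive at the /b/-like end, i.e. `S = −token`).
The psychophysical analysis model is

```
response ~ C * E * S + (1 | subject) + (0 + C | subject) + (0 + C:E | subject)
```

and the scanner model `response ~ E * S` with diagonal random intercept,
`E` and `S` terms. The `||`-style diagonal random structure is fitted by
giving each term its own variance component. `fit_logistic_glmm()`
maximizes the Laplace-approximated marginal likelihood (`lme4::glmer`);
adaptive quadrature is unnecessary here because the recovery tests only
require standard Laplace accuracy for three uncorrelated scalar random
terms. Wald z and two-sided normal-reference p values are reported, the
convention implied by a z/p summary table. With `random = character(0)`
the fit reduces to `stats::glm`, and the package asserts exact agreement
in that limit. A diverging estimate with an exploding standard error is
reported as a separation diagnostic rather than returned silently.

The generator `simulate_behavior()` draws each post-test response from
`Bernoulli(plogis(eta))` with `eta` the fixed-effect predictor plus
per-subject normal random terms. Generating fixed effects default to the
reference estimates bundled in `reference_fixed_effects()`; the
random-effect SDs are not printed in any reference table, so the package
fixes them at 0.5 on all generated terms — a moderate heterogeneity that
a psychophysicist would call realistic for logit-scale subject slopes —
and exposes them as parameters. Recovery at the study's sample sizes
(27 or 15 subjects × 192 trials; 15 × 144 for the scanner session) is
unbiased to within a few percent; the acceptance checks require mean
recovered effects within 15% over 50 simulate-and-refit replicates.

## BOLD simulation on a cortical-sheet surrogate

The real cortical surface is replaced by a regular 2-D lattice
(`make_roi_geometry()`, default spacing 2 mm, matching the acquisition
voxel size) so that millimetre-scale operations — 5 mm weight-map
smoothing, FWHM estimation, cluster areas in mm² — are well defined and
testable. The simulator plants:

* **percept-dependent patterns**: each post-test trial adds
  `effect_amplitude × pattern_weight × (+1 | −1)` (sign by the simulated
  /aba/ vs /ada/ response) on the pattern vertices, convolved with a
  peak-normalized double-gamma kernel at the vertex's time-to-peak.
  Percept- (not token-) dependence mirrors the decoding labels, which are
  perceptual responses;
* **exposure responses** on the seed vertices (one kernel per audiovisual
  trial);
* **task-dependent coupling**: the PPI-target time course gains
  `gain × z(seed) × z(task)` with the HRF-convolved exposure indicator as
  task — the exact generative mirror of the PPI regressor, so the
  noiseless closure `recovered beta = gain` is exact;
* **AR(1) Gaussian noise** (default coefficient 0.3, marginal SD in
  percent-signal units), the simplest temporally autocorrelated model
  consistent with fMRI residuals.

Per-vertex time-to-peak values are drawn from the same 3.2--4.2 s grid the
estimator searches, which makes latency recovery exactly testable. What
the generator deliberately does not emulate: physiological noise
structure, motion, drifts beyond a constant, spatial noise correlations,
and real cortical folding — so passing tests demonstrate estimator
correctness under the stated model, not robustness to every artifact of
real data.

## Single-trial betas with time-to-peak adjustment

The first-level design matrix holds one predictor per exposure block type,
one per post-test trial, and a constant. `estimate_trial_betas()` searches
the 11-point latency grid (3.2--4.2 s, step 0.1 s — the range is standard,
the step is the package's choice): for each candidate the whole design is
refit by least squares, and per vertex the latency minimizing the residual
sum of squares is kept, along with that fit's trial betas. Only the peak
latency is adjusted; the kernel shape (peak delay 6 s, undershoot delay
16 s, unit dispersions, ratio 1/6 — canonical values, config-overridable)
is fixed. Degenerate inputs behave predictably: all-zero data give zero
betas and the first grid latency; rank deficiency is an error naming the
collinear columns.

Group inference uses a one-sample t map across subjects
(`rfx_ttest_map()`; zero-variance vertices yield a flagged sentinel
rather than ±Inf) followed by Monte Carlo cluster-size correction:
Gaussian white-noise maps are smoothed to the map's estimated FWHM
(lag-one spatial autocorrelation inverted under a Gaussian
autocorrelation model), standardized, thresholded two-sided at
`p_vertex`, and the maximal 4-neighbour cluster size recorded; the
minimum cluster size is the smallest size with null exceedance frequency
at most `p_corr`. This construction controls the family-wise error at or
just below the nominal level; the acceptance test measures ≈ 0.035--0.05
at FWHM 6 mm, `p_vertex` 0.005.

## The percept decoder

`decode_subject()` composes, per subject:

1. **balancing** — 10 datasets, each all minority-class trials plus an
   equal-count with-replacement sample of the majority (identity when
   already balanced, so no data are discarded gratuitously);
2. **4 stratified folds** per dataset (40 folds total); stratification
   guarantees both classes in every training set;
3. **z-normalization** by training statistics only (population-SD
   convention), applied to the test set; constant columns are zeroed and
   flagged;
4. **RFE** — 10 levels, 30% elimination, survivors
   `ceiling(0.7 × n)` so at least one feature always survives; 50
   pre-drawn inner splits of 90% of the training trials, consumed 5 per
   level in order; per split a linear SVM (cost 1, config-exposed — the
   reference procedure does not state it) is trained, its weight map
   smoothed (SD 5 mm) on the lattice restricted to the surviving set,
   rectified and ranked, ranks averaged over the 5 splits, ties broken by
   vertex index;
5. **evaluation** — the subject's accuracy is the fold-test accuracy at
   the final (fewest-features) level, the conventional RFE read-out that
   avoids optimistic level selection; per-level accuracies are exposed
   and `report_level = "best"` switches to the level with the highest
   inner-split accuracy (still chosen within training data).

All randomness fans out from one seed through a deterministic sub-seed
scheme per (stage, dataset, fold, permutation), so any stage can be rerun
in isolation and identical seeds give identical results. The permutation
null repeats the identical pipeline 200 times with training labels
shuffled within each training set (test labels intact); group
significance compares subject accuracies with their permutation means by
a two-sided Wilcoxon signed-rank test, exact for n ≤ 25 without ties.
Consistency maps count, per vertex, the subjects whose top 20% most
discriminative vertices (by mean elimination level, ties by vertex index)
include it.

## PPI connectivity

The PPI design appends to the first-level model a z-scored seed
time-course predictor (spatial mean over the seed vertices) and the
interaction `z(seed) ⊙ z(task)`, with the task regressor the
HRF-convolved exposure indicator. Convolution precedes z-scoring by
default; the reverse order is config-exposed since the reference
procedure leaves it unstated, and deconvolution-based PPI is explicitly
out of scope. The exposure main-effect and seed main-effect columns are
retained so the interaction explains only variance beyond the
exposure-evoked responses — a regression test shows that dropping the
seed main effect biases the interaction beta on correlated data.
Per-subject interaction betas feed the same RFX + cluster-correction
machinery as the univariate maps.

## Numerical choices and test scale

* Separable truncated Gaussian convolution (4 SD support) for all
  smoothing; masked smoothing renormalizes by the smoothed mask indicator
  so borders are neither diluted nor leaky. In 2-D the mass within radius
  2σ of a smoothed delta is 1 − e^{−2} ≈ 0.865 (the familiar 95% figure
  is the 1-D interval), and the tests assert that law.
* Ceiling in the survivor recursion; from 1000 features the chain is
  700, 490, 343, 241, 169, 119, 84, 59, 42, 30.
* Exact signed-rank reference: 15 uniformly positive differences give
  two-sided p = 2/2^15 ≈ 6.10 × 10⁻⁵.
* Test problem sizes are the package's own choices for a desk-scale
  validation: closure and decoding tests use a 12 × 12 lattice with a
  100-vertex ROI and 3 blocks per text; the chance/permutation
  calibration uses a reduced pipeline (2 datasets × 2 folds × 2 RFE
  levels) with the full 200 permutations; cluster-correction calibration
  uses 1000 Monte Carlo iterations and 200 null replicates on a 24 × 24
  grid; recovery studies use the full designs at 27 and 15 subjects with
  50 replicates.

## Known limitations

* The lattice surrogate has no curvature, no inter-hemisphere structure
  and no anatomical ROIs; cluster areas are exact multiples of the vertex
  cell area.
* Real-data headline results of the paradigm (group decoding accuracies
  against their permutation chance level, parietal cluster anatomy)
  depend on data that are not publicly deposited and are intentionally
  not reproduction targets; the package validates the *procedures* that
  produce such results.
* Laplace approximation can attenuate very large logit effects at small
  subject counts; within the tested regimes the bias is a few percent.
* The balancing sentence of the reference procedure is grammatically
  ambiguous; the implemented reading (resample the majority down to the
  minority count, with replacement) is recorded as a design decision, not
  asserted as the original authors' intent.
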