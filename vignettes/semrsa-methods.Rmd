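---
title: "Methods: simulation-verified RSA of word semantics in two-group fMRI designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-verified RSA of word semantics in two-group fMRI designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semrsa)
```

## The scientific problem

Condition-rich word-semantics fMRI studies ask whether, and where, the brain
encodes the relational structure of word meanings, and whether that encoding
differs between subject groups — for instance between signers who acquired a
first language from birth and signers whose first-language exposure was
delayed into school age. The analysis chain is long: per-word response
patterns are estimated by a first-level GLM; their pairwise Pearson distances
form a neural representational dissimilarity matrix (RDM); the rank
correlation between the neural RDM and a behaviourally derived semantic model
RDM — partialling out low-level visual and phonological stimulus models —
quantifies semantic encoding per region; the same statistic computed inside a
sphere around every voxel yields a searchlight map; univariate abstractness
effects and individually localised functional ROIs (fROIs) complement the
multivariate results; and group comparisons run through Welch t-tests, mixed
ANOVAs, permutation cluster correction and bootstrap mediation.

None of these stages can be validated on human data alone, because the
ground truth is unobservable. `semrsa` therefore pairs every analysis stage
with a forward simulator whose generative parameters — semantic-encoding
strength and univariate abstractness effect per ROI and group — are known,
so the whole chain is checked by parameter recovery and calibration rather
than by trust.

## The generative model

`gen_word_set()` builds a stimulus set of `n_concrete + n_abstract` words
(default 40 + 50) in `k_categories` semantic categories (default 10). Each
category has a Gaussian centre in an 8-dimensional latent semantic space;
each word is its centre plus isotropic jitter (`within_sd`, default 0.2).
Two structural constraints make the categories behave like real semantic
categories:

* a **domain offset**: concrete and abstract category centres are displaced
  by ±1.25 units along the first axis (`domain_sep = 2.5`), emulating the
  superordinate object/non-object split that dominates real behavioural
  semantic spaces. Without it, a gap-statistic curve can show a spurious
  local maximum at k = 1, a pathology real semantic data do not exhibit;
* a **minimum centre separation** (`min_sep = 3`, rejection-sampled with a
  500-draw cap): the design intent is planted categories that are
  recoverable in principle, and uncontrolled Gaussian draws occasionally
  place two centres nearly on top of each other.

Behavioural distance matrices are Euclidean distances between embeddings
plus i.i.d. symmetric Gaussian noise (`behavioral_noise_sd`), rescaled to
[0, 1] with a zero diagonal. Only ranks enter the downstream statistics, so
the rescaling is immaterial (asserted by a rank-invariance test).

Neural patterns (`gen_subject_patterns()`) use a fixed, seeded linear
projection of the embedding into each ROI's voxels — fixed across subjects,
so neural RDM geometry mirrors behavioural geometry by construction — scaled
by `encoding_strength[roi, group]`, plus `abstractness_effect[roi, group]`
added to every abstract word's voxels, plus unit-variance Gaussian noise.
Voxels outside all ROIs are pure noise. BOLD time series
(`gen_bold_runs()`) follow the design-matrix forward model: per-run event
trains (90 target words, 14 catch trials and 30 null slots of 2.5 s each,
jittered by seeded sampling of the null positions, in 360 s runs at TR 2 s)
convolved with the canonical HRF, weighted by the voxel's pattern
amplitudes, plus cosine drift, motion-coupled components and noise.

What the simulator does *not* emulate: physiological noise spectra, motion
artefacts beyond nuisance-regressor columns, spatial autocorrelation of
noise, inter-subject anatomical variability, and the graded (non-categorical)
semantic structure of real abstract words. Passing recovery tests therefore
demonstrates that the analysis code is correct and well calibrated under its
stated assumptions — not that those assumptions hold for any particular real
dataset.

## First-level GLM

The design follows the SPM conventions: boxcars at a microtime resolution of
16 bins per TR, convolved with the double-gamma HRF (delays 6/16 s,
dispersions 1/1, undershoot ratio 6, 32 s kernel, unit peak), sampled at
microtime bin 8; one regressor per word spanning the concatenated runs plus
one pooled catch regressor; per-run discrete-cosine drift columns implement
the 128 s high-pass (`floor(2 * 360 / 128) = 5` cosines per 360 s run),
alongside per-run constants, six motion columns and a per-run mean-centred
global-mean predictor computed from the data at fit time. Estimation is
voxelwise OLS; no AR(1) prewhitening is applied (a deliberate
simplification — drift and high-pass handling dominate at TR 2 s, and OLS
keeps the degrees-of-freedom bookkeeping exact, `df = T - rank(X)`).
Collinear drift/nuisance columns are pruned with a warning; collinearity in
the word regressors is an error. The abstract-greater-than-concrete contrast
uses weights `+1/50` and `-1/40`, i.e. the difference of type means.

Smoothing is separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` per
axis and reflective boundaries (constants are preserved exactly and mass is
conserved); statistic maps are smoothed within the analysis mask by
renormalising with the smoothed mask.

## Behavioural semantics and categorisation

Subject RDMs are averaged elementwise; similarity between RDMs is the
Spearman correlation of the vectorised lower triangles (column-major,
row > column; 4005 values for 90 conditions; average ranks at ties).
`cluster_words()` determines the number of semantic categories by the gap
statistic with the first-SE-max rule and labels the conditions by k-means
with k-means++ seeding (50 restarts by default).

One design choice deserves emphasis. We cluster the **classical-MDS
embedding** (8 dimensions) of the RDM, not the raw RDM rows. In development
sweeps, the gap statistic computed on 90-dimensional RDM rows was unusable:
splitting a tight low-dimensional cluster keeps reducing log within-cluster
dispersion by a roughly constant decrement, while a 90-dimensional uniform
reference barely declines, so the gap curve creeps upward indefinitely and
the selected k overshoots regardless of how well separated the planted
categories are. In the MDS embedding, the reference dimensionality matches
the data's effective dimensionality and the canonical bounding-box uniform
reference behaves as intended; recovery of a planted k = 10 then succeeds in
≈ 97/100 seeds on group-averaged matrices at the generator defaults. The
categorical benchmark RDM codes same-category pairs 0 and different-category
pairs 1.

## RSA engine

Neural RDMs are one minus Pearson correlation between condition patterns
over voxels. The semantic-encoding statistic is the partial Spearman
correlation: all RDM vectors are rank-transformed (average ranks), the
target and model ranks are residualised on the covariate ranks (visual
silhouette and sub-syllabic phonological models, with intercept), and the
residuals correlated; the result is Fisher-z transformed (`atanh`) before
parametric testing. Searchlights use all in-mask voxels within a
centre-to-centre Euclidean radius (8 mm default, 257 voxels on an unbounded
2 mm grid), clipped — never padded — at mask edges; spheres with fewer than
two usable voxels give missing values. Per-subject z maps are smoothed
(6 mm FWHM) after the transform.

Group-level map inference uses voxelwise t statistics with a primary
uncorrected threshold and cluster-extent family-wise-error correction by
permutation (sign-flipping for one-sample tests, group-label shuffling for
two-sample; 26-neighbour connectivity; corrected
`p = (1 + #{perm max extent >= observed extent}) / (n_perm + 1)`).
Permutation replaces random-field theory deliberately: it is
assumption-light, self-contained, and its calibration is itself testable —
the package's acceptance suite verifies the family-wise error rate on null
smoothed maps within binomial bounds. Note that cluster-extent permutation
tests are conservative when the suprathreshold landscape is very sparse
(max extents of 0 or 1 voxel make the null distribution highly discrete);
the calibration experiment therefore uses a cluster-forming threshold and
smoothness that populate the extent distribution.

## Univariate and fROI analysis

ROI-level abstractness effects are means of word-type betas over ROI voxels,
compared within group by one-tailed paired t-tests and across groups by a
2 × 2 mixed ANOVA (word type within, group between, unbalanced groups
allowed) via the classical single-within-factor decomposition; the
interaction is fitted last, so its F equals the squared pooled-variance
two-sample t on per-subject difference scores (verified to 8 decimals).

The fROI procedure selects, inside an anatomical constraint, the `n_top`
voxels (50 default, 100 variant) with the highest
abstract-greater-than-concrete t in one run fold, averages word-type betas
of those voxels in the held-out fold, swaps folds, and averages the two
estimates. Ties in the selection break by ascending linear voxel index —
deterministic by construction. The statistical point of the procedure is
verified directly: under a null simulation the cross-validated estimate is
centred at zero while naive same-fold selection is strongly positively
biased.

## Group inference

Welch's t (Satterthwaite df) serves every between-group comparison, from
summary moments (`welch_t_summary()`, used for cohort demographic tables)
or raw samples; Hedges' g (pooled SD with small-sample correction
`1 - 3/(4n - 9)`) accompanies between-group tests and Cohen's d
within-group ones. One-tailed conventions follow the scientific directions:
semantic encoding greater than zero, abstract greater than concrete.
Mediation of group effects by a proficiency covariate uses linear models
(`M ~ group`, `Y ~ group + M`), with ACME = a·b, ADE the direct
coefficient, and nonparametric bootstrap percentile intervals over subjects
(5000 resamples at study scale; resamples missing a group are redrawn, at
most 10 times). The bootstrap is chosen over the quasi-Bayesian
approximation because it is simpler and assumption-light.

## Numerical and scale choices

All randomness flows from explicit seeds; fixed seeds give byte-identical
outputs. Simulation problem sizes in the tests and the acceptance script
are chosen to make each check sharp but desk-scale; they are the package's
own validation conditions:

* calibration (200 replicates): 90 words, a 64-voxel ROI on a 4³ grid,
  groups of 16 and 23; cluster-FWE calibration on 200 replicates of 16
  null 12³ maps smoothed 6 mm, cluster-forming p = 0.05, 500 permutations;
* ROI-level recovery (100 replicates): encoding strengths 1.0 vs 0.3 in a
  64-voxel ROI on a 12³ grid, groups 16/23, two-tailed Welch at α = 0.05;
* searchlight recovery (20 replicates, threshold 18): 30 words, 10³ grid,
  27-voxel planted ROI, 6 mm radius, peak of the two-sample t map;
* gap-statistic recovery (100 replicates): fresh 90-word sets, 16-subject
  averaged behavioural RDMs, `k_max = 20`, 20 reference sets, 10 restarts;
* fROI bias (100 replicates): null patterns, 512-voxel constraint,
  `n_top = 50`.

Degenerate inputs are signalled, not silently repaired: zero-variance
patterns or images name the offending condition, covariate collinearity that
exhausts residual variance errors, empty ROIs and mismatched grids error,
and a failed subject in `roi_rsa()` is reported with its id rather than
dropped.

## Known limitations

OLS without prewhitening slightly misstates single-subject t scales under
temporally autocorrelated noise (group inference on Fisher-z summaries is
unaffected). The permutation cluster test is conservative under very sparse
suprathreshold landscapes. The simulator's noise is white in space and time.
The mediation module covers a single mediator without
sequential-ignorability sensitivity analysis. The multi-arrangement
acquisition procedure itself (inverse MDS from partial arrangements) is out
of scope — subject RDMs arrive complete.
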