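# semrsa

Representational similarity analysis (RSA) of word semantics for two-group
fMRI designs, with a forward simulator that makes every analysis stage
verifiable by parameter recovery and calibration.

## The problem this package addresses

Studies of how the brain encodes word meaning — and how that encoding
differs between groups, for example native versus delayed first-language
signers — run a long chain of analyses on condition-rich fMRI data:

1. **First-level GLM.** Per-word response patterns are estimated from BOLD
   runs with a design of 90 word regressors plus a catch-trial regressor,
   each a 2.5 s boxcar convolved with the canonical double-gamma HRF,
   together with discrete-cosine high-pass drift (128 s cutoff), motion and
   per-run global-mean nuisance columns; voxelwise OLS yields per-word
   t-maps.
2. **Behavioural semantics.** Each subject's multi-arrangement task gives a
   90 × 90 semantic distance matrix (RDM); matrices are averaged, the number
   of semantic categories is selected by the gap statistic
   (k-means, first-SE-max rule) and a binary categorical model RDM is built.
3. **RSA.** The neural RDM of a region is `1 − r` (Pearson) between the
   word patterns; the semantic-encoding statistic is the **partial Spearman
   correlation** between neural and semantic RDMs, controlling visual
   silhouette and sub-syllabic phonological model RDMs,

   `z = atanh( cor(resid(rank d_neural), resid(rank d_semantic) | ranks of covariate RDMs) )`,

   computed per ROI and, in a searchlight, inside an 8 mm sphere around
   every voxel (257 voxels on a 2 mm grid), with 6 mm smoothing of the z
   maps and permutation cluster-extent FWE correction of group maps.
4. **Univariate abstractness and fROIs.** Mean betas for abstract vs
   concrete words per ROI, a 2 × 2 mixed ANOVA (word type within, group
   between), and a cross-validated functional-ROI procedure: select the top
   50 voxels by the abstract>concrete t in the odd runs, estimate in the
   even runs, swap, average.
5. **Group statistics.** One-sample/paired t-tests, Welch's t with
   Satterthwaite df and Hedges' g, and bootstrap mediation
   (ACME = a·b, ADE, percentile CIs over 5000 resamples).

Because ground truth is unobservable in human data, `semrsa` ships a
generative model (`gen_word_set`, `ground_truth`, `gen_subject_patterns`,
`gen_bold_runs`) that plants known semantic-encoding strengths and
abstractness effects per ROI and group, so the full chain is tested by
recovery and calibration. See the methods vignette
(`vignettes/semrsa-methods.Rmd`) for the model and every numerical choice.

## Worked example

Simulate two signer groups whose semantic encoding differs only in one ROI
("dATL": strengths 1.0 vs 0.3; abstractness 0.8 vs 0.2) and is matched in a
second ("pMTG"), then run the whole pipeline:

```r
library(semrsa)
cfg <- pipeline_config(
  groups = list(native = 8, delayed = 10),
  behavioral = list(n_subjects = 12, noise_sd = 0.3),
  cluster = list(k_max = 15, n_ref = 20, n_start = 10),
  grid = list(dim = c(10, 10, 10), voxel_mm = c(2, 2, 2)),
  rois = list(dATL = list(x = c(3, 6), y = c(3, 6), z = c(3, 6)),
              pMTG = list(x = c(7, 10), y = c(7, 10), z = c(7, 10))),
  encoding_strength = list(dATL = c(native = 1.0, delayed = 0.3),
                           pMTG = c(native = 0.6, delayed = 0.6)),
  abstractness_effect = list(dATL = c(native = 0.8, delayed = 0.2),
                             pMTG = c(native = 0.5, delayed = 0.5)),
  mediation = list(n_boot = 1000))
res <- run_pipeline(cfg)
res$category_k
res$rsa[, c("mean_z_native", "mean_z_delayed", "welch_t", "welch_p", "hedges_g")]
```

prints

```
k = 10
     mean_z_native mean_z_delayed welch_t welch_p hedges_g
dATL        0.5338         0.2539 73.7510  0.0000  30.4548
pMTG        0.4867         0.4863  0.1049  0.9177   0.0463
```

The gap statistic recovers the 10 planted semantic categories from the
averaged behavioural RDMs; ROI-level RSA finds strong semantic encoding in
both groups and both ROIs (`mean_z_*` are Fisher-z partial Spearman
correlations), and the Welch test isolates the planted group difference to
dATL. (Effect sizes are enormous because this demo simulation is nearly
noise-free; the point is localisation, not realism.) The univariate stage
shows the same dissociation — the group × word-type interaction is
significant in dATL (F₁,₁₆ = 1668, p ≈ 1e-17) and not in pMTG (p = 0.40) —
and the mediation stage reports a null ACME (p = 0.30) for a proxy
covariate, with the direct group effect intact. `res$demographics`
reproduces the cohort comparison table (Welch's t, df, p, Hedges' g) from
the bundled group summary moments.

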