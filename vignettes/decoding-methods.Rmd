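---
title: "Decoding hearing status from source-level ERPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hearing status from source-level ERPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Older adults with mild hearing loss show altered cortical responses to
speech, visible in the event-related potential (ERP) within the first
200 ms after sound onset. Given single-trial source-level activity in the
68 regions of the Desikan-Killiany (DK) parcellation, two questions have
natural machine-learning formulations:

* **When** does brain activity distinguish normal-hearing (NH) from
  hearing-impaired (HI) listeners? — answered by a sliding-window
  classifier over the epoch.
* **Where** in the brain does it? — answered by a sparse,
  resampling-stabilized feature selector over all region x time features.

`erpdecode` implements both analyses end to end, together with a seeded
synthetic cohort generator so that every stage can be exercised and
validated without access to raw recordings.

## Pipeline

1. **Pseudo-trials.** Per subject and condition, random subsets of
   `n_per_average` single trials (disjoint across pseudo-trials, drawn
   without replacement) are averaged into pseudo-trial ERPs. Averaging N
   trials suppresses uncorrelated noise by about $1/\sqrt{N}$, trading
   sample count against SNR.
2. **Baseline correction.** The mean over the prestimulus window
   (default $-10..0$ ms) is subtracted per pseudo-trial and ROI.
3. **Window features.** The 210-ms epoch is tiled with non-overlapping
   10-ms windows, half-open $[t, t+10)$ ms; the feature is the mean
   amplitude in the window. With 68 ROIs and 21 windows this yields
   $68 \times 21 = 1428$ features; one hemisphere yields
   $34 \times 21 = 714$. The window count includes the prestimulus
   window (21 windows only tile a $-10..200$ ms epoch if window 1 covers
   $-10..0$ ms). A window's reported latency is its start time.
4. **Normalization.** Features are z-scored with mean/SD fitted on the
   training partition only and applied unchanged to held-out data. This
   fold-safe policy avoids leaking test statistics into training;
   fitting on all rows is available (`scores_on = "all"` in
   `stability_selection()`) for strict-replication comparisons.
5. **Decoding.** One RBF SVM per time window, trained on that window's
   ROI features. Hyperparameters are grid-searched ($C$ in $10^{-2}..10^2$,
   $\gamma$ in $7\times10^{-4}..10^{-2}$, log-spaced) with stratified
   5-fold cross-validation inside an 80/20 stratified train/test split.
   Accuracy, $F_1$ (HI-positive) and AUC (rank statistic of the SVM
   decision values) are computed on the held-out set; the peak window
   gives the decoder's best accuracy and latency.
6. **Stability selection.** Randomized-lasso scores over resamples (below),
   a threshold sweep with a coupled SVM, and per-ROI aggregation into a
   ranked region table.

## Stability selection

For resample $b = 1..B$ (default $B = 1000$; reduced-scale runs use 100):

* draw $\lfloor 0.75\, n \rfloor$ rows without replacement;
* draw a randomization weight $W_j \sim U[\alpha, 1]$ per feature, with
  weakness $\alpha = 0.5$, and fit an L1-penalized logistic regression in
  which feature $j$'s penalty is $\lambda / W_j$ — the randomized-lasso
  device that decorrelates selection among correlated features;
* fit across a penalty path of 25 log-spaced values from the data-driven
  $\lambda_{\max} = \max_j |x_j^\top (y - \bar y)| / n$ (the same entry
  point a least-angle-regression path starts from) down to
  $10^{-3}\lambda_{\max}$; a feature counts as *selected* in the
  resample if it is active at any $\lambda$ on the path.

The stability score of a feature is its selection frequency across
resamples, a number in $[0, 1]$. Selected sets are nested across
thresholds by construction. The per-ROI score is the maximum over that
region's 21 window features; regions at or above the reporting threshold
(default 0.5) form the ranked network, with hemisphere and lobe labels
for lateralization summaries.

Reproducibility contract: resample $b$ seeds the RNG with `seed + b`,
then draws rows, then weights. The test suite holds the production
implementation to exact equality against an independent brute-force loop
replaying this schedule.

Numerical notes:

* The solver is coordinate descent (glmnet) with `standardize = FALSE`
  (features are already z-scored) and convergence tolerance
  `tol = 0.01`, the stability-selection configuration this analysis
  standardizes on. glmnet rescales per-feature penalty factors to sum to
  $p$; since selection is "active anywhere on a three-decade path", this
  global rescaling is immaterial.
* Solver failures skip the resample with a warning and shrink the score
  denominator; zero-variance features are scaled with SD 1 (they carry
  no information) with a warning.
* Threshold 0 is a valid sweep point and reproduces the all-feature SVM
  under the identical split; thresholds selecting no features produce a
  row with missing metrics rather than an error.
* Grid-search ties are broken toward smaller $C$, then smaller
  $\gamma$ — the simpler model; tied peak windows resolve to the earliest
  window.

The "optimal" sweep threshold maximizes accuracy, then AUC, then $F_1$,
then sparsity. The reported network defaults to the 0.5 operating point,
which trades a few accuracy points for an interpretable region count.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, not any
particular dataset:

* **Cohort**: 13 NH and 19 HI subjects by default, ~6000 trials per
  subject per condition, 68 ROIs, epochs $-10..200$ ms at 500 Hz (so a
  10-ms window is exactly 5 samples).
* **Morphology**: a P1-N1-P2 template of Gaussian deflections
  (defaults: 60 ms/+1.0, 100 ms/-1.5, 170 ms/+1.2; SDs 20/30/40 ms), in
  arbitrary source units.
* **Group effect**: HI multiplies the P1 amplitude by 1.5 inside a
  12-region discriminative set (bilateral superior temporal bank,
  temporal pole R, fusiform R, precentral gyri and associated
  parietal/frontal regions). Regions outside the set follow one
  generative law for both groups.
* **Condition effect**: the noise-degraded condition scales all
  amplitudes by 0.7 and delays all latencies by 20 ms.
* **Noise model**: per-sample white noise (SD 1.5), a $1/f$ background
  (SD 1.0), per-trial latency jitter (SD 5 ms), a per-subject global
  gain (SD 0.1) and a per-subject, per-ROI regional gain (SD 0.2). The
  regional gain matters: without it every discriminative region is an
  identical signal copy, and a sparse selector provably splits its
  selection mass among perfect duplicates instead of ranking all of
  them — real regional effects are expressed with subject-specific
  regional strength, and recovery of a distributed network presupposes
  that structure.

Quantitative effect sizes are free parameters of the generator, chosen
once to give single-trial SNR in the regime typical of source-level
auditory ERPs (evoked peak roughly one third of single-trial noise SD)
with clearly detectable but not trivial group separation after
100-trial averaging. They are not estimates of any dataset.

### What the simulator does not emulate

No volume conduction or inverse-solution spatial correlation between
ROIs (each region's noise is independent), no oscillatory or
phase-locked background structure, no behavioral or attentional state
drift, no heterogeneity of ERP morphology across regions. Passing
recovery tests on this generator therefore demonstrates the
correctness of the *pipeline*, not expected performance on real
recordings, where inter-regional correlation will in particular make
selected networks less sharply localized.

### Subject identity leakage

Under the default pseudo-trial split, pseudo-trials from the same
subject occur on both sides of the split. When subject-trait
variability is present (the gain parameters above), a classifier can
fingerprint *subjects* — in any window with evoked signal — and thereby
recover the group label without using a group effect. This inflates
accuracy relative to subject-disjoint evaluation; it is why
`split_data()` offers `unit = "subject"` as the leakage-safe
alternative, and why planted-latency tests use a trait-free
configuration in which the group effect genuinely is the only
discriminable structure. Both split units are first-class; neither is
claimed to reproduce any published accuracy.

## Problem sizes used in tests and the acceptance script

Validation runs use a reduced scale chosen so the full suite completes
comfortably on one CPU: 8 + 8 subjects, 600 trials per subject, 100
stability resamples, and a compact hyperparameter grid. At 600 trials,
100-trial pseudo-trials would give only 6 rows per subject
(~57 rows per stability resample), which caps the lasso active set far
below the regime of a full-scale analysis (~1500 rows); reduced-scale
runs therefore use 25-trial pseudo-trials (24 per subject), which is
also part of the 25/50/75/100/125 averaging protocol the analysis
design contemplates. The full-scale defaults remain the package
defaults.

## Known limitations

* Stability scores depend on the penalty-path lower bound
  ($10^{-3}\lambda_{\max}$); on separable data the logistic path
  saturates and the active set stops growing, so scores at small $n$
  are conservative.
* The λ-path selection event ("active anywhere") makes scores monotone
  in the path length; per-λ scores are retained internally but not
  exposed.
* AUC uses the decision-value rank statistic; with tiny test sets its
  granularity is coarse.
* The generator's lobe labels follow a standard DK lobe grouping;
  cingulate regions are kept as their own group rather than folded into
  frontal/parietal lobes.
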