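---
title: "Inter-subject decoding of motor imagery: models, simulation, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject decoding of motor imagery: models, simulation, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmi)
```

## The problem

Brain-computer interfaces decode intentions — here, left- versus right-hand
motor imagery (MI) — from multichannel MEG or EEG. A classifier normally
needs a per-user calibration session; *inter-subject* (transfer) decoding
trains on other people's recordings so a new user can start immediately.
`crossmi` implements a complete leave-one-subject-out (LOSO) study of six
inter-subject decoders, the within-subject baselines they are compared
against, and the statistics used to judge them, together with a synthetic
multi-subject generator so the whole pipeline runs and is tested without any
recorded data.

The physiological signal is the sensorimotor rhythm (SMR): oscillations
around 10 Hz (mu) and 20 Hz (beta) over sensorimotor cortex whose power
drops after movement or imagery — event-related desynchronization (ERD) —
predominantly in the hemisphere *contralateral* to the (imagined) hand.
Left-vs-right decoding therefore hinges on the lateralization of band-power
suppression.

## The decoding methods

All methods see epochs band-passed to 6–45 Hz (zero-phase FFT-domain FIR,
filter length = epoch length), cropped to −1…2 s around the cue with the
−1…0 s baseline mean removed, common-average referenced for EEG.

**CSP family.** Spatio-spectral decomposition (SSD) first maximizes power
in the band of interest (default 10 ± 3 Hz; `select_band()` can pick the
centre as the 1-Hz bin in 8–30 Hz with the largest relative rest-to-active
power decrease) against its 2-Hz flanking bands; 20 components are kept.
Common spatial patterns (CSP) then solves the generalized eigenproblem of
the class-1 covariance against the summed class covariance; 5 filters are
taken from each end of the eigenvalue spectrum (10 components), and the
log of the time-averaged component power is the feature vector for a
pooled-covariance LDA. The three variants are

1. `csp_lda` — SSD + CSP + LDA on the pooled training subjects;
2. `csp_bagging` — the same spatial filters, but one LDA per training
   subject; member class-probabilities are averaged (majority vote is
   available) and thresholded at 0.5;
3. `regcsp` — regularized CSP: each class covariance is shrunk first
   toward a *generic* cross-subject pool
   \(G_c = \frac{1}{N}\sum_i \frac{1}{fn_i} C_c^{(i)}\), with
   \(fn_i\) the squared Frobenius distance between the test subject's
   label-free pooled covariance and training subject *i*'s — so subjects
   resembling the test subject dominate and no test labels are used — and
   then toward the identity:
   \(\tilde C_c = (1-\gamma)\bigl[(1-\beta)C_c + \beta G_c\bigr] \pm \gamma I\).
   β and γ are tuned on an 11 × 11 grid (step 0.1) by leave-one-out over a
   deterministic half of the training subjects (even positions after
   sorting by id; the odd half trains the final model), ties toward the
   smaller pair.

**Sparse-regression family.** Epochs are decimated by 10 (plain striding —
the data are already low-passed at 45 Hz; keep the decimated rate above
twice the band of interest), flattened to channel × time feature vectors
and z-scored with training-set statistics. With one *task* per training
subject, the multi-task model minimizes

$$\min_{W,c}\;\sum_{i=1}^{t}\sum_{j=1}^{n_i}
\log\!\bigl(1+e^{-y_{ij}(w_i^\top x_{ij}+c_i)}\bigr)
\;+\;\rho\,\Omega(W),$$

with \(\Omega\) either the \(\ell_{2,1}\) norm
\(\sum_f \lVert W_{f,:}\rVert_2\) (row sparsity: a feature is selected for
all subjects or none; `l21_mtl`), the elementwise \(\ell_1\) norm
(`l1_mtl`), or the single-task \(\ell_1\) fit on all subjects' samples
concatenated (`pooling`). The solver is an accelerated proximal-gradient
(FISTA) iteration with backtracking line search, zero initialization,
unpenalized intercepts, and momentum restart whenever the objective would
rise, so the recorded trace is non-increasing; convergence is a relative
objective change below `tol` (default 1e-6, `max_iter` 2000). The unseen
test subject has no weight column, so predictions use the consensus model
— the mean over task columns plus the mean intercept — a standard choice
for joint-feature multi-task learning applied to a new task. ρ is chosen
by inner leave-one-task-out validation on the \(\ell_{2,1}\) model
*within the training roster only* and shared by all three sparse methods;
an in-sample choice informed by test subjects would leak, so the package
deliberately uses only inner validation.

**Protocol.** Within-subject baselines are 10-fold stratified
cross-validation with \(\ell_1\) logistic regression (`within_subject_l1`)
and an SSD+CSP+LDA model trained on the subject's own passive-movement
(PM) epochs and tested on their MI epochs (`within_subject_pm_csp`).
Subjects are ranked by mean within-subject accuracy and the lowest `k`
(default 5) are excluded from every training roster — but still tested —
via `exclude_poor()`. `run_loso()` then scores every subject with models
trained on the roster minus that subject, using either MI or PM epochs as
training material; the test set is always the subject's MI epochs.

## Statistics

* `chance_level(n, alpha)` — the binomial significance threshold
  `qbinom(1 - alpha, n, 1/2) / n`: a fair coin *strictly exceeds* it with
  probability below alpha. For 80 trials at alpha 0.05 this is 58.75%.
  Comparisons use the unrounded value.
* `friedman_rank_test()` — within-subject midranks, tie-corrected
  chi-square, df = methods − 1. A fully tied table returns 0 (no
  evidence of an effect) rather than 0/0.
* `posthoc_rank_tests()` — pairwise rank-mean comparisons with the
  large-sample standard error \(\sqrt{k(k+1)/(12n)}\), Bonferroni-corrected.
* `compare_to_chance()` — one-sided (switchable) one-sample t-test of
  per-subject accuracies against the chance threshold.
* `paired_ttests()` — all method pairs, two-sided paired t, multiplied by
  the number of pairs and capped at 1.

The per-subject accuracy tables of the study this package re-implements
are bundled as plain-text fixtures (`ref_table()`): the statistics above
recompute, from the printed per-subject values, the published column
means, Friedman chi-squares (34.29 / 19.84 / 16.81 / 34.21 for the four
seven-method tables), the 7 below-chance online subjects, and the excluded
set {3, 5, 11, 12, 14}. Two printed mean-row entries of the EEG/PM table
are arithmetically inconsistent with their own printed cells (the CSP+LDA
column's cells average 55.00 against a printed 55.25, and the
within-subject column is printed at one decimal so its mean cannot be
recovered beyond ±0.02); `verify_fixtures()` reports exactly these two
checks as failing and everything else as passing.

## The synthetic generator

No public recording exists for this study, so `sim_config()` /
`simulate_pool()` generate a multi-subject pool with the statistical
structure the analysis assumes. Per subject, three bilateral source pairs
are mixed into the sensors by a subject-specific unit-norm spatial pattern
(group pattern + `pattern_jitter` × subject deviation):

* narrow-band mu (~10 Hz) and beta (~20 Hz) sources, simulated as
  Gaussian-bump-filtered noise with unit RMS; after the cue (t ≥ 0) the
  amplitude of the source contralateral to the cued hand is multiplied by
  \(\sqrt{1-d}\), so its band *power* drops by the ERD depth
  \(d = \text{erd\_depth} \times \text{performer quality}\); the
  ipsilateral source is suppressed by \(d(1-\text{lateralization})\);
* a cue-locked ~8-Hz oscillatory burst (Gaussian envelope peaking 0.5 s
  post-cue), contralateral-dominant, with amplitude proportional to the
  same depth × quality product.

The burst deserves a comment. Phase-random ERD changes only the
*variance* of the signal, which log-power features see but a linear model
on raw time points provably cannot (the class means are identical). Since
the sparse-regression family decodes flattened time courses, the data must
contain a phase-locked, hand-lateralized component — as real recordings do
in the form of cue- and movement-locked fields. The burst is the minimal
such structure; because it scales with the ERD depth, a null configuration
(`erd_depth = 0`) silences every class difference at once, which is what
the null-calibration tests rely on.

On top of the sources sit 1/f background activity (unit RMS per channel,
exponent `background_exponent`) and white sensor noise. Passive movement
uses its own (smaller) depth and (much smaller) lateralization; rest has
no suppression. Poor performers are modelled by a reduced
`performer_quality` drawn in (0.05, 0.25) instead of (0.75, 1) —
insufficient SMR modulation, not label noise — for `n_low_quality`
subjects. Every subject/condition block gets a seed derived from the
master seed by a counter-based recurrence, so pools are bit-reproducible
and conditions are independent draws.

Defaults mirror the modelled study: 18 subjects (5 poor performers), 80
epochs per condition (40 per class), 3-s epochs spanning −1…2 s at 1 kHz,
64 MEG-like channels (28 for EEG-like data). The free amplitude scale was
fixed once so that within-subject accuracies span roughly 30–90% across
simulated subjects — the spread the study reports — with `evoked_amp = 3`;
it is not a tuning knob for downstream results.

What the generator does *not* emulate: biophysical forward models, ocular
and cardiac artifacts, head movement, non-stationary noise, and volume
conduction differences between MEG and EEG beyond channel count. Passing
tests therefore demonstrate that the algorithms recover the structure this
model encodes, not that they would reach any particular accuracy on real
recordings.

## Numerical choices and tie-breaks

* Covariances are per-epoch sample covariances, trace-normalized, then
  averaged — robust to epoch-level amplitude differences.
* Whitening floors rank-deficient eigenvalues with a relative ridge
  (logged); spatial patterns invert the filter Gram matrix with a tiny
  ridge so zero-power components stay finite.
* The identity term of regularized CSP is scaled to the shrunk
  covariance's own mean diagonal (trace-normalized covariances make a bare
  identity dimensionally wrong). The subtractive sign printed in the
  source formulation is available (`identity_sign = "minus"`) with an
  eigenvalue floor; the default is the positive-definite `"plus"` form.
* Classifier probability exactly 0.5 resolves to class −1, everywhere.
* Grid ties in regularized-CSP tuning go to the smaller (β, γ); ρ ties go
  to the larger (sparser) candidate.
* Filtering precedes baseline correction; decimation uses stride 10 from
  the first sample.
* Zero-variance log-power components are floored at 1e-300 before the log.

## Problem sizes

The test-suite and the acceptance script run the simulation study at
reduced scale — typically 4–10 subjects, 8–16 channels, 128–256 Hz, 12–48
epochs per condition, and a 3 × 3 tuning grid for regularized CSP — sizes
at which every stage remains statistically meaningful (test-set chance
thresholds are recomputed for the actual epoch counts) while a full run
stays interactive. `study_config(scale = "paper")` configures the
recording-scale study instead.

## Limitations

Known limitations beyond the generator's scope: the regularized-CSP β
parameter is only a second-order reweighting in the LOSO design (both
covariance terms pool the same training subjects), so tuning frequently
and correctly settles at β = 0; the MTL solver is a plain dense FISTA,
adequate at these problem sizes but not optimized for very large feature
spaces; and the bundled reference tables inherit the two arithmetic
inconsistencies of their printed source noted above.
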