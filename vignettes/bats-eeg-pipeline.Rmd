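---
title: "Predicting brief acoustic tinnitus suppression from resting-state EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting brief acoustic tinnitus suppression from resting-state EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batseeg)
```

## The problem

A majority of people with chronic tinnitus can briefly suppress the phantom
sound after acoustic stimulation (brief acoustic tinnitus suppression, BATS,
also called residual inhibition). Whether a person can do this appears to be
a stable, trait-like property, and the question this package addresses is
whether that trait can be predicted from naive resting-state EEG — and, if
so, which neural features carry the prediction.

The pipeline classifies 2-second EEG epochs into +BATS (suppressors) versus
−BATS (non-suppressors) from frequency-domain features, then explains the
classifier. Because clinical recordings of this kind are not openly
deposited, the package ships a synthetic cohort generator whose planted
group structure makes every stage testable against known ground truth.

## Outcome scales and binarization

Two self-report scales are supported: a 0–100% post-stimulation loudness
scale (a subject scoring 90 means tinnitus at 90% of baseline loudness
after stimulation) and a 0…−5 ordinal scale (0 no suppression, −5 full).
Subjects are binarized at a threshold on the suppression side: +BATS iff
score ≤ 90 by default on the loudness scale (chosen so the two classes are
roughly balanced), +BATS iff score ≤ −1 on the ordinal scale. The threshold
value itself counts as +BATS. Every epoch inherits its subject's label.
`threshold_sweep()` re-runs the analysis over thresholds 90…50 to show the
conclusions do not hinge on this choice.

## Feature families

All features are computed per epoch from Welch spectral estimates
(`psd_settings()`: 1-s Hann windows, 50% overlap, zero-padded two-fold so
the grid has 0.5 Hz spacing and the 0.5 Hz delta edge is resolvable; three
averaging segments per 2-s epoch). Band membership is half-open,
`f_lo ≤ f < f_hi`, over the canonical scheme delta 0.5–4.5, theta 4.5–8.5,
alpha 8.5–13.5, beta 15–30, gamma 30–80 Hz; the 13.5–15 Hz gap between
alpha and beta is part of the scheme and deliberately not filled.

* **Band power** (`band_power()`): mean PSD over the band's bins, per
  channel — 310 features on a 62-channel montage.
* **Band spectral Shannon entropy** (`spectral_entropy()`): entropy (bits)
  of the band's bins normalized to sum 1; normalized by `log2(n_bins)` to
  `[0, 1]` by default. Low entropy = peaked, oscillatory band; high =
  flat, noise-like. Another 310 features.
* **Aperiodic offset and slope** (`fit_aperiodic()`): least-squares fit of
  `log10 P(f) = offset − slope·log10 f` over 0.5–80 Hz (45–55 Hz excluded
  as a line-noise guard), with iterative exclusion of bins whose positive
  residual exceeds 2.5 residual standard deviations (oscillatory peaks sit
  *above* the 1/f background), at most 5 refits, and a plain-fit fallback
  flagged via `converged` when exclusion would leave fewer than 10 bins.
  124 features (2 × 62). The fit is exact on noiseless power laws; the
  default Hann-windowed Welch estimate carries a small leakage bias at the
  lowest bins (about −0.05 on a slope of 1), common to both groups; for
  slope validation against a known spectrum use the raw full-epoch
  periodogram (`psd_settings(2, 0, 1, "rect")`), which is unbiased. Note
  the direction of the bias from an *unremoved* spectral peak depends on
  where the peak sits inside the fit range — a 10 Hz peak steepens the
  plain fit here rather than flattening it.
* **Source-label band power** (`label_band_power()`): same band-power
  estimator applied to label time courses of the 68-parcel
  Desikan-Killiany atlas — 340 features. Source localization itself is an
  input boundary: real-data users supply label time courses from their
  inverse solution of choice; the generator produces them directly.
* **Network coherence** (`network_coherence()`): magnitude coherence
  `|⟨Sxy⟩|/√(⟨Sxx⟩⟨Syy⟩)` averaged over Welch segments within the epoch,
  then over band bins (alpha and gamma by default), aggregated over all
  label pairs spanning each pair of large-scale networks (within-network
  pairs included) plus named within-auditory pairs. With only three
  segments per 2-s epoch this is a deliberately high-variance estimator
  with a large positive floor for independent signals (≈ 1/√K); it is used
  because the classification design needs one value per epoch, the floor
  is common to both groups, and a pooled per-subject mode
  (`average = "subject"`) is provided for estimation-quality use. Magnitude
  (not imaginary) coherence is used; robustness to volume conduction is
  explicitly not claimed.

The default label→network table (VSN, SMN, DAN, VAN, LBN, FPN, DMN plus an
auditory-network overlay flag) ships as an editable TSV in
`inst/extdata/dk_network_map.tsv`; it follows the standard seven-network
cortical assignment of the DK parcels with the auditory set covering
superior/transverse temporal, supramarginal, superior parietal, middle
temporal, temporal pole, banks of the superior temporal sulcus and insula.
The atlas has no subcortical parcels, so no deep-gray (DGN) labels exist in
the default map, though the format supports them.

## Feature merging

`merge_correlated()` removes multicollinearity while keeping features
interpretable: every pair with |Pearson r| > 0.9 gets a graph edge,
connected components are collapsed to their lowest-column-index member, and
the full mapping (dropped feature → representative) is reported. Absolute
correlation is used because an anti-correlated duplicate carries the same
information; no linear combinations (PCA and the like) are ever formed.
Correlation is computed on all epochs before the train/test split by
default — replicating the original order of operations — with a train-only
`rows` argument as the leakage-safe alternative.

## Classification

`run_suite()` shuffles epochs, splits 70/30, cross-validates (10-fold,
stratified) on the training set only, then fits on the full training set
and evaluates on the held-out test set. Ten model families run with frozen
default parameters (no tuning): random forest, gradient boosting, QDA,
Gaussian naive Bayes, decision tree, RBF and linear SVM, Gaussian process,
k-NN, and a small fixed-architecture feed-forward net (the neural-network
member is deliberately small and fixed; no convolutional architecture is
specified upstream, and the features are tabular).

Two accuracies are reported side by side for every model, because the
study's printed accuracy statistic,

$$\mathrm{accuracy} = \frac{\#TP}{\#TP + \#FN + \#FP},$$

is the *threat score* (Jaccard index) of the +BATS class — it ignores true
negatives and is never larger than standard accuracy when true negatives
exist. `eq1_accuracy()` implements it exactly as printed;
`standard_accuracy()` is the usual (TP+TN)/N.

The default split is epoch-level, replicating the original design; epochs
from one subject then appear on both sides of the split, so the test set is
not independent of subject identity. This leak is real: on cohorts with
strong subject fingerprints and weak group effects, epoch-level accuracy
exceeds subject-level accuracy (asserted as a property test). Every report
carries the leakage note, and `split_spec(mode = "subject_level")` gives
the conservative alternative.

Validation instruments: `shuffled_label_control()` permutes the epoch
labels and re-runs the pipeline — test accuracy near the class-prior chance
level demonstrates the unshuffled accuracy reflects label structure, not
pipeline leakage; `top_k_retrain()` ranks features by the forest's impurity
importance on the training split and refits on the top 100.

## Explainability

`gini_importance()` recomputes per-tree impurity decreases by routing the
training data through each tree of the forest, reporting mean and standard
deviation across trees, normalized so the means sum to 1 (Gini importance,
as used for the top-100 ranking). `signed_contributions()` attributes each
epoch's predicted +BATS probability to features with a path-dependent
tree-Shapley algorithm implemented in C++ (`src/treeshap.cpp`): features
absent from a coalition are marginalized using node cover fractions, and
the attribution satisfies local accuracy — base value plus contributions
reproduces each prediction to numerical tolerance. An exhaustive
enumeration oracle over all \(2^p\) coalitions (`exhaustive_shapley()`)
pins the fast algorithm down on small ensembles to 1e-8 in the tests.
Positive contributions push toward +BATS; the attributed output is the
+BATS class probability. `class_aggregate()` sums mean absolute
contributions per feature class (band × family), and
`partial_dependence_2d()` exports the joint dependence of the prediction on
the aperiodic offset/slope pair.

Impurity importance (not |contribution|) drives the top-100 step; both
rankings are available for comparison.

## The synthetic cohort generator

Each source label's signal is synthesized in the frequency domain: an
aperiodic 1/f background with one-sided density
\(P(f) = 10^{\mathrm{offset}} f^{-\mathrm{slope}}\), plus narrowband
Gaussian oscillations per canonical band (bandwidth 40% of the band, so
band spectra are peaked and entropy is informative), inverted with a single
FFT per label. `shaping = "deterministic"` fixes the spectral amplitudes
(random phases only), making each epoch's raw periodogram equal the target
density exactly — the closed-form limit used to validate the aperiodic
fitter.

Group effects are planted as:

* standardized shifts of log oscillation power (`band_effects`; a shift of
  `d` standard deviations of the between-subject spread `subject_sd`, per
  region set),
* shifts of the aperiodic offset and slope (`aperiodic_effect`; the default
  −0.3/+0.3 gives +BATS a lower offset and steeper slope — less aperiodic,
  more oscillatory activity),
* shared band-limited sources in configured label pairs
  (`coherence_effects`); the mapping from shared-source mixing fraction to
  realized coherence is measured, not assumed, by
  `calibrate_coherence_mixing()`.

Every subject draws from an independent random stream derived from
(master seed, subject index), so cohorts are byte-reproducible and
partially regenerable. Sensors are an abstract mixing of labels
(`default_mixing()`, a smooth distance-kernel matrix — explicitly not a
physical leadfield) plus white sensor noise.

Default conditions emulate the target study design: 35 +BATS / 38 −BATS
subjects (47.9% +BATS), 140 two-second epochs per subject, 62 channels on a
10-10 montage (the count at which the aperiodic family has 124 features),
DK-68 labels, 250 Hz sampling (a common EEG rate comfortably above twice
the 80 Hz gamma edge). Oscillation base powers (alpha and gamma 3 µV²,
delta/theta ≈ 1, beta 0.8) keep oscillations dominant over the in-band
aperiodic floor so that a planted shift of `d` standard deviations in log
oscillation power is recovered as a standardized difference close to `d`
in measured log band power (the aperiodic floor compresses it slightly;
the Monte-Carlo recovery test allows ±0.3).

What the generator does *not* emulate: volume conduction through a real
head geometry, non-stationarity within epochs, artifacts (ocular, muscle,
line noise beyond the guard band), correlated noise across subjects from a
shared recording system, and any nonlinear coupling between bands. Passing
tests therefore demonstrate that the pipeline recovers the statistical
structure it assumes — not that real recordings contain that structure.

## Test design and problem sizes

The validation suite runs entirely on generated data, sized to finish
quickly on one CPU: estimator oracles on single subjects; the
permutation-null study on 50 subjects × 100 epochs with a reduced
12-channel/10-label montage over 20 seeds (feature cardinality scales with
the montage, the null behavior does not); the class-recovery study on
20-subject cohorts with the alpha/gamma shifts planted band-wide (the check
concerns recovery of feature *classes*, so every label carries the shift);
and the replication study on pairs of 30-subject cohorts with eight planted
labels per band at d = 1.6, where the top-10 important-label sets of
independently generated cohorts should overlap at least 7/10 per band.
Cross-validation is skipped (`cv = FALSE`) inside repeated-simulation loops
— it informs model choice, not the properties under test.

## Known limitations

* Epoch-level splitting leaks subject identity; headline epoch-level
  accuracies overstate subject-level generalization (quantified by the
  split-mode property test, reported, but retained as the default for
  fidelity to the original design).
* The per-epoch coherence estimator is strongly positively biased at three
  segments; its features separate groups but its absolute values are not
  interpretable as population coherence.
* Cohorts are written as plain-text fixture directories (CSV + JSON
  manifest); no EDF/FIF export is provided.
* The merge representative (lowest column index) is deterministic but
  arbitrary among near-duplicates; the merge report, not the survivor
  name, is the interpretable object.
* Gini importance is computed by routing the full training set through
  trees grown on bootstrap samples — a close, slightly smoothed variant of
  the in-bag impurity decrease.
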