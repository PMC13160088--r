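---
title: "Label-free spectral cytometry of engineered T cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free spectral cytometry of engineered T cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) records a single cell's
vibrational fingerprint — protein and aromatic ring modes, nucleic-acid
backbone and base modes, membrane headgroup and mitochondrial
cytochrome-c-associated modes — in a second or two, without labels.
`spectracyte` implements a complete analysis chain for single-cell SERS
cytometry of engineered (CAR) T cells: spectral cleanup, gradient-boosted
classification of engineered vs. non-engineered cells, manifold
visualization, unsupervised activation pseudotime, and time-resolved band
trajectory statistics for antigen-specific co-culture activation.

Because raw single-cell SERS datasets of this kind are not generally
redistributable, the package ships a synthetic spectrum generator whose
statistical structure mirrors such experiments, with a recorded latent
ground truth. Every pipeline stage is validated against that truth, from
cosmic-ray despiking through pseudotime recovery.

## The data model

A spectra set is an ordinary wide tibble (`spectra_tbl`): five metadata
columns (`spectrum_id`, `donor_id`, `class_label`, `time_min`,
`batch_id`) followed by one column per wavenumber over the 700–1700
cm$^{-1}$ biological fingerprint region. The axis lives in the column
names, so dplyr verbs pass through untouched and
`as_spectra_tbl()` re-validates after manipulation. Two CSV dialects
(wide, and long + metadata) round-trip bit-exactly; doubles are printed
with up to 17 significant digits and re-parsed with correctly rounded
`strtod`, which is why the package reads them with base R rather than a
faster parser.

## The synthetic generator

Each spectrum is

$$ I(\nu) \;=\; g(t)\,h_i \sum_k A_k\,P(\nu; c_k, w, \eta)
   \;+\; b_i(\nu) \;+\; \varepsilon(\nu) \;+\; \text{spikes}, $$

with pseudo-Voigt band profiles $P$ (default Lorentzian fraction
$\eta = 0.5$, FWHM 12 cm$^{-1}$ — the standard Raman line-shape
compromise), band amplitudes

$$ A_k = a_k \cdot \underbrace{e_{\text{class}}}_{\text{class effect}}
        \cdot \underbrace{d_{\text{donor}}}_{\text{lognormal, } \sigma = 0.15}
        \cdot \underbrace{j_{ik}}_{\text{per-cell, } \sigma = 0.1}
        \cdot \underbrace{\tau_k(t)}_{\text{trajectory}}, $$

a lognormal per-spectrum hotspot factor $h_i$ ($\sigma = 0.3$,
mimicking plasmonic hotspot variability), a smooth fluorescence baseline
$b_i$ (quartic polynomial plus a broad Gaussian, $\sigma \approx 300$
cm$^{-1}$, scaled to about 3× the mean peak height so baseline removal is
consequential), additive Gaussian channel noise ($\sigma$ = 5% of the
mean peak amplitude), and Poisson-count cosmic-ray spikes 10–50× the
peak height, 1–3 channels wide.

Class effects encode only *directions* reported for engineered T cells:
CAR cells enriched in protein/aromatic and membrane bands, Mock/Unstim
cells relatively enriched in nucleic-acid bands, and red blood cells
dominated by hemoprotein modes. Magnitudes are free parameters; nothing
downstream assumes them beyond sign.

### The activation trajectory program

Co-culture time courses draw acquisition times uniformly over 15–95 min
and apply four curves to antigen-engaged (CAR) cells:

* **protein/aromatic**: quadratic rise to +40% at 60 min, then a partial
  linear decline (40% of the rise given back by 95 min) — the
  rise-then-partial-decline shape of activation-driven protein synthesis
  and synapse formation;
* **nucleic acid**: monotone decline to −30% with a mildly concave shape
  (steeper early, leveling late), the chromatin-decondensation signature;
* **membrane/mitochondrial**: a late-accelerating rise (+30%,
  $\propto u^{2.5}$), standing for the sustained membrane reorganization
  and metabolic ramp of prolonged effector engagement;
* **amide shift**: the amide-region protein bands (≥1200 cm$^{-1}$)
  drift upward in position by up to 4 cm$^{-1}$ ($\propto u^{2}$),
  emulating secondary-structure reorganization. A position shift
  re-shapes the spectrum strongly while leaving 20 cm$^{-1}$ band means
  nearly unchanged — it matters for trajectory geometry, not for band
  statistics.

The last two curves deserve a design note. A time course driven only by
band *amplitudes* that rise early and saturate is nearly a straight line
through the centroid of the z-scored data cloud. Under the pseudotime
metric used here (cosine distance on centered principal-component
scores), such a line degenerates: the angular metric discards radial
progress, so the late course becomes unorderable no matter how small the
noise. Real activation courses carry continuing late-phase biochemical
recomposition; the late membrane/mitochondrial rise and the amide
position drift supply exactly that, bending the trajectory around the
centroid so that angular progress tracks time across the whole course.
These defaults were calibrated once, against the package's own recovery
contracts (bin-level pseudotime correlation reaching 1.00 and never
below 0.94 over seeded replicates; trajectory Spearman statistics of
−1.00 and ≳0.8), and are not revisited per analysis.

An unstimulated arm is generated without trajectory multipliers, and a
shared multiplicative acquisition drift $g(t) = e^{0.002\,t}$ is applied
to both arms so that only statistics which properly reference the
control can cancel it.

## Preprocessing

The cleanup chain is: per-batch intensity outlier exclusion (computed on
raw spectra), then per spectrum despiking → wavelet denoising → airPLS
baseline correction → normalization.

* **Despiking** uses robust z-scores (median/MAD, with an SD fallback
  when the MAD collapses) of the channel-to-channel first differences;
  threshold 6 with a 5-channel replacement window. The flag/replace pass
  iterates to convergence (≤5 passes) because the plateau center of a
  2–3-channel spike has small first differences and only becomes visible
  once its flanks are cleaned. At these settings, injected spikes of
  ≥10× peak height are removed completely while sharp Raman peaks are
  never flagged (the steepest pseudo-Voigt slope at FWHM 12 is ~0.11 of
  peak height per channel, far below threshold at realistic noise).
* **Denoising** is a sym8 orthogonal wavelet transform with per-subband
  BayesShrink soft thresholds, $T_j = \sigma^2 / \sqrt{\max(\sigma_j^2 -
  \sigma^2, 0)}$, the noise scale $\sigma$ estimated from the finest
  detail coefficients by MAD/0.6745. Signals are reflected to the next
  power of two and transformed with periodized filters; even shifts of
  an orthogonal quadrature-mirror pair form an orthonormal basis, so
  reconstruction is exact to machine precision (tested). No wavelet
  package is declared: the transform is 16 standard filter taps and two
  short loops, implemented in-package.
* **Baseline correction** is airPLS: iteratively reweighted Whittaker
  smoothing with a second-difference penalty, weights vanishing on peaks
  ($d_i \ge 0$) and growing exponentially below the baseline. The
  pentadiagonal system is solved by a banded Cholesky in compiled code
  (~10,000 solves per full-pipeline run). $\lambda = 10^5$ suits
  1 cm$^{-1}$ sampling over ~1000 channels and scales with channel
  count; non-convergence after 30 iterations is flagged, not fatal.
* **Normalization** is per-spectrum z-scoring (population SD, fixed for
  bit-reproducibility; immaterial at ~1000 channels). A `"total"` mode
  (divide by summed intensity) provides the strictly positive
  representation needed by log-ratio band statistics.
* **Outlier screening** excludes spectra whose average raw intensity
  exceeds their acquisition batch's mean by more than 3 batch SDs —
  one-sided, because the failure modes (laser artifacts, detector
  saturation) only inflate intensity. The grouping key is `batch_id`;
  whether the natural group is a session, donor or condition is genuinely
  ambiguous, so the key is an argument.

The chain is invariant to per-spectrum positive rescaling (hotspot
factors) and, on default synthetic data, the preprocessed spectrum
correlates >0.95 with the z-scored noise-free generative signal.

## Classification

Features are the normalized intensities, optionally augmented with
first- and second-order Savitzky–Golay derivatives (window 11, order 3;
edge channels handled by the asymmetric-window polynomial fits, no
padding). The booster is a gradient-boosted tree ensemble (xgboost
behind a pluggable fit/predict/gain contract — the protocol, not the
booster, is the point). The protocol: class-stratified 80:20 split;
hyperparameter search (random, default 50 trials over learning rate,
depth, child weight, subsampling, column subsampling, L2) scored by
5-fold stratified CV AUC (log loss for multiclass) with early stopping
after 150 stagnant rounds and a 2000-round cap; positive-class weight =
class imbalance ratio; final accuracy and row-normalized confusion from
10-fold stratified CV on the training split; ROC/AUC from the untouched
held-out 20%. With `tune_trials = 0` the documented default
hyperparameters are kept and only the boosting-round count is selected
from the tuning CV — the test suite uses this to stay fast.

Per-donor training (`train_per_donor()`) fits one model per donor and
pools: mean donor-level CV accuracy, and per-donor ROCs interpolated on
a 101-point false-positive grid, bootstrap-averaged over donors with a
95% band. Importance profiles require non-augmented features: per-donor
gain per wavenumber is sum-normalized, min-max scaled to [0, 1], and
summarized by across-donor mean and SD.

## Embedding and difference curves

UMAP (2 components, 20 neighbours, min_dist 0.1, city-block metric) on
class/donor-balanced subsamples is a visualization product: apart from
time-binned centroids (mean coordinate ± SE), no downstream statistic
consumes embedding coordinates. Difference curves contrast class-mean
spectra per donor, normalized by each donor's own maximum absolute
difference, median-aggregated across donors, with both a donor-bootstrap
95% band and the 25–75% across-donor quantile range (two conventions
found in practice; both are emitted rather than resolved).

## Pseudotime

Centered, unscaled PCA to 45 components; a k-nearest-neighbour graph
(k = 30 default, cosine distance, union-symmetrized); the largest
connected component; a minimum spanning tree; root = the
earliest-acquired member cell (ties broken by smallest `spectrum_id`).
Pseudotime is the tree-path edge-weight sum from the root, normalized to
[0, 1] — the canonical MST pseudotime scalar. Correlation with real time
is reported two ways: per spectrum, and per time bin (median pseudotime
of each bin vs. the bin start time, which is what the recovery contract
uses — bin medians over ~150 spectra are robust to graph noise in a way
single-cell path lengths are not). Equal-width interval bins (not
k-means) realize the "12 clusters" used for trajectory overlays.

## Band dynamics

Time bins are 15–25, 25–35, 35–45, 45–55, 55–75, 75–95 min, labeled by
their earliest time point, half-open with the last bin closed. The
tracked panel is six protein/aromatic bands (898, 1002, 1025, 1222,
1262, 1602 cm$^{-1}$) and three nucleic-acid bands (728, 1092, 1334
cm$^{-1}$), each 20 cm$^{-1}$ wide, closed at both ends.

The trajectory statistic, per band $b$ and bin $t$:
$r(b,t) = \ln \bar I_{\text{CAR}}(b,t) - \ln \bar I_{\text{Unstim}}(b,t)$,
where $\bar I$ is the mean band intensity over member spectra of a
positive representation (total-normalized, baseline-corrected spectra).
Any multiplicative drift common to both conditions within a bin cancels
exactly. Each band's series is z-scored across bins and the z-series are
averaged (mean by default; median by flag) within each biochemical
class. The total-intensity representation trades a small shape coupling
(a strongly rising band class inflates everyone's denominator) for
removal of per-spectrum hotspot noise, which otherwise contaminates all
bands of a bin coherently; at the default effect sizes the trade favors
total normalization, and the representation remains a documented
parameter because the convention is genuinely unsettled.

Uncertainty comes from a block bootstrap honoring serial dependence in
semi-continuous acquisition: within each (condition, bin), contiguous
acquisition-order blocks of length $\lceil\sqrt n\rceil$ are resampled
with replacement and the entire statistic is recomputed; percentile
intervals per (class, bin). In a 200-replicate study against the
population trajectory value (one large noise-free reference run), the
95% interval covers in ~93% of cells at 100 spectra per bin —
percentile bootstraps of z-scored statistics run slightly below nominal
at these sizes, within the package's published 90–98% calibration band.
Monotonicity is assessed by two-sided Spearman rank correlation (midrank
ties) between each class series and the bin start times.

## Problem sizes and what the tests show

The validation suite runs, per seed, two conditions of ~1000 spectra
(the scale of one donor's co-culture course), 20 seeded replicates for
pseudotime recovery, and 200 replicates of ~600 spectra per condition
for interval calibration. Classification checks run at 40–60 spectra
per class on a 2 cm$^{-1}$ axis with the fixed default hyperparameters.

Passing these tests shows the pipeline recovers structure *that the
generator encodes*: band-amplitude class differences, donor-dominant
variance, monotone and unimodal band programs, and a smooth activation
manifold. Real SERS data adds what the generator deliberately omits —
correlated hotspot spectral coloring (enhancement here is a scalar per
spectrum, not wavelength-dependent), peak-shape heterogeneity beyond a
global pseudo-Voigt, instrument wavenumber calibration error, mixed
cell-cell interaction states, and non-Gaussian noise tails — so
synthetic recovery is necessary, not sufficient, evidence for
performance on instrument data.

## Known limitations

* The booster contract is implemented with xgboost; gain values (hence
  importance profiles) are backend-dependent in fine detail.
* The pseudotime scalar needs a connected, curve-like manifold; data
  whose dominant variation is a single amplitude axis will degrade
  under the angular metric, as the trajectory-geometry discussion above
  explains.
* Embedding determinism holds for a fixed uwot version and thread
  count (both pinned to single-threaded here).
* Log-ratio band statistics require every tracked band mean to be
  positive; deeply baseline-subtracted regions can violate this, which
  is why the z-scored representation is rejected with guidance rather
  than silently logged.
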