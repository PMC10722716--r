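---
title: "Methods: resting-state EEG networks and Simon-task ERPs for MCI screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state EEG networks and Simon-task ERPs for MCI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmci)
```

## Scope and study design

`eegmci` implements, as a synthetic-first pipeline, a clinical-neurophysiology
analysis for discriminating mild cognitive impairment (MCI) from healthy
cognitive aging using two EEG sessions per subject: five minutes of
eyes-closed resting EEG (19 channels, 10-20 montage, 500 Hz, linked-ear
reference) and a cue-locked Simon task (150 trials; 50 congruent, 50
incongruent, 50 no-response; blue cue = right hand, red = left hand, yellow =
withhold; 1500 ms intertrial interval). Because no clinical recordings are
distributable, the package ships a cohort generator that plants known group
effects, so every downstream stage can be validated against ground truth.

The analysis has two branches. The resting branch goes
filtering (0.53--120 Hz band-pass, 60 Hz notch) →
spherical-head forward model → weighted minimum-norm inverse →
band-wise source power ("spectrocortical" images over delta 2--4, theta 4--8,
alpha 8--13, beta 13--30, gamma 30--60 Hz) → group ICA → per-subject network
loadings → one-tailed group comparison. The task branch goes filtering
(0.1--30 Hz) → cue-locked -200..700 ms epochs → infomax-ICA ocular
correction → automated rejection (peak-to-peak > 200 µV in 200 ms, or
activity < 0.5 µV in 100 ms) → baseline correction (-200..0 ms) →
condition averages → N2 (151--230 ms) and P3 (300--600 ms) peaks at Fz, Cz,
Pz. A final discrimination stage combines cognitive tests, a composite
network-activity score, confounders and MRI volumes in six nested models,
classified by radial-kernel SVM and logistic regression under 100 iterations
of Monte-Carlo five-fold cross-validation after class rebalancing.

## The forward and inverse model

The head is modelled as three concentric spheres (brain/skull/scalp radii
87/92/100 mm, conductivity ratio 1 : 1/80 : 1) with radial current dipoles
on a configurable cubic grid. The reference tomography uses a realistic
6239-voxel atlas at 5 mm; that atlas is an external resource, so the grid
spacing and radius are parameters, with desk-scale tests running on 30--40 mm
grids (32--56 voxels). Potentials are computed from the exact Legendre series
of the layered-sphere boundary-value problem (80 terms; radii are normalized
to the scalp sphere so the per-order linear systems stay well conditioned),
and lead-field columns are average-referenced. A source at the exact centre
of the head has no defined radial direction; its lead-field column is zero by
convention. Electrode positions are ideal 10-20 placements on the unit
sphere: landmarks on the equator, arcs divided in 10/20-percent steps, and
F3/F4/P3/P4 as geodesic midpoints of neighbouring sites.

The inverse is the weighted minimum-norm solution with data-independent
voxel weights obtained by the fixed-point iteration
\(w_v \leftarrow \sqrt{k_v^\top (K W^{-1} K^\top + \alpha H)^+ k_v}\), iterated
until the largest relative weight change falls below 1e-6 (at most 100
iterations), where \(K\) is the lead field, \(H\) the average-reference
centering matrix and \(\alpha \ge 0\) the regularization (default: 0.05 times
the mean eigenvalue of the unweighted Gram matrix, so it scales with the
data). This weighting has the defining exact-localization property: for
noiseless single point sources the squared source estimate peaks at the true
voxel, which the test suite verifies at every voxel of the desk grid —
whereas the unweighted minimum norm (available as `weights = "identity"`)
mislocalizes deep sources. Source power spectra use Welch's method (2-s Hann
windows, 50% overlap), integrated over half-open band intervals so the five
bands partition 2--60 Hz exactly. We project to source space first and then
estimate the PSD; the order is not fixed by the protocol, and this choice
keeps every voxel's spectrum interpretable.

## Group ICA and network loadings

Subjects' Nv x 5 images are flattened band-major into a subjects × (5·Nv)
matrix. After centering each feature across subjects, a spatial group ICA is
fitted with FastICA (symmetric fixed-point, tanh contrast) on the whitened
transpose: the estimated components are spectrocortical maps that are
maximally independent across features, and the mixing coefficients are the
per-subject loadings ("network activities"). The algorithm choice is ours
(the protocol names no estimator); FastICA is deterministic given the seed,
retried with up to five seeds on non-convergence. Components are ordered by
total power (loading energy × map energy), signs are fixed so each map's
largest-magnitude weight is positive, and k defaults to 15. Identifiability
rests on non-Gaussianity of the maps, which holds for sparse,
blob-structured networks like the generator's (and real spectrocortical
networks); loadings may be Gaussian.

New subjects are projected by least squares onto the fixed maps after
centering with the training means. Because the maps span the training PCA
subspace, projecting a training subject returns its own loadings exactly,
and the cohort-mean image projects to zero.

Group differences in loadings use the two-sample t statistic (MCI − HC) with
a one-tailed label-permutation p-value (default 5000 permutations,
alternative "MCI lower", artifact-flagged components excluded). A
permutation null is our declared choice: the published t/p pairs for this
comparison are inconsistent with a parametric t null at the clinical group
sizes, so the package does not attempt to reproduce those exact pairs.
Artifact components are identified by a configuration list (default none),
replacing the visual inspection step of the original workflow.

## ERP quantification

"Semi-automatic" peak picking is made fully automatic: N2 is the most
negative interior local minimum in 151--230 ms and P3 the most positive
interior local maximum in 300--600 ms; when a window contains no interior
extremum the window-edge extremum is returned with `edge_flag = TRUE`. N2 is
found as a minimum (its amplitudes are negative) even though both components
are described as "local maxima" in the source protocol. The rejection rule
slides sample-by-sample over all 19 channels — "activity" is the
peak-to-peak range within the window, the convention of the standard
analyzer software. Ocular correction runs infomax ICA (natural gradient,
logistic score, learning-rate annealing; the unmixing is estimated on at
most 30 000 concatenated samples) and zeroes components whose scalp pattern
correlates with a frontal blink template above |r| = 0.8.

## The discrimination stage

Loadings of the discriminative networks are z-scored, clustered by
complete-linkage on the distance 1 − |Spearman correlation| cut at 0.5, and
weighted 1/(cluster size × number of clusters) — correlated networks share
one cluster's weight, so the weights sum to one; signs are aligned so a
higher composite points in the healthy direction. The cluster-weighting
construction is our concrete reading of the under-specified
"weighted z-score" description. Class imbalance is handled by a
bootstrap-based combined over/under-sampler (class drawn with probability
0.5, a same-class row resampled, optional Gaussian kernel smoothing with a
per-feature Silverman bandwidth times a shrink factor), with plain random
oversampling also available. Model feature sets: M1 cognitive tests, M2 the
composite, M3 = M1+M2, M4 = M3 + confounders, M5 = M1 + confounders + MRI
volumes, M6 everything; confounders default to age, sex and education (the
protocol does not enumerate them). SVM uses a radial kernel with cost 1 and
no class weights (rebalancing handles the imbalance); logistic regression is
unpenalized.

Cross-validation runs `iters` random 5-fold partitions; metrics (accuracy,
sensitivity, specificity, precision, F1, rank-statistic AUC) are computed per
iteration from the pooled held-out predictions and averaged, a choice the
protocol leaves open. Two protocols ship: `paper_faithful` resamples once
before partitioning, which reproduces the original workflow but lets
duplicated subjects straddle fold boundaries; `leak_safe` (the recommended
default) resamples and fits the composite parameters inside each training
split only. On null cohorts `leak_safe` is calibrated (AUC ≈ 0.5), which the
acceptance suite verifies.

## The synthetic cohort generator

The generator is first-class, tested code. Its defaults are the study
conditions:

* **Behavior.** Accuracy is Bernoulli per condition (HC 0.98/0.98/0.99,
  MCI 0.98/0.96/0.99) and RTs are lognormal with parameters fitted to the
  published medians and IQRs (HC congruent median 0.574 s, IQR 0.521--0.624;
  MCI slower in both response conditions). The source figure labels RTs "ms"
  with magnitudes near 0.6; the generator treats them as seconds.
* **ERPs.** Epochs are white noise (SD 2 µV) plus Gaussian-pulse N2
  (fronto-central topography) and P3 (centro-parietal) components whose Cz
  amplitudes and latencies vary between subjects. The HC no-response N2 at
  Cz is centred on −10.3 µV and the MCI arm on −6.67 µV (the published
  medians); the between-subject SD is set to 3.5 µV, a realistic
  between-subject ERP spread (the published IQR-implied ~6.8 µV also folds
  in measurement noise from ~30-epoch averages). A configurable fraction of
  epochs (default 10%) carries a planted step (> 200 µV), a flatlined
  channel, or a frontal blink — the first two exercise the rejection rule,
  the blink the ICA correction.
* **Resting networks.** Each network is a sparse nonnegative map over
  (band, voxel); a subject's source signal adds, per network and band,
  spectrally band-limited Gaussian noise with amplitude
  `sqrt(loading × map weight)`, so the source band power is exactly the
  loading-weighted mixture the group ICA assumes. HC loading location/scale
  follow the published loading summaries (e.g. 2760 ± 808 on the µV²/M⁴/Hz
  scale); the MCI deficit is planted at one pooled SD. The clinical effect
  sizes (d ≈ 0.1--0.3) are only detectable at the full 402/47 cohort scale;
  the one-SD deficit is the desk-scale study condition at which a 40/40
  cohort has high power, and the effect direction (MCI lower) matches the
  clinical finding.
* **Subject tables.** Demographics and brain volumes are drawn identically
  in both groups (the clinical comparison found no volume differences);
  cognition is drawn consistently with the case definition — HC subjects are
  redrawn until no domain is ≥ 1.5 SD below its norm, MCI subjects until at
  least one is, and both groups satisfy MMSE ≥ 24 — so generator labels obey
  the diagnostic rule by construction.

What the generator does *not* emulate: 1/f background spectra, volume-borne
artifact topographies beyond the blink template, non-stationarity, electrode
impedance drift, or realistic cortical geometry. Passing tests therefore
demonstrate the correctness and calibration of the pipeline's *operations*,
not field performance on clinical recordings.

## Case definition and statistics

A subject with MMSE < 24 is labelled `global_impairment` and excluded from
the HC/MCI contrast; otherwise MCI requires at least one cognitive domain
z ≤ −1.5 against age- and education-stratified norms (inclusive threshold;
timed tests are sign-flipped first so negative z is always impairment). The
source text also contains a contradictory sentence describing HC as below
threshold in *all* domains; the package implements HC = no domain at or
below −1.5 SD, the reading consistent with the MCI rule. The normative
strata ship as synthetic configuration because the original normative
database is unpublished.

Group statistics are the nonparametric set the protocol uses: Wilcoxon
rank-sum (exact when both n ≤ 10 and tie-free, otherwise normal
approximation with tie and continuity correction), Yates-corrected 2×2
chi-squared (the correction reproduces the published cohort-table p-values
from their printed counts), Spearman correlation (t approximation),
Shapiro-Wilk for annotation only, and Bonferroni correction
(`min(1, p·m)`; the six-test ERP family works at 0.05/6 ≈ 0.008).

## Numerical choices and problem sizes

Zero-phase filtering is forward-backward Butterworth (a 2nd-order high-pass
cascaded with a 2nd-order low-pass; biquad notch, Q = 30) with reflection
padding covering three impulse-response timescales of the low edge. The
filter family and order are ours; the protocol states only cut-offs.
Welch segments are 2 s; PSD bins are assigned to bands half-open. The
rejection window stride is one sample, implemented in C++ with monotonic
deques so cohort-scale sweeps stay linear-time. FastICA tolerance is 1e-6
(500 iterations); infomax anneals its learning rate and freezes after ~200
iterations of slow drift. Permutation tests include the observed labelling
in the null set, so one-tailed p-values in opposite directions sum to
1 + P(t = t\*).

Tests and the acceptance script run at desk scale, chosen as the package's
own reference problem sizes: 32--56-voxel grids, 12--300 s records, cohorts
of 40/40 (the clinical 402/47 is reproducible via `cohort_spec` and
`pipeline_config`), 100 replicate cohorts for power and calibration checks,
2000 label permutations, and 100 Monte-Carlo CV iterations as the default.

## Known limitations

* The spherical forward model and radial-only sources are a deliberate
  simplification; no claims are made about anatomical localization of
  components (network names are metadata, not computed labels).
* Projection of new subjects assumes the group maps span the relevant
  subspace; it degrades when a new subject expresses a network absent from
  the training cohort.
* `paper_faithful` cross-validation is optimistic by construction; it exists
  to reproduce the original protocol, not for use.
* The composite-score weighting and the permutation null are concrete
  constructions of under-specified steps; alternatives (e.g. equal weights,
  parametric one-tailed t) are easy to swap in but are not implemented as
  options.
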