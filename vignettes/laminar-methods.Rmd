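---
title: "Layer-resolved decoding and connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-resolved decoding and connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(laminar)
```

This vignette documents the models behind `laminar`, the assumptions they
make, the parameters that matter, and the design decisions taken where the
methodology left genuine choices open. The package analyses sub-millimetre
gradient-echo BOLD block designs at the resolution of cortical depth: it
assigns voxels to three laminar compartments (deeper, middle, superficial),
corrects the vascular superficial bias that plagues gradient-echo laminar
imaging, decodes stimulus content (near vs far binocular disparity) from
multivoxel patterns per depth, and measures informational connectivity
between depths of different visual areas. A synthetic generator with full
ground-truth bookkeeping exercises every stage.

## The equi-volume depth model

Cortical laminae preserve their *volume* fractions under folding: on a gyral
crown the deep laminae are compressed and the superficial laminae stretched,
and vice versa in a sulcal fundus. Equidistant depth sampling therefore
misassigns voxels wherever the cortex curves. `laminar` uses the standard
linear-area wedge model: along a cortical column, the local cross-sectional
area grows linearly from the white-matter boundary area \(A_w\) to the pial
boundary area \(A_p\). The depth \(x \in [0,1]\) enclosing volume fraction
\(\alpha\) solves

\[
\int_0^x \!\big(A_w + (A_p - A_w)t\big)\,dt \;=\;
\alpha \int_0^1 \!\big(A_w + (A_p - A_w)t\big)\,dt ,
\]

with closed form
\(x = \frac{-A_w + \sqrt{(1-\alpha)A_w^2 + \alpha A_p^2}}{A_p - A_w}\)
and the continuous limit \(x = \alpha\) for flat cortex
(`equivolume_fraction()`). Four grids at \(\alpha = 0, \tfrac13, \tfrac23, 1\)
(`build_grids()`) bound three bands; each voxel joins the band between its
two closest grids (`assign_voxels()`). Tests verify the closed form against
brute-force numerical inversion of the volume integral to \(10^{-9}\) over
random curvatures, and the exact reduction to equidistant spacing on flat
cortex.

**Tie rule.** A voxel exactly on an interior grid is equidistant to the two
bands the grid separates. We assign it deterministically to the shallower
band (toward the pial surface). This is a documented convention, not a
reconstruction of any particular software's behaviour; with sub-voxel jitter
in real data the case has measure zero.

**Geometry is column-parameterised.** The cortical patch is a set of columns
(normals), each carrying its own \(A_w, A_p\); there is no triangulated
surface. This exercises the full equi-volume arithmetic without a surface
reconstruction dependency, at the cost of not modelling in-plane partial
voluming. For real data the entry point (`read_laminar_nifti()`) accepts a
precomputed integer layer-label volume instead.

## The synthetic laminar-BOLD generator

`simulate_bold()` realises the generative structure the analysis assumes,
per voxel \(v\) (area \(a\), layer \(l\), depth \(d_v\)) and block \(b\):

\[
y_v(t) = \beta_0 + (1 + b\,d_v)\Big[ h * \big( \mu\,m_v +
A_{a,l,c(b)}\, g_b\, s_b\, p_v \big) \Big](t) + \text{leak}_v(t) + \varepsilon_v(t),
\]

- \(h\): canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6),
  sampled at TR. The analysed experiment never states an HRF (it uses a fixed
  TR window); the generator needs one to create realistic haemodynamic
  delays, and the GLM uses the same canonical form by default (configurable
  to study mismatch).
- blocks are single boxcars; the ten 1.2 s stimuli inside a block are
  metadata only (the analysis operates on block-level responses).
- \(\mu\) (`mean_amplitude`, default 2 in units of the noise SD): univariate
  stimulus-evoked response common to all conditions. It exists because the
  pipeline's own machinery demands it — voxel preselection, the vein t-cut
  and top-t voxel ranking all use the stimulus-vs-fixation t map, which is
  undefined without a mean evoked response. \(m_v\) is the vein amplitude
  multiplier (2 for vein voxels).
- \(A_{a,l,c}\) (`pattern_amplitude`): near-vs-far pattern amplitude of the
  cell; \(s_b = \pm 1\) for near/far; \(p_v \sim \mathcal N(0,1)\) a fixed
  random pattern direction. The default scenario puts signal only in the
  superficial and middle layers of the two higher dorsal areas (A3A, A7) for
  correlated stereograms — the configuration the pipeline is designed to
  detect — at amplitude 0.08.
- \(g_b\): a mean-1 log-normal per-block gain,
  \(g_b = \exp(\sigma u_b - \sigma^2/2)\) with `block_gain_sd` \(\sigma = 0.8\).
  Coupling entries make the latent \(u_b\) of a target cell correlate at
  \(\rho_{\text{true}}\) with a source cell's, which induces correlated
  block-wise *discriminability* fluctuations with no univariate signature —
  the simplest generative process to which informational connectivity, but
  not univariate connectivity, is sensitive. The log-normal form keeps gains
  positive without clamping and, being monotone in \(u_b\), transfers the
  coupling correlation to the rank scale that Spearman correlation sees.
- superficial bias: the depth gain \(1 + b\,d_v\) (default \(b = 1\), i.e.
  the evoked signal roughly doubles from white matter to pia, a typical
  gradient-echo gradient) plus draining-vein leakage: superficial voxels
  receive `leak_fraction` (0.2) of their column's mean deeper+middle evoked
  signal.
- veins: 5% of voxels get noise SD ×3 and amplitude ×2, which lands them
  below the tSNR cut and above the t percentile cut by construction.
- \(\varepsilon\): AR(1) Gaussian noise (lag-1 correlation 0.3, marginal SD
  `noise_sd` = 1), independent across runs, on a baseline of 100 (so tSNR
  is realistically ~100 for clean voxels and ~33 for veins).

**Operating point.** Effect sizes (% signal change per condition) are free
parameters of the generator, not published quantities; the defaults were
chosen once, as a design decision, so that the synthetic experiment sits in
a realistic and informative regime: signal-cell decoding accuracy around
85–95% for a single subject at 175 voxels, chance accuracy in the deeper
layer and for anti-correlated stimuli, injected coupling of
\(\rho_{\text{true}} = 0.5\) recovered at \(\hat\rho \approx 0.35\) (inside
the package's own recovery band of \([0.3, 0.7]\); attenuation comes from
classifier-distance noise), 100% vein recovery, and a superficial-bias gap
reduced to ~30% of its uncorrected size after correction.

**What the generator does not emulate.** No vascular physiology (the bias is
a phenomenological gain), no motion or distortion artefacts, no per-stimulus
dynamics, no retinotopy, and no between-area mean-signal correlations
(physiological noise is voxel-independent). Passing tests therefore show
that the *analysis machinery* recovers the structure it assumes, not that
real cortex satisfies those assumptions.

**Determinism.** Every draw flows from one integer seed through fixed-order,
labelled sub-seeds (`veins`, `patterns`, `gains`, `noise.<area>`), so an
identical (model, design, spec) triple is byte-reproducible and the block
order, which is itself seeded, never perturbs the noise stream.

## The analysis chain and its conventions

The canonical order is: temporal filtering → condition GLM → voxel
preselection → vascular exclusion → layer matching + z-scoring → (optional
spatial regression) → block responses → decoding / LDC → connectivity.
Every dataset records its `applied_steps`.

- **Filtering** (`highpass_and_detrend()`): per run, OLS removal of
  intercept, linear trend, and a Fourier basis at 1–2 cycles per run.
- **GLM** (`fit_glm()`): one HRF-convolved regressor per condition
  (stereo × disparity), per-run intercepts, optional nuisance columns. The
  t map contrasts the mean of the four condition regressors against
  baseline. Preselection keeps voxels with \(t > 1.53\); since the contrast
  asks for responses *stronger* than fixation, the cut is one-sided (the
  two-sided p of 1.53 is 0.125; the null retention rate is ~6.3%).
- **Vascular exclusion** (`vascular_exclusion()`): per area, drop voxels
  with tSNR below mean − 2 SD of the area's tSNR distribution (the "2 SD"
  rule is distributional — area-wise cut values, not a fixed constant) or
  stimulus t above the 90th percentile. A zero-variance voxel gets tSNR
  +Inf and is never excluded by the tSNR rule.
- **Matching + z-scoring** (`match_and_zscore()`): equalise layer voxel
  counts to the within-area minimum keeping top-t voxels (consistent with
  the later top-t pattern selection; random subsampling would discard the
  same information the selection step wants), then z-score each voxel
  within *run*. The normalisation granularity is a documented choice: runs
  are the natural normalisation unit (independent noise, separate
  baselines); whether session-wise normalisation was intended upstream is
  not stated anywhere we could anchor to.
- **Block responses** (`block_responses()`): average TRs 3–7 (1-based,
  inclusive) after block onset — 0-based offsets 2..6, i.e. 4–14 s,
  a 2-TR haemodynamic shift plus one trailing TR to catch the response to
  the last stimulus of a 12 s block. A unit test pins this window to the
  4–14 s interpretation.
- **Spatial regression** (`regress_out_middle()`, control analysis): for
  each superficial voxel, the average time course of its `k_neighbors = 3`
  nearest middle-layer voxels is regressed out. The neighbour count is a
  package default ("nearest neighbours" without a count is underspecified);
  it is configurable.
- **Decoding** (`crossval_decode()`): linear soft-margin SVM (LIBSVM via
  e1071), cost C = 1, no internal scaling (the pipeline's z-scoring is the
  only normalisation), leave-one-run-out folds, decoded separately within
  each stereo condition. Signed hyperplane distances are stored per test
  block with the convention positive = "near"; a distance of exactly zero
  counts as incorrect (deterministic and conservative). Voxel selection
  (top 175 per layer by stimulus-vs-baseline t) happens once on the
  label-agnostic contrast, not per fold: because the ranking contrast never
  sees the near/far label, it cannot leak label information into the folds
  (a leakage unit test inflates a test block and asserts the trained model
  is unchanged). Re-selecting per training fold is the stricter alternative;
  with a label-agnostic criterion the two coincide in expectation.
- **Permutation null** (`permutation_null()`): disparity labels are shuffled
  *within run*, preserving the run structure the cross-validation relies
  on; the full CV is re-run per permutation and
  \(p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})\).
- **LDC** (`ldc_crossvalidated()`): per fold, the training near−far mean
  difference is whitened by the inverse shrinkage covariance of the
  *training runs'* GLM residuals (restricting residuals to training runs
  keeps the weights independent of the test data) and dotted with the
  held-out run's difference. The covariance is shrunk toward its diagonal
  with the Schäfer–Strimmer analytic intensity — the published method names
  no particular sparse estimator, so we claim equivalence only at the level
  of the property that matters: the cross-validated contrast is centred on
  zero under the null, which the test suite verifies over 200 null
  datasets.
- **Informational connectivity** (`build_distance_series()`,
  `informational_connectivity()`, `pathway_contrast()`): per (area, layer,
  stereo) cell, test-block distances are oriented toward the correct class
  (×+1 near, ×−1 far, so larger = more discriminable — whether to orient is
  an open choice; orientation makes the series a discriminability measure
  rather than a class-prediction measure) and concatenated across folds in
  block-onset order. Series are correlated between cells with Spearman
  (average ranks on ties), Fisher-transformed with arctanh (|ρ| clamped at
  1 − 10⁻¹²). Pathways follow the laminar circuit motifs: feedforward =
  superficial of the lower area with middle of the higher area; feedback =
  deeper with deeper. Superficial↔deeper pairs are never emitted because
  that motif cannot separate the two directions. Per-fold-mean correlation
  (rather than per-block) is available by correlating fold aggregates
  externally; the per-block series is the default because it has ~an order
  of magnitude more samples.

## Group statistics

`rm_anova()` handles up to three fully crossed within-subject factors on
complete balanced tables, taking sums of squares from the classical
subject-by-effect partitioning (via `stats::aov()` error strata) and
computing, per multi-df effect, the Greenhouse–Geisser \(\hat\varepsilon\)
and Mauchly's W from the covariance of orthonormalised effect contrasts.
The correction is applied exactly when \(\hat\varepsilon < 0.75\) (both
corrected and uncorrected df/p are always reported); two-level effects have
\(\varepsilon = 1\) by definition and skip Mauchly. Tests verify F, df and
\(\varepsilon\) against an independent closed-form contrast oracle to
\(10^{-8}\), the \(F = t^2\) identity for two-level designs, and Mauchly
against `stats::mauchly.test()`. Within-subject error bars use the
Cousineau–Morey normalisation (subject-mean-centred values, bias correction
\(\sqrt{C/(C-1)}\)); multiple testing uses Benjamini–Hochberg (note that
BH step-up adjustment is order-preserving but *not* idempotent — re-running
`p.adjust` on adjusted values inflates them; the tests assert the hand
step-up formula instead).

`run_experiment()` assembles the full simulated study: `n_subjects = 7`
(a typical 7T laminar group after exclusions), runs drawn per subject from
{4, 5, 6} (mirroring variable scan time across participants), per-subject
seeds derived from the master seed, and the group ANOVAs: the three-way
condition × depth × area on accuracy, per-area two-way condition × depth
for accuracy and LDC, and per-pathway condition × area-pair on Fisher-z
connectivity.

## Numerical and scale choices

- Problem sizes: 84 columns × 9 voxels per area (756 voxels, 252 per layer)
  keep the 175-voxel pattern size feasible after ~15% vascular exclusion
  and layer matching while a full subject runs in a few seconds. The test
  suite's end-to-end checks use 10 experiment seeds × 7 subjects for
  recovery rates, 20 seeds for the vascular and connectivity properties,
  1000 permutations for the null calibration and 200 datasets for LDC
  unbiasedness — sizes chosen so the whole suite runs on a laptop in
  minutes while leaving the binomial success criteria well-powered.
- `generate_design()` counterbalances by sweeps: each consecutive group of
  four blocks is a random permutation of the four conditions, giving exact
  per-run balance (finer-grained balance than quarters-of-run, which cannot
  be exact with 10 blocks per quarter and 4 conditions).
- Degenerate inputs fail loudly: empty preselection, layers emptied by
  masking, rank-deficient designs (with the collinear columns named),
  training folds missing a class, constant distance series (returned as
  missing with a reason, never silently dropped).
- The equi-volume closed form switches to its continuous limit when
  \(|A_p - A_w| < 10^{-9}\max(A_p, A_w)\) to avoid catastrophic
  cancellation.

## Known limitations

- The spatial model has no mesh, no partial voluming, and perfectly known
  columns; layer-assignment accuracy on real anatomy is not addressed.
- The vascular model is phenomenological; the correction properties shown
  (vein recovery, bias-gap reduction) certify the pipeline's rules, not
  their adequacy for real venous physiology.
- Informational connectivity attenuates with classifier-distance noise:
  recovered \(\hat\rho\) underestimates \(\rho_{\text{true}}\) unless the
  gain fluctuations dominate the distance variance. The package reports the
  attenuated value, as any real analysis would.
- Uncoupled layer pairs show a small positive informational-connectivity
  bias (\(\hat\rho\) on the order of +0.02 to +0.06) whenever both cells
  carry stimulus signal. The cause is design-locked: every block's response
  window contains haemodynamic carryover from the preceding block, the
  block sequence is shared across areas, and orienting distances by the
  class label turns that shared deterministic variation into common
  variance. Counterbalancing reduces but cannot eliminate it; contrasting
  conditions (correlated vs anti-correlated z), as the pathway analyses do,
  cancels it to first order.
- The spatial-regression control is a *partial* unmixing: the middle-layer
  reference is an average over a few noisy neighbours, so only the leak
  component correlated with it is removed, and when a strong shared
  univariate response is present the regression acts mostly as common-mode
  removal (which can even raise decoding accuracy). Its diagnostic value is
  comparative — results that survive it are not driven by leakage — not a
  guarantee that leakage is gone.
- `rm_anova()` supports only complete balanced within-subject designs —
  exactly what the simulated experiments produce; unbalanced real data
  would need a mixed-effects approach out of scope here.
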