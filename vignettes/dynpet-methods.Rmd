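---
title: "Quantifying dynamic FDG-PET without arterial sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic FDG-PET without arterial sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dynpet)
```

## The problem

Absolute quantification of cerebral glucose metabolism from dynamic FDG-PET
requires the arterial plasma input function $C_p(t)$ — traditionally obtained
by invasive arterial blood sampling. A non-invasive alternative extracts an
image-derived input function (IDIF) from the internal carotid arteries (ICA).
But the carotids are only 4–6 mm across, comparable to the scanner's
point-spread function (PSF), so the measured IDIF suffers two degradations:

* **partial volume** — the bolus peak is diluted because the vessel fills
  only part of the resolution element, and
* **spillover** — activity from surrounding tissue contaminates the vessel
  signal (and vice versa).

`dynpet` implements the complete correction pipeline: bolus-frame selection,
carotid segmentation (classical and learned), IDIF extraction, recovery of a
model-corrected input function (MCIF), Patlak Ki mapping, and regional
z-score screening for hypometabolism. Because no public dynamic PET study
accompanies the method, the package ships a first-class synthetic phantom
module whose ground truth is generated by the same kinetic model the
correction inverts; every quantitative claim in the test suite is made
against that known truth.

## The kinetic forward model

**Plasma input.** A Feng-type tri-exponential with an appearance delay
$\tau$:
$$C_p(t) = \left[A_1 (t-\tau) - A_2 - A_3\right] e^{-\lambda_1 (t-\tau)}
  + A_2 e^{-\lambda_2 (t-\tau)} + A_3 e^{-\lambda_3 (t-\tau)},\quad t>\tau,$$
with $\lambda_1 > \lambda_2 > \lambda_3 > 0$. Defaults
(`default_plasma_params()`) give a bolus peaking near 20 kBq/cc within the
first minute and a slow tail of a few hundred Bq/cc at 60 min; the decay
rates (4.13, 0.119, 0.0104 /min) follow classic tri-exponential plasma fits
for intravenous FDG.

**Tissue.** The two-tissue compartment model with rates $K_1$ (mL/cc/min),
$k_2, k_3, k_4$ (1/min):
$$C_t(t) = \frac{K_1}{\alpha_2-\alpha_1}\left[(k_3+k_4-\alpha_1)
  e^{-\alpha_1 t} + (\alpha_2-k_3-k_4)e^{-\alpha_2 t}\right] \ast C_p(t).$$
The exponential convolutions are evaluated by an $O(n)$ recursive filter on
a uniform fine grid (default 0.1 s; 0.5 s inside optimization loops) with
trapezoidal within-step quadrature; degenerate cases ($k_2=k_3=k_4=0$,
repeated roots) use their analytic limits. The test suite verifies the
solution against an independent stiff ODE integrator (`deSolve::lsoda`) to
0.1% over random rate draws.

**Measurement (mixing).** The measured curves are convex mixtures of the
frame-averaged model curves:
$$\mathrm{IDIF} = r_b\,C_p + s_t\,C_t,\qquad
  \mathrm{tissue} = s_b\,C_p + r_t\,C_t,$$
with blood recovery $r_b \in (0,1]$, spillover fractions $s_t, s_b \ge 0$
and tissue recovery $r_t$. Together with the 7 plasma and 4 tissue
parameters this is the 15-parameter model the MCIF fit inverts.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a 38-frame, 60-minute study on a 64³ grid of
2 mm voxels (12×10 s, 8×30 s, 8×60 s, 2×180 s, 8×300 s — fine early binning
to resolve the bolus). Two carotid tubes (radius 2.5 mm, 28 mm apart,
spanning the lower third of the grid) carry the plasma curve inside a
soft-tissue head ellipsoid; the upper portion holds a brain ellipsoid
partitioned into 36 super-regions (18 per side) by a seeded,
mirror-symmetric Voronoi parcellation. Each frame is blurred with a
stationary isotropic Gaussian PSF of 4.1 mm FWHM and degraded with additive
Gaussian noise of per-voxel SD
$\sigma = s\sqrt{\max(v,0)/\Delta t}$ — long frames are less noisy, as in
reconstructed PET. The defaults are the package's study conditions:

* `psf_fwhm_mm = 4.1` — the quoted scanner resolution; it produces a
  carotid recovery coefficient of ≈0.5 on this geometry, squarely in the
  regime the MCIF correction targets.
* `noise_scale = 15` — ≈2–5% relative noise on bolus-frame carotid voxels
  and ≈3% on late tissue frames, chosen once as representative of a modern
  TOF scanner at these frame durations.
* Regional kinetics: gray-matter-like FDG rates
  ($K_1 = 0.102$ mL/cc/min, $k_2 = 0.130$, $k_3 = 0.062$/min, $k_4 = 0$,
  i.e. irreversible trapping so the analytic
  $K_i = K_1 k_3/(k_2+k_3)$ exists) with independent log-normal per-region
  multipliers of sdlog 0.03 per rate, giving ≈4–5% inter-regional CV on
  Ki. The choice is a power calculation made at design time: with 36
  regions, a −2 SD cutoff then sits near the 1‰ tail of the natural
  spread (≈3 expected false flags per 100 studies) while a 30% focal Ki
  reduction lands at z ≈ −4, detectable in essentially every seed. A much
  larger natural CV would make a −2 SD rule useless against a 30% lesion;
  much smaller would make the screening trivially easy.

The phantom deliberately omits: anatomical realism, attenuation and scatter,
reconstruction artifacts, head motion (injected explicitly in tests instead)
and inter-frame kinetic model mismatch. Passing tests therefore demonstrate
that the pipeline inverts the degradations it models — PSF mixing and
count-limited noise — not that it is robust to everything a clinical scan
contains.

## Frame selection and motion correction

The bolus-transit frame used for segmentation is found from the summed
intensity $S_i$ of a center crop over the first 10 frames and its
difference series $D_i$ ($D_1 = S_1$): the selected frame is the one
immediately before the first interior local maximum of $D$ — the moment
most tracer is still intravascular. Interior means $2 \le i \le n-1$, with a
strict rise and a non-strict fall, ties resolved to the earliest index; a
monotone ramp has no local maximum and raises an error asking for manual
selection rather than guessing. The crop defaults to the central 50% per
axis, since the anatomical crop the procedure assumes is undefined for
phantoms. The rule is invariant to positive intensity rescaling.

Motion correction registers every frame to the mean of the first 14 frames
with a 6-parameter rigid transform minimizing mean squared intensity
difference (mono-modal PET-to-PET, so MSE rather than mutual information).
Numerical details that matter:

* the metric is evaluated on a 2× coarse grid, pre-smoothed to twice the
  voxel size — on noisy frames plain MSE rewards *any* resampling because
  trilinear interpolation averages noise, so acceptance of a fitted
  transform requires ≥1% improvement of the band-limited metric (and never
  a worse plain MSE);
* a coarse integer-shift search precedes Nelder–Mead, because the carotids
  are only ~2 voxels wide and a 3-voxel displacement is outside the local
  capture range;
* failed optimization degrades to the identity transform with a warning,
  never an error.

## Segmentation

**Classical.** Threshold at a configurable fraction of the bolus-frame
maximum, label 26-connected components, drop islands below a minimum size,
keep the two largest and merge them. On a noise-free default phantom this
reproduces the true carotid mask (Dice 1.0 at the 50% threshold).
`keep_largest_components()` applies the same cleanup to predicted masks.

**ICA-net.** A 3D U-Net: two 3×3×3 convolutions per stage, filters doubling
from `base_filters` up to `max_filters` (64→512 at full scale, five
stages), max pooling, nearest-neighbour upsampling with skip concatenation,
and a squeeze-and-excitation gate (global average pool → bottleneck of
`channels/se_reduction` → sigmoid channel weights) after each encoder
stage. The loss is the equal-weight combination
$0.5\,(1-\mathrm{Dice}) + 0.5\,\mathrm{BCE}$ with Dice smoothing
$10^{-5}$ and BCE clipping $10^{-7}$; optimization is Adam with early
stopping and best-checkpoint restore. Convolutions run as im2col + GEMM in
single precision (C++/Armadillo) with hand-derived backpropagation — ample
precision for training, and the directional-derivative tests in the suite
confirm the gradients.

Training-set expansion applies identical random affines to image and mask
(rotations ≤4°, shifts ≤5 voxels, zooms ±0.05, optional mirroring and a
smooth elastic field), nearest-neighbour for masks, zero-padding/cropping
to the target shape; each subject yields 3 items by default. Augmentation
happens after the subject-grouped fold split, so no subject's data can
reach both sides of a fold.

The packaged benchmark trains a reduced net (depth 3, 8 base filters) on
16 phantom subjects with per-subject anatomy jitter, subject-grouped
5-fold cross-validation, 8 epochs per fold, on 32³ mask-centred crops —
the net is fully convolutional, so validation Dice is computed on the full
64³ volumes. Measured mean validation Dice is ≈0.98. These sizes are the
package's benchmark conditions; the full-scale architecture is available
through `unet_config()` but is not what the tests exercise.

## MCIF recovery

### Identifiability, and the convexity anchor

The data constrain only the products $r_b C_p$ and $s_b C_p$: scaling
$C_p \to cC_p$, $K_1 \to K_1/c$, $r_b \to r_b/c$, $s_b \to s_b/c$ leaves
both measured curves *exactly* unchanged, so a pure least-squares fit of
the 15-parameter model has a flat ridge and cannot pin the absolute scale
of the input function (the classical remedy is a venous blood sample,
which this pipeline by design does not use). The package's resolution is a
physical constraint rather than a calibration: under a mass-preserving
PSF, a measured region fully covered by blood and tissue is a convex
combination of the two, so $r_b + s_t = 1$ and $s_b + r_t = 1$ hold to the
extent the neighbourhood contains no third compartment — exactly the
geometry the phantom builds (carotids embedded in soft tissue). The fit
adds soft penalties $w\,(r_b+s_t-1)^2$ and $w\,(s_b+r_t-1)^2$ (scaled to
the mean squared IDIF; weight 1 by default). On the noise-free ridge any
positive weight selects the physical scale; with noise the anchors compete
mildly with the data misfit. Synthetic mixing draws in the tests follow
the same construction ($r_b \sim U(0.6, 0.9)$, $s_t = 1-r_b$).

Two honest caveats. First, the anchor pins the scale exactly only on
noise-free data drawn from the fitted model family (the setting of the
packaged recovery check). Second, on realistic noisy phantom data the
absolute scale remains weakly identified even with the anchor: the
perivascular soft-tissue curve is dominated by its free (non-trapped)
compartment and is therefore nearly a smoothed copy of the plasma curve,
so decompositions ranging from "little recovery, much spill" to "full
recovery, no spill" all fit the two measured curves to within the noise
floor while satisfying both anchors. The fitted MCIF then reproduces the
input's *shape* faithfully but can carry a global scale error of tens of
percent — the reason arterial or venous calibration samples exist in the
wider literature. The pipeline's clinical endpoint is immune to this:
regional z-scores are exactly invariant to a global input-scale error
(shown below), which is why the end-to-end localization check passes
regardless. Absolute Ki values obtained from fitted (rather than true or
network-predicted) inputs should be read with that caveat.

### The cost and the optimizer

Two cost terms mirror the correction's priorities: a peak term — residuals
on the three frames bracketing the IDIF maximum, weight 10 — because the
partial-volume effect is worst at the bolus peak and Patlak's
$\int C_p$ is dominated by it; and a whole-curve term over both measured
curves. The four mixing coefficients enter the model linearly given the
curve shapes, so they are solved in closed form (anchored, weighted,
box-constrained 2×2 linear least squares) inside the objective — variable
projection — leaving an 11-parameter outer problem. The outer search runs
in unit-box coordinates (the raw parameters span five orders of magnitude,
which defeats finite-difference quasi-Newton stepping) with `nlminb`,
multi-started from one data-driven initialization (delay from the IDIF
take-off, amplitude from the peak at mid-range recovery, gray-matter rates)
plus uniform draws within bounds. Bounds: rates in [0, 2]/min; disjoint
boxes for the three plasma decay rates enforce their ordering;
$r_b \in [0.2, 1]$, spillovers in [0, 0.6], $r_t \in [0.5, 1]$. On
noise-free degraded pairs the fit recovers the true input to ≲2% relative
RMSE; the packaged check requires ≤5% in ≥9 of 10 draws.

### MCIF-net

The learned alternative maps normalized IDIF sequences directly to MCIF
sequences: stacked LSTM blocks of increasing width with one bidirectional
GRU block before the last LSTM, dropout between blocks, and a
time-distributed affine head; MSE loss, Adam. The full-scale default is
LSTM 50→100→200 with a 100-unit Bi-GRU, dropout 0.2, 1000 epochs, batch
32; the packaged benchmark uses a reduced net (24/24 units, 120 epochs) on
200 synthetic pairs. Normalization is per-sample min-max by the *input*
curve's range, and predictions are de-normalized with that same scale, so
the network's job includes restoring the suppressed peak (targets exceed
1). Both cells are implemented with exact backpropagation through time
(verified against numerical directional derivatives). The benchmark
requires the net to beat the no-correction baseline (IDIF vs true MCIF) in
held-out MSE and in downstream |Ki| error; measured gaps are roughly 5×
in MSE and 1.5–2× in Ki error.

## Patlak analysis and z-scores

For frames with mid-time ≥ $t^*$ (default 1200 s — FDG metabolism
equilibrates 15–20 min post injection; configurable), the Patlak plot
regresses $C_t/C_p$ on $\int_0^t C_p/C_p$. Because the sampled values are
frame averages, the running integral is computed as the exact frame sum
$\sum v_i \Delta t_i$ up to each frame mid (a trapezoid on mid-times
undersamples the bolus peak and biases Ki by up to ~1%; irregular grids
fall back to trapezoids). Two method properties worth knowing:

* the equilibration transient decays like $e^{-(k_2+k_3)t^*}$, so at
  $t^* = 1200$ s the fitted slope carries an intrinsic negative bias that
  stays within 2% for cortical gray-matter washout ($k_2+k_3 \gtrsim
  0.2$/min) but grows to ~4% by $k_2+k_3 = 0.13$/min — slow-washout tissue
  needs a later $t^*$;
* a global scale error in the input function multiplies all Ki by the same
  factor, so regional z-scores are invariant to it — the z-map is robust
  to precisely the degradation mode the MCIF scale anchor addresses.

`ki_map()` runs the regression voxelwise (fully vectorized — the regressor
depends only on the shared input function), clips negative slopes to zero
on the map, and excludes those voxels from regional means.
`regional_zscores()` standardizes the 36 regional mean Ki values against
their own mean and sample SD (the normalization population is the region
means, not voxels) and flags $z < -2$. With all regions equal the SD is
zero and the function refuses rather than divides.

The end-to-end check generates phantoms with one region's Ki reduced by
exactly 30% (via `inject_hypometabolic_region()`, which rescales $k_3$ and
$K_1$ so the reduction is exact), runs the full pipeline — motion
correction, frame selection, classical segmentation, IDIF, fitted MCIF,
Ki map, z-report — and requires the lesion flagged in ≥9/10 seeds with no
false flag in ≥8/10.

## Problem sizes and numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| Phantom grid | 64³ @ 2 mm | `phantom_spec()` |
| Kinetic fine grid | 0.1 s (0.5 s in fits) | `two_tissue_tac()`, `fit_mcif()` |
| Frame quadrature | ≥128 points/frame (callable); exact cumulative trapezoid (gridded) | `frame_average()` |
| MCIF fit | 11 outer + 4 projected parameters, ≤400 iterations/start | `fit_mcif()` |
| U-Net benchmark | 16 subjects, 5 folds, depth 3, 8 filters, 8 epochs, 32³ crops | acceptance suite |
| MCIF-net benchmark | 200 train / 40 held-out pairs, 24/24 units, 120 epochs | acceptance suite |
| Localization check | 10 seeds, 30% lesion, region 7 | acceptance suite |
| Dice smoothing / BCE clip | 1e-5 / 1e-7 | `combined_loss()` |
| Connectivity | 26-neighbourhood | `threshold_islands_segment()` |
| Probability threshold | 0.5 | `predict_mask()` |

## Known limitations

* The scale anchor assumes the carotid neighbourhood is blood + tissue
  only; near air or bone (not modelled in the phantom) $r_b + s_t < 1$ and
  the recovered MCIF would carry a scale error — which regional z-scores,
  but not absolute Ki, are immune to.
* The Gaussian-PSF, Gaussian-noise phantom does not emulate reconstruction
  correlations, scatter, or attenuation artifacts; learned components are
  trained and validated on the same generative family.
* Patlak assumes irreversible trapping; $k_4 > 0$ bends the plot (the test
  suite checks the $r^2$ degradation but the map does not correct for it).
* Training the full-scale networks (128³ inputs, 64–512 filters;
  LSTM 50→100→200) is supported by the configuration objects but is far
  beyond a single-CPU session; all packaged evidence comes from the
  reduced benchmarks above.
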