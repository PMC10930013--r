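---
title: "Residual-learning quantum-noise removal for thin-slice CAC CT: models, calibration and design choices"
author: "CACdenoise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
denoising model, the phantom simulator that stands in for physical phantoms,
the calibration behind its defaults, the numerical conventions, and the
limits of what the synthetic study can show about real scanner data.

## 1. The denoising model

Thin-slice CAC reconstructions trade partial-volume averaging for quantum
noise: for filtered-back-projection images the noise SD scales as
$1/\sqrt{z \cdot \mathrm{mAs}}$ with slice thickness $z$. The package removes
that noise by *residual learning*: instead of mapping a noisy image to a
clean image (which tends to over-smooth, since the network must reproduce
anatomy), a network estimates the **noise itself**, and denoising is a
subtraction,

$$I_\mathrm{denoise}^z = I^z - \sigma_\mathrm{CNN}^z .$$

Two noise maps drive training:

* the **real map** $\sigma_\mathrm{real}^z = I^z - I^{3\mathrm{mm}}$, the
  label — it contains essentially no anatomy because both reconstructions
  share the same noise-free content;
* the **pseudo map** $\sigma_\mathrm{pseudo}^z = I^z - U(D(I^z))$, the
  input — $D$ averages 2×2 pixel blocks (512² → 256²) and $U$ upsamples
  back bicubically, so the map is a high-pass view of the slice that is
  computable *without* a 3-mm reference at inference time.

The estimator is a small fully convolutional DenseNet-style regressor:
an initial 3×3 convolution, dense blocks whose 3×3 layers concatenate their
outputs with all earlier features, a 1×1 transition after each block, and a
3×3 reconstruction layer to one channel. Zero padding keeps the output on
the input grid, so a patch-trained model evaluates on whole 512×512 maps
with no tiling seams (verified against a tiled-with-halo computation in the
tests). Weights are MSRA-initialised ($\mathcal{N}(0, 2/\mathrm{fan_{in}})$,
zero biases), the loss is RMSE in HU, and optimisation is Adam with
minibatch 32, learning rate $10^{-4}$, first-moment decay 0.9 and weight
decay $10^{-4}$.

Interpretation choices where the training recipe leaves room:

* "momentum 0.9" is read as Adam's first-moment decay $\beta_1$ (Adam has no
  classical momentum); $\beta_2$ is fixed at 0.999;
* weight decay is decoupled L2 on convolution weights only, not biases;
* patches are fed in HU without normalisation (an affine pre-scaling hook
  exists in the code but is off by default);
* one model is trained per thickness $z$ and `denoise()` refuses a
  thickness mismatch — the per-$z$ notation of the workflow suggests per-$z$
  models, and mixing them silently would be an analysis error.

The exact published topology constants are not part of the package's claims;
`denseNetConfig()` defaults to a desk-scale network (4 blocks × 4 layers,
growth 12, ≈0.1 M parameters) and the test profile uses a smaller one
(2 × 3, growth 8) that trains in minutes on one CPU.

## 2. The phantom simulator

The simulator replaces the physical phantoms with parametric geometry plus a
measured material table.

**Geometry.** Electron density phantoms CIRS_S/M/L (circle 180 mm, circle
230 mm, ellipse 320×270 mm) carry nine 30-mm tissue-equivalent rods — one
central (liver) and eight on a 60-mm ring. The rod-removal acquisition
protocol scans configurations 0..4, removing one designated opposite pair of
ring rods per step (9, 7, 5, 3, 1 rods; 3 phantoms × 5 scans = 15 training
datasets). Which pair leaves at each step is not physically constrained, so
the order is a fixed package convention (`removalRank` in the insert table).
Thorax phantoms QRM_S/M/L (ellipses 300×200, 350×250, 400×300 mm) carry a
calibration insert with nine cylindrical calcifications, 3 diameters (1, 3,
5 mm) × 3 hydroxyapatite densities (200/400/800 mg/cc), on a 30-mm ring.
Tube currents are the protocol values: 40/80/300 mA (CIRS) and 40/50/140 mA
(QRM).

**Materials.** Mean HU and 3-mm noise SD per material and phantom size come
from measured reference tables (e.g. liver 71.83 HU / 24.31 HU SD in
CIRS_S). The calcification *noise* SD is set bone-like (40 HU at the 3-mm
anchor): the much larger HU spread seen inside a thresholded calcification
ROI is a partial-volume gradient, not quantum noise, and it emerges here
from rasterisation rather than being injected as noise. Air gets a modest
12 HU anchor SD. The water/soft-tissue body SD is taken from the
corresponding soft-tissue row of each phantom's table, so body noise grows
with phantom size as measured.

**Rasterisation.** Pixels take the HU of the innermost containing primitive
(air outside the body at −1000 HU). Boundaries use 4× supersampled
area-weighted blending, because the small calcifications (2-12 pixels
across at the 0.43-mm pixel pitch) are boundary-dominated; the noise-SD
field is blended on the variance scale. Rasterisation is deterministic.

**Noise.** Each thin slice receives a zero-mean correlated Gaussian field:
white noise is low-pass filtered in Fourier space with an isotropic Gaussian
transfer function (autocorrelation FWHM 2 px by default, a smooth
soft-kernel-like mottle) and normalised analytically to unit variance, then
scaled pixelwise by the material SD field times the quantum-noise factor
$\sqrt{3\,\mathrm{mA_{ref}} / (z\,\mathrm{mA})}$. The 3-mm image is the
exact pixelwise mean of the $n = 3/z$ thin realisations, so thin and thick
share their noise-free content bit-for-bit.

**Inter-slice correlation.** Measured thin/3-mm SD ratios (for example
34.08/25.29 ≈ 1.35 for muscle at $z = 1.5$) are *below* the
independent-slice prediction $\sqrt{2} = 1.41$, so adjacent slices share
noise. The simulator models this with a shared-field fraction `rho`: slice
$i$ gets $\sqrt{\rho}\,u + \sqrt{1-\rho}\,v_i$ with $u, v_i$ independent
unit fields. The ratio law is $\sqrt{2/(1+\rho)}$ at $z=1.5$, and
`rho = 0.10` reproduces 1.35 exactly; the same value predicts ratios within
a few percent at 1.0 and 0.5 mm. `rho = 0` is the independent-slice mode,
in which the SD follows $1/\sqrt{z}$ exactly and the 3-mm SD sits at the
anchor value — that mode is what the scaling tests check.

**Seeds.** All randomness flows through explicit seeds; dataset $i$ of the
acquisition protocol uses `baseSeed + i`, so any single dataset is
regenerable. RNG state of the session is restored after every simulator
call.

## 3. Patch construction

Pseudo/real map pairs are cut into co-located 25×25 patches at stride 25
from the map origin; a 512×512 map yields a 20×20 patch grid (400 pairs)
and the residual 12-pixel right/bottom margin is discarded — the simplest
tiling consistent with a 25-pixel stride without overlap. Provenance
(dataset, row, column) is carried per patch and permits exact reconstruction
of every patch origin; shuffling is a seeded permutation applied identically
to inputs, labels and provenance. One 15-dataset protocol run at one $z$
yields 6 000 patch pairs; the published corpus size (~70 000 sub-images,
counting inputs and labels over several slices per dataset) is not exactly
recoverable from the protocol description, so the generator simply reports
its own exact count.

## 4. Numerical conventions

* **Bicubic upsampling**: separable Keys kernel with $a = -0.5$, half-pixel
  centre alignment (each 2×2 output block's mean sits at its source pixel
  centre, matching the block-average downsample), edge replication at the
  borders. Interior weights are dyadic rationals summing to 1 exactly, so
  constants are reproduced to machine precision and the pseudo map of a
  constant image is zero.
* **Subtraction closure**: $I^z - \sigma_\mathrm{real} = I^{3\mathrm{mm}}$
  holds to machine precision (a handful of ulps), not bitwise — IEEE-754
  does not guarantee $a - (a - b) = b$.
* **PSNR**: $20\log_{10}(\mathrm{HU_{max}}/\mathrm{RMSE})$ with
  $\mathrm{HU_{max}}$ the reference-image maximum, so different candidates
  are compared against a common ceiling; identical images report `Inf`.
* **t-tests**: Welch (unequal variance), two-sided, significance at
  $p < 0.01$ — thin and 3-mm images have demonstrably different variances,
  so the pooled test would be mis-specified.
* **Thresholding**: calcification pixels are HU ≥ 130 (boundary included);
  Agatston bins are half-open upward (200/300/400 land in the higher bin).
  `dice(∅, ∅) = 1` by convention (perfect agreement on absence).
* **ROIs**: rod ROIs are circles at the rod centre with radius 2/3 of the
  rod radius (10 mm), clear of boundary partial volume; the thorax
  background ROI is a 10-mm circle at the calibration-insert centre (no
  calcification sits there); per-calcification regions are discs with a
  2-mm halo used to localise Dice comparisons. 1-mm calcifications are
  excluded from reference-based evaluation — they are undetectable on 3-mm
  images.
* **Storage**: HU are floating point throughout; quantisation (signed
  16-bit, half-to-even rounding, slope 1/intercept 0) happens only at DICOM
  export. The array-container backend is lossless.

## 5. Problem sizes used by the tests

The shipped test profile runs the whole workflow at a reduced scale chosen
to exercise every stage faithfully on one CPU: one training phantom
(CIRS_S, all five rod configurations, $z = 1.5$ mm, 2 000 patch pairs), a
2-block × 3-layer growth-8 network, 1 500 Adam iterations, and one held-out
QRM_S series for validation. Statistical checks (SD scaling, ROI means) use
ROIs of $10^4$–$4\times10^4$ pixels, where the Monte-Carlo error of an SD
estimate under the 2-px-correlated noise is ~1–2%.

## 6. What the simulator does and does not emulate — and a performance bound

The simulator reproduces the features the method depends on: paired
thin/3-mm reconstructions with shared anatomy, material-dependent
heteroscedastic correlated noise calibrated to measured SDs and thin/thick
ratios, in-plane partial volume on small calcifications, and the
acquisition protocol's dataset structure. It deliberately omits sinogram
physics (no FBP reconstruction, beam hardening, streaks or windmill
artifacts), tube-current modulation dynamics, cardiac motion/ECG gating,
and **through-plane partial volume** — thin and 3-mm images share one 2-D
anatomy by construction, so the 1-mm-calcification invisibility on 3-mm
images is enforced as a protocol rule rather than emerging from z-blur.
Passing tests therefore demonstrate the correctness and internal
consistency of the pipeline under a controlled noise model, not clinical
performance on scanner data.

One quantitative consequence of the noise model is worth stating plainly.
The pseudo map only retains frequencies the 2×2-block/bicubic smoother
removes (roughly above 0.25 cycles/px), while a FWHM-2px Gaussian noise
field has most of its variance below that band; and at $z = 1.5$ the label
$\sigma_\mathrm{real} = (n_1 - n_2)/2$ contains a co-slice term $n_2$ that
is statistically independent of the input. An empirically estimated optimal
linear (Wiener) predictor on simulated pairs achieves a residual RMSE of
about 17.5 HU against a label RMS of about 20 HU — i.e. only ~25% of the
label variance is predictable under these study conditions. The trained
network plateaus at ~18 HU, essentially at that bound, and the denoised
images show exactly the qualitative behaviour expected from a near-optimal
estimator: every flat-ROI SD decreases, ROI means shift by well under 5 HU,
and Dice agreement of thresholded calcifications with the 3-mm reference
improves or ties for every 3/5-mm insert. On real FBP data, whose noise
power spectrum is band-pass rather than low-pass, a larger fraction of the
noise lives in the pseudo map's band and deeper loss reductions are
attainable; the simulator's Gaussian mottle is the conservative case.

## 7. Known limitations

* Single-slice 2-D simulation; no volumetric stacks or through-plane
  effects.
* The DenseNet topology is a configurable stand-in at desk scale, not a
  replica of any specific published network.
* The DICOM backend implements a minimal single-frame explicit-VR-little-
  endian CT object (it round-trips with itself and parses in pydicom); it
  is not a general DICOM toolkit.
* The Agatston analysis counts pixels per weighting bin; it is not a
  clinical per-lesion Agatston score (no connected components or 3-mm
  axial scoring rules).
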