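---
title: "Methods: amyloid-PET lesion segmentation on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amyloid-PET lesion segmentation on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Amyloid PET with tracers such as ^18^F-flutemetamol visualizes beta-amyloid
plaque deposition, a pathological hallmark of Alzheimer's disease. Clinical
reads score five regions — the frontal lobe, posterior cingulate cortex and
precuneus, lateral temporal lobe, inferolateral parietal lobe, and striatum
— as amyloid-positive or -negative by visual assessment on a color scale.
That assessment depends on reader experience and on scanner- and
reconstruction-dependent intensity scales, which motivates (a) normalizing
intensities to a reference region and (b) delegating the delineation of
positive regions to a segmentation network.

`amypetseg` implements that pipeline end to end — reference-region
normalization, threshold-derived gold-standard masks, a 2D U-Net trained
with a soft-IoU loss, hemispheric-swap post-thresholding, and a
confusion-matrix evaluation suite — and pairs it with a seeded synthetic
brain-phantom generator so every stage is testable without clinical data.

## Pons-ratio normalization

Voxel intensities are divided by the arithmetic mean over a pons mask, so
the reference region sits at exactly 1 afterwards. The pons is a standard
reference for flutemetamol because it shows no specific amyloid binding.
The statistic is the plain mean — the convention for SUVR reference
regions; the operation is idempotent and invariant to global rescaling of
the input, and both properties are asserted in the test suite.

## Ground truth by zone-restricted thresholding

Clinical gold standards for this task are produced semi-automatically:
a reader delineates the zone, and within it the lesion is the set of voxels
above a fixed multiple of a background level. Here the background level is
the mean over an explicit background-reference region (a cerebellar-gray
surrogate in the phantom), and the rule is

> lesion = zone AND (intensity > 1.5 x background).

Two numerical choices are deliberate and covered by tests: the inequality
is *strict* (a voxel exactly at threshold is excluded), and the output is
always a subset of the zone mask. The post-processing threshold (1.3x, see
below) is an independent configuration value, not reconciled with the 1.5x
ground-truth factor: the two factors serve different stages.

## The synthetic phantom

`default_phantom_spec()` lays out the five zones as parametric
ellipsoid unions with the right *topology*, not anatomy: four bilateral
pairs mirrored about the mid-sagittal plane (so every lesion has a
contralateral homologue for hemispheric swaps), one midline posterior
PCC/precuneus zone, a midline pons, and a separate background-reference
region. Intensities are background (1.0) everywhere, `uptake_ratio` x
background (default 2.0) in positive zones; then an isotropic Gaussian
point-spread blur (FWHM 3.0 mm at 2.0 mm voxels, matching a typical
post-reconstruction filter) and additive Gaussian noise (sigma 0.05,
clamped at zero). The additive-Gaussian noise model is the weakest
assumption available — no noise model is prescribed for the clinical data —
and the sigma was fixed once at a visually plausible contrast-to-noise
level. Geometry jitter (±1.5 voxels on centers and semiaxes, seeded,
symmetry-preserving) emulates anatomical variability across subjects.

What the phantom does *not* emulate: attenuation/scatter artifacts,
anatomical texture, partial-volume effects beyond the Gaussian PSF,
off-target binding, or asymmetric lesions. Passing tests on phantoms
therefore demonstrate that the pipeline machinery (normalization, truth
derivation, optimization, post-processing, evaluation) is correct and
recovers known generating parameters — not that the network would reach
clinical accuracy on patient data.

The default test-scale matrix is 64 x 64 x 40; clinical-scale 256 x 256
matrices are supported by the same code path (`resize_volume()` provides
the linear-interpolation resizing used to bring clinical volumes to a
common grid).

## The network

A symmetric 2D U-Net (`unet_config()`): per contracting stage two 3 x 3
same-padded convolutions each followed by ReLU, then 2 x 2 max-pooling;
a two-convolution bottleneck; per expanding stage a 2 x 2 stride-2
transposed convolution, concatenation with the matching encoder features,
and two 3 x 3 convolutions; finally a 1 x 1 convolution onto two classes
and a per-pixel softmax. Same-padding keeps predictions aligned with the
input slice so they can be overlaid directly. The depth-2 configuration
has the canonical 11 convolutional layers. Channel widths are this
package's choice (base 8, doubling per stage) since no width schedule is
prescribed anywhere; `n_parameters()` reports the resulting count and is
checked against a closed-form layer-by-layer oracle in the tests.

The forward and backward passes are implemented natively on BLAS matrix
products: convolutions gather im2col patch matrices (cached index
tables) and multiply; the input gradient of a same-padded convolution is
computed as another gather-GEMM against the 180°-rotated,
in/out-transposed kernel, avoiding scatter operations entirely. Gradients
of every layer are verified against central finite differences (agreement
to ~1e-11 on desk-scale configurations, asserted at 1e-4).

## Losses

Training minimizes the soft-IoU (Jaccard) loss

$$L = 1 - \frac{\sum_i p_i g_i}{\sum_i p_i + \sum_i g_i - \sum_i p_i g_i}$$

with \(p_i\) the foreground softmax probability and \(g_i\) the binary
gold standard. The *soft* intersection (probabilities, not a binarized
map) keeps the loss differentiable; on binary inputs it equals one minus
the Jaccard index exactly, and the test suite asserts this duality
bitwise on 1000 random mask pairs. IoU is preferred over plain
cross-entropy because the five zones occupy a small fraction of each
slice, and the Jaccard objective is invariant to that class imbalance.
A two-class cross-entropy term for the pathological-state (positive /
negative) head is exposed as `lambda_ce` (default 0, segmentation-only):
no combination weight is prescribed, so the package trains pure Jaccard
by default and provides slice-level classification via `classify_slice()`
on the predicted mask instead of a separate classifier subnetwork.

Degenerate cases are defined, not left to NaN: empty-prediction vs
empty-mask is loss 0 / IoU 1 (a correct empty prediction), with a warning
in the user-facing functions and silently inside the training loop, where
amyloid-negative slices make this routine.

## Augmentation and splitting

Augmentation draws, per image per epoch, a rotation in [−10°, +10°],
x/y translations in [−0.1, 0.1] of the image extent, and a shear in
[−10°, +10°] — the closed ranges are enforced. One affine transform is
applied identically to image (bilinear) and mask (nearest-neighbour, so
masks stay binary), with out-of-bounds pixels filled with 0 (background
is near zero after standardization). Augmentation is applied online
rather than by pre-expanding the dataset. The train/validation split is
a seeded random partition with `round(0.8 n)` training items.

## Post-processing

Predicted probability maps are binarized at a strict 0.5, dilated with a
3 x 3 square (3 x 3 x 3 cube when run volumetrically — the network is 2D,
so the square is the default), and filtered by the hemispheric-swap rule:
the slice is mirrored about the left-right axis (array dimension 1 by the
package's coordinate convention), the mean intensity under the mirrored
predicted mask defines a subject-internal reference, and only pixels
strictly above 1.3 x that reference survive. The 1.3 factor is applied to
*normalized intensities* under the mirrored mask (not to probabilities) —
the procedure mirrors how the ground-truth thresholding operates on
intensities; this interpretation is flagged here because the source
protocol wording admits both readings. For sagittal slices there is no
in-plane left-right axis; the pipeline uses the swap on axial and coronal
planes, and a contralateral sagittal slice would have to be supplied
explicitly.

## Training protocol and problem sizes

The clinical-scale defaults are Adam, learning rate 1e-5, batch size 4,
up to 2000 epochs, one network per (zone, plane) pair. The bundled demo
(`demo_config()`) is desk-scale: 8 phantoms of 64 x 64 x 40 (≈ 85 axial
slices through the frontal zone, split 68/17), a depth-2/8-channel U-Net
(~37k parameters), Adam at 1e-3, batch 4, at most 120 epochs with early
stopping after 15 epochs without validation-IoU improvement. The larger
learning rate is deliberate: at 1e-5 the small network on the easy phantom
task would spend thousands of epochs traversing the same monotone path;
1e-3 is standard Adam practice at this scale and converges in under 100
epochs. With seed 1 the demo early-stops at epoch 64 with mean validation
IoU 0.987.

Determinism: every stochastic step (phantom noise, geometry jitter,
weight init, batch shuffling, augmentation draws) is seeded from the run
seed; reruns are bit-identical, which the test suite asserts on histories
and metric files.

## Known limitations

- Phantom realism as above; headline phantom IoU values are not
  comparable to clinical per-zone IoUs.
- The 2D network treats slices independently; no 3D context.
- `classify_slice()` is a rule on the segmentation output, not a trained
  classification head.
- The hemispheric-swap rule assumes approximately symmetric background
  uptake; strongly asymmetric pathology would defeat the contralateral
  reference (a known property of the method, not of this implementation).
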