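---
title: "Rodent brain extraction with a 3D U-Net: models, phantoms and design choices"
author: "ratbex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rodent brain extraction with a 3D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Skull stripping — separating brain tissue from scalp, skull and
background — is the first consequential step of almost every rodent MRI
pipeline. Rodent heads are a harder target than human heads: the
brain-to-scalp distance is small relative to voxel size, high-field
acquisitions carry strong bias fields from surface coils, and most
laboratories still draw brain masks slice by slice. `ratbex` implements
an automatic brain-extraction pipeline for isotropic rat brain MRI built
around an encoder–decoder convolutional network (U-Net) with fully 3D
convolutions, trained with a soft Dice loss on randomly cropped
volumetric patches and applied to whole volumes by overlap-averaged
sliding-window inference.

The network is implemented natively in this package (R with C++
kernels for the im2col unfolding, max pooling and strided transposed
convolution; BLAS matrix products for the convolutions themselves),
including the backward pass, the Adam optimiser and global
gradient-norm clipping. The backward pass is verified against central
finite differences in the test suite.

## Pipeline and model

For a raw volume the pipeline is:

1. **Min–max intensity normalisation** to [0, 1].
2. **Nearest-neighbour (NN) resampling** to a 0.2 mm isotropic working
   grid. NN is used in both directions because the labels are binary;
   the output grid size per axis is `round(size × spacing / target)`,
   with voxel-centre physical coordinates and 0-based indices. If the
   resampled matrix is smaller than the patch along any axis, the
   working spacing is halved until the patch fits.
3. **Sliding-window prediction**: patches are tiled at a configurable
   stride (default one quarter of the patch edge, i.e. 16 for 64³
   patches and 4 for 16³); per-axis offsets are `0, s, 2s, …` plus a
   final offset clamped to `size − patch` so no patch leaves the
   volume. Every voxel's probability is the arithmetic mean of all
   patch predictions covering it (uniform weights; the accumulated
   coverage count divides a running sum, so the weights at each voxel
   sum to exactly one).
4. **Thresholding** at 0.5 with a strict `>` at the working resolution,
   then NN resampling of the binary mask back onto the exact native
   grid.

The network follows the classic U-Net layout. Encoder level *l* applies
`convs_per_block` (default 2) repetitions of 3³ convolution (stride 1,
zero padding 1) → batch normalisation → ReLU, followed by 2³ max
pooling between levels. The reference rodent configuration uses
encoder channels 32/64/96/128/256 on 64³ patches. The decoder mirrors
the encoder: a kernel-2 stride-2 transposed convolution doubles the
resolution, the same-scale encoder output is concatenated along
channels, and two conv–BN–ReLU blocks follow. A final 1×1×1 convolution
with a sigmoid produces per-voxel brain probabilities. Both 2D and 3D
variants share the code path; the 2D variant applies the same machinery
slice by slice at prediction time.

Architectural gaps in the published figure were resolved as follows
(and are configurable where reasonable):

* convolutions per block: 2, kernel 3, stride 1, zero padding 1;
* upsampling: transposed convolution with stride 2, matching the
  original volumetric U-Net lineage;
* batch-norm placement: conv → BN → ReLU;
* a 16³-patch model cannot support five resolution levels
  (16/2⁴ = 1 voxel); the 16³ variant therefore uses four levels
  (32/64/96/128), and the same rule is enforced for any configuration:
  every patch edge must be divisible by 2^(levels−1) with at least 2
  voxels at the bottleneck;
* decoder channel widths mirror the encoder level widths after each
  concatenation.

## Training

Training draws random patches whose offsets are uniform over all
positions where the patch fits entirely inside the volume; image and
mask are cropped congruently. Optimisation uses Adam with initial
learning rate 1e-3 and batch size 16, with all parameter gradients
clipped to a maximum global L2 norm of 1 per step. The loss is the soft
Dice loss

$$L = 1 - \frac{2\sum_i p_i t_i + s}{\sum_i p_i + \sum_i t_i + s},$$

with smoothing constant $s = 1$ by default (configurable); Dice loss is
used instead of cross-entropy specifically because brain voxels are a
minority class and Dice is insensitive to that imbalance, so no class
weighting is applied. Per-sample losses are averaged over the batch.

The split protocol holds out 20% of subjects as a fixed test set
(`n − floor(0.8 n)`), then repeatedly re-partitions the remaining pool
into fit (`floor(0.8 · pool)`) and validation subjects; with 87
subjects this gives the 18/55/14 test/fit/validation sizes. Across
repeated trainings the model with the highest mean validation score is
selected, ties breaking toward the lowest repeat index. "Validation
accuracy" is computed as whole-volume validation Dice through the same
sliding-window inference used at test time (voxel accuracy is also
logged); the weights of the best validation epoch are returned. Epoch
count is not part of the reference protocol, so training runs for a
configurable `max_epochs` with early stopping on validation Dice.
`patches_per_epoch` defaults to 10× the number of fit subjects.
Validation inference defaults to non-overlapping tiles (stride = patch)
purely for speed; the final evaluation can use any stride.

With fixed seeds the whole training loop is reproducible on CPU to
bitwise identity; all randomness (initialisation, patch sampling,
phantom generation, noise draws) flows from explicit seeds.

## The phantom generator

Real acquisitions (the public CAMRI rat dataset this pipeline was
designed around) are never required: a phantom module generates paired
image/mask volumes emulating a rodent head. The model is deliberately
minimal — a bright brain ellipsoid, a darker skull shell and a brighter
scalp shell over near-zero background, modulated by a smooth random
second-order polynomial multiplicative bias field (amplitude 10% by
default, emulating RF coil inhomogeneity), min–max normalised, plus
additive Gaussian white noise. The ground truth is the voxelised brain
ellipsoid of the noiseless model, so it is exactly invariant to noise
and bias settings.

Defaults are the package's study conditions:

* unit-test grid 64×64×48 at 0.2 mm isotropic (semi-axes
  4.8/4.0/3.2 mm);
* cohort grid 96×80×72 at 0.2 mm with base semi-axes 7.4/6.2/5.4 mm
  (~1040 mm³) and 4% per-subject jitter of semi-axes and tissue
  intensities, keeping brain volumes within 900–1300 mm³ — the adult
  rat range;
* tissue intensities background/skull/scalp/brain =
  0.03/0.15/0.45/0.85;
* noise variance 1.4e-3 on the normalised scale. The normalised brain
  signal sits near 0.97, so this puts the clean-image SNR (mean of two
  1 mm signal spheres at the volume centre over the standard deviation
  of two 1 mm background spheres) at about 26, the typical value for
  the acquisitions this pipeline targets.

What the phantom does **not** emulate: MR physics (no k-space, Rician
noise, or EPI distortion), anatomical detail (olfactory bulb,
brainstem, ventricles), partial-volume texture, or realistic
skull/scalp contrast variation. Passing phantom tests therefore
demonstrates that the pipeline's machinery — geometry handling,
optimisation, stitching, metrics — is correct and that the network can
learn a contrast-defined boundary under bias and noise; it does not
certify segmentation accuracy on real rodent data.

## Evaluation metrics

Comparisons between a predicted voxel set *B* and a ground-truth set
*A* report Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|`, positive
predictive value `|A∩B|/|B|`, sensitivity `|A∩B|/|A|`, the
centre-of-mass distance in physical mm, and the Hausdorff distance
`max{h(A,B), h(B,A)}` with `h` the directed max–min Euclidean distance.
Hausdorff is evaluated in-plane per slice along the acquisition axis
(the third stored axis by default, configurable) and the worst slice is
reported, in mm. Design details worth knowing:

* Hausdorff point sets are all mask voxels rather than an extracted
  boundary; for solid shapes the worst-slice max–min value is the same
  and the brute-force oracle in the tests covers exactly this
  definition.
* Slices where exactly one mask is empty are skipped rather than
  assigned infinity (an infinite value would dominate the maximum,
  whereas reported reference values are finite); if no slice has both
  masks non-empty an error is raised.
* Metrics whose denominator is empty are reported as `NA` with an
  explanatory note, never silently as 0.
* Metrics are computed at whatever resolution the masks share — in the
  full pipeline, the native resolution of the raw image.
* The units of the in-plane Hausdorff are mm; published values around
  4.3–4.7 for this task do not state units, so comparisons should be
  made with that ambiguity in mind.

## Robustness harnesses

Two desk-scale experiments mirror the published robustness analyses:

* **Noise sweep**: Gaussian white noise with variance 5e-5 … 5e-4 in
  steps of 5e-5 is added to normalised test images (independent draws
  per image and per level; images are not re-normalised afterwards),
  SNR is estimated per subject from the spherical VOIs and averaged,
  and segmentation Dice is scored per level (mean ± standard error
  across subjects). The sweep fixtures use noiseless phantoms so the
  ladder is the only noise source and the SNR trend is attributable to
  it.
* **Sample-size sweep**: for each training-set size on a ladder, fresh
  models are trained from scratch on subjects drawn without
  replacement, repeated with independent draws, and scored on a fixed
  held-out test set (mean ± SE across repeats). A leakage check
  refuses cohorts that share subjects with the test set.

## Desk-scale problem sizes

The package's default experiment sizes are chosen so that everything —
training included — runs on a single CPU: the desk preset is the
4-level 16³-patch 3D U-Net with reduced-width channels 12/24/36/48,
trained on 8 phantom subjects with 2 validation and 2 held-out test
subjects for up to 10 epochs. The width was chosen for convergence
robustness: a quarter-width variant (8/16/24/32) reaches the same
accuracy on most seeds but occasionally plateaus near Dice 0.8 within
the short desk-scale optimisation budget, whereas 12/24/36/48
converges to validation Dice above 0.95 across the seeds examined
while still training in a few minutes. The learning-curve harness uses
the small phantom grid with training ladders of 2/4/6 subjects, 2
repeats, and the narrower 8/16/24/32 model (many models are trained,
and brief training is exactly the regime where the learning curve is
informative); the noise sweep uses 3 noiseless compact phantoms with
inference at stride 16. The full-scale variants (64³ patches,
channels up to 256, 55 training subjects) are expressible with the
same configuration objects and are exercised structurally
(construction, shape contracts) rather than trained.

## Known limitations

* The native network is CPU-oriented; no GPU path exists, so
  full-scale training on real cohorts is out of reach here.
* Bias-field correction is not included; input volumes are expected to
  be bias-corrected externally if needed (the pipeline's normalisation
  is a plain min–max).
* No post-processing (connected components, hole filling) is applied —
  the raw network output is reported.
* Binarisation happens at the working resolution before the mask is
  resampled back to the native grid; with a strict `>` threshold, ties
  at exactly 0.5 go to background.
* The phantom's simplicity means phantom Dice values are optimistic
  relative to real data.
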