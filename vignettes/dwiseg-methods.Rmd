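---
title: "Segmenting acute ischemic lesions in DWI with a two-stage convolutional cascade"
author: "dwiseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting acute ischemic lesions in DWI with a two-stage convolutional cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute ischemic stroke lesions appear hyperintense on diffusion-weighted MR
imaging (DWI). Delineating them matters clinically — lesion volume and
location feed directly into treatment decisions — but manual segmentation
is slow and requires expertise. Automatic segmentation is hard for two
reasons that dominate everything in this package's design:

* **Extreme size variation.** Lesions range from a few pixels to hundreds,
  can occur anywhere in the brain, and the small ones carry activations so
  weak that ordinary encoder-decoder architectures lose them during
  down-sampling.
* **Bright artefacts.** Air interfaces (sinuses, skull base) produce
  hyperintense blobs that locally look exactly like small lesions. They
  are the dominant source of false positives.

`dwiseg` addresses both with a two-stage cascade:

1. **Stage 1 — an ensemble encoder-decoder network.** Each branch is a
   DeconvNet-style encoder-decoder: stacks of 3x3 stride-1 convolutions
   (batch normalisation + ReLU) separated by 2x2 max poolings that
   *record the location of each window maximum*; the decoder mirrors the
   encoder and upsamples with *unpooling*, scattering each pooled value
   back to its recorded position. This pooling-mask route is the crucial
   design element: a small lesion whose activation survives pooling is
   reconstructed at exactly its original location, where bilinear
   upsampling would smear it away. N branches (default 2) are initialised
   with independent seeds, so they converge to different optima; their
   softmax maps are fused by the pixel-wise arithmetic mean (the "naive
   ensemble" h), and a refinement head — the input image concatenated
   with h, followed by a few 3x3 convolutions — produces the final
   stage-1 map H. Training minimises a deeply supervised loss: the sum of
   per-pixel cross-entropies of H, h and every branch, with weights
   lambda all 1 by default.
2. **Stage 2 — multi-scale candidate evaluation.** The stage-1 map is
   thresholded (0.5) and connected components are extracted slice-wise
   with 8-connectivity. Components of at most 60 px — the size range that
   contains essentially all false positives — become candidates. For each
   candidate, square windows of sides s, 2s and 4s (s = max(bounding-box
   side, 8)) are cut from the image around the centroid, plus the
   s-window of the probability map; all four are resized to 16x16 and
   stacked. A small VGG-style classifier (4 convolutions, 1 pooling,
   3 fully connected layers) scores each candidate, and the instance
   probability q is fused back into the pixel map as independent
   evidence: the per-pixel lesion odds are multiplied by q/(1-q). q = 0.5
   is exactly neutral, q near 0 removes the component, and re-binarising
   at the same threshold yields the final mask. Large components always
   bypass evaluation, so the cascade can only ever shrink the stage-1
   mask — false-negative recovery is out of scope by design.

## Preprocessing and sampling

Clinical DWI is strongly anisotropic (5 mm slices, 1.4-1.8 mm in-plane),
so everything is 2-d and slice-wise; the slice axis is never resampled.
Slices are resampled in-plane to a uniform 1.6 mm pixel (bilinear for
images, nearest-neighbour for masks, output side `round(extent/1.6)`),
and each volume is normalised to zero mean and unit variance. The
normalisation statistics are computed over **all** voxels of the 3-d
volume: the alternative — brain-masked statistics — would need a brain
mask the pipeline otherwise does not require, and per-volume statistics
keep all slices of a subject on one scale.

Training patches are **lesion-anchored**: every lesion pixel generates
exactly one patch, with the anchor placed uniformly at random inside the
patch and out-of-slice regions zero-padded. This simultaneously
rebalances the label distribution (patches have a far higher lesion
fraction than whole slices), multiplies the number of training examples,
and keeps full-slice inference valid because the network is fully
convolutional. Augmentation applies horizontal flips (p = 0.5) and
rotations drawn from {0, 90, 180, 270} degrees; right angles are the
default because they permute pixels exactly and keep labels binary — a
continuous-angle variant (bilinear image, nearest-neighbour label) is
available behind a flag. Train/validation splits are always by subject.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nBranches` | 2 | ensemble size N |
| `convStacks` / `convsPerStack` | 3 / 2 | encoder depth; two poolings |
| `baseChannels` | 32 | width of the first stack, doubling per stack |
| `patchSize` | 64 px | training patch side |
| `learningRate` / `momentum` / `weightDecay` | 0.05 / 0.9 / 0 | SGD settings |
| `lambda` | all 1 | loss weights of H, h and the branches |
| binarisation threshold | 0.5 | argmax-equivalent for two classes |
| small-object limit | 60 px | components above it bypass stage 2 |
| stratification boundary | 37 px | "small" vs "large" lesion subjects |

The receptive field is computed by the standard recursion over the layer
sequence (3x3 convolution: +2 x jump; pooling: +1 x jump, jump x2;
mask-driven unpooling: jump /2, no extent — each fine pixel descends from
exactly one pooled cell). With the full defaults this gives 60 px against
a 64 px patch; a configuration with one convolution per stack gives
exactly 32 px, and that patch-equals-receptive-field operating point is
the one used throughout the test suite at patch size 32.

## What the phantom emulates — and what it does not

Because clinical DWI cannot ship with the package, a synthetic phantom
generator makes every stage trainable and testable. Each subject is an
elliptical "brain" (tissue intensity ~1 over air ~0, with smooth
Gaussian-blurred texture and additive noise) shared across slices;
lesions are unions of 1-3 rotated ellipses placed in the brain interior
with intensity raised by `lesionContrast`; artefacts are similar blobs
whose centroids lie in a thin ring just inside the brain boundary
(within 10% of the semi-minor axis), mimicking air-interface artefacts,
and are excluded from the ground truth. Lesion sizes are log-normal with
a controlled fraction below the 37 px boundary, so size stratification
is exercised. Object placements are rejection-sampled with a one-pixel
halo so distinct objects never merge into one component. Intensities are
produced pre-normalisation and the pipeline always normalises, so the
real preprocessing path is exercised.

The phantom deliberately does **not** model diffusion physics, b-values,
partial-volume effects, 3-d lesion coherence across slices, or the full
texture statistics of brain tissue. Interior lesions and boundary
artefacts are separable by construction (their placement zones are
disjoint), which is what makes the stage-2 classification learnable from
tens of subjects. Passing the phantom checks therefore demonstrates that
the machinery is implemented correctly and that the cascade behaves as
designed — high lesion recovery, large false-positive reduction at
stable detection rate — not that clinical-grade accuracy would be
reached on real data.

## Numerical choices

* Pooling argmax ties break to the first position in row-major order,
  fixed for reproducibility; the pooled shape requires divisible spatial
  dimensions, and whole-slice inference reflect-pads to the next
  pooling-divisible size and crops back.
* Cross-entropies clip probabilities to [1e-7, 1 - 1e-7]; a non-finite
  loss aborts training with a diagnostic.
* Weights are Xavier-initialised (uniform, variance 2/(fan_in+fan_out));
  batch-norm statistics use the biased variance with eps 1e-5 and running
  momentum 0.1; inference always uses running statistics.
* Model selection: the epoch with the best validation Dice (stage 1) or
  validation accuracy (stage 2) is returned. Stage-2 minibatches are
  balanced by oversampling the minority class.
* The instance-evidence clip `q -> [1e-6, 1 - 1e-6]` keeps the odds
  product finite; fused background probabilities are renormalised.
* All randomness flows through derived 32-bit seeds; two single-threaded
  runs with the same configuration are bit-identical (the pipeline
  manifest records per-stage output digests to verify this).
* Intensity normalisation uses the population standard deviation, so a
  two-valued volume maps exactly onto {-1, +1}.

## Design choices where the design was open

* **Ensemble fusion** is the arithmetic mean of softmax maps: the naive
  ensemble must itself be a valid probability map (it is evaluated as a
  segmentation in its own right), and averaging is the canonical choice.
* **Bayes fusion** of instance and pixel evidence is an
  independent-evidence odds product. It has the required limits (neutral
  at 0.5, removal at 0, reinforcement at 1) and returns per-pixel
  probabilities rather than a hard gate.
* **Connectivity** is 8 in 2-d, slice-wise, everywhere (candidates,
  metrics, phantom statistics); sizes are always quoted in pixels. A
  4-connectivity flag exists. Components are never linked across slices.
* **Candidate scales are relative** (s, 2s, 4s around the bounding box)
  rather than fixed pixel sizes: the evaluation question is "does this
  blob's context look like brain interior or boundary?", which is
  scale-relative.
* **Positive-candidate rule** is any one-pixel overlap with the ground
  truth; no IoU threshold is imposed anywhere.
* **Stage-2 re-binarisation reuses the stage-1 threshold** so the only
  difference between the stages is the evidence fusion.
* **Joint training** of branches and refinement from scratch (single
  optimiser) is the default; per-branch pre-training is possible by
  training single-branch models and transplanting parameters, but is not
  needed at phantom scale.
* Mean FP/FN component sizes pool components across subjects rather than
  averaging per-subject means; subjects without such components
  contribute nothing to the size mean (flagged NaN when none exist).

## Problem sizes used by the tests and the acceptance script

The repository's checks run the full cascade at a reduced scale chosen
once as the package's demonstration conditions: 20 training/validation
subjects plus 10 test subjects of the 128 px phantom with 3 slices each,
1-3 lesions per subject (log-normal, median 18 px, 60% small), 2-4
boundary artefacts at contrast 1.8 versus lesion contrast 2.0; the
scaled-down network (one convolution per stack, 8 base channels,
receptive field = patch = 32 px) trained 10 epochs. Under these
conditions the held-out subject-level Dice is about 0.7, and the
candidate-evaluation stage removes essentially all false-positive
components without losing any detected subject, which reproduces the
qualitative behaviour of the cascade (a large m#FP drop at unchanged
detection rate). The full-size defaults (`networkConfig()`) are intended
for real training runs on adequate hardware.

## Known limitations

* No false-negative recovery: the cascade only removes components.
* The two stages are trained separately; candidate extraction is not
  differentiable, so end-to-end training is not possible in this design.
* 2-d slice-wise analysis ignores through-plane context by construction
  (thick anisotropic slices make 3-d convolution unattractive without
  super-resolution).
* No CRF or other post-processing; no skull stripping, bias-field
  correction or registration.
* The phantom's separability-by-construction means phantom accuracy
  numbers must not be read as clinical performance estimates.
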