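---
title: "Detection-guided tumour segmentation: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection-guided tumour segmentation: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(boxseg)
```

## The problem

Encoder-decoder segmentation networks trained on a common tumour type
(e.g. supratentorial high-grade glioma) degrade sharply when applied to a
rare tumour in an unseen brain region, because they learn both what a
lesion looks like *and* where it tends to be. Object detection is a
simpler, more transferable problem: a detector that merely brackets the
lesion with a per-slice rectangle carries over to new lesion locations far
better than a voxel-accurate segmenter. boxseg implements a two-stage
strategy that exploits this asymmetry: detect first, then segment inside
(or guided by) the detected region, with the two models trained
independently and combined only at inference.

## The pipeline

For each available modality (FLAIR-like and T2w-like):

1. **Normalisation.** Intensities are min-max normalised between the 5th
   and 95th percentiles, with out-of-range values capped:
   $\hat v = \max(\min((v - p_{05})/(p_{95} - p_{05}),\, 1),\, 0)$.
   Percentiles are computed over brain voxels (the skull-stripped
   background would otherwise dominate); whether the original protocol
   used brain-only or whole-volume percentiles is not documented, so the
   choice is exposed as a switch (`over = "brain"` / `"all"`). The
   interpolation rule is linear between order statistics
   (`stats::quantile` type 7); this affects third-decimal values only.

2. **Detection.** The volume is cut into axial slices, zero-padded
   centrally and replicated to three channels (so external detectors
   pretrained on RGB natural images remain drop-in compatible), and a
   per-slice single-object detector emits at most one rectangle plus a
   confidence per slice.

3. **Box-mask construction.** Rectangles are rasterised into a 3D mask
   carrying their confidences, then regularised along the axial axis by a
   morphological closing followed by an opening with a $(1,1,6)$
   structuring element: per-slice detection guarantees no axial
   continuity, so gaps shorter than 6 slices are bridged and isolated
   runs shorter than 6 slices are discarded.

4. **Ensembling.** With two modalities, box maps are fused voxelwise by a
   weighted average and thresholded at 0.5; segmentation confidences are
   fused the same way. The weight $\omega^*$ minimises the cross-entropy
   of the fused confidence against the ground truth over the *DISCR* set
   — the voxels where the two modalities' thresholded labels disagree —
   pooled across validation cases. Fusing cannot change a label outside
   DISCR, which is why the objective is restricted to it; when DISCR is
   empty the weight is immaterial and 0.5 is returned. The scalar problem
   is solved by Brent's method (`stats::optimize`), with the endpoints
   checked explicitly.

5. **Combination.** Two strategies:
   * **pYU (parallel):** UNet segments each modality independently; the
     fused, thresholded segmentation is intersected with the box mask.
   * **sYBBU (sequential):** the box mask is additionally an *input* to a
     BB-UNet, whose skip connections are gated by the encoded box; the
     output is then masked as in pYU.

   Masking is a pure intersection, so per-case recall can only fall — a
   set identity asserted exactly in the tests. Precision rises whenever a
   voxel inside the box is more likely tumoral than one outside, which
   the phantom's bright distractors make true by construction.
   Ensembling always precedes masking: averaging does not commute with
   intersection, and a regression test pins the implemented order.

6. **Failure handling.** A tiny box mask (< 0.1% of the brain by default)
   flags a failed detection; the pipeline then returns an empty mask and
   a failure record rather than a silent fallback, so cohort statistics
   can exclude failed cases explicitly.

## The networks

No deep-learning runtime is assumed: the three networks are implemented
natively (compiled im2col + GEMM kernels for the 3×3 convolutions,
vectorised R for pooling, transposed convolution and the heads), and
every backward pass is verified against central finite differences in the
test suite.

**UNet.** `depth` levels per path (default 5, the published
configuration), channels doubling per level from `base_channels`; two 3×3
convolutions + ReLU per level, 2×2 max-pooling down, 2×2 transposed
convolutions up, skip connections between symmetric levels, 2-channel
soft-max head. Training minimises the voxel-averaged binary cross-entropy
with Adam (default 100 epochs, initial learning rate 0.001) and no data
augmentation. A one-channel sigmoid head would be mathematically
equivalent for binary segmentation; the 2-channel soft-max form is kept
because that is the published formulation.

**BB-UNet.** A parallel box path encodes the binary box mask per level
(downsampling, then a 3×3 convolution squashed to $[0,1]$) and gates each
skip connection by element-wise multiplication before concatenation. Two
choices are deliberate and load-bearing:

* the box-path convolutions are *bias-free* and the squashing
  ($\min(\max(u,0),1)$) is zero-preserving, so an all-zero box mask gates
  every skip to exactly zero — an exact, testable property rather than an
  approximate one;
* gating happens before concatenation (multiply the encoder features,
  then concatenate to the decoder), matching the published description of
  multiplying encoded image by encoded box;
* the box-path weights are initialised positive with a per-channel sum
  just below 1, so the initial gate is close to a pass-through inside the
  box: training starts from "a UNet restricted to the box". With
  zero-mean random initialisation roughly half the gate channels start
  closed inside the box, blocking gradient flow through those skips and
  letting the network converge to ignoring the box entirely at desk
  scale.

The original BB-UNet reference does not pin down the box-path layer
composition; these choices are documented as this package's, not claimed
faithful to that reference.

**Reference detector.** The detection stage is a *contract* — any source
of per-slice boxes with confidences can be substituted via JSON-lines
files (`load_external_boxes()`), including a full-scale external
detector. The built-in reference detector is a small fully-convolutional
network: three 3×3 conv stages with two 2×2 poolings and a 1×1 objectness
head over a grid of 4×4-pixel cells, trained with a positively-weighted
cell-wise cross-entropy (a cell is positive when it intersects the
ground-truth box). A slice's box is the bounding rectangle of its
above-threshold cells, shrunk by $(\text{cell}-1)/2 = 1.5$ px per side to
undo the expected outward quantisation bias; its confidence is the
maximum cell probability. An earlier design iteration used a global
average pooling encoder with a 5-output (objectness, centre, size)
regression head; global pooling destroys spatial information, so such a
head cannot localise and, worse, is not translation-equivariant — a fatal
flaw for the domain-shift experiment, where the lesion moves to a region
never seen in training. The objectness-map design is
translation-equivariant by construction. The default confidence threshold
(0.25) is permissive: the box exists to hand the segmenter a region that
reliably contains the whole tumour, so recall is deliberately favoured
over precision.

## The phantom generator

The generator emulates the statistical structure the method assumes, not
anatomy: an ellipsoidal "brain" (skull-stripped, isotropic, LPS), a
compact lesion blob (union of three perturbed ellipsoids, scaled by
bisection so the lesion occupies on average 7% of the brain volume — the
documented property of the data regime the method was built for),
hyperintense on both modalities with modality-specific gain; bright
distractor spots outside the lesion; smooth intensity inhomogeneity;
additive Gaussian noise inside the brain. Distractors are mandatory in
the default spec: they create exactly the out-of-box false positives that
make box masking consequential, mirroring the observation that a plain
UNet segments healthy bright spots the same way it segments tumour. Their
design is deliberate on three axes: they are lesion-like *in-plane*
(0.35–0.6 of the lesion's equivalent radius, so a per-slice segmenter
confuses them with tumour) but *thin along z* (1.4–2.2 voxels, so the
$(1,1,6)$ axial opening rejects the box detections they trigger — the
same mechanism that motivates the morphology step); their geometry is
shared across modalities (like real bright anatomy, so confidence
ensembling cannot vote them away); and their brightness is independent of
the lesion gain (healthy structures do not dim when tumour contrast
drops, which is why the shifted cohort hits the unguided UNet hardest).

The domain-shifted cohort relocates the lesion to the central-inferior
brain (standing in for a pontine location never seen in training),
reduces lesion gain by 20% and increases noise by 25%. No quantitative
contrast difference between the training-domain and shifted-domain
tumour types is documented anywhere; these deltas are free parameters of
the generator, exposed in `shift_domain()`, and nothing downstream
depends on their exact values.

What the phantoms do *not* model: anatomy, bias fields, registration
artefacts, partial-volume effects, multi-compartment lesion structure.
Passing the benchmark therefore shows that the pipeline's machinery and
its directional claims (masking trades recall for precision; box guidance
survives a domain shift better than an unguided UNet) hold under the
method's own assumptions — it does not certify performance on real MRI.

## Numerical choices

* Rectangles are 0-based half-open `(x_min, y_min, x_max, y_max)` with x
  indexing columns; slice indices are 1-based. Stated once, used
  everywhere.
* The even-sized axial structuring element has no canonical centre; the
  origin sits at index $\lfloor 6/2 \rfloor = 3$, and the closing/opening
  pair uses adjoint max/min windows so closing is extensive and opening
  anti-extensive (verified exactly against an independent run-length
  oracle). The operator is grey-scale (running max/min), so the same code
  regularises binary masks and confidence-carrying box maps; on binary
  input it reduces exactly to binary morphology.
* Cross-entropy log arguments are clamped to $[10^{-7}, 1-10^{-7}]$ so
  the ensembling objective stays finite at saturated confidences.
* An empty predicted mask has precision 0 (the pessimistic convention,
  flagged on the result); an empty ground truth is an error, not a 0.
* The PR-curve AUC integrates mean precision over mean recall
  (trapezoid, thresholds 0.1–0.9 by default), extending the
  lowest-recall precision as a rectangle down to recall zero. The exact
  AUC construction behind the original figures is not described; this is
  a documented convention, not a reproduction.
* Multiple detections per slice are rasterised as a union (the
  recall-favouring choice); the reference detector emits at most one box
  per slice by default.
* In sYBBU the same ensembled box mask both feeds BB-UNet and masks its
  output; `mask_per_modality = TRUE` switches to per-modality masks for
  users who want the alternative reading.
* The box-ensembling weight and the segmentation-ensembling weight are
  optimised independently on the validation split; their coupling is not
  documented in the original procedure.

## Desk-scale benchmark

`run_benchmark()` reproduces the study design end to end at desk scale:
40 training, 8 validation, 10 source-test and 10 shifted-test volumes of
64×64×32 voxels; detector trained for 8 epochs on all lesion-bearing
slices plus sampled negatives (8 epochs); UNet and BB-UNet per modality trained for
6 epochs at depth 3, base 8, on 5 lesion-bearing + 3 negative slices per
case; splits are by case, never by slice, to avoid leakage between
slices of one volume. BB-UNet is trained with ground-truth boxes dilated
by 2 px per side: trained with *tight* boxes (where most in-box voxels
are tumour) the network learns to fill the box and over-segments inside
the looser predicted boxes it sees at inference; the small dilation
forces it to find the lesion boundary away from the box edge. These sizes are the package's choice of a
configuration that trains from scratch in minutes on one CPU core while
preserving every structural property the acceptance checks assert; the
paper-scale defaults (depth 5, 100 epochs, full slice sets) remain the
documented defaults of `seg_config()`. Headline numbers from full-scale
training on real cohorts (Dice ≈ 0.85 on the source domain, ≈ 0.62 on
the rare-tumour domain) are *not* reproducible at this scale and are not
claimed; the benchmark asserts directions, identities and calibrations
only.

## Known limitations

* The reference detector is desk-scale: no multi-scale grid, no anchors,
  no pretraining. It exists to exercise the contract; serious use should
  substitute an external detector through the box-file interface.
* Grey-scale morphology propagates box confidences into closed gaps by
  the max/min window mechanics; a different interpolation of gap
  confidence is conceivable but unobservable after thresholding in
  practice.
* Only two modalities are supported in the ensembling machinery, and one
  weight is shared across all cases (per-case weights are out of scope).
* The benchmark's correlation analysis needs at least 3 unfailed cases
  to report anything.
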