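# boxseg

Detection-guided binary brain-tumour segmentation for multimodal MR
volumes, built for the situation where a segmenter must be applied to a
rare tumour type in a brain region it never saw during training (the
motivating case: a diffuse midline glioma in the pons, with models trained
only on supratentorial high-grade gliomas).

The idea: voxel-accurate segmenters transfer poorly across lesion
locations, but *detection* — bracketing the lesion with a per-slice
rectangle — transfers well. So detection and segmentation are trained as
independent networks and combined only at inference:

* **pYU** (parallel): a UNet segments each modality; the detected,
  regularised 3D box mask then removes every segmented voxel outside it,
  `SEG ∩ BBOX`. Masking can only lower recall (a set identity), and it
  raises precision whenever false positives concentrate outside the box.
* **sYBBU** (sequential): the box mask is additionally an *input* to a
  BB-UNet whose skip connections are gated by the encoded box
  (element-wise multiplication per level), then the output is masked as
  in pYU.

Per-modality confidence volumes `ŷ_FLAIR`, `ŷ_T2w` are fused as
`ŷ(ω) = ω·ŷ_FLAIR + (1−ω)·ŷ_T2w`, where `ω*` minimises the cross-entropy
against ground truth over **DISCR** — the voxels where the two
modalities' thresholded labels disagree (fusing cannot change any other
label) — solved with Brent's method. Per-slice boxes are rasterised with
their confidences and regularised along the axial axis by a morphological
closing then opening with a `(1,1,6)` structuring element, bridging
missed slices and deleting isolated spurious detections.

Everything runs on synthetic paired-modality phantoms (ellipsoid brain,
compact hyperintense lesion occupying on average 7% of the brain, bright
distractor spots, a domain-shifted cohort with the lesion relocated to
the central-inferior brain), so the full pipeline is testable without any
imaging download. The three networks (reference detector, UNet, BB-UNet)
are implemented natively in R + Rcpp — no deep-learning runtime — and
their gradients are verified against finite differences in the test
suite. An external detector can be dropped in via JSON-lines box files.

## Worked example

```r
library(boxseg)

spec  <- phantom_spec(seed = 1)          # source-domain regime
case  <- generate_case(spec, case_seed = 42)
case
#> <phantom_case> modalities: FLAIR, T2w  tumour/brain: 0.040  region: hemisphere

# train a detector and a UNet per modality on a small cohort, then:
res <- run_pipeline(case, strategy = "pyu",
                    detectors = detectors, segmenters = unets,
                    omega_boxes = 0.5, omega_seg = 0.5)
precision_recall(res$seg_unmasked, case$gt)   # plain UNet
precision_recall(res$seg, case$gt)            # after box masking
dice(res$seg, case$gt)
```

The one-command benchmark reproduces the study design at desk scale
(40 train / 8 validation / 10 source-test / 10 shifted-test volumes of
64×64×32 voxels) and prints a summary table of cohort means:

```r
bench <- run_benchmark(benchmark_config(seed = 1), verbose = TRUE)
bench$summary    # cohort means per stage and strategy
bench$omega      # optimised ensembling weights (boxes, unet, bbunet)
bench$failures   # detection-failure counts per cohort
```

At seed 1 this run prints (mean over the test cohorts; the same numbers
are written by `scripts/acceptance.R`):

| quantity | source test | shifted test |
|---|---|---|
| detection precision / recall (ens. boxes) | 0.424 / 0.981 | — |
| Dice, UNet (unmasked) | 0.852 | 0.884 |
| Dice, pYU | 0.869 | 0.907 |
| Dice, sYBBU | 0.908 | 0.944 |
| Dice, BB-UNet with GT boxes | 0.965 | — |
| Dice, BB-UNet with predicted boxes | 0.908 | — |

with optimised weights ω(boxes) = 0.940, ω(UNet) = 0.839,
ω(BB-UNet) = 0.999, zero detection failures, and a cohort-mean masking
precision gain of +0.047 for UNet → pYU. Read the rows the way the study
reads its tables: detection deliberately favours recall (0.98) over
precision (0.42); masking trades a little recall for precision; the
box-guided strategies beat the unguided UNet, and ground-truth boxes
bound what predicted boxes can achieve.

A thin CLI wraps the two verbs users run from a shell:

```sh
Rscript inst/cli/boxseg phantom   --out cohort/ --n 20 --seed 1 --shifted
Rscript inst/cli/boxseg benchmark --out results/ --seed 1
```

## Package layout

| Area | Contents |
|---|---|
| `R/phantom.R` | phantom spec, case/cohort generation, domain shift |
| `R/preproc.R` | percentile min-max normalisation, axial slicing, padding |
| `R/boxes.R` | box extraction/rasterisation, axial morphology, box ensembling, failure flag, generic-region baseline |
| `R/detector.R` | pluggable detection contract + reference detector |
| `R/nn.R`, `src/` | native conv-net engine (im2col + GEMM kernels) |
| `R/segnets.R` | UNet, BB-UNet, training, confidence inference |
| `R/combine.R` | DISCR, weight optimisation, fusion, masking, pipeline |
| `R/metrics.R` | precision/recall, Dice, PR-curve AUC, correlations |
| `R/benchmark.R` | end-to-end desk-scale benchmark |

The methods vignette
(`vignettes/detection-guided-segmentation.Rmd`) documents the models,
the phantom's assumptions and limits, and every numerical convention.
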