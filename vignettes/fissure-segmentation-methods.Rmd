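---
title: "Methods: semi-automatic labels and a 3D inception U-Net for cerebellar fissures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic labels and a 3D inception U-Net for cerebellar fissures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissureseg)
```

# The problem

Cerebellar fissures are the thin, dark sheets of cerebrospinal fluid that
separate the folia of the cerebellar cortex in a T1-weighted MR image. Their
geometry carries clinically relevant information (fissures widen as the
cerebellum atrophies), but they are too thin — often one voxel or less — and
too convoluted to delineate by hand at scale. No public dataset ships
voxel-wise fissure labels, so the central methodological problem is not the
network: it is **where the training labels come from**.

`fissureseg` implements a complete answer in three parts:

1. a **semi-automatic label-construction procedure** that converts an MR
   volume plus an externally produced whole-cerebellum mask into three binary
   label maps (fissures, fissure-free tissue, whole cerebellum);
2. a **3D U-Net built from inception modules** that learns each map from the
   contrast-enhanced image, one model per target;
3. a **synthetic cerebellum phantom** generator, so the entire pipeline —
   label construction, training, inference, evaluation — can be exercised and
   tested end to end without clinical data.

This vignette describes the science and the design decisions; the README
shows a worked example, and `?function` documents each interface.

# Label construction

## Contrast enhancement

Fissures are detected by intensity, so the intensity scale must first be made
comparable across scans. `enhance_contrast()` composes three global
operations:

* `normalize_intensity()` — subtract the volume mean and divide by the
  population standard deviation (divide-by-*N*). Population rather than
  sample SD because the volume *is* the population of interest; for millions
  of voxels the difference is negligible anyway.
* `rescale_range()` — map the result linearly onto [1, 255], an 8-bit-style
  range that makes the subsequent histogram operations well conditioned. The
  output is clamped to the target interval so floating-point round-off can
  never push a voxel above 255.
* `equalize_histogram()` — global histogram equalization on 256 equal-width
  bins: each voxel is mapped through the empirical CDF of its bin and the CDF
  is mapped linearly back onto the observed range. Equalization spreads the
  intensity mass so that the dark fissure voxels and the bright tissue voxels
  end up in well-separated histogram modes, which is precisely what the next
  step needs.

The enhanced image is used twice: it is binarized to construct the labels,
and (divided by 255) it is the network input. Using the same image for both
keeps the learning target consistent with what the model sees.

## Smoothing the external mask

The whole-cerebellum mask comes from an external tool and typically has a
slightly ragged, voxelized border. `smooth_mask()` regularizes it with a
*morphological* active contour (a discrete Chan–Vese "snake"): each iteration
applies the region-competition update driven by the inside/outside mean
intensities, followed by a curvature-smoothing step implemented as
alternating morphological opening and closing with a 6-neighborhood cross
element. With the default `image = NULL` the mask itself plays the role of
the image, so the update reduces to pure border smoothing — one-voxel spikes
and pits are removed while large structures are untouched. We chose the
morphological formulation over a PDE level-set because it is
unconditionally stable, parameter-light, and operates directly on binary
volumes; it converges in a handful of iterations (default 10).

## Thresholding and mask algebra

`otsu_threshold()` picks the cut that maximizes the between-class variance of
the intensity histogram. When the volume has at most 256 distinct values the
candidate set is exactly those values, so the result provably matches an
exhaustive search; otherwise a 256-bin histogram is used. The function
returns the *midpoint* of the optimal split so the reported threshold
separates the two classes strictly; `binarize()` then keeps voxels **strictly
greater** than the threshold, i.e. the bright tissue.

The three label maps follow by set algebra (`build_label_triplet()`):

* **fissures** = `whole AND NOT bright` — the dark voxels *inside* the
  cerebellum. Restricting to the mask support is essential: it stops dark
  background or bright extra-cerebellar structures from contaminating the
  label. This is the XOR of the binarized image with the mask, restricted to
  the mask.
* **tissue** = `whole AND NOT fissures` — the cerebellum with the fissures
  carved out.
* **whole** = the (smoothed) external mask itself.

By construction the triplet satisfies two invariants that the
`mask_triplet` container enforces and the test suite checks everywhere:
`fissures OR tissue == whole` and `fissures AND tissue == ∅`. Three separate
binary targets, rather than one 3-class softmax, keep each learning problem a
balanced-enough binary segmentation and let the fissure model specialize on
the hardest, thinnest class.

On a noiseless phantom this pipeline reconstructs the ground-truth fissure
map *exactly* (Dice 1.0) — the label-fidelity acceptance test — which is the
right sanity check for a procedure whose whole point is to manufacture
training labels.

# The network

## Architecture

`build_unet(arch_spec())` constructs a 3D encoder–decoder with ten
**inception modules**. Each module runs four parallel branches over its
input — 1×1×1, 3×3×3 and 5×5×5 convolutions plus a 3×3×3 max-pool followed
by a 1×1×1 convolution — each emitting `filters` feature maps, ReLU after
every convolution, and concatenates them: a module with filter parameter
$f$ emits $4f$ maps. Mixing kernel sizes in one block lets the network see a
fissure (a 1–2 voxel sheet) and its surrounding lobule at the same depth,
without committing to a single receptive-field size.

The default filter schedule is 16, 16, 32, 64, 128 down the encoder and 128,
64, 32, 16, 16 up the decoder:

* **encoder**: four stages of (inception module → instance normalization →
  2×2×2 max-pool, stride 2), with filter parameters 16, 16, 32, 64 — so the
  contracting path emits 64, 64, 128, 256 feature maps;
* **bottleneck**: two modules at filter parameter 128 (512 maps each);
* **decoder**: four stages of (2×2×2 transposed convolution, stride 2 →
  concatenation with the matching encoder skip → inception module → instance
  normalization), filter parameters 64, 32, 16, 16;
* **head**: dropout (rate 0.3, training only) and a single-filter 1×1×1
  convolution with a sigmoid, producing one probability per voxel.

**Instance normalization** (normalize each channel of each volume by its own
spatial mean/variance, $\epsilon = 10^{-5}$, learned scale and shift) is the
right choice for batch size 1 — batch statistics would be meaningless — and
makes the network insensitive to residual inter-scan intensity scaling.
Because the four pooling stages each halve the grid, input sides must be
divisible by 16; `check_input_shape()` raises an error that names the fix
(`crop_to_mask(..., pad_multiple = 16)`).

## Why no deep-learning framework

No GPU deep-learning runtime is assumed. The forward and backward passes are
hand-written: convolutions are lowered to matrix multiplication (im2col +
BLAS GEMM) in C++, chunked over z-slabs so the im2col buffer stays under
~48 MB regardless of volume size; max-pooling stores argmax indices for the
backward scatter; the 2×2×2-stride-2 transposed convolution has direct
loops (every output voxel touched exactly once, so no overlap bookkeeping).
Instance-norm, dropout, and the losses are differentiated in R. The entire
backward pass is verified against central finite differences on a miniature
network (worst relative error ~2×10⁻⁷), which is the test that makes a
hand-rolled autodiff trustworthy.

## Loss and optimization

Training minimizes the **soft Dice loss** with the squared-denominator form,

$$ L = 1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2}, $$

whose gradient is smooth in the predicted probabilities and which directly
optimizes the evaluation overlap rather than a proxy. Dice is preferable to
cross-entropy here because fissures occupy a few percent of the volume:
a voxel-wise loss is dominated by the easy background. Optimization is Adam
(learning rate 10⁻³, β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸) with batch size 1 —
whole volumes are large, and instance norm removes the usual reason to want
larger batches. `train_model()` tracks the hard validation Dice each epoch
and returns the best-scoring weights alongside the final ones.

## Augmentation

`augment_image()` produces rigid perturbations — rotations up to ±10° about
a random subset of axes and shifts up to ±10 voxels along a random subset of
axes — matching the anatomical variability left after affine registration.
The image is pulled through the inverse transform with trilinear
interpolation; the three label maps use nearest-neighbor so they stay binary
and, crucially, so the triplet invariants (`fissures OR tissue == whole`)
survive resampling *exactly*. The default protocol generates 40 augmented
copies per training image. All randomness flows through seeded generators
(`with_seed()` saves and restores `.Random.seed`), so a training run is
reproducible bit for bit.

# The phantom

Real cerebellar MRI cannot ship inside a package, so `generate_phantom()`
builds a synthetic cerebellum with known ground truth:

* the **cerebellum** is a solid ellipsoid (default semi-axes 18, 15, 12
  voxels in a 48³ grid, centered);
* **fissures** are thin slabs: each is the set $|s(\mathbf{x})| < w/2$ of a
  planar level-set $s$ whose plane is sinusoidally warped, giving the
  curved-sheet geometry of real fissures (default 3 fissures, width 2,
  warp amplitude 2);
* intensities: tissue 150, fissure 30, background 10 — the bright/dark
  contrast the label construction exploits;
* optional **bias field** — a smooth low-order polynomial rescaled to
  $[1-a, 1+a]$, multiplied into the image — models coil inhomogeneity;
* optional additive **Gaussian noise**.

The generator returns the volume *and* the exact ground-truth triplet, so
every stage of the pipeline can be scored against a known answer. Defaults
are study conditions, not tuning knobs: tests use them as-is.

**Realism and limits.** The phantom reproduces the features that matter to
this pipeline — a bright convex body crossed by thin dark curved sheets,
smooth intensity inhomogeneity, additive noise — but it is not an MR
simulator: noise is Gaussian rather than Rician, there is no partial-volume
mixing at boundaries, no gray/white contrast inside the tissue, and the
fissure sheets are analytically smooth. Conclusions about *absolute*
clinical accuracy cannot be drawn from phantoms; conclusions about the
*correctness* of the implementation (does label construction recover the
truth, does training converge, do the metrics compute what they claim) can.

# Evaluation

`evaluate_masks()` reports five scalars from the voxel confusion counts
(TP, TN, FP, FN):

* **DSC** $= 2|P \cap G| \,/\, (|P| + |G|)$ — the primary overlap score;
* **OC** $= |P \cap G| \,/\, \min(|P|, |G|)$ — overlap relative to the
  smaller mask, useful when one mask is a near-subset of the other
  (OC of a mask with itself is 1; of disjoint masks, 0);
* **SP** $= TN/(TN+FP)$ and **SN** $= TP/(TP+FN)$;
* **AUC** $= 1 - \tfrac12(FPR + FNR)$ — the balanced accuracy, the area
  under the one-point ROC approximation for a hard classifier.

Two empty masks compare with Dice 1 (and a warning): agreement on absence is
agreement. The test suite checks every metric against an independent
voxel-loop oracle to 10⁻¹².

At inference, `segment()` thresholds the sigmoid output at 0.5 and
`largest_component()` keeps the largest 26-connected component — the
cerebellum is a single object, so smaller components are false positives.
Connected components are labelled by a BFS in C++. The fissure map can also
be obtained indirectly as `fissures_from_difference(whole, tissue)`, the
predicted whole minus the predicted tissue.

# Problem sizes and runtime

Everything runs single-threaded on a CPU. Representative costs:

* default phantom: 48³ grid, generated in well under a second;
* one forward+backward pass of the reduced network (filter schedule
  4, 4, 8, 16, 32) on a 32³ volume: ≈ 2.5 s;
* the reduced-scale training experiment shipped in the tests — 8 phantoms at
  32³, 6/2 train/validation split, 20 epochs, no augmentation — finishes in
  ≈ 5–6 minutes and reaches validation Dice ≈ 0.996 for the whole-cerebellum
  target;
* the full default architecture (1.6 M+ parameters at the reduced schedule;
  far more at the default schedule) is practical for inference on CPU but is
  sized for training on a GPU-class budget, which is out of scope here.

# Design decisions

Choices a reader might reasonably question, and why they were made:

* **3D only.** `arch_spec(spatial_rank = 2)` is rejected: fissures are
  sheets, and slice-wise 2D models sever them. Supporting a rank the package
  cannot test end to end would be worse than refusing it.
* **Filter-schedule interpretation.** The 5-element encoder list covers the
  four encoder stages plus the *first* bottleneck module; the 5-element
  decoder list covers the *second* bottleneck module plus the four decoder
  stages. This yields exactly ten modules and the contracting-path feature
  counts 64, 64, 128, 256, 512.
* **Hand-rolled primitives.** Otsu, histogram equalization, morphological
  snakes, and 3D connected components have no suitable 3D implementations in
  the available R stack, so they are implemented here and each is tested
  against an exhaustive oracle.
* **Input scaling.** Network inputs are the enhanced image divided by 255,
  keeping activations O(1) at initialization (He-scaled weights assume
  unit-scale inputs).
* **No augmentation in the reduced experiment.** The shipped training test
  must fit a CPU time budget; 40× augmentation is the *protocol* default
  (`training_config()`), exercised separately by the augmentation tests.
* **Text-only checkpoints.** Weights serialize to JSON (`save_weights()`),
  trading file size for portability and diffability.

# Limitations

* Labels inherit the quality of the external cerebellar mask and of a global
  threshold; pathologies that change tissue contrast would need a local
  threshold.
* The phantom's simplifications (Gaussian noise, no partial volume) mean
  reported scores overstate what clinical data would give.
* CPU-only training restricts practical experiments to reduced schedules and
  small grids; the code is the reference implementation, not a performance
  port.
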