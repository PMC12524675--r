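---
title: "Methods: desk-scale muscle segmentation and DEXA agreement with limbseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale muscle segmentation and DEXA agreement with limbseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sarcopenia management needs accessible muscle-mass measurement. DEXA is the
reference for appendicular lean mass and the skeletal muscle index
(SMI = appendicular lean mass in kg / height in m, squared), but it is rarely
available in primary care, and metal implants bias its soft-tissue estimates.
Standing lower-extremity radiographs are cheap and ubiquitous; if muscle
compartments can be segmented on them and converted to physical areas via the
pixel spacing, the resulting areas can be calibrated against, and compared
with, DEXA indices.

`limbseg` implements that pipeline end to end: a synthetic phantom cohort
with known ground truth, the standard radiograph preprocessing stack,
encoder-decoder segmentation networks trained with a soft Dice loss, a
multiclass metric suite, region-area quantification, and the
method-agreement statistics (Pearson, OLS, Bland-Altman, paired t) used to
compare an image-derived estimate with DEXA.

# The phantom generator

Clinical radiograph/DEXA cohorts are not freely distributable, so the
package's study conditions are defined by a synthetic generator,
`make_phantom()` / `make_cohort()`. Each phantom is a portrait grid (default
256 x 128 pixels at 4 x 4 mm) holding two mirrored leg silhouettes built
from filled ellipses: a subcutaneous-fat envelope, five muscle regions
(lateral, medial, posterior, gluteal, calf; a four-region schema without
the posterior compartment is also supported, since both labelings occur in
annotation practice), and bone (femur, tibia, iliac blade) painted last so
the shafts overwrite the muscle projections they cross. Region widths and
lengths are drawn uniformly from per-region millimetre ranges chosen to
match plausible projected compartment widths in an elderly cohort (thigh
envelope 130-160 mm wide, muscle compartments 42-80 mm, bone shafts
20-28 mm); positions are fixed anatomical fractions of the image with a
small jitter. The intensity model is class-mean attenuation (background
0.05, fat 0.35, muscles 0.55-0.62, bone 0.90) plus Gaussian noise
(sd 0.03), clipped to [0, 1]. There is no beam-hardening, scatter, or
projection-overlap simulation: each pixel belongs to exactly one class, so
`region_areas()` on the emitted mask reproduces the truth areas exactly,
which is what makes the quantification round-trip testable.

The paired DEXA-style record is a linear link: legs lean mass (g) =
35 g/cm^2 x true total muscle area + Gaussian noise (default sd 900 g);
appendicular mass adds an arms factor of 1.3, and height is uniform on
1.45-1.75 m. The defaults give total muscle areas around 300-500 cm^2 and
legs lean masses around 10-18 kg, the right order of magnitude for an
elderly clinical population. The slope and noise control the achievable
area-mass correlation exactly (`r = 1/sqrt(1 + (sd_e / (slope sd_area))^2)`),
and `tune_mass_noise()` inverts that relation: given a target r (0.7 is the
regime of interest for X-ray-vs-DEXA agreement), it estimates the area sd by
rendering the cohort's masks once and sets the mass noise accordingly.
Because every sample draws from its own stream derived from
`(seed, subject index)`, tuning does not perturb the geometry.

What passing tests on phantoms do *not* show: robustness to projection
overlap (the main reason calf correlations are weak on real radiographs),
intensity inhomogeneity across scanners, rotated limbs, or implants. The
phantom validates the machinery, not clinical performance.

# Preprocessing

`preprocess_pipeline()` applies, in order: intensity scaling to [0, 1],
histogram equalization, z-scoring, and gamma contrast adjustment
(gamma = 1.6). Conventions that the contracts fix:

* **Scaling** maps the observed range affinely; a constant image maps to the
  lower bound.
* **Histogram equalization** uses 256 bins over the observed range and maps
  each pixel to its bin's empirical CDF, so the mapping is monotone (rank
  order preserved up to ties) and idempotent up to bin quantization. The
  transform is named "histogram normalization" in imaging pipelines; plain
  equalization is the standard algorithm behind that name.
* **Z-scoring** uses the population (divisor n) standard deviation -- at
  image scale the n vs n-1 difference is far below float noise, but exact
  tests need one convention.
* **Gamma** is applied on internally min-max-normalized values and mapped
  back to the original range. This makes the transform well defined after
  z-scoring (negative intensities have no real power) and fixes the
  endpoints; it is the usual medical-imaging convention.

The listed order is also the order the four transforms are described in by
preprocessing documentation for this task; nothing in the package depends on
it beyond `preprocess_pipeline()` composing them that way, and the stages
are exported individually. Augmentation (seeded horizontal flip, p = 0.5) is
applied only during training, never at inference or evaluation, and flips
image and mask jointly without relabeling the side-specific classes: the
flip is geometric, and with bilateral region codes (left and right lateral
share one code) no relabeling is needed.

`resize_pair()` resamples the image bilinearly and the mask by nearest
neighbor (so no new labels appear) and rescales the spacing by the size
ratio, conserving the physical field of view; areas are conserved up to one
boundary pixel per edge.

# The networks and training

Three encoder-decoder architectures are provided behind one interface:
`unet` (conv-norm-ReLU double blocks, 2 x 2 max pooling, nearest-upsampling
decoder with skip concatenation), `vnet2d` (a 2D adaptation of the residual
encoder-decoder: double-conv residual blocks with 1 x 1 projections,
strided-convolution downsampling), and `unetpp` (nested dense skip pathways
X[i][j], with deep supervision averaging the loss over the full-resolution
heads X[0][j]). The original V-Net is a 3D architecture; the 2D layer plan
here (residual blocks + strided conv) keeps its two defining ingredients
without claiming to reproduce any particular 2D port. Every 3 x 3
convolution is followed by instance normalization, the convention of the
standard U-Net-family implementations; without it, desk-scale training
plateaus well short of sharp boundaries.

The engine is written directly on BLAS matrix products: a feature map is an
(H*W) x C matrix, a 3 x 3 convolution is nine shifted-matrix products
("shift-and-add"), and a small tape autograd links convolutions, instance
norm, ReLU, pooling, nearest upsampling, concatenation, and the loss.
Gradients are verified against central finite differences for all three
architectures in the test suite (relative error below 1e-4 on sampled
parameters).

The loss is `1 - mean_c softDice_c` on softmax probabilities, background
included by default (configurable), with an epsilon guard so a class absent
from both prediction and truth contributes Dice 1; an auxiliary
cross-entropy term can be mixed in (`ce_weight`, default 0). The optimizer
is AdamW.

Multiclass softmax Dice has a well-known failure mode that desk-scale
training exposes sharply: a class whose probability is suppressed early
saturates toward zero, and because the loss gradient through the softmax is
proportional to that probability, it vanishes -- the class can never
recover, an initialization lottery. Three design choices address it.
Classification heads are zero-initialized, so every class starts at exactly
uniform probability. Level-0 feature width is kept at least twice the class
count (16 channels for 8 classes), which removes most of the feature
competition that triggers collapse. And training performs multi-start
collapse recovery, the same idea as `kmeans(nstart=)`: at the end of
training the classes present in the labels are compared with the classes
the model actually predicts on a sample of training images, and if any
labeled class is entirely absent, optimization restarts from a fresh
seed-derived initialization (up to `max_restarts`, default 2,
deterministically).

Two profiles express the scale split. The `paper` profile carries the
reference full-scale settings (learning rate 8e-5, weight decay 1e-5, batch
size 8, 3000 epochs, 512 x 1024 inputs, depth 4); it is the configuration a
GPU user would run and is not exercised by the tests. The `desk` profile is
the package's own CPU-scale choice, used by all examples, tests, and the
acceptance script: 128 x 64 portrait inputs (matching the phantom's 2:1
portrait aspect), depth 2 with channels (16, 16) for `unet`/`vnet2d`, depth
3 with channels (16, 16, 32) for `unetpp` (three levels are needed for deep
supervision to have two heads), batch size 2, 50 epochs for cohort
training, and learning rate 3e-3 -- above the range a fine-tuning grid
search would explore, appropriate for a thin normalized network trained
from scratch for tens of epochs rather than thousands. Training is
deterministic for a fixed seed on one device: initialization, shuffling,
flips, and any collapse restarts all flow from `cfg$seed`.

Desk-scale problem sizes used by the tests and the acceptance script: the
single-phantom memorization check renders one noiseless phantom directly at
the 128 x 64 network resolution (so boundary pixels are not blurred by
resampling and the task is pure memorization) and trains U-Net++ for 200
epochs; the cohort check trains on 16 of 20 phantoms (subject-level 80/20
split, mirroring a 281/70-style split rule) for 50 epochs and evaluates
mean validation Dice on the held-out 4.

# The metric suite

`evaluate_segmentation()` binarizes each class out of the two label maps
and reports IoU, Dice, symmetric average distance, Hausdorff distance, and
relative absolute area difference (RAAD), with these conventions:

* empty union: IoU = 1; both masks empty: Dice = 1 (consistent with the
  IoU convention and the identity `Dice = 2 IoU / (1 + IoU)`);
* distances: both empty = 0, exactly one empty = infinity; distances are
  computed on full per-class pixel coordinate sets (not extracted
  boundaries) via the exact Euclidean distance transform of the mask
  complements; units are pixels by default (the scale on which reported
  AD/HD magnitudes of order 1-2 are interpretable), with a physical-mm
  option for isotropic spacing;
* RAAD: |pred area - label area| / label area x 100, with 0/100 for an
  empty label class, aggregated with label-area weights (hence asymmetric);
* class means exclude background by default (configurable) and are
  reported both with infinities propagated and with infinite classes
  excluded, flagged -- a finite published mean under-determines which
  convention produced it, so both are available.

All five metrics are property-tested against a brute-force pixel-set oracle
(explicit pairwise distances) on random 4 x 4 binary and 16 x 16 multiclass
pairs.

# Quantification and agreement

`region_areas()` converts per-class pixel counts to cm^2 via
`count x row_spacing x col_spacing / 100`; left/right instances share a
class code, matching bilateral DEXA legs lean mass. `compute_smi()` is the
kg/m^2 index; `percent_change()` is reported to one decimal, the convention
used in follow-up tracking.

`agreement_report()` emits the region-by-index Pearson matrix (each muscle
region and the total against SMI and legs lean mass), an OLS fit, the
Bland-Altman triple, and paired t-tests. Two comparison modes exist because
areas (cm^2) and lean mass (g) live on different scales: `"area"` correlates
raw areas (scale-invariant statistics are unaffected), while `"mass"` first
maps total area to grams through `fit_calibration()` (OLS of legs lean mass
on total area) -- the only way to obtain a grams-scale Bland-Altman from
areas without an externally supplied conversion. Bland-Altman limits use
the 1.96 x sample-sd convention; the difference direction defaults to
DEXA minus estimate and is configurable and recorded in the report, since
the sign of a published mean difference depends on an orientation choice
that is easy to leave implicit. Two-sided p-values are used throughout and
no multiple-testing correction is applied across the correlation matrix,
matching standard practice for descriptive agreement tables.

# Numerical and design choices

* Coordinates are (row, col), 1-based, column-major; spacing is ordered
  (row mm, col mm). NRRD files written by the package store the fastest
  axis as matrix rows and always carry `spacings:`; files without spacing
  metadata are refused rather than defaulted to 1 mm.
* The DICOM importer handles the explicit-VR little-endian single-frame
  grayscale case (with PixelSpacing and rescale slope/intercept) and
  rejects everything else explicitly.
* Degenerate inputs have fixed conventions: constant images scale to the
  lower bound / z-score to zero / pass through gamma unchanged; zero-variance
  vectors are errors in correlation and paired-t; argmax ties in prediction
  resolve to the first (lowest-code) class.
* Seeds: per-sample phantom streams are derived as
  `(1000003 |seed| + 7919 index) mod 2147483629` so cohort generation is
  reproducible per sample and independent of generation order.

# Known limitations

The phantom is geometric, not radiographic; no claim about clinical
segmentation accuracy follows from it. The desk profile's thin networks
cannot reach the boundary precision of full-scale training -- validation
Dice around 0.85-0.95 on phantoms is the expected regime, not 0.95+ as
reported for full-scale clinical training. Physical-unit distances require
isotropic pixels. The paired-record time-window logic of a real
X-ray/DEXA pairing (scans taken within some interval of each other) is not
modeled, and no sarcopenia diagnostic cutoffs are implemented.
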