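# limbseg

Muscle-mass assessment from standing lower-extremity radiographs, end to
end: semantic segmentation of limb muscle compartments, conversion of label
maps to physical areas via pixel spacing, and statistical agreement with
DEXA-derived indices. The package targets the desk-scale study of that
pipeline: everything runs on one CPU, with a synthetic phantom cohort
standing in for clinical data.

## What it implements

* **Phantom cohort** (`make_phantom()`, `make_cohort()`, `tune_mass_noise()`):
  standing two-leg phantoms with bone, subcutaneous fat, and five muscle
  regions (lateral, medial, posterior, gluteal, calf), plus paired
  DEXA-style records (legs and appendicular lean mass, height) linked to the
  true muscle area by `mass = 35 g/cm² · area + ε`, with the noise sd
  tunable to hit a target Pearson correlation.
* **Preprocessing** (`preprocess_pipeline()`): intensity scaling to [0, 1],
  256-bin histogram equalization, z-scoring (population sd), gamma contrast
  (γ = 1.6), plus bilinear/nearest `resize_pair()` and seeded
  `random_flip_pair()` augmentation.
* **Segmentation networks** (`build_model()`, `train_model()`): U-Net, a 2D
  V-Net adaptation (residual blocks, strided-convolution downsampling), and
  U-Net++ with nested skip pathways and deep supervision, trained with a
  soft Dice loss (`1 − mean_c 2|P∩G| / (|P|+|G|)` on softmax probabilities)
  and AdamW. The engine is pure R on BLAS matrix products, with gradients
  verified against finite differences in the test suite.
* **Metric suite** (`evaluate_segmentation()`): per-class and mean IoU,
  Dice, symmetric average distance and Hausdorff distance (exact Euclidean
  distance transform, pixel units), and relative absolute area difference
  (RAAD, label-area-weighted aggregate), with the standard empty-mask
  conventions (empty union → IoU 1; one side empty → infinite distance;
  empty label → RAAD 0 or 100).
* **Quantification** (`region_areas()`, `compute_smi()`, `percent_change()`,
  `fit_calibration()`): areas in cm² from pixel counts and spacing, the
  skeletal muscle index SMI = appendicular lean mass (kg) / height² (m²),
  and an OLS area→mass calibration.
* **Agreement** (`agreement_report()`): the region-by-index Pearson matrix,
  OLS fit, Bland–Altman mean difference with 1.96·sd limits of agreement,
  and paired t-tests, in raw-area or calibrated-mass mode.
* **Pipeline + I/O** (`run_pipeline()`, `read_nrrd()`/`write_nrrd()`,
  `import_dicom()`, YAML configs, the `inst/cli/limbseg` command-line
  front end): simulate → preprocess → train → predict → evaluate →
  quantify → agree under a single seed, with a run manifest.

## Worked example

```r
library(limbseg)

# a 20-subject phantom cohort whose area-mass correlation targets r = 0.7
spec   <- tune_mass_noise(phantom_spec(), target_r = 0.7, n = 20, seed = 1)
cohort <- make_cohort(spec, n = 20, seed = 1)

# desk-profile U-Net++: preprocess, split by subject, train, evaluate
cfg      <- train_config("unetpp", "desk", seed = 1)
prepared <- lapply(cohort$samples, prepare_sample, cfg = cfg)
fit      <- train_model(NULL, prepared[1:16], cfg)
report   <- evaluate_segmentation(predict(fit, prepared[[17]]$image),
                                  prepared[[17]]$mask)
print(report)

# areas from predicted masks, agreement with the simulated DEXA records
masks <- setNames(lapply(prepared, function(p) segment_image(fit, p$image)),
                  cohort$dexa$subject_id)
agree <- agreement_report(region_area_table(masks), cohort$dexa, mode = "mass")
print(agree)
```

On this seed the evaluation prints per-class Dice around 0.85–0.97 with a
mean Dice near 0.9 on the held-out phantom, and the agreement report's
total-area-vs-lean-mass correlation lands near the generator's target
(r ≈ 0.7); the Bland–Altman limits bracket the mean difference
symmetrically at ±1.96 sd of the paired differences. (Numbers are printed
by the code above; exact values vary with the seed.)

A full artifact-producing run of the same stages is one call:

```r
run_pipeline(pipeline_config(out_dir = "out", n = 20, seed = 1,
                             target_r = 0.7))
```

or, from a shell, `inst/cli/limbseg run --config config.yaml`.

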