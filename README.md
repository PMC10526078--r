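# palseg

Segmentation of high-intensity focused ultrasound (HIFU) thermal lesions in
multi-wavelength photoacoustic (MWPA) image cubes.

## The problem

HIFU ablation permanently changes the optical absorption spectrum
μ<sub>abs</sub>(r, λ) of tissue. MWPA imaging samples that spectrum per
pixel: the same scene is imaged at many laser wavelengths (690–950 nm in
5-nm steps, 53 channels in the reference geometry), so each pixel carries a
53-point absorption spectrum. `palseg` is for researchers developing
lesion-monitoring pipelines on such data: it implements the physics-based
preprocessing, the per-pixel classical baselines, a small fully
convolutional segmenter, greedy wavelength selection, an F1 evaluation
harness — and a synthetic phantom that emulates a 19-block × 4-frame ex
vivo acquisition, because the real datasets in this literature are not
public.

## The model

A pixel value follows the linear photoacoustic imaging model

    v(r,λ) = E(r) · Γ(T) · μ_abs(r,λ) · F(λ) · γ(r,λ) + N

(E system sensitivity, Γ Grüneisen coefficient, F laser pulse energy,
γ depth transmission, N noise). Two normalizations cancel the nuisance
factors: divide each channel by F(λ), then divide each pixel spectrum by
its own maximum. What remains is a normalized absorption spectrum; ablated
and non-ablated tissue differ most between 720 and 790 nm, which is where
sequential forward selection finds the informative wavelengths.

Segmenters operating on the normalized cube:

* per-pixel: quadratic discriminant analysis, a 53-hidden-node neural
  network, an RBF SVM (C = 16), a random forest (50 trees, ≥ 1000 samples
  per leaf) — each classifies a pixel from its spectrum alone;
* spatial: a six-layer fully convolutional network (three 3×3-conv +
  ReLU + 2×2-max-pool blocks, two 1×1 convolutions, bilinear upsampling)
  trained with class-weighted cross-entropy in which unlabeled pixels carry
  zero weight.

Evaluation is recall / precision / F1 over labeled pixels, averaged
per-frame across test frames that contain lesions.

## Worked example

Simulate a small study, preprocess it, train a baseline and the CNN, and
compare:

```r
library(palseg)

cfg    <- reduced_phantom_config(seed = 1)        # 96 x 128 px, 53 channels
frames <- make_study(cfg, n_blocks = 6, frames_per_block = 4, seed = 1)
frames <- preprocess_frames(frames, cfg$fluence)
split  <- split_blocks(frames, n_train = 4, n_test = 2, seed = 1)

pixels <- balance_pixels(extract_pixels(split$train), seed = 1)
qda    <- train_classic(model_spec("qda"), pixels, seed = 1)
cnn    <- cnn_fit(cnn_build(cnn_spec(53), seed = 1), split$train,
                  cnn_train_config(epochs = 6, lr = 2e-4, batch_size = 1))

evaluate_model(qda, split$test)
#> [1] 0.9492995
evaluate_model(cnn, split$test)
#> [1] 0.979651
```

The QDA score (~0.95) is capped by scattered ablated-spectrum confuser
pixels in the phantom's background tissue — a per-pixel classifier must
flag them; the CNN (~0.98) ignores them because isolated bright pixels do
not look like lesions after three pooling stages. The same mechanism at
full study scale (19 blocks, 15/4 block split, three seeds) produces the
model × wavelength-count F1 grid via `run_experiment()`:

```r
res <- run_experiment(experiment_config(output_dir = "scratch/run"))
print(round(100 * res$mean_f1, 2))
```

Wavelength selection and the reduced-wavelength grid:

```r
trace <- sequential_select(pixels, seed = 1, max_k = 5)
trace$order      # most important first; here 785 750 (small-study trace
                 # stops once the held-out error floor is reached)
trace$errors     # strictly decreasing: 0.0091 0.0030
```

## Layout

* `R/`, `src/` — implementation (R orchestration, Rcpp/Armadillo numerics)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/lesion-segmentation.Rmd` — methods notes: the phantom's
  stated world, model assumptions, numerical choices, limitations
* `inst/cli/pals` — small command-line front end
  (`pals simulate | preprocess | select-wavelengths | run`)
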