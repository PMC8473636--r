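# scaraug

Small-cohort binary classification of myocardial scar on contrast-enhanced
cardiac MRI is usually imbalance-limited: a few hundred late-gadolinium-
enhancement (LGE) slices against far fewer controls. `scaraug` is an R
implementation of a GAN-augmentation workflow for this setting — balanced
traditional augmentation, per-class PGGAN synthesis and CycleGAN domain
translation, PCA + k-means one-sigma filtering of generated images with
Fréchet-inception-distance (FID) scoring, a MobileNetV2-style classifier
with pluggable attention units, and Grad-CAM explanation — exercised
end-to-end on synthetic cardiac phantoms with ground-truth scar masks, so
no clinical data is required.

The quantitative core, in the field's standard notation:

* **Pool arithmetic.** A class with `b` base images, `n` rotations (angles
  `i·360/(n+1)`) and flip/shift/scale extras yields `b·(1+n+3)` pool
  images; 557 scar images with 8 rotations give 6,684. Balancing 104
  controls against 557 scars needs 453 sampled images, and "4x"
  augmentation draws 4·557 = 2,228 images per class without replacement.
* **FID.** `‖μr − μg‖² + Tr(Σr + Σg − 2(Σr Σg)^{1/2})` over feature
  means/covariances, with the matrix square root computed in the
  symmetrized PSD form.
* **One-sigma filter.** PC1 scores of 1000-d embeddings, k-means (k = 1,
  whose centroid is the mean), removal of scores beyond 1σ — on Gaussian
  scores the removed mass is `2Φ(−1) ≈ 31.7%`.
* **Channel attention.** `S = σ(W₂ δ(W₁ z))` on the pooled channel
  descriptor `z`, multiplied channelwise into the feature map; spatial
  attention gates pixels via a conv over the channel mean; mix attention
  adds the two.
* **Grad-CAM.** `relu(Σ_k w_k A_k)` with `w_k` the spatial mean of
  `∂(class logit)/∂A_k` at the last convolutional map, upsampled and
  max-normalized.

All networks run on the package's own deterministic convolutional engine
(Rcpp/RcppArmadillo kernels, analytic gradients, seeded end to end).

## Worked example

```r
library(scaraug)

# 1. phantoms with ground-truth scar masks, stratified split
data  <- make_phantom_dataset(n_scar = 120, n_control = 120, seed = 1)
split <- split_dataset(data, n_test_per_class = 20, seed = 2)

# 2. traditional augmentation: pool, then 4x balanced sampling
pool <- build_pool(split$train, augmentation_plan(n_rotations = 8, seed = 3))
pool_counts(pool)
#> # A tibble: 2 x 2
#>   label       n
#>   <chr>   <int>
#> 1 control  1200
#> 2 scar     1200
train <- sample_balanced(pool, factor = 4, n_base_majority = 100, seed = 4)

# 3. classifier with channel attention (the default)
model <- train_classifier(train, split$test,
                          classifier_config(epochs = 5, seed = 5))
ev <- evaluate_classifier(model, split$test)
ev
#> <scar_eval> accuracy 0.975, AUC 1.000
#>           control scar
#>   control      20    0
#>   scar          1   19

# 4. Grad-CAM localization against the ground-truth arc masks
scars <- split$test[split$test$label == "scar", ]
stats <- heatmap_stats(grad_cam(model, scars), scars)
round(mean(stats$overlap), 3)
#> [1] 0.149
```

Each pool image is one of the 12 per-base variants (`1 + 8` rotations
`+ flip + shift + scale`), so 100 base images per class give 1,200; the
balanced sample takes 400 per class of them. The evaluation report prints
the confusion matrix (rows = truth); `overlap` is the intersection-over-
union between the thresholded heatmap and the phantom's true scar arc —
well above the untrained-model baseline, i.e. the trained network attends
to the hyperenhanced arc rather than arbitrary tissue.

GAN augmentation and filtering follow the same tibble-in/tibble-out style:

```r
h    <- train_pggan(split$train[split$train$label == "scar", ],
                    progressive_schedule(target_resolution = 16, seed = 6))
gen  <- generate_images(h, 120, seed = 7)
bb   <- feature_backbone(input_size = 16, seed = 8)
kept <- filter_images(gen, bb, k_sigma = 1)$kept
fid_score(resize_dataset(split$train, 16), gen, bb)   # before filtering
```

`run_pipeline()` (and the thin `inst/scripts/scaraug` CLI) orchestrates the
stages end to end from a single master seed and writes a JSON summary per
run.

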