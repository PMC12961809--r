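# gliomaseg

Binary glioma segmentation on 2-D multi-channel brain MRI slices, in pure
R. Lower-grade gliomas appear hyperintense on FLAIR-weighted MRI; their
delineation drives diagnosis, monitoring and treatment planning, and
manual contouring is slow and observer-dependent. `gliomaseg` provides a
complete, CPU-only, fully seeded pipeline for learning and evaluating that
delineation — sized so that every component can be exercised end to end on
a laptop with synthetic phantoms.

## What is inside

* **An attention encoder–decoder.** A four-channel input (three image
  channels plus a tumor-likelihood prior map) feeds a residual-style stem
  (7×7 stride-2 conv + BN + ReLU + max-pool) and a hierarchy of
  DownBlocks, each refined by CBAM — channel attention
  `M_c = σ(MLP(AvgPool F) + MLP(MaxPool F))` followed by spatial attention
  `M_s = σ(f_{7×7}[AvgPool; MaxPool])`. The decoder upsamples bilinearly,
  gates each encoder skip with an additive attention gate
  `α = σ(ψ(ReLU(W_s s + W_g g)))`, concatenates *extended* skips (all
  shallower encoder stages, pooled and channel-reduced), and carries two
  auxiliary deep-supervision heads whose losses enter as
  `L = L_main + λ₁ L_aux1 + λ₂ L_aux2`.
  The network runs on an in-package reverse-mode autodiff tape over
  compiled (Rcpp/Armadillo) convolution kernels; every backward pass is
  finite-difference checked in the tests.
* **A composite loss**: `w_bce·BCE + w_dice·(1 − (2ΣSG+1)/(ΣS+ΣG+1)) +
  w_focal·Focal(γ=2, α=0.25)`.
* **A prior channel**: brain masking, within-mask Z-scores, intensity
  K-means (k = 3), highest-mean-cluster selection, morphological closing +
  median filtering, and distance-to-boundary softening to `[0, 1]` — an
  unlearned tumor-likelihood map that is exactly invariant to affine
  intensity changes.
* **A polar-bear foraging optimizer** for the mixed hyperparameter space
  (log learning rate, discrete batch sizes and filter counts, categorical
  optimizer, loss weights, …): roaming exploration
  `H ← H + α R₁(H_best − H) + β R₂(H_j − H_k)` and hunting exploitation
  `H ← H + γ(H_best − H)` under linear schedules, greedy replacement and
  an asynchronous incumbent.
* **The evaluation suite**: Dice, IoU, accuracy, precision, recall,
  specificity, F1, HD95, ASSD, MSD and SSIM, all cross-checked against
  brute-force oracles in the tests.
* **A phantom generator** producing seeded brain-like slices (bright
  elliptical brain, hyperintense tumor blobs, Gaussian noise) with exact
  ground-truth masks.

See `vignettes/methods.Rmd` for the full model description, parameter
semantics and design rationale.

## Worked example

Train a tiny model on seeded phantoms and evaluate it on held-out slices:

```r
library(gliomaseg)

phantoms <- lapply(1:140, function(i) generate_phantom(phantom_spec(seed = i)))
images <- lapply(phantoms, `[[`, "image")
masks  <- lapply(phantoms, `[[`, "mask")

fit <- gliomaseg_fit(images[1:100], masks[1:100],      # training slices
                     images[101:115], masks[101:115],  # validation slices
                     net_cfg   = net_config(base_filters = 8, n_stages = 3,
                                            cbam_reduction = 4),
                     train_cfg = train_config(epochs = 12, batch_size = 8,
                                              learning_rate = 2e-3,
                                              patience = 5, seed = 1),
                     verbose = TRUE)
#> epoch 1  loss 1.4874  val dice 0.0958
#> epoch 5  loss 1.0426  val dice 0.7650
#> epoch 9  loss 0.8797  val dice 0.9277
#> epoch 11  loss 0.8153  val dice 0.9333
fit
#> Attention encoder-decoder glioma segmenter
#>   stages: 3, base filters: 8, parameters: 33,468
#>   trained 12 epoch(s); best validation Dice 0.9333 at epoch 11

ev <- evaluate_model(fit, images[116:140], masks[116:140])
round(unlist(ev$mean), 3)
#>        dice         iou    accuracy   precision      recall specificity
#>       0.927       0.865       0.992       0.872       0.991       0.992
#>          f1        hd95        assd         msd        ssim
#>       0.927       1.204       0.646       0.880       0.949
```

The fitted model finds the hyperintense blobs almost exactly: mean
held-out Dice 0.93, boundaries on average within ~0.6 px of the truth
(ASSD), and the 95th-percentile boundary error (HD95) around one pixel.
`predict(fit, image)` returns binary masks (or probability maps with
`type = "prob"`), padding odd-sized inputs reflectively. Checkpoints
round-trip through `save_checkpoint()` / `load_checkpoint()`.

Hyperparameter tuning plugs the trainer into the forager:

```r
space <- default_search_space()
fitness <- make_dice_fitness(images[1:40], masks[1:40],
                             images[41:50], masks[41:50], budget_epochs = 2)
best <- run_pbfo(space, fitness, pbfo_config(m = 8, t_max = 10, seed = 1))
```

A thin command-line wrapper over the same functions ships in
`inst/cli/gliomaseg-cli.R` (`generate-data`, `prior`, `train`, `tune`,
`predict`, `eval`).

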