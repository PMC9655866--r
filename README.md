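# fusedose

Voxel-wise prediction of radiotherapy dose distributions with a
full-scale feature-fusion 3D conditional generative adversarial network,
plus the complete dosimetric evaluation toolbox used to judge such
predictions. The package is aimed at medical-physics and imaging
researchers who want a self-contained, CPU-runnable implementation of the
whole pipeline: preprocessing, networks, losses, training protocol,
synthetic phantoms and evaluation.

## The model

A generator G maps a normalized multichannel conditioning volume X (CT,
planning target volume and organ-at-risk masks, depending on the scheme)
to a dose map G(X); a fully convolutional 3D patch discriminator D sees
the conditioning stack concatenated with either the clinical dose (label
1) or G(X) (label 0) and emits a field of patch logits with a 70³-voxel
receptive field. Training alternates the two with the objective

```
L_D = ( -mean log σ(D(X|GT)) - mean log(1 - σ(D(X|Pre))) ) / 2
L_G = λ_cGAN · L_cGAN + λ_AVD · L_AVD + λ_L1 · L_L1
```

where `L_cGAN = -mean log σ(D(X|G(X)))`, `L_AVD` penalizes mismatched
adjacent-voxel dose differences along the transverse, coronal and sagittal
axes (edge preservation), and `L_L1 = mean |GT - G(X)|`. The generator is
a five-scale encoder–decoder with *full-scale* skip fusion: every decoder
step receives a 32-channel branch from every encoder scale and every
deeper decoder scale (5 × 32 = 160 fused maps). The recorded plans total
11.077 M (generator) and 29.026 M (discriminator) trainable parameters.

Evaluation covers MAE (% of prescription), cumulative DVH with Dp/Vd
queries, homogeneity index (D2−D98)/D50, conformity index
V_TP²/(V_T·V_P), isodose-volume Dice coefficients, 3 %/3 mm gamma
analysis with a 10 % dose threshold, dose-difference histograms and
paired t-tests.

Since no deep-learning framework is available in this stack, the networks
run on the package's own C++ kernels (vol2col + BLAS convolutions with
analytic gradients) under a small reverse-mode autodiff tape; gradients
are verified against finite differences in the test suite.

## Worked example

Train at desk scale on seeded synthetic pelvic phantoms (scheme B: dose +
CT + PTV, no organ contours) and evaluate a prediction:

```r
library(fusedose)

cases <- generate_phantom_set(8, phantom_spec(shape = 48, seed = 100))
stacks <- lapply(cases, function(cs)
  assemble_channel_stack(cs$ct, cs$structures, cs$dose, scheme = "B"))

cfg <- train_config("B", epochs = 30, decay_start = 12, batch_size = 2,
                    crop_size = 32, width_mult = 1/16, seed = 11)
fit <- train_adversarial(stacks, cfg)
tail(fit$loss_log[, c("epoch", "L_D", "L_G_cGAN", "L_G_AVD", "L_G_L1")], 1)
#> # A tibble: 1 × 5
#>   epoch   L_D L_G_cGAN  L_G_AVD L_G_L1
#>   <int> <dbl>    <dbl>    <dbl>  <dbl>
#> 1    30 0.646    0.756 0.000948 0.0369

cs <- cases[[1]]
stack <- assemble_channel_stack(cs$ct, cs$structures, dose = NULL,
                                scheme = "B", prescription = 5400)
pred <- predict_dose(fit$generator, stack)
report <- evaluate_case(cs$dose, pred, cs$structures)
glance(report)
#> # A tibble: 1 × 5
#>   mae_body_pct mean_dsc gpr_global_pct hi_diff ci_diff
#>          <dbl>    <dbl>          <dbl>   <dbl>   <dbl>
#> 1         1.90    0.901           92.3   0.175  -0.122
```

The generator's training L1 fell from 0.371 (epoch 1) to 0.037 (epoch
30); on a training phantom the prediction reaches a body MAE of 1.9 % of
the 54 Gy prescription, a mean isodose Dice of 0.90 across the 10–100 %
levels and a global 3 %/3 mm gamma passing rate of 92 %. `autoplot()`
methods draw DVH comparisons, difference histograms and loss curves;
`tidy()`/`glance()` return the report as tibbles. Command-line wrappers
(`make_phantoms.R`, `train.R`, `predict.R`, `evaluate.R`) live in
`inst/cli/`.

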