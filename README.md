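# abdomenseg

Multi-organ segmentation of multi-station two-point Dixon abdominal MRI.

Whole-body MRI in population imaging studies is acquired in several table
stations, in four Dixon contrasts per subject (water, fat, in-phase,
opposed-phase), with scanner- and protocol-dependent geometry and intensity
scales. Before any cross-cohort analysis of abdominal organs, the scans
must be standardized and the organs segmented. `abdomenseg` provides that
pipeline end to end, in R:

- **Standardization** — reorientation to RAS, sigmoid-blended stitching of
  overlapping stations via the table-position affines, bias-field
  correction estimated on the in-phase contrast and shared by all four
  contrasts, resampling to 2 × 2 × 3 mm, and a fixed region-of-interest
  crop; optional histogram-matching or linear intensity normalization.
- **Segmentation network** — a 2D encoder/decoder with three encoders,
  a bottleneck and three decoders; dense blocks of three
  BN → PReLU → convolution layers (the third consumes the concatenation of
  the first two); octave convolutions (channel split α between a
  full-resolution and a half-resolution branch) everywhere except the first
  encoder and last decoder; concurrent spatial and channel
  squeeze-and-excitation (CSSE) after every block; max-pooling whose argmax
  indices drive the decoder's un-pooling; a 1 × 1 softmax classifier over
  9 classes (background + liver, spleen, kidneys, adrenal glands, pancreas,
  gallbladder). The network, including backpropagation, is implemented in
  this package on Rcpp/RcppArmadillo kernels.
- **Training** — per-view 2D slice datasets (axial, coronal, sagittal),
  the combined loss

  `L = − Σ_x ω(x) g_l(x) log p_l(x) − mean_l (2 Σ_x p_l g_l + 1) / (Σ_x p_l + Σ_x g_l + 1)`

  (weighted logistic term plus a +1-smoothed Dice term, so true-negative
  classes are not penalized), with weight maps
  `ω(x) = 1 + w_class·c(label(x)) + w_edge·boundary(x)` using
  median-frequency class weights; SGD with momentum followed by stochastic
  weight averaging (SWA) at a constant learning rate, with batch-norm
  statistics recalibrated for the averaged weights; best-validation
  checkpointing.
- **Inference** — per-view slice-wise prediction, equal-weight averaging of
  the per-view probability volumes, argmax label maps.
- **Metrics** — per-organ Dice and average symmetric surface distance
  (ASSD, mm, anisotropic spacing respected).
- **Phantom cohorts** — a synthetic multi-station Dixon generator (body +
  eight ellipsoidal organs from liver-sized to adrenal-sized, exact Dixon
  contrast relations, smooth multiplicative bias field, Gaussian noise,
  overlapping stations with correct affines) so the whole pipeline is
  testable without cohort data.

## Worked example

```r
library(abdomenseg)

pcfg  <- read_phantom_config(system.file("extdata", "phantom_small.yaml",
                                         package = "abdomenseg"))
ppcfg <- read_preprocess_config(system.file("extdata", "preprocess_small.yaml",
                                            package = "abdomenseg"))

cohort  <- make_cohort(pcfg, 10, seed = 1)
studies <- lapply(cohort, function(p) preprocess_study(p$study, ppcfg))
labels  <- lapply(cohort, function(p)
  preprocess_labelmap(p$labels, p$labels_affine, ppcfg)$volume)

train <- build_slice_dataset(studies[1:8], labels[1:8], view = "axial")
val   <- build_slice_dataset(studies[9], labels[9], view = "axial",
                             class_weights = train$class_weights)

net <- build_abdomennet(model_config(in_channels = 2, filters = 16, seed = 1))
fit <- train_view(net, train, val,
                  train_config(epochs = 10, batch_size = 10, base_lr = 0.01,
                               swa_lr = 0.005, swa_start_epoch = 8, seed = 1))
tail(fit$history, 3)
#>    epoch    lr train_loss  val_dice
#> 8      8 0.005 -0.7736652 0.8816528
#> 9      9 0.005 -0.7956851 0.8579128
#> 10    10 0.005 -0.8165602 0.8898621

set_weights(net, fit$swa_weights)
seg <- segment(list(axial = net), studies[[10]])
evaluate(seg$labels, labels[[10]], spacing_mm = c(2, 2, 3))
#>   class_id  class_name  dice assd_mm
#> 1        1       liver 0.976   0.437
#> 2        2      spleen 0.961   0.419
#> 3        3    kidney_r 0.942   0.754
#> 4        4    kidney_l 0.931   0.520
#> 5        5   adrenal_r 0.836   3.392
#> 6        6   adrenal_l 0.832   0.417
#> 7        7    pancreas 0.852   0.820
#> 8        8 gallbladder 0.899   0.460
#> 9       NA        mean 0.904   0.902
```

The run takes a few minutes on one CPU. The history table shows the
per-epoch training loss (the combined loss above, which approaches −1 at
a perfect fit) and the validation mean Dice over foreground organs.
`evaluate()` prints one row per organ with its Dice overlap (1 = perfect)
and its ASSD in millimetres (0 = perfect), plus a final mean row — the
tiny adrenal-gland-sized organs score lowest, exactly as small organs do
on real scans.

A command-line front end for each stage ships in `inst/cli/abdomenseg`:
`make-phantom`, `preprocess`, `train`, `predict`, `evaluate`, `describe`.

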