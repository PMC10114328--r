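# fundusdr

Binary diabetic-retinopathy (DR) grading for retinal fundus photographs,
built around a *revised* ResNet-50 in which the outputs of the first two
stage-5 residual blocks are merged elementwise (multiplication by default)
before a regularized single-sigmoid head. The revision targets
overfitting: on the published Kaggle-scale benchmark it shrinks the
train/test generalization gap from 14.14 to 9.63 percentage points while
keeping test accuracy essentially unchanged.

The package is a complete, self-contained stack in R:

* **Preprocessing SOP** — black-border auto-crop (clip-mask + tight
  bounding box), circular crop about the retinal disc, HSV hue/value
  histogram equalization, resize (`run_sop()`).
* **Quality gate** — a transparent three-metric good/usable/reject triage
  (foreground fraction, Laplacian-variance sharpness, brightness)
  standing in for an external pretrained quality network
  (`assess_quality()`, `filter_usable()`).
* **Classifier** — the 3/4/6/3 bottleneck residual network with named
  block outputs, the merged-feature revised head (five elementwise
  operators), kernel-L2 + activity-L1 head penalties, and a
  width/input-size scaling so desk-scale replicas train in minutes
  (`drnet()`, `fit_drnet()`). The convolution/batch-norm engine and
  backpropagation are implemented in vectorized base R on BLAS — no deep
  learning framework is required.
* **Training** — SGD with momentum, reduce-on-plateau schedule
  (lr 0.01, halving after 2 stagnant epochs, down past 1e-11 under a
  sustained plateau), accuracy and clipped cross-entropy metrics,
  bit-reproducible from one seed.
* **Visualization** — named-layer activations, merged heatmaps for all
  five operators, overlay panels (`viz_panels()`).
* **Synthetic data** — a seeded fundus generator (shaded disc, vessels,
  optic disc, red blob lesions, blur/darkening degradations) so the whole
  pipeline is testable without clinical data (`generate_fundus()`,
  `generate_dataset()`).
* **CLI** — `simulate → preprocess → quality → train → evaluate →
  visualize` subcommands with run manifests (`run_cli()`,
  `inst/bin/fundusdr`).

## Worked example

A desk-scale run of the full stack — synthetic cohort, preprocessing,
the revised classifier, evaluation:

```r
library(fundusdr)

## generate a balanced synthetic cohort and preprocess it
spec <- synthetic_spec()
labels <- rep(c(0L, 1L), each = 30)
cfg <- sop_config(output_side = 64, quality = NULL)
images <- lapply(seq_along(labels), function(i) {
  s <- generate_fundus(spec, labels[i], "good", seed = 100 + i)
  run_sop(s$image, cfg)$image
})
x <- stack_images(images, 64)

## revised classifier: multiplication merge of the two stage-5 taps
model <- drnet(model_config(input_side = 64, width_multiplier = 0.25,
                            init_seed = 1))
print(model)
#> Residual DR classifier (revised structure)
#>   input: 64 x 64  width multiplier: 0.25
#>   fusion: multiplication of conv5_block1_out and conv5_block2_out
#>   head: global average pool -> 1 sigmoid unit (kernel L2 1.0e-04, activity L1 1.0e-05)
#>   parameters: 1,494,769

val <- c(1:6, 31:36)                    # balanced hold-out
fit <- fit_drnet(model, x[, , , -val], labels[-val],
                 validation = list(x = x[, , , val], y = labels[val]),
                 epochs = 4, batch_size = 16, seed = 1)
print(fit)
#> Fitted DR classifier: 4 epochs
#>   final train acc 0.9583 / loss 0.1730
#>   final val   acc 0.8333 / loss 0.6700 (lr 1.000e-02)

round(predict(fit, x[, , , val]), 3)
#>  [1] 0.004 0.003 0.004 0.005 0.010 0.002 1.000 1.000 0.979 1.000 0.009 0.039

evaluate(fit, x[, , , val], labels[val])$accuracy
#> [1] 0.8333333

benchmark_gaps()
#> original  revised
#>    14.14     9.63
```

The standing end-to-end check, `run_synthetic_benchmark()`, trains the
same architecture for 10 epochs on a 200-image set and reaches validation
accuracy ≥ 0.90 for most seeds (seed 1 gives 0.975) in about two minutes
on one CPU. Heatmaps of the merge operators for any image:

```r
viz_panels(fit, images[[31]], "panels.png")   # five-operator overlay strip
```

## Command-line pipeline

```sh
fundusdr simulate   --out data --n0 100 --n1 100 --val 20 --test 20 --seed 7
fundusdr preprocess --in data --out prep --size 64
fundusdr quality    --in data --report quality.csv
fundusdr train      --config train.cfg --out run     # key=value config
fundusdr evaluate   --model run/model.rds --data data --split test --out pred.csv
fundusdr visualize  --model run/model.rds --image data/img_00001.png \
                    --merge all --out panels.png
```

Every stage writes a `run_manifest.json` with its config and seed.

## Scope

The generator emulates only the gross structure of a fundus photograph;
synthetic accuracies say nothing about clinical performance. Reproducing
the published Kaggle-scale accuracies would require the full 35,126-image
download and long training; the published table is therefore an input
(`kaggle_benchmark()`) and the package recomputes the quantities derived
from it. See the vignette (`vignettes/fundus-dr-pipeline.Rmd`) for the
full method conventions and design rationale.
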