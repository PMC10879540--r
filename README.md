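# ercpnet

Compact convolutional networks for multi-class plant leaf disease
classification, built around three ideas:

* **CER block** (channel-expansion residual): triples the channel width of a
  feature map *without any learnable parameters* in the expansion itself,
  by concatenating three parallel max-pooling branches with windows
  3×3 / 5×5 / 9×9 (stride 2), refined by a 1×1 → 3×3 → 1×1 aggregation
  path and a strided 1×1 residual projection.
* **ACA block** (adaptive channel attention): CBAM-style channel + spatial
  gating with a residual shortcut, whose 1D-convolution kernel size adapts
  to the channel count `C` through the inverse Gaussian probability density
  function,

  ```
  y = C / N,    x = sqrt(-2 σ² ln(y σ √(2π))) + μ,    k = nearest odd ≥ 1
  ```

  with defaults μ = 0, σ = 1, N = 2048 — so wider maps get narrower
  kernels, with no manual tuning (48 → k = 3, 144 → k = 1, 432 → k = 1).
* **BIF head** (bidirectional information fusion): upsamples the deepest
  stage, merges it with the mid-level stage, downsamples and re-merges with
  the deep stage, then expands to 3×C₃ channels — so the classifier sees
  both semantic and pixel-level information.

The default assembly (stem → 3 × (CER + ACA) → BIF → GAP → FC/softmax) maps
a 3×416×416 image through 16→48→144→432 channels into a 1296-dimensional
feature and 38 classes. Four ablation variants are available
(`er_net`, `er_net_cbam`, `erc_net`, `ercp_net`).

Everything — convolutions, batch norm, pooling, backprop, SGD with momentum
and plateau learning-rate decay (`LR = 0.3 × lr` after 3 stale epochs),
Grad-CAM — is implemented in base R, so the package has no compiled or deep
learning dependencies. A deterministic synthetic leaf-image generator makes
the whole pipeline testable at desk scale.

## Worked example

```r
library(ercpnet)

set <- generate_synthetic_dataset(synthetic_spec(num_classes = 4, per_class = 24,
                                                 image_size = 64, seed = 42))
sp  <- split_dataset(set, seed = 1)                 # stratified 6:2:2

cfg <- network_config("ercp_net", stem_width = 4, input_size = 64,
                      num_classes = 4, seed = 1)
net <- build_network(cfg)
net
#> <ercp_network> variant=ercp_net  input=64x64  classes=4  parameters=234,273

res <- train_network(net, sp$train, sp$val, train_config(epochs = 12, seed = 1))
tail(res$history, 3)
#>    epoch train_loss train_accuracy val_accuracy   lr
#> 10    10 0.01908440              1       1.0000 0.01
#> 11    11 0.04607406              1       1.0000 0.01
#> 12    12 0.01693081              1       0.9375 0.01

ev <- evaluate_network(res$net, sp$test)
ev$metrics
#> accuracy: 1.0000  macro precision: 1.0000  macro recall: 1.0000
ev$confusion
#>     predicted
#> true 0 1 2 3
#>    0 4 0 0 0
#>    1 0 4 0 0
#>    2 0 0 4 0
#>    3 0 0 0 4
```

The history rows are (epoch, mean cross-entropy, train accuracy, validation
accuracy, learning rate); `ev$metrics` reports accuracy = trace/total and
unweighted one-vs-rest precision/recall. The parameters restored at the end
are those of the best validation epoch.

Interpretation and layer bookkeeping:

```r
shape_summary(build_network(network_config(seed = 1)))  # the 416x416 contract
hm <- grad_cam(res$net, sp$test$items[[1]]$image, target_class = 0)
```

A thin command-line interface wraps the same functions
(`inst/cli/ercpnet.R`): `summary`, `gen-fixtures`, `train`, `eval`,
`predict`, `gradcam`, driven by a YAML config (see `read_config()`).

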