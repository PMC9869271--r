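# glandnet

Detection and counting of cotton pigment glands in RGB leaf images.

Pigment glands are dark, near-circular structures roughly 100–400 µm
across (a few pixels at ~45 µm/px) that pepper the leaves of glanded
cotton by the hundreds; their density tracks gossypol content, so they
get counted — traditionally by hand, at hours per leaf. `glandnet`
automates this with a semantic-segmentation approach built for dense,
tiny objects on a confounding background of dark leaf-vein shadows.

The package provides:

* **An interpolation–pooling segmentation network** — an inverted U-Net
  that *enlarges* the tile first (two stages of double 3×3 same
  convolutions + batch norm + ReLU, each followed by ×2
  nearest-neighbour interpolation: 120 → 240 → 480) and only then
  contracts back with max pooling (480 → 240 → 120), fusing each
  down-path stage with the matching up-path features by channel
  concatenation. A 1×1 convolution + rectifier yields a single-channel
  response map; thresholding gives the gland mask. Enlarging before
  pooling avoids collapsing 3-px glands to points, which is what defeats
  the classic contract-first design here. Forward, backward and the Adam
  optimiser are implemented in single-precision RcppArmadillo (no
  deep-learning framework required) and verified against an independent
  double-precision reference plus finite differences.
* **Training** with mean-squared-error loss against {0, 1} masks
  (defaults: Adam, 60 epochs × 250 steps × batch 2), per-epoch
  validation metrics, best-checkpoint retention, JSON checkpoints.
* **Tile-based inference**: 100×100 cores expanded to 120×120 context
  windows, predicted, margin-trimmed and stitched seam-free
  (`stitch(crop(m)) == m` exactly).
* **Post-filtering and counting**: connected-domain labeling (4/8
  adjacency), optional disk closing, area filtering (default 2–938744
  px), per-region tables, whole-leaf counts.
* **Evaluation**: confusion-matrix mIoU / precision / recall / F1 /
  pixel accuracy, and counting agreement as squared Pearson r².
* **A synthetic leaf-scene generator** with exact ground truth (counts
  provably equal mask components) at three density strata (<40, 40–79,
  ≥80 glands per 4.5×4.5 mm), with vein-like confounders — every stage
  is testable without real leaf data.
* **A CLI** (`exec/glandnet`) with `generate`, `train`, `predict`,
  `count` and `evaluate` subcommands driven by YAML configs.

## Worked example

Train on synthetic low-density tiles and count glands in a fresh scene:

```r
library(glandnet)

train <- generate_tile_set(200, density_level = 1, size = 120, seed = 1)
held  <- generate_tile_set(50,  density_level = 1, size = 120, seed = 100001)

fit <- glandnet_fit(train$x, train$y, held$x, held$y,
                    control = train_config(epochs = 5, steps_per_epoch = 100,
                                           batch_size = 2, seed = 1),
                    verbose = TRUE)
#> epoch 1: train loss 0.02203, val loss 0.00420, val F1 0.9767
#> ...
#> epoch 5: train loss 0.00109, val loss 0.00088, val F1 0.9957
```

Each history line reports the mean training MSE over the epoch and the
validation loss/F1 at threshold 0.5 — F1 near 0.98 after a single epoch
means the network almost immediately separates gland pixels from
background and veins on these scenes. Counting the held-out tiles:

```r
cfg <- filter_config(min_area = 2, closing_radius = 0)
pred <- vapply(held$x, function(t)
  count_glands(binarize(net_forward(fit, t), 0.5), cfg), numeric(1))
head(cbind(truth = held$counts, pred))
#>      truth pred
#> [1,]    32   32
#> [2,]    43   43
#> [3,]     9    9
#> [4,]    20   20
#> [5,]    12   12
#> [6,]    43   43
count_r2(pred, held$counts)
#> [1] 0.9994152
```

An r² of 0.999 against the generator's true counts says the full chain —
forward pass, thresholding, area filtering, domain counting — recovers
per-tile gland numbers almost perfectly at this density. For a full
leaf image, `predict()` runs the tiling chain end to end:

```r
scene <- generate_scene(scene_config(width = 1600, height = 1200,
                                     spot_count = 300, seed = 7))
p <- predict(fit, scene$image)
p
#> Gland prediction: 301 glands in a 1600x1200 px image (tau 0.50)
```

(The scene truly contains 300 glands; one spurious extra domain
survived the area filter — the kind of residual error the shape-feature
filtering stage is documented to leave. A 1600×1200 leaf takes about
70 s to segment on one CPU core.)

Published pixel tallies can be scored directly:

```r
segmentation_metrics(confusion_counts(tp = 42681, fp = 10645,
                                      fn = 10644, tn = 666030))
#> Segmentation metrics
#>   mIoU:      0.8181 (fg 0.6672, bg 0.9690)
#>   Precision: 0.8004
#>   Recall:    0.8004
#>   F1-score:  0.8004
#>   Pixel acc: 0.9708
```

## Command line

```sh
exec/glandnet generate --config cfg.yaml        # synthetic scenes + manifest
exec/glandnet train    --config cfg.yaml        # fit + checkpoint + history
exec/glandnet count    --config cfg.yaml        # masks, region tables, counts
exec/glandnet evaluate --config cfg.yaml        # metrics JSON from mask pairs
```

Flags such as `--seed`, `--out_dir` or `--train.epochs 5` override the
YAML config; every run writes a `provenance.json` with the config digest
and package version. Exit codes: 0 success, 2 config error, 3 data
error, 4 runtime failure.
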