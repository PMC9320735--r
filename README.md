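# tomseg — two-stage RGB-D segmentation for tomato sucker detection

Tomato suckers (axillary shoots) emerge at stem nodes, always between the
stem and a branch, and must be pruned while young. `tomseg` finds them in
RGB-D images by four-class semantic segmentation — other (0), stem (1),
branch (2), sucker (3) — with a lightweight confidence-gated cascade:

1. **Stage 1**, a small depthwise-separable network, produces a first
   softmax map. The per-pixel confidence `Premax(p) = max_c p_c` is
   thresholded at `t1 = 0.7`: pixels at or below it are *hard*.
2. **Stage 2** consumes the full RGB image plus the hard-pixel-masked RGB
   and the hard-pixel-masked *mean-centered* depth
   (`D_ij = d_ij − mean(d)`), concatenated at a 12:16:4 channel ratio,
   and emits the final full-resolution map through bottleneck residual
   blocks, three multi-kernel grouped feature blocks, pyramid pooling and
   a skip-fused classifier.

Selective depth fusion is the point: a far stem crossing behind a near
stem–branch junction mimics a sucker in 2-D, but sits at the wrong depth.
Detected suckers are scored by a connected-component procedure: predicted
sucker regions smaller than `t = 160` px are discarded as noise, and a
true sucker counts as found when its component overlaps the filtered
prediction (the elementwise sum reaches 2).

The package is self-contained scientific R: depth codec
(`d = R + 256·G + 65536·B`, lossless in an 8-bit RGB PNG), a seeded
synthetic scene generator replacing the undeposited farm dataset, the
network blocks with exact trainable-parameter accounting, a
forward/backward layer engine in R/C++ (no deep-learning framework), the
two-phase training protocol (SGD momentum 0.9, lr 0.025 decaying ×0.997
per step, batch 12, 40 epochs), and the IOU/counting metrics.

## Worked example

```r
library(tomseg)

# a small synthetic scene set: thin stems/branches, suckers in the axils,
# a far plant crossing behind the near one
scenes <- generate_dataset(5, scene_params(height = 120, width = 160, seed = 42))

# two-phase training: stage 1 first, then stage 2 with stage 1 frozen
model <- build_variant("proposed", seed = 7)
model <- train_phase(model, scenes,
                     train_config(batch_size = 1, iterations = 120,
                                  augment = FALSE, seed = 5, phase = "stage1"))
model <- train_phase(model, scenes,
                     train_config(batch_size = 1, iterations = 380,
                                  augment = FALSE, seed = 5, phase = "stage2"))

evaluate_dataset(model, scenes)
#> mean IOU 0.9527 (foreground 0.9404); sucker detection 71.4% on 5 images

pr <- predict_sample(model, scenes[[1]])
table(pr$label)            # pixels per predicted class
#>     0     1     2     3
#> 14024  2775  1515   886
pr$diagnostics$n_hard      # pixels routed to stage 2
#> [1] 1866

count_params(model)
#> total trainable parameters: 680,763
```

The mean IOU line says the trained cascade reproduces the five training
scenes almost pixel-perfectly (a capacity check, not a generalization
claim): about 10% of pixels are flagged hard by stage 1 and re-examined
with depth, and 5 of the 7 ground-truth suckers overlap a predicted
region that survives the 160 px noise filter. The parameter total sits 3 entries (0.0004%) above the published
680,760; `resolve_variant()` shows no reading of the printed block tables
matches exactly (one group count is a typo) and freezes the nearest one —
see `inst/extdata/variant_report.txt` for the per-block report.

A command-line launcher wraps the same functions:

```sh
Rscript inst/cli/tomseg.R synth --n 10 --seed 1 --out data --small
Rscript inst/cli/tomseg.R train --data data --out model.rds --no-augment
Rscript inst/cli/tomseg.R predict --weights model.rds \
    --rgb data/rgb/scene_0001.png --depth data/depth/scene_0001.png --out pred.png
Rscript inst/cli/tomseg.R eval --weights model.rds --data data --report report.json
Rscript inst/cli/tomseg.R count-params --variant proposed
```

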