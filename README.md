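# milwsi

Weakly-supervised multiple-instance learning (MIL) for whole-slide-image
(WSI) carcinoma classification in R.

## The problem

Tile classifiers drive most computational-pathology pipelines: a gigapixel
slide is cut into square tiles at a working magnification, each tile gets a
carcinoma probability from a classifier, and the slide-level call is the
maximum tile probability ("max aggregation"). Fully supervised (FS)
training derives tile labels from pathologists' polygon region
annotations — but surgical-specimen annotations are not cell-accurate:
carcinoma outlines deliberately include internal necrosis, fibrosis and
inflammatory infiltrate, tissue that also occurs in purely non-neoplastic
lesions. Region-derived tile labels are therefore noisy in a structured
way, and an FS model learns to call benign necrosis/inflammation
"carcinoma".

The weakly-supervised (WS) alternative implemented here needs only
slide-level diagnoses after a short warm phase. Each MIL epoch alternates
inference and training: the frozen model scores every tissue tile of each
slide in sliding-window fashion, the top-k tiles by carcinoma probability
are selected (k decaying linearly 5 → 1 across epochs) and labelled with
the *slide* label, and the model trains on them whenever an accumulation
buffer (n = 512) fills, in Adam batches of 64. On a carcinoma slide the
top tiles are true positives; on a non-neoplastic slide they are exactly
the model's would-be false positives — hard negatives. Slide probability
is `max_i p(tile_i)`; evaluation is slide-level ROC AUC and log loss with
95% percentile-bootstrap confidence intervals (1000 iterations).

The package implements both regimes end to end — slide tiling and tissue
masking, GeoJSON region annotations with the carcinoma-priority slide
label rule, the FS warm-start/decay schedule (0.001 → 0.05, 0.9/epoch,
early stopping patience 10), the WS warm phase (k = 32 tiles/slide,
2 epochs) and MIL loop, max-aggregation scoring, probability heatmaps,
and bootstrap evaluation — plus a synthetic-slide generator whose cohorts
reproduce the tile-label-noise structure (a necrosis/inflammation texture
shared between carcinoma regions and non-neoplastic slides), so the whole
pipeline is testable on a laptop with no external data.

## Worked example

The desk-scale protocol (512×512-px synthetic slides, 64-px tiles,
120 slides: 64 train / 16 validation / 40 held out) compares the two
regimes on one confounded cohort:

```r
library(milwsi)

res <- desk_compare_regimes(seed = 11, confounded = TRUE)
round(c(fs = res$auc_fs, ws = res$auc_ws), 3)
#>    fs    ws
#> 0.984 0.989
round(c(fs = res$log_loss_fs, ws = res$log_loss_ws), 2)
#>   fs   ws
#> 0.39 0.43
```

Both models see the same slides; only the supervision differs. The FS
baseline is trained on region-labelled tiles — including necrosis tiles
labelled "carcinoma" — so at test time it scores the same texture highly
on non-neoplastic slides, and its held-out slide AUC drops. The WS model's
hard-negative stream pushes that texture down and recovers the ranking.

Lower-level pieces compose explicitly:

```r
spec    <- desk_cohort_spec(seed = 11)       # 120-slide cohort spec
records <- generate_cohort_records(spec)     # in-memory slide records
ws      <- mil_train(records[1:64], records[65:80], desk_mil_config(11))
preds   <- predict(ws, records[81:120])      # slide_id, probability, ...
head(preds, 3)
#>    slide_id probability predicted_label n_tiles
#> 1 slide_081   0.3457694  non_neoplastic     184
#> 2 slide_082   0.7389706       carcinoma     155
#> 3 slide_083   0.2364459  non_neoplastic     165
```

A YAML-configured pipeline (`run_pipeline()`, stages synthesize /
train-fs / train-ws / predict / evaluate) and a thin command-line wrapper
(`inst/cli/milwsi.R`) wire the same functions together with provenance
files and byte-deterministic outputs under a fixed master seed.

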