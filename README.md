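# phenodistill

Crop phenology — the ordinal march of a wheat stand through emergence,
tillering, jointing, booting, heading, anthesis, filling and maturity
(stages 1–8) — is far easier to classify from a *series* of field images
than from one photograph: adjacent stages look alike in a single frame,
while the growth history disambiguates them. But a model that needs all 30
past frames at inference time is a poor fit for cameras at the field edge.

`phenodistill` is for researchers and agronomic-tooling engineers who want
the accuracy of a temporal model in a single-image classifier. It trains a
**teacher** (shared convolutional backbone applied per frame + LSTM over
the frame features) on image series, then distills it into a **student**
(the backbone alone) with two transfer signals:

* **Knowledge distillation** — the student matches the teacher's
  temperature-softened class distribution
  `q_i = exp(z_i/T) / Σ_j exp(z_j/T)` in addition to the one-hot ground
  truth: `L = α·L_soft + (1−α)·L_hard` with `T = 3`, `α = 0.7`.
* **Multi-layer attention transfer** — at five backbone tap points the
  activation is collapsed to a spatial attention map `Σ_c A_c²`
  (L2-normalized), and the student's maps are pulled toward the teacher's:
  `L = α·L_soft + (1−α)·L_hard + β·Σ_{i∈S} ‖vec(A_i^S) − vec(A_i^T)‖₂`
  with `β = 0.001` and layer subset `S = {1,3,4}` by default.

Everything runs on one CPU: the package ships a compact pure-R neural
engine (BLAS-backed im2col convolutions, LSTM with backpropagation through
time, Adam), a synthetic ordinal growth-stage image generator (so no
download is ever needed), manifest/series data handling with series-level
6:2:2 splits and temporally coherent 3× augmentation, the full ordinal
metric suite (OA, macro F1, Cohen's kappa, ordinal MAE), ablation
harnesses (loss components; all 31 attention layer subsets), and
attention-map interpretability panels.

## Worked example

```r
library(phenodistill)

## a synthetic world: 250 series of 8 frames at 16 px; sigma blurs
## adjacent stages in single frames, temporal context resolves them
cfg  <- synth_config(n_series = 250, frames_per_series = 8,
                     image_size = 16, sigma = 0.05, seed = 101)
data    <- generate_dataset(cfg)
samples <- assemble_series(data, L = 8)
sp      <- split_series(samples, split_spec(seed = 1))   # 150 / 50 / 50

mc      <- backbone_config(input_size = 16L)             # "mini" preset
teacher <- train_teacher(sp$train, sp$val,
                         train_config(epochs = 25, seed = 1), mc)
student <- train_student(sp$train, sp$val, teacher$model,
                         train_config(epochs = 50, seed = 1),
                         mode = "kd_at", model_config = mc)

evaluate_model(teacher$model, sp$test)
#> OA 0.6200 | macro F1 0.5489 | kappa 0.5616 | MAE 0.4200 (n = 50)
evaluate_model(student$model, sp$test)
#> OA 0.5200 | macro F1 0.4640 | kappa 0.4432 | MAE 0.5400 (n = 50)

## the same student trained on hard labels only, for comparison
baseline <- train_student(sp$train, sp$val, NULL,
                          train_config(epochs = 50, seed = 1),
                          mode = "baseline", model_config = mc)
evaluate_model(baseline$model, sp$test)
#> OA 0.4800 | macro F1 0.4628 | kappa 0.4017 | MAE 0.6000 (n = 50)

render_attention_panel(student$model, sp$test[[1]]$images[[8]],
                       "panel.png")   # input frame + 5 layer heatmaps
```

Reading the numbers: the teacher sees the frame history and clearly beats
any single-frame model on this deliberately ambiguous world (OA 0.62 vs
0.48–0.52; its ordinal MAE 0.42 means its errors are mostly one adjacent
stage). The distilled student recovers part of that margin from one frame
alone (0.52 vs the hard-label baseline's 0.48, with lower MAE).
`run_component_ablation()` systematizes that comparison over seeds, and
`run_layer_sweep()` sweeps attention-layer subsets.

A command-line wrapper covering the same pipeline
(`generate / prepare / train-teacher / train-student / evaluate / ablate /
visualize / report`) is installed at
`system.file("cli", "phenodistill.R", package = "phenodistill")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, by running the installed package from scratch: the
augmentation-accounting quantities of the reference study (the per-stage
training counts expanded 3×, their totals, and the overall sample total)
from the published before-augmentation counts shipped as a plain-text
fixture, and then exercises the full generate → split → train-teacher →
distill-student → evaluate → visualize pipeline at desk scale, printing
the resulting test metrics. Results are written as JSON to `--out`.

## Notes

* The `resnet50` preset builds the full bottleneck architecture (≈23.5M
  parameters at 8 classes) for parameter accounting and full-scale use;
  the `mini` preset (≈0.1M) preserves the same 5-tap topology at desk
  scale. See `vignettes/distillation-methods.Rmd` for the model,
  assumptions, design decisions and limitations.
* Images are 8-bit RGB PNGs written by a deterministic built-in codec, so
  generated datasets and attention panels are byte-stable across runs.
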