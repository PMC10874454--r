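# signalfate

Tools for asking how dynamic BMP–SMAD4 signaling controls the
amnion-versus-pluripotency decision in human pluripotent stem cells, at
single-cell resolution. The package is written for quantitative biologists
analyzing live-imaging signaling data: it implements the full computational
pipeline from tracked nuclei to a mechanistic gene-circuit model, and ships a
synthetic-data generator with known ground truth so every stage is testable
end to end without imaging data.

## The science in brief

A cell's SMAD4 signaling history after BMP4 is a descending sigmoid

    s(t) = L + (H − L) / (1 + exp((t − d)/τ))

with high plateau `H`, low plateau `L`, duration `d` and timescale `τ`. The
central quantity is the signaling integral Σ = ∫(s(t) − b) dt: fate is
threshold-like in Σ, so a lower signaling level can be compensated by a longer
duration. The pipeline quantifies this four ways:

1. **Features and prediction** — sigmoid fits, PCA of histories,
   MAGIC-style graph-diffusion denoising (knn = 3, t = 3) with a
   randomized-pairing artifact control, the continuous fate score
   log(ISL1/NANOG), an exact optimal-threshold (Bayes) classifier per
   feature, and cross-validated full-history classifiers (ridge logistic,
   quadratic SVM). The full history predicts fate no better than Σ alone.
2. **Dose-response collapse** — differentiation curves at different signaling
   levels have different duration thresholds (≈26 h at full level, ≈32 h at
   0.8×) but a single common threshold on the Σ axis; a level+duration
   alternative model fails this collapse.
3. **Micropatterns** — 30 equal-count radial bins, kymographs, soft k-means
   (k = 3) signaling-class maps and dominant-fate maps that agree bin by bin.
4. **Mechanism** — an RNA-seq screen for integrator genes (CPM ≥ 2.5,
   cumulative |log2FC| above mean + 1 SD, Ward/Euclidean clustering into
   three temporal classes, dose-correlation > 0.9 and slope > 0.1 filters,
   TF intersection) singles out SOX2-like candidates; a two-ODE SOX2/ISL1
   model — SMAD4 linearly represses SOX2 production, SOX2 autoregulates and
   mutually represses ISL1, decay fixed at the FRAP-measured ln(2)/7 h⁻¹ —
   integrates signaling, commits permanently past a bistable switch, and
   collapses ISL1 output onto one Σ threshold.

Division-aware single-cell tracking (global assignment with birth/death
costs, metaphase-labeled division hypotheses, live-to-fixed matching) feeds
the pipeline from detection tables.

## Worked example

```r
library(signalfate)

# 500 synthetic signaling histories with known ground truth
hs <- gen_histories(history_gen_params(n_cells = 500, noise_sd = 0.1, seed = 1))
ft <- gen_fates(hs$truth, fate_gen_params(seed = 1))   # 7 fate markers/cell

# features: sigmoid fits + integral + PCs
feat <- extract_features(hs$histories, hs$time, baseline = 1)
median(abs(feat$d - hs$truth$d))   # 0.125  (duration recovered to ~8 min)

# fate score and the optimal integral threshold
sc <- fate_score(ft)                         # log(ISL1/NANOG), amnion if > 0
bt <- bayes_threshold(feat$integral, sc$label)
bt$accuracy                                  # 0.854
bt$threshold                                 # 26.3  (generator planted 26)

# the full history adds nothing beyond the integral (5-fold CV)
bayes_threshold_cv(feat$integral, sc$label, seed = 1)$cv_accuracy   # 0.836
history_classifier(hs$histories, sc$label, "svm_quadratic",
                   seed = 1)$cv_accuracy                            # 0.850

# integral collapse: duration thresholds shift with level, Σ threshold doesn't
dr <- gen_dose_response(levels = c(1, 0.8), seed = 2)
ct <- collapse_test(dr)
ct$feature_thresholds   # 26.0 h (full level)  32.5 h (0.8x level)
ct$sigma_cv             # 0.00023 -> same integral threshold in every condition
```

The numbered scripts under `analysis/` run the complete study — simulate,
track, extract features, denoise and predict fate, map micropattern colonies,
fit the integrator model, run the RNA screen — and write their tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Example output (`analysis/02_track.R`, `analysis/07_screen.R`):

```
link accuracy   99.47% of 5140 true links
division recall 100% of 10 divisions
...
147 genes pass the dynamic-change filter (cumulative |log2FC| > 7.83 = mean + 1 SD)
Ward clustering vs planted classes: ARI 0.989
21 immediately decreasing and 9 immediately increasing TF candidate integrators
candidate recovery: F1 down 1.00, F1 up 1.00
```

`run_pipeline(default_config(seed = 1), "out/")` runs the same study as one
call with a checksummed manifest; reruns are bit-identical.

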