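# esper

Carbon-footprint-aware benchmarking of machine-learning model zoos, built
for computational pathology but applicable to any classification
benchmark with energy measurements.

Deep-learning models for whole-slide-image (WSI) diagnosis are usually
ranked by performance alone, yet their training and inference emit
measurably different amounts of CO2-equivalent (CO2eq). `esper`
implements the *environmentally sustainable performance* score family,
which integrates both: for model *i* in a comparison series with metric
*M<sub>i</sub>* ∈ [0, 1] and emission *E<sub>i</sub>*,

```
ESPer_i = M_i^2 / exp(w * E_i')          E_i' = (E_i - min E) / (max E - min E)
```

with weighting factor *w* ∈ [0, 1] (default 1; *w* = 0 scores
performance only). **iESPer** uses per-inference emissions; **fpESPer**
uses training plus projected cumulative inference emissions over a usage
horizon, with the normalization recomputed at every horizon point so
rankings can cross over time. Around the score the package provides:

- energy → CO2eq conversion with regional carbon intensity and facility
  PUE, with strict unit canonicalization (Wh/g internally);
- the five standard metrics (macro one-vs-rest AUROC via midrank
  Mann–Whitney, balanced accuracy, macro precision/recall/F1) computed
  from per-case prediction tables;
- mortality-cost-of-carbon usage budgets (4400 t CO2eq per
  temperature-related excess death) and per-country comparisons;
- tile-size/resolution and tile-fraction data-reduction sweeps scored by
  iESPer;
- percentile-bootstrap confidence intervals over cases and energy
  replicates;
- a deterministic synthetic benchmark (mock energy meter with a
  tile-count cost model, model-zoo generator, binormal prediction
  simulator with closed-form AUROC) replacing GPU measurement;
- a command line (`score`, `project`, `mortality`, `sweep`, `simulate`)
  installed at `system.file("scripts", "esper", package = "esper")`.

## Worked example

Score the bundled kidney-transplant (KTX) benchmark of five WSI
classifiers:

```r
library(esper)
ser <- load_series(system.file("extdata", "benchmark_ktx.csv", package = "esper"))
scores <- iesper(ser, esper_config(w = 1, metric = "auroc"))
scores[order(scores$rank), c("model_id", "metric_value", "emission_g",
                             "normalized_emission", "value", "rank")]
#>   model_id      metric_value emission_g normalized_emission value  rank
#> 1 TransMIL             0.761      0.046              0      0.579     1
#> 2 CLAM                 0.744      0.048              0.0109 0.547     2
#> 3 ViT                  0.698      0.065              0.104  0.439     3
#> 4 InceptionV3          0.673      0.073              0.148  0.391     4
#> 5 Prov-GigaPath        0.715      0.229              1      0.188     5
```

TransMIL has the lowest per-slide emission (0.046 g CO2eq), so its score
is exactly its squared AUROC (0.761² = 0.579). Prov-GigaPath's AUROC is
third-best, but as the series-maximum emitter (0.229 g/slide,
normalized emission 1) its squared metric is divided by *e*, dropping it
to last — the intended behaviour: comparable accuracy does not excuse a
5× emission footprint.

Pick the most sustainable tile configuration for one architecture:

```r
res <- resolution_sweep(read.csv(system.file("extdata",
         "resolution_sweep_ktx.csv", package = "esper")), w = 1)
res$scores[, c("config", "metric_value", "emission_g", "iesper")]
#>   config       metric_value emission_g iesper
#> 1 224px/1024um        0.702      0.025  0.493
#> 2 224px/256um         0.762      0.138  0.546
#> 3 512px/256um         0.678      0.383  0.379
#> 4 224px/128um         0.64       1.87   0.151
res$best$config
#> [1] "224px/256um"
```

The coarsest tiles (1024 µm) are cheapest but lose structural detail;
the finest (128 µm) cost 75× more CO2eq per slide for the *worst*
AUROC. 256 µm tiles at 224 px balance both and win.

How many inferences before the emissions statistically cost one life?

```r
usages_until_one_death(0.128, 361)   # 0.128 Wh/slide on the German grid
#> [1] 95221606648
```

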