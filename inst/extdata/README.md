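# Bundled fixture tables

Small plain-text fixtures for examples and tests. Provenance of each value:

- `benchmark_ktx.csv`, `benchmark_rcc.csv` — five whole-slide-image
  classifiers benchmarked on a kidney-transplant (KTX) and a renal-cell-
  carcinoma (RCC) task. The energy and CO2eq columns are the published
  per-model measurements (training once over 300 epochs on 1000 slides;
  inference averaged over 1000 slides of 1000 tiles each, German grid).
  The `metric_*` columns are **recovered**, not published: the source
  tables print iESPer scores rather than raw metrics, so metric values
  here were obtained by inverting M = sqrt(score * exp(w * norm)) from
  the printed scores and emissions (w = 1). They carry the rounding error
  of the printed 3-decimal scores.
- `resolution_sweep_ktx.csv` — published per-slide CO2eq and AUROC of one
  architecture (TransMIL) at four tile size/resolution configurations on
  the KTX task.
- `carbon_intensity.csv` — the DE row (361 g/kWh) is **recovered** from
  the published training-row emission/energy ratios, which agree on it to
  within 0.1 g/kWh; it is not an officially sourced grid figure. All
  other rows are **synthetic illustrative** magnitudes for demonstrating
  cross-country comparisons, not sourced statistics.
- `prevalence_illustrative.csv` — **synthetic illustrative** per-class
  positive rates for converting usage budgets into expected positive
  predictions; the source work does not publish the rates it used.
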