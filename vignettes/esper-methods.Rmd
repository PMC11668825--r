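---
title: "Scoring model zoos on performance and carbon footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model zoos on performance and carbon footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esper)
```

## The problem

Benchmarks of deep-learning models for computational pathology rank
architectures almost exclusively by diagnostic performance. Training and
inference on gigapixel whole-slide images (WSIs), however, consume enough
electricity that widespread clinical deployment carries a real carbon
footprint, and two models of near-identical AUROC can differ in
per-inference emissions by a factor of five. This package implements a
family of *environmentally sustainable performance* (ESPer) scores that
fold operational CO2-equivalent (CO2eq) emissions into model selection,
together with the surrounding machinery: energy-to-CO2eq conversion,
mortality-cost-of-carbon usage budgets, data-reduction sweeps, and a
synthetic benchmark generator that stands in for GPU power metering.

## The score

For model $i$ in a *comparison series* with performance metric
$M_i \in [0,1]$ and emission $E_i$,

$$\mathrm{ESPer}_i \;=\; \frac{M_i^2}{\exp\!\big(w \cdot E_i'\big)},
\qquad E_i' = \frac{E_i - \min_j E_j}{\max_j E_j - \min_j E_j},$$

with weighting factor $w \in [0,1]$. The square rewards highly accurate
models; range normalization puts arbitrarily scaled emissions on $[0,1]$;
the exponential penalizes high emitters while avoiding a zero division at
the series minimum. Two variants share this form:

* **iESPer** (`iesper()`) uses per-inference emissions $E_i$ — the
  steady-state cost of one more slide.
* **fpESPer** (`fpesper()`) uses the combined emission
  $E_i(n) = \mathrm{train}_i + n \cdot \mathrm{perUse}_i$ after $n$
  projected usages, so training cost matters early and inference cost
  dominates in the long run.

Structural consequences, all enforced by tests:

* $0 \le \mathrm{ESPer}_i \le M_i^2 \le 1$, with equality exactly when
  $w = 0$ or model $i$ has the series-minimum emission.
* Scores are invariant under affine rescaling of emissions
  ($x \mapsto ax + b$, $a > 0$): units cancel in the normalization.
* Scores are **series-relative**: adding or removing a model moves the
  normalization bounds and hence every other model's score. The score
  ranks models *within* one benchmark; it is not comparable across
  benchmarks, by design.
* For fpESPer the normalization bounds are recomputed at every $n$ over
  the current combined emissions. This is what makes projection curves
  non-trivially time-varying and lets a cheap-to-train/expensive-to-run
  model be overtaken by its converse; normalizing once at $n = 0$ would
  freeze the ranking geometry and was rejected for that reason.

A degenerate series (all emissions equal, or a single model) normalizes
to all zeros, so every score reduces to $M^2$ — with no emission spread
there is nothing to discriminate on, and the $w = 0$ limit is preserved.

The weighting factor defaults to $w = 1$ (full emission weighting);
`weight_sweep()` tabulates how rankings respond as $w$ moves to 0.
Rankings break ties deterministically: lower emission wins, then
lexicographic model id.

## Emissions and units

CO2eq is obtained by multiplying measured energy with a regional carbon
intensity (g CO2eq per kWh of electricity produced), optionally after a
facility power-usage-effectiveness (PUE) factor (default 1.58) when the
meter reported device-level draw. Internally all energies are Wh and all
emissions grams; interchange files use the mixed kWh/kg (training) and
Wh/g (inference) units conventional in published tables, converted
exactly once at load time. Values are stored at full precision and
rounded (3 decimals, g or kg by magnitude) only in rendered reports.

The bundled `benchmark_ktx.csv` / `benchmark_rcc.csv` fixtures carry the
published energy and emission measurements of five WSI classifiers; their
training emission/energy ratios agree on an implied German carbon
intensity of 361 g/kWh to within 0.1, and that recovered value ships in
`carbon_intensity.csv` (clearly labeled recovered, not sourced — see
`inst/extdata/README.md`). One published inference cell (0.170 Wh printed
as 0.065 g) is inconsistent with this intensity, and with its own running
text (0.062 g); loaders take what the file states and the discrepancy is
documented rather than resolved. The fixtures' `metric_*` columns are
likewise recovered by inverting the score formula from printed scores,
since the source tables print scores rather than raw metrics.

## Performance metrics

`macro_auroc()` computes one-vs-rest AUROC per observed class via the
midrank Mann–Whitney statistic (ties credit 0.5 per pair, so permuting
equal scores never changes the value) and averages unweighted over
classes. The one-vs-rest reading of "macro averaged" was chosen over
pairwise class–class averaging as the standard interpretation of that
phrase. `classification_report()` applies the argmax decision rule (ties
to the lowest class index) and returns balanced accuracy (mean per-class
recall) plus macro precision, recall and F1; a class that is never
predicted contributes precision 0 with a warning — the common reporting
convention for zero denominators.

Confidence intervals (`esper_ci()`) use a percentile bootstrap
(2.5/97.5) resampling cases (performance) and energy replicates
(emissions) jointly, recomputing the whole series' scores per draw so the
interval reflects the series-relative normalization. The bootstrap is our
choice; the published intervals do not state their method.

## Mortality cost of carbon

Using the published estimate that 4400 t of added CO2eq cause one
temperature-related excess death by 2100, `usages_until_one_death()`
converts a per-inference emission into a usage budget
$\lfloor 4.4\times10^9 / g_{\mathrm{use}}\rfloor$ (floored: usages are
counts). Budgets are exactly inversely proportional to carbon intensity,
so the model ranking is identical in every country — only the absolute
budgets move with the energy mix. Per-class positive-prediction counts
multiply the budget by a user-supplied prevalence; the shipped prevalence
table is illustrative, as the source work does not publish its rates.

## Data-reduction sweeps

WSIs are processed as square tiles (physical edge in µm, resized to a
fixed pixel count), so per-slide cost scales with the tile count:
`tiles_per_slide()` is $\lceil \mathrm{area}/\mathrm{edge}^2 \rceil$
(partial border tiles are still processed). Two reduction strategies are
scored by iESPer *with the sweep itself as the comparison series* — the
published per-resolution scores are only reproducible under this reading,
since the sweep's own min/max set the normalization bounds:

* `resolution_sweep()` over (pixels, edge-length) configurations; argmax
  returned, ties toward lower emission.
* `fraction_sweep()` over random tile subsets, which must include the
  full-data point (fraction 1.0) as reference and must have emissions
  strictly increasing in the fraction (a violation indicates a corrupted
  sweep, not a modeling choice). Besides the argmax it reports the
  smallest fraction whose performance is within a plateau tolerance of
  the 100% value; the default 0.005 absolute AUROC operationalizes
  "comparable performance", which the source leaves unquantified.

## Synthetic benchmark

Because GPU power metering and patient cohorts are unavailable at a desk,
the generator supplies deterministic stand-ins at the published
magnitudes:

* `mock_meter()` prices a slide at
  `n_tiles × Wh/tile × PUE × (1 + ε)`, ε ~ Normal(0, cv) truncated at
  −0.99; training multiplies by epochs × backprop-multiplier × slides.
  The default protocol mirrors the published measurement setup: 300
  epochs, 1000 training slides of 1000 tiles, 15 inference replicates,
  with the training run metered once and noise-free (the source measured
  training with n = 1) — which also confines generated training
  emissions to 1–50 kg CO2eq by construction.
* `generate_model_zoo()` draws per-model Wh/tile log-uniformly in
  [4e-5, 5e-4] (per-slide inference ≈ 0.04–0.5 Wh, bracketing the
  published 0.128–0.63 Wh) and backprop multipliers in [0.25, 0.9]
  (the published training/inference energy ratios imply ≈ 0.3), then
  computes all metrics end-to-end from simulated predictions.
* `simulate_predictions()` uses a binormal score model. For two classes
  each case carries a single discriminant
  $x \sim \mathcal N(d'\,[y{=}1],\,1)$ mapped to a class-1 probability by
  a strictly increasing logistic transform, so the one-vs-rest AUROC of
  either class is exactly $\Phi(d'/\sqrt2)$ — an analytic anchor the
  tests invert to recover $d'$. A naive alternative (per-class scores
  with softmax) was rejected for $K = 2$ because the softmax ranks by the
  score *difference*, doubling the separation and breaking the closed
  form; for $K > 2$ that construction is retained and documented as
  approximate.

What passing synthetic tests do **not** show: real WSI cohorts have
correlated tiles, class imbalance, scanner/stain domain shift and
non-Gaussian score distributions, and real energy draw varies with
batch shape and hardware contention. The generator validates the scoring
machinery, not any claim about real cohort performance.

## Numerical choices

* Crossing detection (`find_crossings()`) locates sign changes of the
  score difference on a 512-point usage grid and refines each bracket by
  bisection on the continuous formula (real-valued $n$) to a relative
  tolerance of 1e-6; curves that merely touch yield no crossing, and
  identical curves return an empty list by contract.
* Projection grids round $n(t) = \mathrm{annual} \times t$ to whole
  usages.
* Metric values are validated against $[0,1]$, never clipped: an
  out-of-range input is a data error, not a value to repair.
* Bootstrap draws in which a resampled cohort loses a class (making
  AUROC undefined) are dropped as NA rather than silently rescored.

## Problem sizes

The test suite and the acceptance script run the binormal simulator at
20,000 cases (Monte-Carlo error ≈ 0.003 in AUROC, comfortably inside the
±0.01 check), model zoos of 3–6 models with 120–300 evaluation cases,
and bootstrap intervals at 150 draws — sizes chosen so the full suite
exercises every path in under a minute of CPU while keeping every
stochastic assertion far from its tolerance boundary.

## Known limitations

Only operational energy is modeled: hardware manufacture, water use and
the rest of the life cycle are out of scope, as in the source framework.
Carbon intensities are static historical values, not live grid data. The
score is deliberately not comparable across series, and no Pareto-front
machinery beyond the scalar score is provided. Published per-country
figure values and real-cohort metric values are not reproducible from
printed data and are not targets of this package's checks.
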