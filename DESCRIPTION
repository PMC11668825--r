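Package: esper
Title: Environmentally Sustainable Performance Benchmarking for Computational Pathology Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarking of deep-learning model zoos on both diagnostic
    performance and operational carbon footprint. Implements the
    environmentally sustainable performance (ESPer) scores, which divide a
    squared classification metric by an exponential penalty on
    range-normalized CO2-equivalent emissions, for single-inference (iESPer)
    and multi-year usage-projection (fpESPer) settings. Includes energy to
    CO2eq conversion with power-usage-effectiveness and regional carbon
    intensity, mortality-cost-of-carbon usage budgets, tile-size and
    tile-fraction data-reduction sweeps, macro-averaged multiclass
    classification metrics computed from per-case predictions, a
    deterministic synthetic benchmark generator standing in for GPU energy
    metering, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
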