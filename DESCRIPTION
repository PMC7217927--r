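Package: scvcn
Title: Single-Cell Vector Copy Number Analysis for Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lentiviral vector copy number (VCN) at the single-cell
    level from multiplexed droplet digital PCR (ddPCR) readouts. Converts
    classified droplet counts into absolute target abundances by Poisson
    statistics, applies well-level quality control, computes per-measurement
    and bulk-population VCN, and infers the integer vector copy number of each
    isolated single cell with a Bayesian framework (variance-stabilizing
    transform, constant Gaussian noise, half-normal likelihood for the
    zero-copy hypothesis, uniform prior over candidate copies). Population
    summaries include the copy-number distribution, PCR-based transduction
    efficiency, and the percent difference between single-cell and bulk VCN.
    A seeded synthetic-data generator emulates the full assay, from per-cell
    integer copies down to binomial droplet partitioning, so the pipeline can
    be exercised and validated end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
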