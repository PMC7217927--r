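# scvcn

Single-cell vector copy number (VCN) analysis for droplet digital PCR
(ddPCR).

Gene-modified cell therapies built on integrating lentiviral vectors are
released against, among other specifications, the number of vector copies per
cell and the transduction efficiency. The conventional assay measures both on
bulk genomic DNA and reports only a population average, hiding the
cell-to-cell copy distribution — including the high-copy clones that drive
insertional-mutagenesis risk. `scvcn` implements the single-cell alternative:
each isolated cell is assayed in up to six multiplexed ddPCR reactions, each
pairing a vector-gene (VG) target with a human reference-gene (RG) target,
and a Bayesian model converts the six noisy measurements into one integer
copy call per cell.

The pipeline:

1. **Poisson quantification.** Per well and target,
   `λ̂ = −ln(1 − n_pos/n_tot)` copies/droplet; wells with fewer than 11,000
   accepted droplets, near-saturated wells, and (optionally) amplitude
   outliers are excluded.
2. **Per-measurement VCN.** `VCN = 2 × vector / reference` from same-well
   target pairs; QC failures become reasoned NAs, and cells with more than 3
   NAs out of 6 are removed.
3. **Bayesian integer calls.** After a variance-stabilizing transform `T`
   (default square root) with pooled within-cell noise SD `σ`, candidate copy
   `k` has likelihood `N(T(k), σ/√n)` for `k ≥ 1` and a half-normal at the
   origin for `k = 0`; a uniform prior over `0..K_max` and log-space
   normalization give each cell a posterior and its MAP copy call.
4. **Population reporting.** Copy-number proportions, safety range bins
   (0 / 1–4 / 5–10 / ≥11), mean single-cell VCN, PCR-based transduction
   efficiency (% of cells with ≥1 copy), ΔVCN against a bulk companion
   sample, and chip-to-chip consistency tests (Kruskal–Wallis + Dunn,
   Mann–Whitney).

A fully seeded synthetic generator (`simulate_dataset()`,
`make_fixture_bundle()`) emulates the assay from true per-cell integers down
to binomial droplet partitioning, so the whole pipeline can be exercised and
validated without laboratory data.

## Worked example

Simulate a nonsorted population (Poisson copies, mean 2, two microfluidic
chips), write it as a wells + layout CSV bundle, and run the full pipeline:

```r
library(scvcn)

cfg <- simulation_config(seed = 42, n_cells = 120, n_chips = 2,
                         copy_model = "poisson_moi",
                         copy_params = list(mean_copies = 2))
dir <- tempfile()
make_fixture_bundle(cfg, dir)

res <- run_pipeline(file.path(dir, "wells.csv"), file.path(dir, "layout.csv"))
print(res$summary)
print(res$inference$noise)
chips <- compare_chips(res$inference$cells)
cat(sprintf("Kruskal-Wallis across chips: p = %.3f\n", chips$kruskal$p.value))
```

```
Population summary over 120 cells
  mean scVCN: 2.12 | transduction efficiency: 87.5%
  copy proportions: 0: 12.5%, 1: 24.2%, 2: 26.7%, 3: 20.8%, 4: 10.0%, 5: 2.5%, 6: 3.3%
  range bins: 0: 12.5%, 1-4: 81.7%, 5-10: 5.8%, >=11: 0.0%
  bulk pVCN 2.21 | deltaVCN 4.0%
VCN noise model: sigma = 0.1038 on the sqrt scale (720 measurements from 120 cells)
Kruskal-Wallis across chips: p = 0.435
```

Reading the output: 12.5% of cells carry no integration (transduction
efficiency 87.5%), the copy distribution peaks at 2 copies, no cell exceeds
the 5–10 range, and the mean of the single-cell integer calls (2.12) agrees
with the bulk companion measurement (2.21) to within a ΔVCN of 4%. The
chip-to-chip Kruskal–Wallis p-value of 0.435 shows the two chips are
consistent subsamples of the same population.

`res$inference$posteriors` holds the full per-cell posterior vectors, and
`run_pipeline(..., out_dir = "results")` writes per-well, per-measurement and
per-cell CSVs plus JSON summaries and run metadata.

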