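---
title: "Single-cell vector copy number inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell vector copy number inference: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvcn)
```

## The problem

Lentiviral transduction of a cell-therapy product leaves each cell with an
integer number of integrated vector copies, but the standard release assay —
quantifying vector and reference gene abundance in bulk genomic DNA — only
reports a population average (pVCN). Two products with the same pVCN can hide
very different cell-to-cell copy distributions, which matters for safety
(regulators care about high-copy clones) and for transduction efficiency
(the fraction of cells with at least one copy).

`scvcn` implements a single-cell version of the assay: material from each
isolated cell is measured in up to six droplet digital PCR (ddPCR) reactions,
each pairing one vector gene (VG) target with one human reference gene (RG)
target, and a Bayesian model turns those six noisy, non-integer VCN
measurements into an integer copy call per cell.

## From droplets to VCN

ddPCR partitions a reaction into thousands of droplets and classifies each as
positive or negative after end-point PCR. Under Poisson loading the mean
target copies per droplet is recovered as

$$\hat\lambda = -\ln\!\left(1 - \frac{n_{pos}}{n_{tot}}\right),$$

and a concentration follows by dividing by the droplet volume (default
0.00085 µL, the nominal QX200 value; it cancels in every ratio the pipeline
reports, so it only affects the per-well concentration table). Wells are
excluded when fewer than 11,000 droplets were accepted (a well with exactly
11,000 passes), when fewer than 3 negative droplets remain (saturation — the
inversion is unstable or infinite there), or, optionally, when a well's mean
fluorescence amplitude is a robust outlier (|z| > 3.5 on median/MAD within
same-target wells). The amplitude rule is a reproducible stand-in for the
visual "clearly different amplitude" judgement used at the instrument; it only
fires when amplitude columns are present.

Each well pairs every vector target with every reference target it contains
(one pair for duplex wells, two for triplex wells), and

$$VCN = 2 \times \frac{\text{vector copies}}{\text{reference copies}}$$

assuming a diploid genome. A QC failure invalidates exactly the measurements
that consume the failed well — the data point becomes NA, not the whole cell.
Cells with more than 3 NAs out of 6 measurements are removed (a cell with
exactly 3 NAs is retained).

## The Bayesian copy model

For a retained cell with valid measurements $y_1,\dots,y_n$, let $T$ be a
variance-stabilizing transform and

$$y^\ast = T\!\left(\tfrac{1}{n}\sum_j y_j\right), \qquad
\sigma_{\text{eff}} = \sigma/\sqrt{n}.$$

The likelihood of candidate copy $k$ is

$$L(k) = \begin{cases}
2\,\phi\!\left(|y^\ast|;\,0,\,\sigma_{\text{eff}}\right) & k = 0
\quad\text{(half-normal: signal cannot be negative)}\\[4pt]
\phi\!\left(y^\ast;\,T(k),\,\sigma_{\text{eff}}\right) & k \ge 1,
\end{cases}$$

the prior is uniform over the candidate support, and the normalized posterior
$P(k \mid y) \propto \pi(k) L(k)$ yields the maximum a posteriori (MAP) copy
call — which, under the uniform prior, is identical to the maximum-likelihood
call (both are reported). All products are evaluated in log space and
normalized by log-sum-exp, because the normal tails underflow long before the
support ends on high-copy datasets.

Choices that were genuinely open, and how they were settled:

* **Transform.** Default `sqrt`: for count-like data it decouples replicate
  spread from copy number, and $T(0)=0$ keeps the half-normal construction at
  the origin. `log1p` and `identity` are selectable for sensitivity checks.
* **Noise level.** $\sigma$ is the pooled within-cell standard deviation of
  transformed measurements across the dataset — one constant, per the
  constant-variance assumption — floored at $10^{-3}$ so a degenerate
  no-noise dataset cannot produce point-mass likelihoods. With fewer than 5
  contributing cells the estimate is unreliable and a configurable default
  (0.1) is used with a classed warning.
* **Aggregation.** The six measurements enter through the transformed cell
  mean (the per-cell means-with-SEM view of the data); a per-replicate
  log-likelihood-sum mode is provided as an alternative.
* **Support.** "All possible copies in the dataset" is data-dependent:
  $K_{\max} = \max(\lceil \max_c \bar{y}_c \rceil + 2,\ 5)$, covering the
  observed range with a margin and never collapsing below 0–5.
* **Ties** break toward the smaller copy: deterministic, and conservative for
  a safety-relevant count.
* Sorted (transduced-only) and nonsorted populations use the same support
  including 0; zero calls in sorted samples are reported, not suppressed.

## Population readouts

MAP calls aggregate into: the proportion of cells per copy number, a grouped
"≥5 copies" percentage, cumulative range bins (defaults 0 / 1–4 / 5–10 / ≥11,
reflecting presumed decreasing safety), the mean single-cell VCN (the mean of
MAP integers; a posterior-mean diagnostic is a one-liner from the posteriors),
PCR-based transduction efficiency (percent of cells with ≥1 copy), and — when
a bulk companion sample is available —

$$\Delta VCN = \frac{|pVCN - \overline{scVCN}|}{pVCN} \times 100,$$

the accuracy proxy against the orthogonal bulk measurement. Chip-to-chip
consistency is tested with Kruskal–Wallis on the MAP-call distributions
followed by Dunn's pairwise z tests (Bonferroni-adjusted by default; the
adjustment is configurable), and two-group comparisons use a two-tailed
Mann–Whitney test — exact by enumeration of the permutation distribution for
small groups (valid under ties), normal approximation with tie correction
otherwise. Tests run on MAP integers by default; the spec of the assay leaves
open whether per-cell means could be used instead, and the long measurement
table makes that variant trivial to run by hand.

## What the synthetic generator emulates

`simulation_config()` + `simulate_dataset()` generate data with exactly the
structure the pipeline assumes: true integer copies per cell (fixed list,
Poisson by multiplicity of infection, zero-truncated Poisson for sorted
populations, or empirical weights), six VG/RG abundance pairs per cell with
independent multiplicative lognormal noise (mean-1 parameterisation; default
CV 10%, in line with replicate ddPCR variability of a few percent per target),
an optional heavy-tailed per-target "preamplification bias" mode that
reproduces the whole-genome-amplification failure mode (targeted
preamplification is assumed linear, i.e. bias factor 1, by default), and
binomial droplet partitioning at $P(\text{positive}) = 1 - e^{-\lambda}$ with
15,000 droplets per well. The reference-gene occupancy defaults to
$\lambda = 0.2$ copies/droplet, placing vector occupancies comfortably inside
the quantifiable range for copies up to ~40. Everything is driven by a single
seed and is byte-reproducible.

Because both the vector and the reference abundance receive an independent
lognormal factor, the realized CV of the VCN *ratio* is about $\sqrt{2}$
times the configured `measurement_cv`, and its mean carries a small
$(1+cv^2)$ ratio bias — the tests assert against these closed forms.

What the generator does **not** emulate: droplet "rain" and misclassification,
fluorescence cross-talk, PCR inhibition, cell doublets at capture, and
reference-gene copy-number variation. Passing recovery tests therefore show
that the inference is correct *given* the assumed noise structure; they do not
validate droplet classification or chemistry.

## Problem sizes and numerical checks

The validation suite uses populations of 80–400 cells with 6 measurements
each, 1,000-cell brute-force posterior cross-checks, 100-replicate null
calibrations of the chip comparison, and $10^4$–$10^6$ draws for
distributional oracles — sizes at which every Monte-Carlo assertion has a
3-standard-error margin and the whole suite runs in under a minute. The
headline performance study (nine zero-truncated-Poisson populations with true
mean VCN spanning 1–10, ~80 cells each, CV 10%) is recomputed from scratch by
`scripts/acceptance.R`; across seeds the maximum $\Delta VCN$ between the mean
MAP call and the true population mean stays in the low single digits percent,
well inside the ≤ ~20% envelope the assay is designed to meet.

## Known limitations

* The constant-variance assumption is an approximation: on the sqrt scale the
  within-cell spread still grows mildly with copy number under multiplicative
  noise, so $\sigma$ is a dataset-level compromise. Posterior probabilities
  are therefore best read as rankings, not calibrated uncertainties.
* At high copies the transformed spacing $T(k)-T(k-1)$ shrinks; with 6
  replicates at CV 10% individual calls above ~15 copies increasingly admit
  ±1 errors (population summaries remain accurate because the errors are
  nearly symmetric).
* Diploidy is assumed via the factor 2; aneuploid or copy-variable reference
  loci would bias every VCN proportionally.
* Droplet classification (threshold placement) is upstream input; the package
  starts from classified counts.
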