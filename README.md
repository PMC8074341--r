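# rhythmscan

Detection of circadian (≈24-h) rhythms in gene-expression time series, for
experiments where sampling is short, sparse and weakly replicated — the
typical mammalian design of 24 h, one sample every 2–4 h, three animals per
time point. No single statistic performs well across all such designs, so
`rhythmscan` implements three complementary callers and a combined call:

* **Parametric curve fitting** — each gene is standardized,
  `Z = (X − μ)/S`, and fitted by bounded non-linear least squares to seven
  circadian templates (cosine, sign-preserving squared cosine, triangle wave,
  dampened cosine, cosine + linear trend, cosine + exponential trend, and a
  periodic Gaussian pulse train), each with amplitude `A`, period
  `T ∈ [20, 28]` h, phase `φ` and a free baseline (MESOR). The lowest-AIC
  template wins; rhythmicity is summarized by Fisher's method on the
  amplitude and period Wald p-values, `X² = −2 Σ ln pᵢ ~ χ²₂ₖ`, BH-adjusted
  across genes; a gene is rhythmic when `q < 0.05` and `R² ≥ 0.7`. Handles
  uneven sampling and missing time points; with replicates, a shrunk
  per-individual intercept approximates a random effect.
* **JTK-style rank test** — Kendall concordance of the data with cosine
  reference waveforms over a period × phase-lag grid, with the *exact* null
  distribution of Kendall's S under the reference's tie structure (replicates
  form tied groups), Bonferroni-corrected over the grid.
* **Lomb–Scargle periodogram** — variance-normalized spectral power, valid
  for uneven sampling, with false-alarm probability
  `p = 1 − (1 − e^(−P))^M`; integrated with the rank test per gene via
  Fisher's method, MetaCycle-style.

`full_mode_analysis()` runs all three on one dataset and reports one row per
gene with every method's statistics plus a combined (union) call. A seeded
synthetic-data generator with known ground truth, a confusion-matrix
benchmark harness, upset-style overlap counts and CV diagnostics are
included, along with a small CLI.

## Worked example

```r
library(rhythmscan)

sim <- simulate_dataset(sim_config(n_genes = 300, seed = 7))  # 30% rhythmic
es  <- downsample(sim$expr, 2)                                # 2-h sampling
res <- full_mode_analysis(es)

head(res[res$combined_rhythmic,
         c("gene", "circan_shape", "circan_amplitude", "circan_period",
           "circan_r2", "circan_q", "jtk_q", "meta_q")], 3)
#>         gene circan_shape circan_amplitude circan_period circan_r2     circan_q        jtk_q       meta_q
#> 1 gene_00001   triangular         6.390972      24.71347 0.7539567 1.000000e+00 1.505870e-07 3.469406e-11
#> 2 gene_00002         peak         3.282805      26.57461 0.9371061 2.197089e-29 2.253653e-04 5.525688e-08
#> 3 gene_00003         peak         4.170049      21.62357 0.9471122 1.038787e-43 8.228691e-07 4.974176e-11

confusion(res, sim$truth)
#> <benchmark_summary: TP=88 FP=1 FN=2 TN=209 | sensitivity=97.8% fp_rate=0.48% fdr=1.12%>

overlap_counts(list(circan = res$gene[res$circan_rhythmic],
                    jtk    = res$gene[res$jtk_rhythmic],
                    meta   = res$gene[res$meta_rhythmic]))
#>             combo circan   jtk meta count
#> 3 circan&jtk&meta   TRUE  TRUE TRUE    73
#> 2        jtk&meta  FALSE  TRUE TRUE    14
#> 1            meta  FALSE FALSE TRUE     2
```

Reading the output: amplitudes are reported back on the original expression
scale (the fit itself runs on standardized data), periods and phases in
hours with the phase reduced into `[0, T)`. Gene 1 shows why the union
matters: a triangle wave with `R² = 0.75` whose combined parametric q-value
misses, caught decisively by both non-parametric tests; the 88/90 recovered
rhythmic genes at one false positive are typical for this design. The
`jtk&meta` row counts genes that only the non-parametric side detects
(usually the outlier-containing cosines), while low-amplitude sinusoids tend
to be `meta`-only.

Most parameters live in three config constructors with documented defaults:
`sim_config()` (generator), `circan_config()` (fitting engine, period box,
thresholds, random effect) and `np_config()` (period grid, oversampling).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rhythmscan.R", package = "rhythmscan"))') \
    simulate --out-prefix toy --seed 3 --n-genes 300 --interval 2
# ... then
...rhythmscan.R full --expr toy_expr.csv --meta toy_meta.csv --out results.csv
...rhythmscan.R benchmark --seed 5 --out summary.csv
```

Subcommands: `simulate`, `circan`, `jtk`, `meta2d`, `full`, `benchmark`;
plain CSV in and out; every run is reproducible from `--seed`.

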