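# synpid

Synergy, redundancy and long-range correlations in neural population
recordings.

`synpid` is an R package for analysing spatially embedded binary neuron
activity rasters — the kind produced by binarizing deconvolved calcium
traces from mesoscale two-photon imaging. It asks how far pairwise
correlations extend in space and what kind of statistical interaction
carries them: **redundant** information (either neuron alone predicts the
pair's future) or **synergistic** information (only the pair jointly does,
as in an XOR relation).

## What it computes

For a raster `T x N` with neuron positions in micrometres:

* **Time-delayed mutual information (TDMI)** per pair,
  `I(X_t, Y_t ; X_{t+tau}, Y_{t+tau})`, and its **partial information
  decomposition** (minimum-mutual-information redundancy):

  `TDMI = UI(X) + UI(Y) + RI + SI`,
  with `RI = min{ I(X_t; F), I(Y_t; F) }`, `F = (X_{t+tau}, Y_{t+tau})`.

* **Null-model Z-scores** of the four components, against ensembles of
  random binary-pair processes with calibrated flip noise matched on the
  pair's TDMI (removing biases from rate, recording length and the
  redundancy measure).

* **Correlation length** `lambda` from the exponential decay fit
  `C(d) = C_inf + (C0 - C_inf) exp(-d / lambda)` of distance-binned
  pairwise values, and the **effective information length**
  `lambda_eff = (1/C0) * integral of C(d) over [d0, dmax]`
  (defaults `d0 = 100`, `dmax = 1500` µm).

* **Partial network decomposition**: k-nearest-neighbour synergy and
  redundancy layers, their edge union, and per-pair classification of
  union shortest paths as complementary (`d_union < min(dA, dB)`), shared
  (`d_union = max(dA, dB)`) or unique to one layer.

* **Group statistics**: exact (exhaustive) or Monte-Carlo permutation
  tests of group mean differences, plus Hedge's g.

A dichotomized-Gaussian synthetic-data generator with a planted spatial
correlation length, temporal persistence and optional XOR-coupled triplets
provides ground truth for every stage, and a 2-state Gaussian HMM
binarizes continuous traces when the input is not already binary.

## Worked example

```r
library(synpid)

pos <- generate_positions(200, field_size = 3000, seed = 101)
params <- generator_params(n_neurons = 200, n_timepoints = 20000,
                           lambda_true = 300, c0_true = 0.1,
                           c_inf_true = 0.01, seed = 201)
raster <- simulate_raster(pos, params)

prof <- spatial_profile(pairwise_pearson(raster, pos))
prof$fit
#> Exponential decay fit: C0 = 0.02445, Cinf = 0.002379, lambda = 283.3 um (converged)
prof$lambda_eff
#> [1] 314.5965
```

The fitted `lambda` of 283 µm recovers the planted 300 µm correlation
length (the binary `C0` is attenuated relative to the latent kernel's 0.1
by the dichotomization — the length scale, not the amplitude, is the
target). The effective length integrates the same fit over the
100–1500 µm window.

PID, normalization and the network stage run either individually
(`pid_pair_table()`, `numit_table()`, `build_knn_layer()`,
`classify_paths()`) or chained behind one configuration:

```r
res <- run_pipeline(modifyList(default_config(), list(
  generator = list(n_neurons = 100L, n_timepoints = 10000L,
                   xor_triplets = list(c(0L, 1L, 2L))),
  n_null = 50L, k = 5L, out_dir = "synpid_out")))
print(res)
```

which writes every stage table (pair PID/Z-scores, curves, fits, edge
lists, path classes) plus `summary.json` with a provenance block to
`synpid_out/`. A thin command-line dispatcher over the same functions is
installed at `inst/cli/synpid.R`
(`Rscript synpid.R run --config config.yaml`, plus per-stage
subcommands).

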