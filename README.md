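# mothnets

Structural analysis of plant–pollinator networks that combine diurnal
flower-visitation records with pollen-load evidence from light-trapped
nocturnal moths.

Diurnal transects and nocturnal light-trapping observe different slices of
the same mutualistic community. `mothnets` is for ecologists who want to
ask, quantitatively, what the nocturnal slice changes: does adding moth
interactions behave like *more sampling* of the same network, or does it
*restructure* the network? The package implements the full chain:

* **Assembly** — qualitative (0/1) plant × animal incidence matrices from
  long-format records; a nocturnal plant × moth link is scored only when an
  individual moth carried **≥ 3 pollen grains** of that plant (per
  individual, collapsed to species level).
* **Structure** — the fifteen standard descriptors: A, P, matrix size, i,
  web asymmetry (A−P)/(A+P), connectivities i/A, i/P, i/(A+P), connectance
  i/(A·P), NODF nestedness (total / animals / plants), Barber bipartite
  modularity Q = (1/i) Σ<sub>g<sub>p</sub>=g<sub>a</sub></sub> (B<sub>pa</sub> − k<sub>p</sub>k<sub>a</sub>/i)
  maximized by a multi-start label-propagation + greedy-merge search
  (DIRTLPAwb+-style), module count, and R50 robustness both ways.
* **Inference** — fixed–fixed (curveball) null-model Z-tests for NODF and
  Q; a pooled-variance t-test on diurnal degree *ranks* (ties averaged) for
  preferential attachment of moths to well-linked plants.
* **Robustness** — random primary-extinction curves (100 replicates); R50 =
  smallest fraction of removals driving ≥ 50% of the partner guild extinct.
* **Completeness** — Chao 2 asymptotic richness and sampling completeness
  for species and pairwise interactions from session-structured incidence.
* **The break experiment** — subsample the diurnal network from 10% up to
  d−n links, then compare the full diurnal network against "mixed" networks
  (d−n diurnal + all n nocturnal links): a metric *breaks* when the
  full-diurnal value falls outside the mixed 95% CI.
* **Synthetic communities** — a seeded generator with `random`,
  `preferential` and `syndrome` (planted night-module) scenarios, so the
  whole pipeline is testable and calibratable without field data.

## Worked example

```r
library(mothnets)

records <- generate_community(scenario_config(scenario = "syndrome", seed = 42))
d  <- build_network(records, "diurnal")
n  <- build_network(records, "nocturnal")
cb <- combine_networks(d, n)
d; n; cb
#> <bipartite_network: diurnal> 39 plants x 83 animals, 300 links (connectance 0.093)
#> <bipartite_network: nocturnal> 8 plants x 15 animals, 25 links (connectance 0.208)
#> <bipartite_network: combined> 39 plants x 98 animals, 325 links (connectance 0.085)

attachment_test(d, n$plants)
#> degree-rank t-test: t37 = 2.319, P = 0.026 (groups 8 vs 31)

null_test(cb, "Q", n_reps = 100, seed = 42)
#> null test (Q): observed 0.4114, null 0.3948 +/- 0.0064, z = 2.609, P = 0.009082 (n = 100)

break_test(d, n, n_reps = 100, seed = 42)
#> <break_result> d = 300, n = 25, 100 mixed replicates
#>              metric mixed_mean       lo       hi diurnal_full significant direction
#>         connectance     0.0809  0.07849  0.08469      0.09268        TRUE  decrease
#>       web_asymmetry     0.4269  0.40909  0.44245      0.36066        TRUE  increase
#>  connectivity_total     2.2273  2.18978  2.27273      2.45902        TRUE  decrease
#>          nodf_total    19.8260 18.81010 20.97984     26.65171        TRUE  decrease
#>                   Q     0.4268  0.41625  0.43672      0.37571        TRUE  increase
#>               R50_A     0.8884  0.87368  0.90676      0.87952       FALSE  increase
#>               R50_P     0.7816  0.74005  0.81827      0.79487       FALSE  decrease
```

Reading the output: this is the *syndrome* world — moths visit a planted
set of night-flowering plants. Substituting the 25 nocturnal links for 25
random diurnal links (at equal total sampling) breaks the undersampling
trend: connectance, total connectivity and nestedness drop below the mixed
CI while web asymmetry and modularity rise — the same qualitative pattern
as the field comparison this package models. The positive rank-test t says
the moth-visited plants rank *worse* in diurnal degree (rank 1 = most
linked), i.e. no preferential attachment; and modularity of the combined
network clears its degree-preserving null (z = 2.6).

The same pipeline runs end-to-end on a record CSV via
`run_pipeline(run_config(input = "records.csv", out_dir = "run"))`, or the
CLI (`exec/mothnets`): `mothnets report --input records.csv --out run
--seed 1`.

## Layout

`R/` user-facing modules (assembly, metrics, null inference, robustness,
completeness, resampling, synthetic data, pipeline/CLI) · `src/` Rcpp
kernels · `tests/testthat/` unit, property and acceptance suites (with
brute-force/enumeration oracles in `helper-oracles.R`) ·
`vignettes/mothnets-methods.Rmd` the methods vignette (model, parameters,
calibration bands, design choices, limitations).
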