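# specnet

Complex-network representation and classification of spectral
(metabolomic) data in R.

## The problem

Metabonomic studies compare NMR or Raman spectra of biofluids between a
control cohort and a patient cohort, and then try to classify new subjects
and to track disease progression. `specnet` implements a network-based
alternative to classifying the raw spectra: each subject's spectrum is
turned into a graph whose **nodes are spectral bins** and whose **links mark
bin pairs that behave the way the disease cohort behaves**. Classification
and monitoring then operate on a handful of structural descriptors of that
graph rather than on hundreds of raw intensities, which makes the result
robust to additive measurement noise.

## The model

For every ordered pair of bins *(i, j)* two linear models are fitted by
ordinary least squares, one per training cohort:

```
control:  c_j = α  c_i + β  + ε
disease:  d_j = α' d_i + β' + ε'
```

with residual spreads σ = sd(ε), σ′ = sd(ε′) (denominator m − 2, floored
away from zero so exact fits stay proper). For a new subject with
intensities (x_i, x_j), the two models predict ŷ_c = α x_i + β and
ŷ_d = α′ x_i + β′; Gaussians of width σ and σ′ centred on those
predictions are evaluated at x_j and the **link weight** is the normalized
disease probability

```
w(i, j) = φ(x_j; ŷ_d, σ′) / [ φ(x_j; ŷ_c, σ) + φ(x_j; ŷ_d, σ′) ]  ∈ [0, 1]
```

computed in log-density space (a stable logistic), so distant points never
overflow. The n(n−1) ordered weights are symmetrized (mean by default) into
a weighted network; thresholding at *w* > 0.65 gives a binary adjacency
matrix on which four descriptors are computed:

* **link density** L = edges / [n(n−1)/2]
* **clustering coefficient** (transitivity) C = 3 N_Δ / N_3
* **global efficiency** E = mean over pairs of 1/d_ij (disconnected pairs
  contribute 0)
* **eigenvector centrality** per node (power iteration on the largest
  component, unit-maximum normalization)

A linear SVM on (L, E) with leave-one-out validation reproduces the
headline behaviour: perfect separation of structured two-class cohorts,
chance-level scores on null cohorts, and graceful degradation under noise.

## Worked example

```r
library(specnet)

# a synthetic two-class cohort: 200 bins, 25 control vs 25 disease subjects,
# disease couplings concentrated on 3 hub bins with 30 partners each
cohort <- generate_cohort(cohort_config())
#> <spectral_dataset: 50 subjects x 200 bins>
#>   labels: 25 control, 25 disease, 0 unlabeled

fit <- fit_pair_models(cohort)
#> <dual_class_model: 200 bins, 39800 ordered pairs>
#>   trained on 25 control and 25 disease subjects

net <- reconstruct(cohort, fit, subject_id = "disease_001")
#> <subject_network 'disease_001': 200 nodes, 19900 undirected weights>
#>   weight range [0.040, 1.000], mean 0.764 (symmetrization: mean)

extract_features(net, threshold = 0.65)
#>   density clustering efficiency centrality_gini
#> 1   0.676      0.708      0.838           0.132

loo_classify(cohort)
#> <classification_result: 100.0% correct (50/50 subjects)>
#>   classifier svm_linear on [density, efficiency], threshold 0.65, refit_models TRUE
```

The disease subject's network has two thirds of all possible links
expressed (density 0.676) and near-complete reachability (efficiency
0.838); control networks in the same cohort average density ≈ 0.01. The
leave-one-out run refits all 39,800 pairwise models without each held-out
subject before reconstructing that subject's network, so the 100% score is
leakage-free.

Higher-level experiments mirror the method's published use cases:

```r
noise_sweep(cohort, sigmas = c(0.5, 1, 2, 5), n_replicates = 10, seed = 1)
binning_sweep(cohort, bin_sizes = c(1, 2, 5, 10), seed = 1)
track_evolution(fit, generate_trajectory(cohort_config(),
                                         strengths = c(1, 0.6, 0.3, 0.8),
                                         seed = 1))
```

Each returns a tidy tibble with `glance()` summaries and `autoplot()`
figures. A command-line front end with the same capabilities ships in
`inst/cli/specnet.R` (subcommands `simulate`, `fit`, `reconstruct`,
`metrics`, `classify`, `noise-sweep`, `bin-sweep`, `track`).

## Layout

* `R/` — implementation: dataset container and IO, binning/masking/noise,
  dual pairwise models, network reconstruction and metrics, leave-one-out
  classification, experiments, synthetic-data generator, plots.
* `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for every graph metric.
* `vignettes/spectral-networks.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design and limitations.
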