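---
title: "Spectral networks: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral networks: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specnet)
```

## The model

`specnet` encodes one subject's spectrum — *n* bins of NMR or Raman
intensity — as a weighted graph. Nodes are bins. The weight of the link
between bins *i* and *j* answers one question: *do this subject's values at
(i, j) behave more like the disease cohort or more like the control
cohort?*

Both cohort behaviours are modelled as straight lines. For every ordered
pair (i, j), ordinary least squares is run twice, once within each training
class:

$$c_{\bullet j} = \alpha\, c_{\bullet i} + \beta + \varepsilon, \qquad
  d_{\bullet j} = \alpha'\, d_{\bullet i} + \beta' + \varepsilon'$$

The fitted residual spreads $\sigma = \mathrm{sd}(\varepsilon)$ and
$\sigma' = \mathrm{sd}(\varepsilon')$ quantify how tightly each class
follows its line. A new subject with values $(x_i, x_j)$ gets two predicted
responses, $\hat y_c = \alpha x_i + \beta$ and
$\hat y_d = \alpha' x_i + \beta'$. Treating the residuals as Gaussian, the
probability of membership in each class is proportional to the
corresponding normal density at $x_j$, and because the subject must belong
to one of the two classes, the link weight is the normalized disease
probability

$$w_{ij} \;=\; \frac{\phi(x_j;\, \hat y_d, \sigma')}
  {\phi(x_j;\, \hat y_c, \sigma) + \phi(x_j;\, \hat y_d, \sigma')} \in [0, 1].$$

Assumptions worth stating plainly: pairwise relations are linear within
each class; residuals are homoscedastic Gaussians; subjects are
exchangeable within a class; and the disease expresses itself through
*relations between bins* (possibly in addition to single-bin shifts). The
method inherits all the usual failure modes of those assumptions —
curvature, heavy-tailed residuals, or batch structure will leak into the
weights.

All $n(n-1)$ ordered weights are computed; the two directions of a pair
are combined by arithmetic mean (options: `max`, `directed`) because the
analysis and figures treat networks as undirected while the fit itself is
directional. Thresholding at $w > 0.65$ (strict, matching "weight higher
than 0.65") yields the binary network whose descriptors feed
classification:

* link density $L$ — expressed links over $n(n-1)/2$ possible ones. The
  underlying formula is sometimes printed with denominator $n(n-1)$; for an
  undirected graph with symmetric adjacency that normalization would cap
  density at 1/2, so the undirected denominator is used and a complete
  graph has $L = 1$.
* clustering coefficient — the *global transitivity*
  $3 N_\Delta / N_3$ (triangles over connected triples), not the
  per-node Watts–Strogatz average; the two differ and the defining formula
  names $N_\Delta$ and $N_3$. $N_3 = 0$ returns 0.
* global efficiency — mean of $1/d_{ij}$ over unordered pairs from
  breadth-first shortest paths; disconnected pairs contribute 0, the
  standard Latora–Marchiori convention.
* eigenvector centrality — principal eigenvector of the adjacency matrix
  of the largest connected component (zeros elsewhere), normalized to unit
  maximum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.65 | binarization cut on the weight, strict `>`; the one analysis value the method's source material prints. Fully configurable. |
| `symmetrization` | `"mean"` | how the two ordered weights of a pair combine. |
| minimum class size | 3 (4 with refitting) | 2 points fix a line; a third gives the residual spread one degree of freedom. |
| residual floor | $10^{-9}\times$ response range per class | an exact fit would make the Gaussian a point mass and the ratio ill-defined; floored pairs behave continuously. |
| degenerate pairs | weight 0.5 | if either bin has zero variance in either class the pair is uninformative; fixing it at the neutral weight keeps the node set constant across subjects. (The defining texts mention only the predictor bin; a zero-variance *response* makes the residual spread equally ill-defined, so the same policy applies.) |
| residual denominator | $m - 2$ | the unbiased OLS estimate; the source material says only "standard deviation of the residuals". |
| noise `sigma` | absolute units | additive-noise experiments interpret sigma in intensity units; `sigma_relative = TRUE` rescales by the mean per-bin sd. |

## Numerical choices

Weights are computed as a logistic of the log-density difference,
$w = \mathrm{logit}^{-1}\!\big(\log\sigma - \log\sigma' +
\tfrac12(z_c^2 - z_d^2)\big)$: a naive density ratio under- and overflows
for points far from both lines, while the logistic stays finite and exact.
Fitting is vectorized over all pairs from class sufficient statistics
(column sums and cross-products), which also makes leave-one-out refits a
rank-one downdate instead of a full pass over the data. Eigenvector
centrality uses power iteration on $A + I$ — same eigenvectors, but the
shift makes the dominant eigenvalue strictly largest in modulus on any
connected component, so bipartite components cannot oscillate; convergence
is declared at a relative change of $10^{-10}$ with a hard cap of $10^5$
iterations (exceeding the cap is an error, not a silent result).

## Leave-one-out protocol

With `refit_models = TRUE` (default), every subject's features are computed
*out of sample*: the pairwise models are refitted without that subject and
only then is its network reconstructed. The classifier is then itself
validated leave-one-out on this table of held-out features. This matters
more than it may seem: a subject inside the fit pulls the regression lines
toward itself and shrinks its own residuals, so in-sample and out-of-sample
features have visibly different distributions at cohort sizes of a few
dozen. Mixing the two (training on in-sample features, testing on an
out-of-sample one) systematically misclassifies borderline subjects. The
in-sample variant — fit once on everybody, the historical way such studies
were often run — remains available as `refit_models = FALSE`.

The default classifier is a linear-kernel SVM with unit cost, features
standardized by the training fold, and inverse-frequency class weights.
The class weights are not cosmetic: holding one subject out of a balanced
cohort always leaves the training set imbalanced by one, and on
uninformative features an unweighted maximum-margin classifier degenerates
into a majority vote — which in leave-one-out is systematically *wrong*,
dragging null-data scores toward 0% instead of 50%. With balanced weights
a null cohort scores an honest coin flip, which is exactly what a leakage
guard should show. Naive Bayes, a decision tree (`rpart`) and a small
multilayer perceptron (`nnet`, 3 hidden units) are available as
off-the-shelf baselines and are fed the raw bin intensities in the noise
experiment, standardized per training fold.

## What the synthetic generator emulates

`generate_cohort()` draws two-class cohorts with exactly the structure the
pairwise model assumes: most bins are independent
$\mathcal N(\text{baseline}, \text{noise}^2)$ in both classes, while a few
*hub* bins each drive a block of *partner* bins through a linear coupling
whose parameters differ between classes. Defaults: 200 bins, 25 + 25
subjects, 3 hubs × 30 partners, baseline 10, background noise 1, control
coupling `partner = 1.0·hub + N(0, 0.1²)`, disease coupling
`partner = 2.0·hub + N(0, 0.1²)` — the classes differ by a slope offset of
1.0 and nothing else. `disease_strength` interpolates the disease coupling
linearly toward the control one; at 0 the classes are statistically
identical (the null used for calibration). Longitudinal series draw one
subject per timepoint at a given strength sequence, emulating a patient
whose disease signal recedes under treatment and rebounds when it pauses.

Why equal intercepts: with a slope-only offset the two class lines are far
apart over the whole realistic hub range (they meet only at hub intensity
0, ten background-sds below baseline), so every patient's pattern pairs
are decisively disease-like — the regime in which the published
classification behaviour (perfect leave-one-out separation at these cohort
sizes) is reproducible. Pinning the disease intercept so that partner
*means* match the control class instead puts the line intersection at the
centre of the hub distribution, and patients whose hubs happen to sit near
baseline become indistinguishable from controls; cohort-level accuracy
then stalls in the 80s regardless of classifier.

A deliberate consequence is that partner bins shift in marginal mean and
variance, so plain per-bin classifiers also perform well on clean data —
as they do in the method's motivating comparisons, where the advantage of
the network representation shows under noise and in interpretability, not
in clean-data accuracy. All randomness flows from a single seeded
generator with subjects drawn in a fixed order; generation is deterministic
given the seed.

What the generator does **not** emulate: spectral lineshapes, baseline
drift, chemical-shift variation, peak overlap, batch effects, or any
instrument artifact beyond additive Gaussian noise. Real control cohorts
are also pervasively correlated across bins, which makes their
reconstructed networks far denser than the near-empty control networks
this generator yields (its non-pattern bins are independent by
construction, so null pairs sit near weight 0.5 and below any sensible
threshold). Two published observations depend on that density and are
therefore *not* reproduced here: control centrality histograms being flat
rather than concentrated, and disease centrality being *more* skewed than
control's. The attainable — and scientifically equivalent — statement,
which the tests assert, is that in patient networks the links and the
centrality mass gather around the disease-pattern bins, while control
networks show no such concentration; with 90 partner bins versus 3 hubs,
the partners rather than the hubs legitimately top the centrality ranking.
Passing tests therefore demonstrate correctness of the machinery and of
the qualitative disease signatures, not fidelity to any particular real
data set.

## Experiment design and problem sizes

The noise experiment pollutes the cohort with additive
$\mathcal N(0, \sigma^2)$ noise and scores each method by leave-one-out on
each polluted copy. Sigmas are specified in absolute intensity units; the
test suite uses $\sigma \in \{0.5, 1, 2, 5\}$ — up to five times the
biological background variability, beyond which the data is mostly noise —
with 10 replicates per sigma, and the trajectory checks average 10
replicates per strength. These sizes are the package's own choice of a
compact but statistically meaningful design (Monte-Carlo tolerances in the
tests are 3 standard errors over replicates); the replicate default of the
function itself is 100, matching the full published ensemble.

The bin-size sweep re-bins the raw measurements (mean aggregation — the
mean keeps intensities on a common scale across bin sizes, which matters
because the pairwise fits are scale-sensitive; summation is available
behind a flag), refits everything, and re-scores. A bin size that leaves a
single bin cannot form any pair; it is reported as a flagged `NA` rather
than an error so a full sweep remains representable. A trailing partial
bin is kept and logged in the provenance — silently dropping it would
change *n* depending on divisibility.

## Known limitations

* Pairwise fits are OLS; no robust or regularized variants, by design.
* The Gaussian residual model is what makes the weight a closed-form
  logistic; heavy-tailed residuals will saturate weights too eagerly.
* Weighted-graph metric generalizations are not provided; metrics operate
  on the thresholded network only.
* The exhaustive feature-subset selector scores all subsets up to
  `max_subset` by leave-one-out accuracy; it is a transparent substitute
  for more elaborate published selectors and scales combinatorially.
* Axis units (ppm, cm⁻¹) are opaque metadata; no unit conversion, peak
  picking, baseline correction, or vendor-format IO is attempted.
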