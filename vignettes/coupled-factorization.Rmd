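---
title: "Coupled matrix-tensor factorization of microbiome and metabolome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled matrix-tensor factorization of microbiome and metabolome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Stratified functional profiles assign each pathway's abundance to the taxa
that contribute it, per sample. Arranged as sample x microbe x pathway they
form a three-way tensor `T`; the matched metabolite intensities form a
matrix `M` (sample x metabolite) sharing the sample mode. `cmtfomics`
decomposes both jointly into `R` rank-1 latent factors:

    T ~ sum_r a_r o b_r o c_r        M ~ sum_r a_r o d_r

with a shared sample factor `a` and mode-specific loadings `b` (microbes),
`c` (pathways), `d` (metabolites); `o` is the outer product. Because the
sample factor is shared, a latent factor is a single axis of variation that
expresses itself simultaneously as a microbial/functional signature and a
metabolite signature — the property that makes the loadings directly
interpretable as coupled biomarker panels.

The weighted (advanced) variant adds per-component, per-block weights:

    T ~ sum_r lambda_r a_r o b_r o c_r        M ~ sum_r sigma_r a_r o d_r

A component with `lambda_r` near zero and large `sigma_r` is
metabolome-specific, and vice versa, so shared and block-specific variation
separate without supervision.

## Fitting

### Alternating least squares (`fit_basic`)

Each sweep solves the four conditional least-squares problems in closed
form (updates in the order a, b, c, d), using Khatri-Rao products of the
other factors against the mode-n unfoldings, with Moore-Penrose
pseudoinverses (`MASS::ginv`) so rank-deficient normal matrices never
error. Two details deserve comment:

* **Sample-mode update.** Because `a` appears in both blocks, its exact
  minimizer uses the normal matrix `(b'b * c'c + d'd)` (Hadamard product
  plus the metabolite Gram term). A variant that drops `d'd` from the
  normal matrix circulates in the literature of this model family; it is
  not the joint minimizer and, on collinear data, stalls the iteration
  (see the simulation section below). We default to the exact coupled
  update and expose the variant as `coupled_sample_update = FALSE`.
* **Stopping.** Iteration stops when the relative change of the combined
  per-entry RMSE (over the concatenation of both blocks — the literature
  does not fix this normalization, so `residual_norms()` exposes `sse`,
  `rmse` and `rel_sq` and downstream code picks one explicitly) falls
  below `tol` (default 1e-6), or at `max_iter`. A relative-change rule
  stops wherever progress slows, which may be a swamp rather than a
  minimum; traces are kept so users can inspect this.

Initialization is seeded i.i.d. standard normal. After fitting, components
are ordered by explained variance and sign-fixed (largest-|loading| sample
entry positive, flips applied to `a`, `b`, `d` jointly so both
reconstructions are unchanged). ALS monotonically decreases the combined
squared error; this is asserted in the test suite against independent QR
least-squares solves.

### Gradient-based weighted fit (`fit_advanced`)

The weighted model is fitted by minimizing

    f = ||T - That||^2 + ||M - Mhat||^2
        + beta * sum_r sqrt(lambda_r^2 + eps) + beta * sum_r sqrt(sigma_r^2 + eps)
        + (alpha/2) * sum_cols ||x - mean(x)||^2

over all factor matrices and both weight vectors jointly with BFGS
(`stats::optim`), from seeded random starts (weights start at 1, best of
`n_starts` kept) or a warm start (`init_model`, e.g. a basic fit — in which
case the refinement can only improve the objective).

The penalty forms are the self-consistent pair: the smoothed L1
`sqrt(w^2 + eps)` has gradient `w / sqrt(w^2 + eps)` (defined and zero at
the origin; `eps` defaults to 1e-8 and only rounds the kink), and the
column-centering penalty `(alpha/2) ||x - mean(x)||^2` differentiates to
exactly `alpha (x - mean(x))` because centering is idempotent. The analytic
gradients are verified against central finite differences to a relative
error below 1e-5 in the test suite — the load-bearing correctness check for
this module.

No validated defaults exist for `alpha` and `beta` on real data; both
default to 1 and should be treated as tuning parameters. Larger `beta`
shrinks weights toward zero (sparser block usage) but also floors the
attainable residual; `alpha` discourages within-column spread and mainly
acts as a mild regularizer against scale drift.

## Preprocessing

* `logstack_scale()` — for each (pathway, sample) cell with community total
  `Y`, taxon contributions become `(y_t / Y) * log10(1 + Y)`: the total is
  log-transformed and contributions scaled linearly inside it. The `+1`
  keeps zero totals at zero; base 10 is the display convention of the
  upstream profilers. Within-cell proportions are preserved exactly.
* `clr_transform()` — per-sample centered log-ratio for the metabolite
  block, treating intensities as compositional. Zeros are offset by a
  pseudocount defaulting to half the smallest non-zero intensity of the
  whole matrix (standard compositional-data practice; overridable).
* `collapse_to_subjects()` / `assemble_coupled()` — blocks profiled with
  unequal per-subject sample counts are averaged to the subject level, then
  inner-joined on the shared ids in sorted order; absent
  (pathway, taxon, sample) triples are zero-filled.

## Rank selection by masked cross-validation

`make_mask_pair()` assigns each entry of each block independently to the
test set with probability `fraction` (default 0.2). `fit_masked()` zeroes
the held-out entries and refits; this is the zero-masking scheme, which
deliberately conflates "missing" with "zero" — adequate for rank selection
on dense data but biased when the data contain many structural zeros. An
EM-style alternative (`impute = TRUE`: held-out entries iteratively
replaced by the current reconstruction) is provided and off by default.

Errors are block-weighted relative squared errors,

    W_t ||omega_t * (T - That)||^2 / ||omega_t * T||^2 + W_m (matrix analogue)

with `W_t = size(T) / (size(T) + size(M))`, `W_t + W_m = 1`; no square root
is taken. `cross_validate()` draws one mask per replicate and reuses it
across the whole rank grid, so train errors are comparable across ranks. On
pure-noise data (i.i.d. N(1, 1), dims 40 x 50 x 30 and 40 x 20) train error
decreases with rank while test error does not fall below it — the
no-overfitting pattern the test suite asserts over ten seeds.

## Group separation in latent space

Samples are projected onto the two highest-variance factors
(`project_top2`; explained variance is the squared norm of a component's
joint reconstruction relative to the full reconstruction).
`mahalanobis_separation()` then computes the squared Mahalanobis distance
between group centroids under the *pooled within-group* covariance and the
two-sample Hotelling conversion to an F statistic with
`df = (n, s1 + s2 - n - 1)`. Two choices were genuinely open:

* the covariance is pooled with the Hotelling convention, because the
  stated F law is exactly the two-sample T-squared-to-F conversion, which
  presumes pooling;
* `n` is fixed to the score dimensionality (2 for the standard top-2
  projection), the only reading under which that F law is correct.

Under these conventions the test is calibrated: over 2,000 null datasets
(both groups from one bivariate normal) the fraction of p < 0.05 falls
within [0.035, 0.065] in the acceptance suite. Multi-group designs are
handled pairwise; no global MANOVA is attempted.

## Biomarker ranking

`top_loadings()` ranks a mode's features by absolute loading on a factor
(ties broken by feature id so rankings are deterministic), keeping signs:
negative loadings mean negative association with the factor.
`top_k_hit_ratio()` scores a ranking against a validated id set as
(validated in top k) / k, and `hit_ratio_curve()` traces it over k.

## Synthetic designs and what they show

`simulate_noise_dataset()` draws every entry i.i.d. N(1, 1) at dims
(40, 50, 30, 20) — a structure-free worst case used to probe overfitting.
`simulate_weighted_dataset()` builds exact low-rank data from N(1, 1)
factor matrices with weights lambda = (1, 0.5, 1), sigma = (1, 1, 0.5)
(and `simulate_equal_weights_dataset()` reuses one vector for both blocks;
no canonical second vector exists, so the tensor weights are reused).
Mean-1 factors are deliberately collinear (every column resembles the
all-ones vector): this is the regime where ALS swamps appear, and on it the
relative-change rule stops the uncoupled-update ALS at a large residual
while the gradient-based weighted fit drives the error one to two orders of
magnitude lower and recovers the per-component block weights up to scale
and permutation (matched-component congruence above 0.9 in the tests).

These generators emulate none of the awkward features of real microbiome
data — no counts, no zero inflation, no compositional closure, no
heteroscedastic intensity noise. Passing tests therefore demonstrate the
correctness and the comparative behaviour of the optimizers, not
performance on real sequencing data.

## Numerical choices and problem sizes

* Pseudoinverses throughout ALS; singular normal matrices never error.
* Degenerate inputs: all-zero data blocks make relative errors undefined
  and raise explicit errors; masks that exclude every entry of a block do
  the same; an all-training mask yields `NA` test error.
* Exported tables are tab-separated with 15-significant-digit numbers so
  written models round-trip through `read_model()` to ~1e-12.
* Test problem sizes: oracle and gradient checks run on modes of size 6
  and below; recovery checks on 10-12 per mode; the simulation comparisons
  on the full (40, 50, 30, 20) design with 5 seeds and a 2,000-iteration
  BFGS budget; cross-validation properties on ten seeds at rank grid 1-10.

## Limitations

* The zero-masking CV scheme biases held-out reconstructions toward zero.
* BFGS treats all factor entries as one variable vector; cost grows
  quickly with dimensions, and convergence to the penalty-floored optimum
  can take thousands of iterations on collinear data.
* `alpha`/`beta` are not auto-tuned.
* Only 3-way tensors and two blocks are supported; no sparse storage.
* Metabolite pathway annotation, LEfSe/MOFA2-style benchmarking and BIOM
  or raw-MS input are out of scope.

```{r example}
library(cmtfomics)
sim <- simulate_weighted_dataset(dims = c(12, 10, 8, 6), seed = 1)
fit <- fit_advanced(sim$data, R = 3, seed = 1, n_starts = 1)
block_weight_shares(fit)
```
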