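---
title: "Partial embeddings: removing confounders from distance-based dimension reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial embeddings: removing confounders from distance-based dimension reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pare)
```

## The problem

Nonlinear embeddings such as t-SNE and UMAP are the workhorse visualizations
of single-cell transcriptomics and multi-site neuroimaging, but they embed
*all* structure in the pairwise distances — including structure you do not
want. A batch, study, donor, scanner or age effect that shifts samples in
feature space shows up in the embedding entangled with the biology. Most
remedies modify one specific algorithm; `pare` instead adjusts the *input
geometry*, which works for every method that consumes pairwise distances.

## The model

Let $y_1, \dots, y_n$ be the feature vectors and
$D = (d_{ij})$ their dissimilarity matrix. Classical multidimensional
scaling (PCoA) double-centers the squared dissimilarities,

$$G = J\,A\,J, \qquad A = \left(-\tfrac{1}{2} d_{ij}^2\right), \qquad
  J = I - \tfrac{1}{n} \mathbf{1}\mathbf{1}^\top,$$

and takes coordinates $Z = U \Lambda^{1/2}$ from the eigendecomposition
$G = U \Lambda U^\top$. When $d$ is Euclidean, $Z$ reproduces the original
pairwise distances exactly — so any Euclidean-distance-based method run on
$Z$ behaves as if run on the data.

Adjustment is a linear residualization in coordinate space. Given an
$n \times p$ design matrix $X$ of nuisance covariates with hat matrix
$H = X(X^\top X)^{-1}X^\top$, the adjusted coordinates are

$$E = (I - H)\,Z,$$

orthogonal to every design column, and the adjusted inner-product matrix is
$\Delta = EE^\top = (I-H)\,G\,(I-H)$. A *partial embedding* is any
distance-based embedding computed from this adjusted geometry:

1. compute $Z$ from $D$;
2. residualize against the nuisance design to get $E$;
3. hand $E$ (Euclidean route) — or the distances implied by $\Delta$
   (general route) — to t-SNE, UMAP, or any registered embedder.

Because an additive batch shift lies in the column space of the batch
indicators, $(I-H)$ annihilates it *exactly*: the adjusted geometry of
shifted data equals the adjusted geometry of shift-free data to machine
precision. This identity, not a statistical approximation, is the package's
central guarantee, and the test suite asserts it at `1e-6` and tighter.

### The general (non-Euclidean) route

$\Delta$ is a Gram matrix: its entries are inner products, can be negative,
and its diagonal is nonzero — it is *not* a dissimilarity matrix. The
canonical path therefore converts it to genuine distances,
$\tilde d_{ij} = \sqrt{\Delta_{ii} + \Delta_{jj} - 2\Delta_{ij}}$
(`adjusted_distances()`), which equal the Euclidean distances among the rows
of $E$. Plugging raw $\Delta$ entries directly into the UMAP exponential
kernel is also possible (`umap_affinities(..., input = "gram")`), but only as
an explicitly flagged variant: the two coincide in spirit (both are monotone
in dissimilarity), while the distance form is the one consistent with the
Euclidean route. We deliberately do not guess which literal form a given
analysis intends; the flag makes the choice visible.

### Non-Euclidean inputs

If $D$ is not Euclidean, $G$ has negative eigenvalues. `euclidify()` applies
an additive-constant correction: Cailliez (smallest constant added to the
dissimilarities; the default because it operates on the same scale the user
supplied) or Lingoes (constant added to squared dissimilarities), both
verified against the `ape` implementation. `principal_coordinates()` also
simply drops non-positive eigenvalues — at relative tolerance
$\max(n,1)\,\varepsilon\,\lambda_{\max}$, the standard rank tolerance — and
reports how many were dropped, so mild indefiniteness is handled even
without correction.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `perplexity` (t-SNE, LISI) | 10 (t-SNE), 30 (LISI) | effective neighborhood size of the Gaussian kernel; bandwidths are bisected until the row entropy matches `log2(perplexity)` essentially exactly, which makes affinities invariant under uniform rescaling of distances |
| `n_neighbors` (UMAP) | 15 | neighborhood of the locally adaptive kernel; $\tau_i$ follows the standard smooth-kNN calibration (neighbor sum $= \log_2 k$), the behavior of the reference UMAP implementation |
| `n_coords` | all | number of (adjusted) principal coordinates handed to the embedder; truncation *after* adjustment by default, with `truncate_before_adjust` for the other order — both orders are legitimate reduced-cost variants |
| `output_dim` | 2 | embedding dimension |
| `seed` | 0 | seeds the embedder backends; with single-threaded backends the full pipeline is byte-reproducible |

Eigenvector sign is fixed (largest-magnitude entry positive) so coordinates
are reproducible across linear-algebra backends; order within *tied*
eigenvalues remains backend-dependent, which is why tests compare distance
matrices or Procrustes-aligned configurations, never raw columns.

## Design choices

- **Centering.** The Gower centering matrix $I - \frac{1}{n}\mathbf{11}^\top$
  is used throughout; it is the only choice under which $G = Y_cY_c^\top$
  for column-centered data, which the tests verify directly.
- **Intercept.** PCoA coordinates are exactly column-centered, so the
  intercept column of $X$ is mathematically inert in the residualization; it
  is kept anyway so $H$ is the textbook hat matrix and continuous covariates
  project as in ordinary least squares.
- **Rank-deficient designs are rejected, not pseudo-inverted.** A donor
  factor nested exactly inside batch makes the two unidentifiable; that is a
  modeling error the user must resolve, and the error names the dependent
  columns. The same logic rejects constant covariates (a single-level factor
  carries no information; a constant continuous covariate centers to a zero
  column).
- **Embedder internals are delegated.** Gradient descent, negative sampling
  and initialization belong to `Rtsne` and `uwot`; this package's contract
  covers what it hands them — adjusted coordinates or distances, the spec
  parameters and the seed. Tests and the acceptance checks therefore assert
  on embedder *inputs* and on metric-level outcomes, never on exact
  embedding coordinates, which are legitimately implementation-dependent.
- **Metrics.** LISI is computed exactly, with Gaussian weights over all
  $n-1$ neighbors calibrated to the perplexity and self excluded from the
  category probabilities (self-inclusion would floor the index above 1
  artificially); no approximate kNN is used at these problem sizes.
  Silhouette widths use Euclidean distance in whatever coordinate space is
  supplied — typically the 2-D embedding — with the singleton convention
  $s_i = 0$, and agree with `cluster::silhouette` to machine precision.
  Reports annotate the direction of "better" per label role: a nuisance
  label should mix (higher LISI, lower ASW), a biological label should
  separate (lower LISI, higher ASW).

## The synthetic generator

`simulate_dataset()` draws
$y_i = \mu_{g(i)} + \gamma_{b(i)} + \beta c_i + \varepsilon_i$ with
isotropic Gaussian group means, batch shifts and confounder loadings over a
fully crossed, balanced group × batch layout. Under this model the linear
residualization is *exactly* correct, which is the point: it isolates the
adjustment machinery from model misspecification. An `interaction_effect`
dial adds group-by-batch shifts to probe misspecification, but no guarantee
depends on it. `simulate_counts()` is the count-flavored variant —
Poisson-log-normal counts, library-size normalization, `log1p` — shaped like
log-normalized scRNA-seq with 13 cell-type groups and 4 study batches by
default, and is written in both dense CSV and MatrixMarket form to exercise
both readers.

The `"batchy"` preset (5 groups × 4 batches × 30 samples, 50 features,
`group_effect = 1`, `batch_effect = 3`, `noise_sd = 1`) is the package's
standard strong-confounding regime: batch shifts three times the biological
separation, so batch dominates the unadjusted leading coordinates (median
batch-ASW ≈ 0.86 on the top two) while adjustment drops it to ≈ 0 and
leaves group structure intact. These sizes keep every check in seconds on a
laptop while leaving the effects far from the noise floor.

What the generator does **not** emulate: dropout and overdispersion beyond
Poisson-log-normal, unbalanced or confounded group × batch designs (where
group and batch are partially collinear, adjustment necessarily removes some
biology), nonlinear batch effects, or donor hierarchies. Passing tests
demonstrate the algebra and the metric contracts, not that linear
residualization suffices for any particular real dataset.

## Numerical notes

- Gaussian calibration bisects to an entropy tolerance of `1e-10` bits
  (≤ 300 iterations), so affinities and LISI are invariant to rigid motion
  and uniform rescaling at `1e-8` or better.
- `adjusted_distances()` clamps small negative squared distances (numerical
  noise, or an indefinite input) to zero and warns.
- Degenerate inputs: constant data yields an empty coordinate set with a
  warning; duplicated points make small perplexities infeasible (the error
  names the sample); nearest-neighbor ties in the UMAP kernel break by index
  order.

## Limitations

Partial embeddings are exploratory visualization tools. The adjusted
coordinates are residuals of a *linear* model in coordinate space: they
remove additive nuisance structure and anything correlated with it, and they
should not replace the original data in downstream inference. Longitudinal
or nonlinear nuisance structure (mixed models, additive models) is out of
scope, as are out-of-sample projection and approximate eigensolvers for very
large $n$ — the full eigendecomposition is $O(n^3)$, which is comfortable to
a few thousand samples and is the intended scale here; `n_coords` reduces
the *embedder's* cost, not the decomposition's.
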