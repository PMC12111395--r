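---
title: "Robust sparse smooth PCA: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust sparse smooth PCA: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Let $X = [x_1, \dots, x_n] \in \mathbb{R}^{d \times n}$ hold $n$ vectorized
$h \times w$ images ($d = hw$), mean-centered across samples. Classical PCA
maximizes $\|X^\top w\|_2^2$ over unit vectors $w$; because the objective is
quadratic in each sample's projection, a few grossly corrupted images can
dominate the solution. The family implemented here replaces the objective by
the L1 projection norm and adds two structural constraints:

$$\max_w \ \|X^\top w\|_1
\quad \text{s.t.} \quad \|w\|_2^2 = 1, \quad \|w\|_1 \le c_1,
\quad w^\top L w \le c_2 .$$

* The **L1 objective** $\sum_i |x_i^\top w|$ grows linearly, not
  quadratically, in each sample's projection, so outlying images exert
  bounded leverage.
* The **L1 constraint** induces exact zeros in $w$: the component selects
  pixels instead of weighting all of them.
* The **smoothness constraint** uses the combinatorial Laplacian
  $L = D - A$ of the 4-connected pixel lattice ($A_{ij} = 1$ exactly when
  pixels $i$ and $j$ are at Euclidean distance 1 on the grid; $D$ the
  diagonal degree matrix). Since
  $w^\top L w = \tfrac12 \sum_{ij} A_{ij}(w_i - w_j)^2$, it penalizes
  disagreement between weights of neighbouring pixels, encoding the prior
  that meaningful image features are spatially coherent.

After forming the Lagrangian and absorbing multipliers, two free weights
remain: $\eta_1 \ge 0$ for sparsity and $\eta_2 \ge 0$ for smoothness. The
special cases form a lattice: $\eta_1 = \eta_2 = 0$ is PCA-L1,
$\eta_2 = 0$ is the relaxed-update robust sparse PCA (RSPCA) with shrinkage
level $\eta_1$, $\eta_1 = 0$ is the robust smooth variant (RSMPCA). The
package verifies these reductions iterate-wise to machine precision, which
pins the shared implementation to three independently published update
rules.

## The iteration

Each component solves the problem above by a Minorization-Maximization
scheme. At iterate $w^{(k)}$, the L1 objective is minorized by the linear
function $\mathrm{sign}(X^\top w^{(k)})^\top X^\top w$ (tight at $w^{(k)}$)
and $\|w\|_1$ is majorized by the quadratic
$\tfrac12 w^\top \mathrm{diag}(|w^{(k)}|^{-1}) w + \tfrac12 \|w^{(k)}\|_1$
(also tight at $w^{(k)}$; it requires a nonzero anchor). Maximizing the
resulting quadratic surrogate and rewriting the solution in a division-free
form gives the update implemented in `rsspcaComponent()`:

$$U = \mathrm{diag}(|w^{(k)}|), \qquad v = X\,\mathrm{sign}(X^\top w^{(k)}),$$
$$(U + \eta_1 I + \eta_2 U L)\,u = U v, \qquad
w^{(k+1)} = u / \|u\|_2 .$$

Iteration stops when the relative objective change
$\delta = |f^{(k+1)} - f^{(k)}| / f^{(k)}$ with $f = \|X^\top w\|_1$ falls
to `tol` (default $10^{-4}$) or after `maxIter` (default 100) steps — both
recorded in `SolverConfig`. The trajectory is recorded from $f^{(0)}$, i.e.
including the value at the initialization, so convergence diagnostics cover
the whole path.

### What is, and is not, guaranteed to ascend

For PCA-L1 the update $w \leftarrow v/\|v\|_2$ **exactly** maximizes the
linear minorizer on the unit sphere, so $\|X^\top w^{(k)}\|_1$ is provably
non-decreasing; the test suite asserts this strictly. For $\eta > 0$ the
surrogate argmax is the *unnormalized* vector $u$, and the subsequent
renormalization — part of the published update — steps outside the exact MM
chain. The penalized Lagrangian still ascends at $u$, but the tracked
quantity $\|X^\top w\|_1$ at the normalized iterate can dip by an amount
that scales with $\eta_1$, $\eta_2$: the sparsity and smoothness penalties
may buy their improvement at a small cost in raw projection norm. The
monotonicity test therefore measures the worst relative step across all
variants with $\lg \eta$ drawn from $[-3, 0]$ (the decade range where the
reconstruction and recognition optima of such models live) and documents the
outcome rather than assuming the idealized guarantee extends to the
penalized variants.

### Numerical choices

* `sign(0) = 0` (R's convention); the update is undefined there otherwise.
* The linear system is solved directly by a sparse LU factorization
  ($UL$ is nonsymmetric), never by forming an inverse. If the system is
  singular — possible at $\eta_1 = 0$ when $w^{(k)}$ has exact zeros, which
  are absorbing fixed points of the update — a ridge $\epsilon I$ with
  $\epsilon = 10^{-12} \cdot \mathrm{mean}(|\mathrm{diag}|)$ is added and
  the fallback recorded in the `ComponentResult`.
* A zero update vector (total shrinkage, or $X^\top w = 0$) aborts the
  component with `converged = FALSE`, keeping the last valid iterate.
* $\delta$ guards against $f = 0$ by flooring the denominator at
  $10^{-300}$.
* After convergence, components are flipped so their largest-magnitude
  entry is positive — a pure reporting convention applied only after
  iteration, so it cannot interfere with the ascent property. Eigenvalue
  ties in the L2 baseline make the corresponding subspace non-unique; the
  returned vectors are the SVD's output under that sign convention.

### Initialization and deflation

Multiple components are extracted greedily: the starting vector of the
$i$-th solve is the leading L2 eigenvector of the **current deflated**
matrix, and after each component the data are deflated with the full stack
found so far, $X \leftarrow (I - WW^\top)X$. For the L1 variants $W$ is not
exactly orthogonal, so $(I - WW^\top)$ is not an exact projector; the
deflation is nevertheless applied as written, without re-orthogonalization,
because that is the procedure the update rules were published with. The
alternative initialization — reusing the original data's $i$-th eigenvector
— is equally defensible; the deflated-matrix choice keeps each inner solve
well-posed on the data it actually sees.

## Grid Laplacian

`buildGridGraph()` constructs $A$, $D$ and $L$ sparsely (the lattice has
$O(d)$ edges, and the per-iteration solve exploits this). The neighbourhood
is strictly 4-connected — diagonal neighbours are at distance $\sqrt 2$ and
excluded. The pixel-to-index map (`column_major` by default, R's native
order; `row_major` available) is stored on the graph, and the same order
must be used when vectorizing images; `vectorizeImage()` /
`unvectorizeImage()` and the renderer round-trip it exactly. Degrees are 2
at corners, 3 on borders, 4 in the interior; rows of $L$ sum to zero and
the constant vector spans its null space on a connected grid.

## The synthetic generator

`makeDataset()` emulates the statistical structure the model assumes, at
desk scale:

* **Planted components**: Gaussian-profile blobs of radius `smoothScale`
  (default 2 px) inside a contiguous support covering `1 - sparsity`
  (default 30 %) of the pixels, exact zeros elsewhere, unit-normalized.
  Multiple components are placed on disjoint column bands when they fit
  (making them exactly orthogonal), otherwise Gram-Schmidt orthogonalized.
* **Scores** are Gaussian with geometrically decaying variances (leading
  variance 1, ratio 0.5) so component order is identifiable.
* **Baseline image**: a fixed smooth pattern (amplitude 3 signal standard
  deviations) added to every sample. Real image stacks live on a
  nonnegative intensity scale with a structured mean image; because
  occlusions overwrite *absolute* intensities, it is this baseline that
  makes them coherent outliers after centering. The baseline itself is
  identical across samples and is removed exactly by mean-centering and by
  z-scoring, so clean-data analyses are unaffected by it.
* **Noise**: iid Gaussian, `noiseSd` default 0.1 against unit leading
  signal variance.
* **Occlusions**: `outlierFraction` of images receive one rectangle of
  salt-and-pepper noise — each pixel set to the stack's global minimum or
  maximum intensity by a fair coin. Rectangle sides scale with the grid
  (roughly 0.3–0.6 of the shorter side) because the absolute 10-pixel
  minimum used on full-size face images cannot fit on small grids.
* **Classes**: when requested, class-specific mean offsets are themselves
  sparse-smooth patterns (effect size 1.5 relative to unit score sd), so
  the discriminative signal has exactly the structure the smoothness and
  sparsity constraints favour.

All randomness flows from one master seed through fixed-offset substreams,
so every dataset is replayable. The generator does **not** model
illumination, pose, expression variation, or the heavy-tailed pixel
correlations of real photographs; passing tests on it show that the solvers
recover structure *of the kind the model assumes* under contamination —
they do not certify performance on any particular face database.

## Evaluation protocols

**Reconstruction** (`runReconstructionExperiment()`): a fraction of the
stack (default 20 %, mirroring 80 of 400 images) is occluded; the polluted
stack is centered with its own mean and the basis trained on it; the
average reconstruction error
$\tfrac1m \sum_i \|Z_i (I - WW^\top)\|_F$ is then reported on the clean
subset only, mean-centered with its own mean, for every component count,
plus the mean of the curve over an averaging range (default $[1, 30]$,
matching the convention of averaging the first 30 components).

**Recognition** (`runRecognitionExperiment()`): per repeat (default 3), a
stratified split (default 7 train per class), z-score normalization fitted
on the training images only (denominator $n-1$; constant features mapped to
0 with their sd treated as 1), basis fitted on the normalized training
matrix, nearest-neighbour classification in projection space for each
component count (Euclidean metric, distance ties to the lowest training
index), accuracies averaged over repeats and then over the range.
Per-repeat seeds derive from the master seed by fixed offsets.

**Sweeps** (`parameterSweep()`) traverse $\lg \eta_1 \times \lg \eta_2$
grids ($-\infty$ encoding $\eta = 0$) and report the full table plus the
argmin (reconstruction) or argmax (recognition), mirroring how optimal
parameters are selected in this literature.

The test suite exercises these protocols at deliberately small problem
sizes — grids of $16 \times 16$ and below, around 40–100 images, 20
replicate seeds, and coarse $3 \times 3$ tuning grids — chosen so that the
planted-recovery and ordering properties are measured with enough
replicates to be stable while the whole suite stays quick to run.

## Known limitations

* The objective is non-convex; every solver converges to a local optimum
  that depends on the initialization (the package's fixed-point tests
  demonstrate this dependence explicitly).
* For $\eta > 0$ the tracked L1 objective is not exactly monotone (see
  above); trajectories can end on a dip no larger than the stopping
  tolerance times the objective.
* Deflation with non-orthogonal stacks slightly blurs the meaning of
  "the $r$-th component" for the L1 variants.
* The per-iteration sparse solve makes the smooth variants markedly more
  expensive than PCA-L1; no acceleration (preconditioning, warm starts
  across $\eta$) is attempted.
* Only 4-connected, unweighted, short-range smoothness is implemented —
  no weighted adjacency, normalized Laplacians, or long-range couplings —
  and only the greedy one-component-at-a-time formulation.
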