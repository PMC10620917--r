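---
title: "Objective ROI selection for tiled whole-slide images"
author: "sparseROI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective ROI selection for tiled whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseROI)
```

## The problem

Multiplexed imaging platforms (cyclic immunofluorescence, imaging mass
cytometry, spatial transcriptomics panels) are too expensive and too slow to
apply to every section of a tissue block, so analysts select a handful of
regions of interest (ROIs) — historically by eye, with all the sampling bias
that implies. `sparseROI` replaces that step with a quantitative criterion:
given a whole-slide image (WSI) cut into non-overlapping square tiles, each
tile carrying a composition vector over K tissue/cell-type clusters, find a
small set of candidate ROI windows whose pooled composition reproduces the
slide-wide composition — and, optionally, whose individual compositions are
as heterogeneous as possible.

Formally, let each candidate window be a column of
$A \in \mathbb{R}^{N \times M}$ (N clusters, M candidates), let
$b \in \mathbb{R}^N$ be the slide composition and $E \in \mathbb{R}^M$ the
Shannon entropies of the candidate compositions. The package implements:

* **L1 selection** — $\min_x \lVert x \rVert_1$ subject to
  $|Ax - b| \le \varepsilon$ elementwise and $0 \le x \le 1$: the minimum
  number of ROIs that match the slide's cellular population.
* **Entropy-regularized selection** —
  $\min_x \lVert Ax - b \rVert^2 - \lambda E^\top x$ subject to
  $0 \le x \le 1$, $\sum x = 1$ (default $\lambda = 1$): trade composition
  fidelity against heterogeneity of the selected regions.
* **Random baseline** — repeated draws of k pairwise non-overlapping
  windows (default 1,000 combinations), yielding the reference distribution
  the optimized selections are compared against.

A threshold of 0.01 on the weights $x$ defines the selected support, so only
ROIs making a non-negligible contribution are reported.

## Data model

`TileGrid` stores the tile lattice: per-tile composition vectors (simplex
rows), hard cluster labels (argmax of the composition unless supplied),
optional pathologist annotations, and a validity mask. Background tiles —
more than 70% of pixels with all 8-bit channels above (210, 210, 210) — are
invalid and excluded everywhere. Two pooling conventions are supported and
kept explicit throughout: `"labels"` (fraction of tiles per hard cluster,
the canonical convention for ROI compositions) and `"compositions"` (mean of
the per-tile simplex vectors, which is exact for pixel-derived fractions).

Pixel label maps may be stored at a coarser cell resolution
(`cellSizePx`): each stored value stands for a square block of identically
labeled pixels, and every pixel count is scaled accordingly, which keeps
40,000-px slides tractable without changing any semantics.

Coordinates are 0-based with half-open pixel windows
$[r \cdot s, (r+1) \cdot s)$; trailing partial tiles are dropped (no
padding); per-tile annotation ties break deterministically toward the
lowest id; a tile with at least one annotated pixel keeps its annotation and
enters annotation analyses with full weight.

## Numerical choices in the solvers

Both solvers run on `quadprog`'s dual active-set method.

* **Scale of the fidelity term.** ROI and slide compositions are reported
  as percentages in the field's convention, and $\lambda = 1$ balances the
  two objective terms on that scale. The package therefore computes the
  quadratic term as $\lVert 100\,(Ax - b) \rVert^2$ by default
  (`scale = "percent"`), while storing $A$ and $b$ as fractions;
  `scale = "fraction"` gives the raw simplex scale, in which $\lambda = 1$
  makes the entropy term dominant.
* **L1 as a perturbed QP.** The LP is solved with a tiny ridge
  ($10^{-8}$) plus a graded cost perturbation ($<10^{-5}$); without the
  perturbation the ridge returns the analytic center of the optimal face,
  spreading weight below the 0.01 threshold, whereas the perturbed problem
  has a unique basic (vertex) solution with at most $2N$ nonzero weights.
* **Slack calibration.** Exact equality $b = Ax$ is generically infeasible
  with finitely many candidates, so the constraint carries an elementwise
  slack $\varepsilon$ (default $10^{-3}$) that doubles on infeasibility —
  each retry reported — up to 0.25, after which the closest achievable fit
  is reported in the error.
* **Discrete support polish.** The deliverable is a *set* of ROIs, not a
  weight vector. `selectL1` explores adjacent optimal vertices by
  leave-one-out re-solves and returns the smallest subset of the pooled
  candidates that still admits feasible weights (restricted solves,
  ascending size, lexicographic tie-break). `selectEntropy` returns the
  best subset of its thresholded support under the equal-pooling set
  objective $s^2 \lVert A u_S - b \rVert^2 - \lambda\,\mathrm{mean}(E_S)$.
  Both refinements are exhaustive only *within* the support (or its vertex
  union), so the fractional solve still does the global screening;
  `bruteForceSelect` provides the fully exhaustive oracle for small
  problems.
* **Entropy convention.** $E$ holds standard nonnegative Shannon entropies
  (natural log by default, base configurable) and the objective rewards
  heterogeneity by subtracting $\lambda E^\top x$; `entropySign = -1` flips
  the preference toward homogeneous regions for studies that want them.
* **Non-overlap.** The random baseline enforces pairwise non-overlap by
  construction. The convex selections do not (weights are fractional);
  `greedyDeoverlap()` offers an optional pass that keeps candidates in
  decreasing-weight order.

The paper-scale ROI sizes map to tile windows by
`round(px / tileSizePx)`: 1000/1500/2000/2500-px ROIs become 4/6/8/10-tile
windows at 256-px tiles, keeping every candidate tile-aligned and every
column of $A$ exact.

## Evaluation metrics

A selected set is judged by three quantities computed from the pooled
composition $R$ of all distinct selected tiles against the slide
composition $W$:

* $\mathrm{MSE} = \frac{1}{n}\sum_i (R_i - W_i)^2$;
* the base-2 Jensen–Shannon divergence, bounded by 1 and symmetric, with
  $0 \log 0 = 0$ (an algebraically independent mixture-KL route is kept as
  a cross-check);
* the mean Shannon entropy of the individual ROI compositions.

Cluster-agreement metrics follow the standard definitions: purity (fraction
of items in their predicted cluster's majority reference class), normalized
mutual information with the *arithmetic* mean of entropies in the
denominator (geometric available), Spearman correlation matrices between
mean cluster profiles with an optimal one-to-one Hungarian pairing (a
greedy variant is exposed for comparison), and canonical correlation
analysis with two components by default. The elbow rule for k returns the
maximum second difference of the within-cluster sum-of-squares curve plus
the full curve, flagging low confidence when the knee does not stand out
against the rest of the curve's curvature; callers may override the
automatic choice with a smaller k inside the elbow, which is why the curve
is part of the return value.

Virtual-stain quality on adjacent sections is quantified by windowed SSIM
(11-px uniform window, standard constants, interior windows only) divided
by the Dice coefficient of the two sections' nuclear masks. Because
adjacent sections genuinely differ, the compensation can exceed 1; such
values are reported as-is and flagged. The median across ROIs of the
per-ROI compensated values is the summary statistic. Masks are inputs —
segmentation is out of scope — and positivity gates for marker ratios are
caller-supplied.

## The synthetic tissue generator

Real multiplexed atlases cannot ship inside a package, so every module is
exercised against `syntheticSpec()` tissues with known ground truth. The
generator emulates the *spatial* structure that matters to ROI selection:
per-cluster Gaussian-smoothed noise fields, labeled by argmax after
per-cluster offsets are tuned (coordinate descent with exact quantile
steps) until global proportions sit within ±0.02 of the target. The
reference fixture is a 40 × 40 grid of 256-px tiles with K = 7 clusters at
unequal proportions (0.28, 0.20, 0.15, 0.12, 0.10, 0.08, 0.07) and a
1,024-px blob length scale — about four tiles, the scale of coherent
histologic domains — with noise-free tile compositions
(`dirichletConc = Inf`); finite concentrations add Dirichlet measurement
noise around the pixel-true composition. Paired embeddings are a fixed
random linear map of the compositions plus Gaussian noise, so at zero noise
the first K − 1 canonical correlations are exactly 1; mask pairs reach a
target Dice coefficient by bisection on a label-flip rate.

What the generator does **not** emulate: pixel-level stain texture, nuclei,
imaging artifacts, section-to-section deformation, or any correlation
between morphology and marker intensity. Tests passing on these tissues
therefore validate the algorithms and their contracts, not performance on
real histology.

## Problem sizes used by the test-suite

The tests run the reference 40 × 40-tile fixture for end-to-end properties
(selection vs. 1,000-draw random baseline, clustering recovery, CCA), 20
seeded 6 × 6- and 8 × 8-tile tissues with M = 9 candidates for
solver-vs-oracle equivalence (where exhaustive enumeration over all
supports is exact), and 100 randomized inputs for each metric-vs-oracle
identity. These sizes make every oracle exact while keeping the whole
suite around ten seconds.

## Known limitations

* The L1 problem is solved in its continuous relaxation (the original
  formulation used an integer solver); the vertex-polish step recovers
  minimum-cardinality supports in practice, and `bruteForceSelect` verifies
  this on small instances, but no global optimality certificate is produced
  for large M.
* The entropy selection's support refinement is exhaustive only within the
  thresholded support; a support larger than 14 candidates is returned
  unrefined.
* `randomSelection` uses rejection sampling for non-overlap; for k close
  to the maximum packable number of windows it may fail after the attempt
  budget rather than enumerate packings.
* Weighted per-cluster interest scores and co-localization objectives are
  out of scope, as is any stain normalization, registration or
  segmentation algorithm: masks, labels and embeddings are consumed, not
  produced.
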