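# sparseROI

Objective region-of-interest (ROI) selection for tiled whole-slide images.

Multiplexed tissue imaging (cyclic immunofluorescence, imaging mass
cytometry, spatial panels) is too costly to apply wall-to-wall, so studies
profile a few ROIs — traditionally chosen by eye, which biases every
downstream statistic. `sparseROI` turns the choice into an optimization
problem over the tile decomposition of the slide. It is aimed at
computational-pathology and tissue-atlas groups who already quantify their
H&E or multiplexed slides as tile-level cluster compositions (from pixel
classifiers, cell-type calls, or autoencoder embeddings) and want a
reproducible, quantitative sampling step.

## The method

Cut the whole-slide image (WSI) into non-overlapping 256-px tiles; give
every tile a composition vector over K tissue/cell-type clusters. Each
candidate ROI window is a column of `A ∈ R^{N×M}` (its cluster
composition), `b ∈ R^N` is the slide-wide composition and `E ∈ R^M` the
Shannon entropy of each candidate. Two selection strategies are provided,
plus the random baseline they are judged against:

* **L1 (minimum-count) selection** — `min ‖x‖₁ s.t. |Ax − b| ≤ ε, 0 ≤ x ≤ 1`:
  the fewest ROIs whose weighted composition matches the slide.
* **Entropy-regularized selection** —
  `min ‖Ax − b‖² − λ·Eᵀx s.t. 0 ≤ x ≤ 1, Σx = 1` (default `λ = 1`):
  match the slide while favouring heterogeneous, biologically informative
  regions.
* **Random baseline** — 1,000 random combinations of k non-overlapping
  windows.

The support `{j : x_j > 0.01}` is the selected ROI set. A selection is
evaluated by the composition mean squared error, the base-2 Jensen–Shannon
divergence against the slide, and the mean ROI entropy. The package also
ships the full evaluation suite used around this method: k-means tile
clustering with elbow selection, cluster purity, normalized mutual
information, Spearman cluster pairing, canonical correlation analysis for
paired embeddings, and Dice-compensated SSIM for virtual-stain quality —
together with a synthetic tissue generator with known ground truth so that
everything is testable offline.

## Worked example

```r
library(sparseROI)

spec <- syntheticSpec(seed = 0)        # 40 x 40 tiles of 256 px, K = 7
grid <- generateTileGrid(spec)
grid
#> TileGrid: 40 x 40 tiles (256 px/tile), K = 7 clusters
#>   valid tiles: 1600 / 1600; annotated: 0; embedding dim: 0

problem <- enumerateCandidates(grid, roiSideTiles = 4)  # 1000-px ROIs
sel <- selectEntropy(problem, lambda = 1)
sel
#> SelectionResult [entropy]: 4 ROIs selected (threshold 0.01), objective -1.01097, status optimal

report <- evaluateSelection(grid, problem@candidates[selectedSupport(sel), ])
report
#> SelectionReport: 4 ROIs | MSE 0.003723 | JSD(2) 0.02919 | mean entropy 0.9611 (base 2.71828)

baseline <- randomSelection(problem, k = 4, nDraws = 1000, seed = 0)
round(baseline$summary, 4)
#>         mse    jsd meanEntropy
#> 0%   0.0030 0.0320      0.0000
#> 5%   0.0060 0.0933      0.1206
#> 50%  0.0175 0.2081      0.3900
#> 95%  0.0415 0.3614      0.6792
#> 100% 0.0740 0.5303      0.8901
```

Four optimized ROIs reproduce the slide composition with MSE 0.0037 —
below the 5th percentile (0.0060) of 1,000 random 4-ROI draws — while their
mean entropy (0.96 nats) far exceeds the random median (0.39 nats): the
selection is simultaneously more representative and more heterogeneous
than random sampling.

A command-line wrapper over the same functions lives at
`inst/cli/roiselect.R` with `simulate / tile / cluster / select / evaluate /
staineval` subcommands; every run writes a JSON echo of its resolved
parameters next to its outputs.

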