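---
title: "Parameter studies for segmentation pipelines: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter studies for segmentation pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segstudy)
```

# Scope and model

`segstudy` studies how the parameters of a multi-stage segmentation
workflow shape its output, and tunes them against reference masks. The
workflow is treated as a black box `y = f(x_1, ..., x_k)` whose scalar
output is a mask-comparison metric: during sensitivity analysis, the XOR
pixel count between the mask from the candidate point and the mask from
the default parameters; during tuning, the mean Dice or Jaccard
coefficient against ground truth. Everything operates on the unit
hypercube: each parameter is scaled affinely to `[0, 1]` (categoricals
with m values occupy m equispaced levels by list position), designs are
generated there, and points snap back onto the native grid only at
evaluation time, so a design's structure never depends on parameter
units.

# Screening: Morris one-at-a-time

The space is discretized into `p` levels per numeric parameter
(`p = 20` by default; two-value categoricals keep their two levels). A
screening design consists of `r` trajectories of `k+1` points; each
consecutive pair differs in exactly one parameter by a signed step of
magnitude `Δ = p / (2(p−1))` — slightly over half the unit range, so
effects are probed globally rather than locally. Each move yields an
elementary effect `EE_i = (y_after − y_before) / (±Δ)`; the signed
denominator matters, since a negative step must not flip the sign of the
effect. Per parameter the design collects exactly `r` effects and
reports `μ` (mean), `μ*` (mean absolute) and `σ` (standard deviation
with the `n−1` denominator — `r` is typically 5–15, so the small-sample
correction is not cosmetic).

Trajectory construction is the classic scheme: a random direction per
parameter, a random base point drawn from the grid levels that keep the
signed step inside `[0, 1]`, and a random perturbation order. For even
`p` the step is an integer number of grid cells, so all visited points
lie on the level grid; odd `p` draws a warning and rounds the step up to
whole cells. Categorical parameters flip with `Δ = 1`, making `|EE|`
equal to the output change of the flip.

Screening thresholds are relative by default: a parameter whose
`max(μ*, σ)` falls below 1% of the largest such score is classified
non-influential (a candidate for fixing at its default), below 10%
medium, else influential. Absolute thresholds tied to a particular
metric scale can be supplied instead; the relative rule reproduces the
same conservative pruning intent without assuming the output's units.
Repeated screenings with different `r` are generated as independent
designs, not nested subsets.

A *dummy parameter* — declared to the study but consumed by no stage —
calibrates the noise floor: for the bundled deterministic pipeline its
`μ*` and `σ` are exactly zero, and the test suite asserts this without
tolerance. For stochastic workflows the dummy's effects estimate the
output variation attributable to the workflow's own randomness.

# Importance measures

## Correlation coefficients

Four coefficients are computed per parameter from a space-filling design
(Monte Carlo, Latin hypercube via the `lhs` package, or Halton /
Hammersley radical-inverse sequences): Pearson's CC, Spearman's RCC
(Pearson on average-ranked data, informative when the response is
monotone but nonlinear), and their partial variants PCC/PRCC, defined as
the Pearson correlation between the residuals of `x_i` and of `y` after
least-squares regression on the remaining parameters. On an orthogonal
design the partial and simple coefficients coincide; the identity is
exact when the output carries no contribution from the other columns,
and otherwise the partial coefficient is the larger in magnitude because
variance explained by the other parameters has been removed. Rank ties
use average ranks. Degenerate inputs fail loudly: zero-variance samples
and rank-deficient designs are errors, not NaNs.

## Variance-based decomposition

Sobol indices are estimated on a Saltelli arrangement: two independent
base blocks A and B of `n` points and the k cross blocks `AB(i)` (A with
column i from B), `n(k+2)` runs in total. The first-order estimator is
Saltelli's 2010 form `S_i = mean(y_B (y_ABi − y_A)) / V` and the total
effect is Jansen's `ST_i = mean((y_A − y_ABi)^2) / (2V)`, with `V` the
sample variance over the A and B outputs. Outputs are centered before
estimation; this leaves expectations unchanged and substantially reduces
the Monte-Carlo variance of `S_i` at the sample sizes used here. Small
negative `S_i` are legitimate finite-sample estimates of near-zero
indices and are reported as-is; the sum of main effects is therefore
reported both including and excluding negatives. Estimates with
`ST_i < S_i` are flagged with a message but not rejected. Additivity
diagnostics follow the usual reading: `Σ S_i` near 1 means main effects
explain the output; a shortfall signals interactions, which then load
onto `ST_i − S_i`.

The test suite validates the estimators against closed forms computed
independently inside the tests: an additive model `y = u_1 + 2 u_2`
(`S = ST = (0.2, 0.8)`, checked at `n = 4096` within ±0.03) and the
Ishigami function with `a = 7, b = 0.1` (`S_1 ≈ 0.3139`,
`S_2 ≈ 0.4424`, `S_3 = 0`, `ST_3 ≈ 0.2437`, checked at `n = 8192`
within ±0.05).

# Auto-tuning

All three optimizers move in unit space, snap to the native grid at
evaluation, and serve repeated snapped points from the evaluation log
without re-running the workflow or charging the budget — the same
duplicate-elimination philosophy the compact executor applies at stage
level. Each run stops when the budget (default 100 evaluations) is
exhausted, when the error estimate `1 − score` reaches the threshold,
or when 25 consecutive iterations charge no new evaluations (the search
has settled onto visited grid points).

* **Nelder–Mead**: standard reflection/expansion/contraction/shrink
  (1, 2, 0.5, 0.5) on a simplex of `k+1` vertices, initialized at the
  space's default point plus k vertices perturbed by 0.25 along each
  axis (reflected inward at the boundary).
* **Parallel Rank Order**: per iteration, all k non-best vertices are
  reflected through the best vertex and evaluated as one batch (routed
  through the compact executor), with batch-wise expansion (factor 2) on
  improvement and contraction toward the best vertex (factor 0.5)
  otherwise. Batch acceptance keeps, per vertex, the best of the
  original, reflected and expanded candidates.
* **Genetic algorithm**: population 10, size-2 tournament selection,
  one-point crossover with probability `C = 0.5`, per-gene uniform-reset
  mutation with probability `M = 0.3`, elitism 1. `C` and `M` are the
  package defaults; population size and selection scheme were chosen so
  a 100-evaluation budget spans roughly ten generations. The initial
  population is purely random — seeding the defaults into it is
  deliberately not done.

The objective over a cohort is the unweighted mean metric across images.
A `threshold` of 0 always runs to the budget. Tuning results record the
full, append-only evaluation history, so best-so-far curves are monotone
by construction and every reported best score is the maximum of actually
evaluated points.

# Mask metrics

`xorCount` (the screening metric) counts disagreeing pixels; `diceCoef`
and `jaccardCoef` (the tuning objectives) use the usual set formulas,
related by `J = D / (2 − D)`. Two empty masks score 1.0 on both — an
all-background tile segmented as all-background is perfect agreement,
and penalizing it would bias cohort means for sparse tiles. Labeled
masks are binarized (label > 0) before comparison.

# The bundled watershed pipeline

Six pure stages, with the parameters each consumes:

| stage | parameters | operation |
|---|---|---|
| background | B, G, R | pixel is tissue iff any channel below its threshold |
| candidates | G1, G2, MorphRecon | top-hat by reconstruction + hysteresis thresholds |
| sizefilter | MinSize, MaxSize | candidate area bounds |
| fillholes | FillHoles | interior background regions filled |
| watershed | Watershed, MinSizePl | distance-transform watershed de-clumping |
| sizefilterseg | MinSizeSeg, MaxSizeSeg | final area bounds |

Design notes, in the order the open choices arose:

* The candidate stage computes an inverted grayscale (nuclei bright),
  estimates background shading by opening-by-reconstruction (a 17×17
  grayscale erosion reconstructed under the image — the window exceeds
  the diameter of the largest expected nucleus, so nuclei are leveled
  out of the estimate) and thresholds the residue. The two thresholds
  act as hysteresis: components of `residue ≥ min(G1, G2)` are kept only
  if they contain a seed at `residue ≥ max(G1, G2)`. Which threshold
  seeds and which extends is a convention of this package; the published
  ranges (G1 in 5–80, G2 in 2–40) make G1 the seed level at the
  defaults. Raising either threshold never adds components, which the
  tests assert as a monotonicity property.
* `T1`/`T2` (red-blood-cell thresholds in the original workflow) are
  declared in the bundled space for design-size fidelity but consumed by
  no stage: the synthetic tiles contain no red blood cells, and the
  simplified pipeline has no RBC-removal step. They behave exactly like
  dummy parameters.
* Hole filling uses the complementary-connectivity convention: 4-conn
  foreground pairs with 8-conn background and vice versa.
* Watershed markers are the extended maxima (regional maxima of the
  h-maxima transform) of the Euclidean distance transform, with merge
  depth `h = max(1, 0.5 * sqrt(MinSizePl / π))` — half the radius of a
  disk of the minimum pre-watershed area. Tying `h` to `MinSizePl`
  prevents ridge wobble along an elongated nucleus from fragmenting it
  while leaving genuinely touching nuclei (valley deeper than `h`)
  split. A retained component without a marker receives one at its
  distance maximum, so the labels always partition the retained
  foreground.
* The two area filters use 8-connectivity; the published parameter list
  assigns propagation neighborhoods only to FillHoles, MorphRecon and
  Watershed.
* Color normalization is the identity: the synthetic tiles are generated
  in a fixed color model. A normalization stage can be prepended by
  supplying a custom pipeline.
* `MaxSize`/`MaxSizeSeg` are published as `[900, ..., 1500]` without a
  step; the bundled config assumes a step of 100.

The pipeline is a structural analogue of the original watershed
workflow — same parameter roles, same stage ordering,
parameter-sensitive output — not a pixel-level port; the parameter-study
machinery treats it as a black box either way.

# Synthetic tiles

The generator emulates bright-background tissue tiles: dark, randomly
rotated ellipses (violet, mean RGB (120, 60, 160)) on a near-white
background (mean (235, 225, 235)), per-pixel Gaussian noise (σ = 8),
per-nucleus color jitter, and a configurable fraction of nuclei placed
touching a neighbor (center distance 0.75 × the radius sum) so the
watershed stage has genuine work. Nucleus intensity fades quadratically
toward the boundary (95% of the contrast lost at the rim), which makes
the candidate thresholds move the segmented boundary smoothly instead of
acting all-or-nothing — without the fade, any threshold below the
nucleus contrast segments the full ellipse and the G1/G2 axes of the
space would be flat almost everywhere. Ground truth is the set of pixels
with ≥ 0.5 anti-aliased coverage, labeled per nucleus; defaults are a
64×64 tile with 8 nuclei of 3–7 px radius, a quarter of them touching.

What the generator does *not* emulate: stain variation, texture inside
nuclei, red blood cells, imaging artifacts, out-of-focus regions.
Passing tests therefore demonstrate that the machinery — designs,
estimators, optimizers, executor — behaves correctly on a controlled,
parameter-sensitive workflow; they do not certify segmentation accuracy
on real histology.

The bundled space's defaults (G1 = 40, G2 = 30, ...) are the
generator-matched operating point, established once by scanning the
cohort during development and then frozen. The tuning testbed starts
from a *degraded* default with G1 and G2 shifted three grid levels down
(G1 = 25, G2 = 24), which costs roughly 0.08 mean Dice on the default
cohort; all three optimizers recover it within a 100-evaluation budget.

# Simultaneous parameter evaluation

A batch of parameter sets over a linear stage chain forms a prefix trie:
each node's content key is (stage name, bound parameter values, parent
key, input identity), so two instances share a node exactly when they
agree on the stage's parameters *and* share the whole upstream path —
the operational reading of "same input data and parameter values".
Executing the compact graph runs every node once and reproduces the
replica outputs bit-for-bit (the tests compare masks pixel-by-pixel);
the savings ratio `1 − compact runs / replica runs` is the SPE gain.
Replica-mode content keys additionally carry the instance index, so the
replica baseline never shares computation — re-running it against a warm
store is still free, but two replicas inside one batch are not merged.
Pipelines are restricted to linear chains per input tile, which covers
the bundled workflow; general DAG merging is out of scope.

The result store has two levels: a bounded in-memory level 1 and an
on-disk spill directory as level 2. Insertion past capacity demotes a
victim (FIFO: oldest inserted; LRU: least recently accessed) one level;
eviction from the last level deletes. A level-2 hit promotes the entry
back to level 1. Correctness never depends on the store: a
zero-capacity level 1 changes hit statistics, not outputs, because the
executor keeps the current execution's node results locally.

# Numerical choices and degenerate inputs

* Unit-to-native snapping resolves exact halfway ties to the lower grid
  value — deterministic across platforms.
* Content keys canonicalize numeric parameter values at 17 significant
  digits; input images are identified by an MD5 digest of the file or of
  the serialized object.
* All stochastic operations take an explicit seed and restore the
  caller's RNG state; cohort tiles and study sub-seeds derive from one
  master seed via a fixed linear-congruential map kept within the 32-bit
  integer range.
* MOAT with `k = 0` free parameters, empty designs, mismatched output
  lengths, out-of-range points, zero-variance correlation inputs and
  zero-variance VBD outputs are all errors with the offending quantity
  named.

# Problem sizes

The shipped tests and the acceptance script use sizes chosen to exercise
every code path at interactive speed: 64×64 tiles in cohorts of up to 6,
MOAT with `r` up to 15 (240 runs at `k = 15`), correlation designs of a
few hundred points, VBD at `n = 4096`–`8192` on analytic functions, and
100-evaluation tuning budgets. The machinery is size-agnostic; larger
tiles, cohorts and sample sizes only change runtime.

# Known limitations

* Only linear stage chains are merged by the compact composer.
* No second-order Sobol indices or bootstrap confidence intervals.
* Categorical parameters are ordinal-encoded by list position; with the
  bundled space's binary categoricals the ordering is immaterial, but a
  many-valued unordered categorical would be better served by one-hot
  designs.
* The screening default thresholds are relative to the strongest
  parameter; a study in which *every* parameter is inert classifies all
  of them as non-influential, but one in which every parameter is
  equally influential classifies none.
* Parameter dependencies (conditional ranges, hierarchical activation)
  are not modeled.
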