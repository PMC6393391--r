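---
title: "Sparse refinement of neuron skeletons: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse refinement of neuron skeletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelasso)
```

## The problem

Automated neuron tracers (NeuroGPS-Tree, NeuronStudio, APP2 and kin) turn a
3-D fluorescence or MOST image stack into an SWC skeleton: an ordered set of
centerline points with parent links. Two systematic failure modes remain in
their output. First, where a neurite is genuinely tortuous, the traced
centerline either rounds the corner off or oscillates around it, because most
tracers regularize curvature uniformly. Second, branch points land away from
the true junction whenever the junction region is dim, thick, or crowded.
Both errors bias downstream morphometry (total cable length, branch angles).

`skelasso` post-processes a reconstruction against the image it came from.
It does not trace; it refines.

## The segment model

A neurite segment is a point sequence $p_1,\dots,p_n$ (micrometres). With
terminal points fixed, the interior points are chosen to minimize

$$\sum_{i=2}^{n-1} g(p_i) \;+\; \lambda \sum_{i=2}^{n-1}
  \lVert 2p_i - p_{i-1} - p_{i+1} \rVert_{1},$$

where $g(p) = -\sum_{v \in \Lambda} s(v)\,
\exp\!\big(-\lVert v-p\rVert^2 / 2\sigma^2\big)$ is a Gaussian-weighted local
intensity score over the voxel neighbourhood $\Lambda$ of $p$ (distances in
voxel units), and $2p_i - p_{i-1} - p_{i+1}$ is the discrete second
difference, a curvature proxy. The first term pulls every point toward a
local intensity ridge; the L1 penalty on second differences drives most of
them to zero while letting a few stay large. That asymmetry is the point:
corners are sparse along a neurite, so a sparsity-inducing penalty preserves
them, whereas a squared (L2) penalty — provided here as `l2_comparator()` —
spreads the same total curvature over many points and visibly rounds the
corner.

The split variables $d_i = 2p_i - p_{i-1} - p_{i+1}$ and multipliers $r_i$
turn this into an augmented-Lagrangian problem solved by split-Bregman
(ADMM) sweeps: a gradient-descent position update, a closed-form
soft-threshold update of $d$ (threshold $\lambda\mu$; ridge shrink
$v/(1+2\lambda\mu)$ for the L2 variant), and the additive multiplier update.
Five outer sweeps are the fixed stopping rule; in our experiments more sweeps
do not improve the result, and a fixed count keeps runs deterministic.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lam` | 1 | — | corner sparsity; larger = smoother |
| `mu` | 1 | — | coupling scale; quadratic term carries $1/2\mu$ |
| `sigma` | 1.73 | voxels | width of the intensity score Gaussian |
| `neighborhood_halfwidth` | 6 | voxels | extent of $\Lambda$ ($\lceil 3\sigma\rceil$) |
| `outer_iters` | 5 | — | split-Bregman sweeps |
| `inner_grad_steps`, `step_size` | 20, 0.1 | —, μm | position-update descent |
| `resample_spacing` | 1 | μm | working spacing for branch search |
| `template_sigma` | 1.73 | voxels | skeleton-template width |
| `branch_tol`, `branch_max_iters` | 0.1 μm, 10 | | branch fixed-point stop |

Two normalizations make these defaults portable. Intensities are divided by
the image maximum inside the solver, so `lam`, `mu` and `step_size` do not
depend on bit depth (the exported `intensity_score_g()` is the raw score).
$\sigma = 1.73$ voxels matches a typical neurite radius (under 2.5 μm) at
micrometre-scale voxels; the neighbourhood half-width $\lceil 3\sigma \rceil = 6$
captures over 99% of the Gaussian mass. We calibrated `lam`, `mu` and
`step_size` jointly against the fold-line phantom experiments below: the
defaults are the only swept combination that simultaneously halves the
distance to truth, preserves the corner, keeps second differences sparse,
and preserves the L1-vs-L2 contrast; `lam = 1.5` already erases that
contrast on the weak-corner phantom, and `mu < 1` requires a smaller step
for stability and over-smooths. The `p_update_includes_quadratic` switch
exists because the position update can be read with or without the quadratic
coupling term; we include it (the Lagrangian being minimized contains it)
and expose the alternative reading for comparison.

The gradient of $g$ is analytic, taken with respect to physical micrometre
coordinates through the voxel-size chain rule, so anisotropic stacks are
handled; it is verified against central finite differences in the tests.

### Coordinates

All skeleton math happens in physical micrometres. A point maps to the
0-based voxel index $\lfloor x / \text{voxel size} \rfloor$ per axis, and a
voxel's representative position is its centre. Skeleton points outside the
volume score $g = 0$ with zero gradient rather than raising an error, so
perturbed skeletons near stack borders do not abort a run.

## The branch-point model

At a bifurcation we extract the through path `S1` (up to 16 traced points
spanning parent side and the longer child, split at the branch point into
`S11` and `S12`) and the side path `S2` (up to 21 points along the other
child). The window sizes are fixed; they bound the local structure that
matters for one junction. One refinement pass then:

1. optimizes `S1` against the real image and resamples it at 1 μm Euclidean
   spacing;
2. builds a *skeleton template*: the resampled path rasterized and blurred
   with a Gaussian of width 1.73 voxels, peak-normalized to 255. On this
   synthetic volume every skeleton point has near-equal, near-maximal
   intensity, so a score computed on it cannot prefer one skeleton position
   over another for brightness reasons — it only expresses "stay on the
   skeleton";
3. alternates until the branch point converges (movement < 0.1 μm, at most
   10 iterations): move the branch point to the resampled `S1` point
   minimizing
   $$g_{\text{template}}(p) + \lambda\,(p_{fx}-p)^{\!\top}
     (I - dv_1 dv_1^{\!\top})(p_{fx}-p),$$
   then re-optimize `S2` on the real image with the new branch point and its
   far end fixed. Here $p_{fx}$ is the first `S2` point clearing every `S1`
   point by three voxel sizes, $p_{v1}$ the first subsequent point clearing
   $p_{fx}$ by the same margin, and $dv_1$ their unit direction; the second
   term is the squared perpendicular distance from the line through $p_{fx}$
   along $dv_1$ — the continuation of the side branch.

The full optimizer runs this pass three times, once per pairing of the three
incident segments (each recombined pair forms the through path, the third
segment the side path), and averages the three refined positions. A pass
whose frame cannot be built (the side path never clears the through path —
typical when the input branch point sits far down one arm, making the short
side window double back) is dropped from the average with a warning; if all
three degenerate the input position is kept. On the symmetric Y phantom the
surviving passes localize the junction to within ~0.03 μm for displacements
up to 5 voxels.

Design notes, where the design was genuinely open:

- The objective is minimized by *discrete* search over the 1-μm resampled
  through path, not by continuous refinement: the template makes the first
  term nearly flat along the path, the second term selects along it, and
  1 μm bounds the quantization error — which the three-pass average then
  reduces further.
- Because only the projector $I - dv_1 dv_1^{\!\top}$ enters, no explicit
  orthonormal completion $(dv_2, dv_3)$ is ever chosen; the completeness
  relation makes the objective independent of that choice (tested to 1e-9).
- The template's score is divided by its own maximum magnitude over the
  candidate points before adding the orientation term, since the two terms'
  natural scales (intensity sums vs μm²) are incommensurable; the weight
  `branch_lam` then defaults to 1.
- Step 4 re-optimizes `S2` on the *real* image (the template encodes only
  `S1`, so it has nothing to say about `S2`).
- "Three times the voxel size" is taken as three times the largest per-axis
  size on anisotropic grids, the conservative reading.
- Templates are built over the bounding box of the resampled path padded by
  $4\sigma$, carried in local coordinates, to avoid allocating full-stack
  volumes.

## The whole-tree workflow

`optimize_tree()` finds every node with two or more children, refines each
branch point (in increasing id order), then re-optimizes every maximal
segment between branch/terminal nodes with its — possibly moved — endpoints
fixed. Ids, parent links and type codes never change; terminals and roots
never move. Nodes with three or more children are decomposed into successive
bifurcations (first child paired with each later child) and flagged in the
report, as accuracy is expectedly lower there. A single pass (branches, then
segments) is the default; the CLI exposes `--passes` for repetition.

## The phantom generator

Real MOST/BigNeuron stacks and third-party tracer outputs are not
redistributable, so the package generates its own ground-truthed data, in
two flavours.

*Fold-line phantoms.* A fold line (two straight legs meeting at a corner of
known angle) is rasterized into a 156 × 156 × 57 binary stack (a voxel is 1
iff its centre is within half a voxel diagonal of the line), convolved with
a 3-D Gaussian of standard deviation 1.73 voxels (truncated at 4σ),
normalized to a maximum of exactly 255, and polluted with additive Gaussian
white noise (mean 0, SD 50 or 100), clipped below at 0 because intensities
must stay non-negative — no upper clip and no re-quantization. Corner angles
of 30° (sharp) and 90° (weak) are the standard conditions. The ground truth
is the fold line sampled at 0.5 μm — finer than the 1 μm working spacing, so
distance-to-truth metrics are not resolution-limited. The default geometry
places the corner low in the stack with legs opening upward, symmetric in x,
which makes the 90° phantom monotone in x; the 30° phantom necessarily
reverses in x (a 30° included angle is a 150° direction change), so the
x-resampling consistency metric does not apply to it and the consistency
experiment uses the 90° phantom.

*Y-junction phantoms.* Three straight arms radiate from a junction, each
rasterized, blurred with its own kernel width and scaled to its own peak
intensity before summation — so arm diameter and brightness can differ the
way they do around real branch points — plus optional noise. The default is
a symmetric Y: arms 120° apart, 22 μm long, equal intensity 255, in a
64 × 64 × 32 stack. The ground-truth tree has one branch node at the
junction, nodes every 1.5 μm.

*Initial skeletons.* Tracing error is emulated by `perturb_polyline()`:
i.i.d. uniform per-axis offsets in ±2 μm by default, endpoints fixed,
deterministic per seed. The corner-recovery experiments perturb the dense
ground truth directly. The consistency experiment instead perturbs a 2-μm
resampling of the truth and only in y and z: it emulates three tracers
disagreeing transversely about the same centerline, and keeps both the
initial and the optimized skeletons strictly x-monotone, which the
x-resampling protocol requires.

What the phantoms deliberately do not model: realistic PSFs (Airy,
Gibson–Lanni), Poisson/shot noise, multi-neuron crowding, intensity
inhomogeneity along the neurite. Passing the phantom experiments therefore
shows that the optimizers do what their models claim under controlled
tortuosity and noise — not that they are robust to every artefact of real
tissue; on real stacks the branch-point machinery in particular relies on
junction regions being locally tube-like.

## Measurements

`total_length()` sums parent–child edge lengths. `branch_angle()` walks 10
μm of arc down each child arm from the branch point and returns the angle
between the two chords — arc-length walking with linear interpolation, the
natural reading of a fixed-length local angle. `matched_pair_distances()`
x-resamples two skeletons (51 points, 1 μm x-steps by default), pairs each
segment of one with its nearest segment on the other (minimum distance
between 3-D line segments, the standard oracle-checkable choice), and
reports per-pair distances; it is the package's consistency measure between
two reconstructions of the same neurite and errors, by design, on paths that
are not x-monotone over the sampled range.

## Numerical choices and degenerate inputs

- Coincident consecutive input points (closer than 1e-6 μm) are merged
  before optimization.
- Segments with fewer than 3 distinct points are returned unchanged with a
  warning; there is nothing to optimize.
- Ties in the discrete branch search break toward the smaller index;
  together with the fixed iteration counts this makes every optimizer a pure
  function of its inputs (whole-tree runs are bitwise reproducible).
- Non-finite positions or objective values abort with an error naming
  `lam`, `mu` and `step_size`, rather than returning garbage.
- `resample_path()` places each point at exactly its spacing (Euclidean,
  measured across corners too) from the previous one by sphere–polyline
  intersection; the final interval may be shorter, and the last input point
  is always kept.
- Arms shorter than the requested chord in `branch_angle()` are used whole,
  with a warning, rather than erroring.

## Problem sizes

The shipped experiments run on one CPU in a few minutes total: the
156 × 156 × 57 fold-line conditions (around 460 path points, 5 sweeps of 20
gradient steps), the 15-case branch-displacement grid on the 64 × 64 × 32 Y
phantom, and the three-tracer consistency comparison. These sizes exercise
every code path at full fidelity; larger stacks scale linearly in voxels
for the generator and in path points for the optimizers, and the algorithms
are local, so users can crop.

## Known limitations

- The position update is plain gradient descent with a fixed step; extreme
  `lam`/`mu` choices need a matched step size (the divergence guard says so
  explicitly rather than adapting silently).
- Multifurcations are handled by pairwise decomposition, at reduced
  accuracy, and are flagged rather than modelled.
- The x-resampling consistency metric is undefined on skeletons that
  reverse in x; that is a limitation of the protocol itself, reported as an
  error.
- The intensity term attracts points to local maxima, so where a region is
  much brighter than the neurite — e.g. a synthetic junction where three
  arms add — nodes within a few micrometres of it crowd toward the hot
  spot during segment re-optimization. Junction position and topology are
  unaffected, but arc-length-based measures taken right at such a junction
  should use the pre-optimization geometry or a longer chord.
- No radius estimation, no gap closing, no tracing: the input topology is
  trusted and preserved exactly.
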