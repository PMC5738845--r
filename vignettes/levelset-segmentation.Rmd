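---
title: "Level-set segmentation of 3D plant-tissue stacks: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-set segmentation of 3D plant-tissue stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`levelset3d` segments 3D confocal stacks of membrane-stained plant tissue at
three scales: the outer tissue surface, the individual cells, and the nuclei
of a second reporter channel. All three tasks share one engine: a level-set
function (LSF) \(\phi\), negative inside the object, whose zero level is the
evolving contour, driven by the gradient flow of the energy

\[
E \;=\; \lambda L_g \;+\; \beta L_1 \;+\; \alpha A_g \;+\; \mu R_p .
\]

* **Image term** \(L_g\) (weight \(\lambda\), default 5): attracts the
  contour to valleys of an edge map \(g \in (0,1]\), built from the image by
  a Hill function \(g = 1/(1+|f/\gamma|^2)\) of an indicator \(f\).
* **Smoothing term** \(L_1\) (weight \(\beta \ge 0\), default 0): motion by
  mean curvature; used when global tissue shape matters more than cell-scale
  relief.
* **Accelerating (balloon) term** \(A_g\) (weight \(\alpha\), default 0,
  with a direction): motion along the contour normal at speed
  \(\alpha\,g\) — inward to push a surface contour into deep creases,
  outward to inflate cell seeds against their walls.
* **Regulariser** \(R_p\) (weight \(\mu\), default 0.02): a double-well
  penalty on \(|\nabla\phi|\) that keeps \(\phi\) numerically conditioned
  without re-initialisation.

\(\alpha\) and \(\beta\) are meant to stay small relative to \(\lambda\);
the recommended starting point is \(\alpha = \beta = 0\), staying as
faithful as possible to the image, adding acceleration or smoothing only
when the application needs them.

## The evolution scheme, and why the image term is pure advection

The discrete flow advances all level sets (the \(|\nabla\phi|\) extension of
the variational flow):

\[
\phi_t \;=\; \mu\,\mathrm{div}\!\big(d_p(|\nabla\phi|)\nabla\phi\big)
\;+\; \beta\,\kappa\,|\nabla\phi|
\;+\; \lambda\,\nabla g\cdot\nabla\phi
\;-\; \mathrm{dir}\cdot\alpha\, g\,|\nabla\phi|,
\]

with \(\kappa = \mathrm{div}(\nabla\phi/|\nabla\phi|)\). Three consequences
of this design are worth stating explicitly, because they differ from the
textbook variational form in which the driving terms are multiplied by a
smoothed Dirac \(\delta_\varepsilon(\phi)\):

1. **Front speeds are exact.** A planar front in a uniform edge map moves at
   \(\alpha\,g\,\delta t\) per step, and a sphere under pure smoothing
   follows the mean-curvature law \(R(t) = \sqrt{R_0^2 - 4\beta t}\). A
   \(\delta_\varepsilon\)-restricted flow rescales both speeds by
   \(\delta_\varepsilon(0)\approx 0.67\) (for the conventional
   \(\varepsilon = 1.5\)), which would defeat any quantitative check of the
   dynamics. The smoothed Heaviside/Dirac pair is retained only for the
   energy diagnostic reported per iteration.
2. **The image term vanishes on a uniform edge map.** The geodesic flow
   \(\mathrm{div}(g\nabla\phi/|\nabla\phi|)|\nabla\phi|\) contains a
   \(g\)-weighted curvature component; folding it into the image term makes
   pure-smoothing behaviour unreachable (a uniform \(g\) would still move
   contours). Here the image term is only the edge advection
   \(\lambda\nabla g\cdot\nabla\phi\) and all curvature motion is carried by
   \(\beta\).
3. **Pipelines that rely on the implicit contraction of the variational
   image term need it restored explicitly.** This matters for nuclei (see
   below).

Numerics: the balloon and advection terms are discretised with second-order
ENO (minmod-limited) upwind differences; curvature and regulariser use
central differences; anisotropic voxel spacing divides every derivative. The
explicit step is subject to a CFL limit that depends on \(\lambda\,
|\nabla g|\) — for a sharp Hessian edge map this is far stricter than for a
gradient map — so the engine computes a stable substep count once per run
(the speed bounds are static) and advances each reported iteration in that
many substeps. A per-substep cap of 0.49 voxel units on \(|\Delta\phi|\)
guards the rare case where local level-set compression exceeds the static
bound. The default \(\delta t = 0.2\) with \(\mu\,\delta t = 0.004\)
honours the \(\mu\,\delta t < 0.25\) stability contract with a wide margin.

**Stopping.** The contour is declared converged when the fraction of voxels
whose \(\phi\)-sign changed, averaged over the last `conv_window = 10`
iterations, falls below `conv_tol = 2e-4`. This deceleration criterion is
load-bearing: at a thin wall the advection holds the front in a valley whose
barrier is only one or two voxels wide, and over very long runs the
regulariser slowly relaxes the level-set compression that maintains the
barrier, letting the contour creep. Runs end when the front parks, which is
both what the method promises and what keeps it robust. The criterion
normalises by the grid volume, so small patches (per-cell fields) use a
tighter tolerance; `segment_nuclei()` does this by default.

**Known limitation.** Because the sign-change fraction is global, a small
front crawling through an extended low-\(g\) region (a bright crease halo)
can look converged; conversely, on a featureless fixture a parked front can
eventually creep if forced to run far past convergence with a tiny
tolerance. The band \(|\phi|<3\) around a parked front also carries
compressed level sets (\(|\nabla\phi|>1\)): any regulariser strong enough to
fully restore the signed-distance profile there would transport the contour
off its edge. \(\mu = 0.02\) keeps \(\phi\) bounded and finite (the tests
assert a mean band deviation below 1) without destabilising parked fronts.

## Edge maps

Three indicators are available, selected by `indicator_spec(kind, gamma, s)`:

| kind | \(f\) | valleys per wall | typical use |
|------|-------|------------------|-------------|
| `g`  | \(|\nabla\hat I|\) | two (one per side) | tissue surface; conservative cell contours |
| `i`  | \(\hat I\) | one | simple bright-wall cellular segmentation |
| `h`  | \(\min(\lambda_3, 0)\) | one | cells incl. dim outer walls; nuclei-adjacent tasks |

\(\hat I\) is the Gaussian-smoothed image (scale `s`, voxel units) and
\(\lambda_1\ge\lambda_2\ge\lambda_3\) are the eigenvalues of its local
Hessian (second-order central differences; closed per-voxel Jacobi
eigensolver). A bright thin wall has one strongly negative eigenvalue across
it regardless of how dim it is relative to other walls, which is why the
`h` indicator marks outer periclinal walls as sharply as bright anticlinal
walls and leaves a single valley per wall — cells segmented with it meet at
the wall instead of stopping one valley early on each side.

The Hill scale \(\gamma\) must track the span of \(f\) in the image at
hand. The numeric defaults (8 for `g`, 60 for `i`, 0.8 for `h`) correspond
to 8-bit-like membrane images; `gamma = "auto"` scales \(\gamma\) to a tenth
(a quarter for `i`) of the 99.5th percentile of \(|f|\), and is the default
for the cellular pipeline. Smoothing `s` defaults to 1 voxel; use smaller
values when the structures of interest (narrow creases, sub-voxel nuclear
envelopes) would be blurred shut — the edge of a convex blob of radius
\(R\) detected from gradients sits inward of the true boundary by
\(\approx \sigma^2/R\), with \(\sigma^2\) the summed variance of optics and
smoothing, so volume estimates of small objects need \(\sigma \ll \sqrt{R}\).

## The four pipelines

**Tissue surface** (`detect_surface`). Initialisation thresholds the image
with a threshold varying linearly in z (stacks lose brightness with depth),
keeps the largest component, fills enclosed cavities, and converts to a
signed distance by an exact Euclidean distance transform; `fill_below = TRUE`
additionally marks everything beneath the first detected signal of each
column as interior, appropriate for samples imaged from the top. An inward
balloon (\(\alpha = 1\), the Fig-style surface defaults `g`, \(\gamma = 8\),
`s = 1`) pushes the contour into surface creases that the image term alone
cannot enter. For deep narrow creases use `s = 0.5` so the crease channel
survives smoothing. The detected contour adheres to the outer gradient
valley of the wall, i.e. about one composed wall half-width outside the wall
centre-line — the accuracy tests account for that offset explicitly.

**Outer-layer watershed rescue** (`enhance_image` + `watershed_segment`).
Raw seeded watershed on tissue with dim outer walls loses or trims L1 cells:
with seeds detected as h-minima at a depth that avoids over-segmentation
inside the tissue, the dim outer walls are shallower than the h threshold
and the outer cells merge with the background basin. The rescue rewrites the
image: the detected surface becomes a white cap (the shell
\(|\phi|\le 1\) plus the sign-change faces of \(\phi\), which is watertight
by construction — a leaky cap lets the background flood back in), and the
exterior becomes the most frequent interior intensity (exact counts for
integer images, 256-bin histogram mode for floating point). Watershed floods
raw intensity, so boundaries settle on wall crests.

**Cellular segmentation** (`segment_cells`). One LSF per cell, initialised
from seeds (dilated by `r0`) or from an existing segmentation eroded by a
Euclidean ball of radius `d`, evolved independently (`alpha = 1` outward,
`beta = 0`) in the shared edge map, then rasterised: the most negative
\(\phi\) wins, exact ties to the lowest label, and remaining wall-gap voxels
are assigned to the nearest labelled object (exact Euclidean distances,
lowest label on ties). Independence is also an implementation contract: each
cell evolves on a padded bounding-box patch (`margin`), which makes 200-cell
stacks tractable in memory and time; the margin must cover the distance a
front can travel, about one cell radius for seed inflation.

**Nuclei** (`segment_nuclei`). Cells are eroded by `d = 1` and each contour
contracts in the edge map of the nuclear channel until the nucleus edge
halts it. Two deliberate deviations from an \(\alpha = \beta = 0\)
configuration follow from the advection-only image term: with no driving
term at all a contour in featureless cytoplasm would never move, so the
contraction that a variational image term supplies implicitly is restored
explicitly by a weak inward balloon (\(\alpha = 0.4\)) plus a small
\(\beta = 0.2\). Constant-speed contraction is used rather than
curvature-driven contraction because mean-curvature flow flattens \(\phi\)
around a shrinking contour (interior level sets vanish first) and stalls on
sheet-like residuals. A short drive-free relaxation phase then lets the edge
attraction place the contour on the valley floor. Results are clipped to the
parent cell (hard containment); a cell whose contour collapses keeps one
voxel so `filter_small()` (default `min_voxels = 10`) can remove and report
it — the record of nucleus-free cells is part of the output, not an error.
`measure_volumes()` converts voxel counts with the physical spacing and
`nucleus_cell_stats()` reports the volume distributions, the nucleus:cell
ratio and their Pearson correlation.

## Synthetic fixtures and what passing them shows

Real stacks of this kind are not redistributable, so the package ships
generators whose ground truth is voxel-exact and whose pathologies mirror
the ones that break naive pipelines:

* `make_shell_sphere()`: a Gaussian-profile spherical wall
  (\(\sigma = 1\) voxel, a realistic membrane width at quarter- to
  half-micron sampling), optional linear z-attenuation, optional cell-scale
  sinusoidal relief, clipped additive Gaussian noise.
* `make_foam()`: a ball tessellated into convex cells (nearest-seed
  tessellation with minimum-distance seed sampling and small-cell
  rejection); walls rendered by convolving single-voxel wall skeletons with
  a Gaussian, so junctions add up into bright halos as doubly-stained wall
  crossings do; the outer wall is dimmed by `rho_outer` (default 0.3) and
  the stack attenuated along z (default 0.4) — the study conditions of the
  rescue experiment.
* `make_folded_tissue()`: a dome split into two lobes by a flat-bottomed
  channel (stated depth and width), with the shared wall continuing beneath
  the groove as a septum, as the boundary wall between two pressed organs
  does. Walls here default to \(\sigma = 0.5\): with thicker walls a
  3-voxel-wide crease is solid wall material and no contour, by any method,
  can sit within 2 voxels of its floor.
* `add_nuclei_channel()`: one blob per cell, centred at the cell's deepest
  voxel with a 2-voxel cytoplasm rim; the truth nucleus is the drawn number
  of nearest cell voxels (a ball clipped to the cell), so the realised
  nucleus:cell ratio equals the drawn one exactly; the blob is that mask
  convolved with a sharp Gaussian edge (\(\sigma = 0.5\)), and the mixing
  between cell-size-linked and independent ratio variation is calibrated on
  the drawn sample to hit the requested volume correlation.

Everything is bit-reproducible from the stored seed. What these fixtures do
not emulate: anisotropic point-spread functions, Poisson photon statistics,
multi-angle fusion artefacts, non-convex cells, and textured cytoplasm —
passing the suite shows the machinery is correct at the stated contrast and
noise levels, not that real acquisitions of arbitrary quality will segment
equally well.

## Problem sizes and determinism

The shipped tests and the acceptance script run the surface fixtures at
\(96^3\), the watershed-rescue foam at \(128^3\) with 15 cells, the cellular
pipeline at \(96^3\) with 8 cells, and the nuclei statistics at \(128^3\)
with 200 cells — sizes at which every claim of the method is measurable with
comfortable statistics while a complete run stays in the minutes range on a
single core. The engine contains no randomness; generators draw all
randomness from their seed argument and restore the caller's RNG state, so
identical seeded invocations produce checksum-identical outputs end to end.
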