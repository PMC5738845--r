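# levelset3d

Level-set segmentation of 3D confocal stacks of plant tissues, at three
scales: the outer tissue surface, the individual cells, and the nuclei of a
second reporter channel.

Quantifying development requires turning image stacks into digital tissues,
and the weak point of the standard watershed route is the outer (L1) cell
layer: outer periclinal walls image far more dimly than anticlinal walls, so
seeds go missing and surface cells end up trimmed or absent. `levelset3d`
addresses this with geodesic active contours: a level-set function (LSF)
φ — negative inside, its zero level the contour — evolves under the gradient
flow of

    E = λ L_g + β L_1 + α A_g + μ R_p

where `L_g` attracts the contour to valleys of an edge map
`g(x) = 1 / (1 + |f(x)/γ|²)`, `L_1` is a smoothing (mean-curvature) term,
`A_g` an accelerating "balloon" term moving the contour along its normal at
speed `α·g` (inward to push a surface contour into deep creases between
organs, outward to inflate cell seeds), and `R_p` a distance regulariser.
Three indicator functions `f` are available: gradient magnitude `|∇Î|`,
image intensity `Î`, and a Hessian wall indicator `min(λ₃, 0)` built from
the eigenvalues of the local Hessian — a thin bright wall has one strongly
negative eigenvalue across it however dim it is, so this indicator marks
outer walls as sharply as inner ones and shows a single valley per wall.

The package provides:

* `detect_surface()` — tissue-surface detection with z-linear threshold
  initialisation and an inward balloon;
* `enhance_image()` + `detect_seeds_hminima()` + `watershed_segment()` —
  3D seeded watershed with h-minima seeding, on an image whose detected
  surface is set to white and whose background is set to the most frequent
  interior intensity, which stops the background basin from swallowing
  outer-layer cells;
* `segment_cells()` — one LSF per cell (from seeds or an eroded existing
  segmentation), evolved independently, rasterised, and gap-filled by
  nearest-object assignment;
* `segment_nuclei()`, `filter_small()`, `measure_volumes()`,
  `nucleus_cell_stats()` — nuclei from eroded cells, with per-cell volume
  statistics (nucleus:cell ratio, volume correlation, detected fraction);
* `make_shell_sphere()`, `make_foam()`, `make_folded_tissue()`,
  `add_nuclei_channel()` — synthetic 3D fixtures with voxel-exact ground
  truth emulating dim outer walls, z-attenuation, junction halos, deep
  organ-boundary creases and a nuclear channel;
* multi-page TIFF I/O (`read_stack()` / `write_stack()`) and a command-line
  interface (`run_cli()`, with a thin wrapper script in `inst/cli/`).

## Worked example

Segment a synthetic eight-cell tissue and its nuclei:

```r
library(levelset3d)

tissue <- make_foam(shape = c(96, 96, 96), n_cells = 8, seed = 1)
tissue <- add_nuclei_channel(tissue, ratio_mean = 0.17, ratio_sd = 0.05,
                             target_corr = 0.6, seed = 1)

seeds <- array(0L, dim(tissue$image))
seeds[round(tissue$truth$seed_points)] <- 1:8

cells <- segment_cells(tissue$image, seeds = seeds, margin = 24,
                       domain_mask = tissue$truth$tissue_mask)
compare_segmentations(cells$labels, tissue$truth_labels)
#> segmentation metrics: 0 lost cells, agreement 0.996
#>   mean |volume error|: 0.017

nuclei <- filter_small(segment_nuclei(tissue$nuclear, cells$labels), 10)
nucleus_cell_stats(measure_volumes(nuclei$labels, c(0.5, 0.5, 0.5)),
                   measure_volumes(cells$labels, c(0.5, 0.5, 0.5)))
#> nuclei detected in 8 of 8 cells (100.0%)
#>   cell volume: 4289.5 +/- 1063.8
#>   nucleus volume: 735.5 +/- 150.5
#>   nucleus:cell ratio: 0.176 +/- 0.039
#>   volume correlation: 0.59
```

All eight cells are recovered at 99.6% voxel agreement with the generator's
ground truth, every cell's nucleus is detected, and the recovered
nucleus:cell volume ratio (0.176 ± 0.039) matches the imposed 0.17 within
the edge-location bias discussed in the vignette. Volumes are in μm³ at the
stated 0.5 μm voxel spacing.

The methods vignette (`vignettes/levelset-segmentation.Rmd`) documents the
evolution scheme, parameter meanings and defaults, the numerical choices
(upwinding, CFL sub-stepping, stopping criterion), and what the synthetic
fixtures do and do not emulate.

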