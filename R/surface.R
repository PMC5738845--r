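#' Initialise a level-set function by a z-linear intensity threshold
#'
#' Confocal stacks typically lose brightness when descending along the z axis,
#' so a single global threshold cannot place the initial contour at a uniform
#' distance from the sample. The threshold here varies linearly from `t_top`
#' (first z slice) to `t_bottom` (last z slice); voxels brighter than the
#' local threshold form the initial interior. Speckle is removed by keeping
#' only the largest connected component, enclosed cavities (dark cell lumina
#' inside the tissue, not connected to the image border) are filled, and the
#' result is converted to a signed distance function (negative inside) by an
#' exact Euclidean distance transform.
#'
#' @param I 3D numeric array with at least 2 z slices.
#' @param t_top,t_bottom intensity thresholds at the first and last slice.
#' @param clean remove speckle (largest component) and fill enclosed
#'   cavities; default `TRUE`. With `clean = FALSE` the thresholded mask is
#'   used as is.
#' @param fill_below if `TRUE`, every voxel beneath (larger z than) an
#'   above-threshold voxel of its column is included in the interior —
#'   appropriate for samples imaged from the top, where everything below the
#'   detected signal is tissue or its shadow. Default `FALSE`.
#' @param spacing voxel spacing per axis.
#' @return a signed-distance level-set function (3D numeric array).
#' @export
init_z_threshold <- function(I, t_top, t_bottom, clean = TRUE,
                             fill_below = FALSE, spacing = c(1, 1, 1)) {
  assert_grid3d(I, "I")
  nz <- dim(I)[3]
  if (nz < 2L) stop("image must have at least 2 z slices")
  tz <- t_top + (t_bottom - t_top) * (seq_len(nz) - 1) / (nz - 1)
  thr <- aperm(array(tz, c(nz, dim(I)[1], dim(I)[2])), c(2, 3, 1))
  interior <- I > thr
  if (fill_below && any(interior)) {
    interior <- aperm(apply(interior, c(1, 2), cummax) == 1, c(2, 3, 1))
  }
  if (clean && any(interior)) {
    interior <- largest_component(interior)
    interior <- fill_holes3d(interior)
  }
  mask_signed_distance(interior, spacing)
}

#' Detect the outer surface of a tissue
#'
#' Single level-set pipeline for tissue-contour detection: threshold
#' initialisation outside the sample ([init_z_threshold()]), edge map from
#' the membrane signal, then evolution with an inward balloon (default
#' `alpha = 1`, `beta = 0`) that pushes the contour into deep surface creases
#' where the image term alone would leave it suspended.
#'
#' @param I 3D numeric array (membrane channel).
#' @param t_top,t_bottom initialisation thresholds (see [init_z_threshold()]).
#' @param spec an [indicator_spec()]; default gradient indicator, `gamma = 8`,
#'   `s = 1`.
#' @param params an [evolve_params()]; default `alpha = 1`, `beta = 0`,
#'   direction inward.
#' @param shell_thickness thickness (voxels) of the reported surface shell.
#' @param spacing voxel spacing per axis.
#' @param init optional: a pre-existing coarse interior mask (3D logical or
#'   0/1 array) used instead of the threshold initialisation.
#' @param fill_below passed to [init_z_threshold()] (top-down imaged
#'   samples).
#' @param track_energy record the energy series in the diagnostics.
#' @return an object of class `surface_result`: list with `phi`,
#'   `surface_mask`, `interior_mask`, `edge` (the edge map) and `diagnostics`.
#' @export
detect_surface <- function(I, t_top, t_bottom,
                           spec = indicator_spec("g", 8, 1),
                           params = evolve_params(alpha = 1, beta = 0,
                                                  direction = "inward"),
                           shell_thickness = 2, spacing = c(1, 1, 1),
                           init = NULL, fill_below = FALSE,
                           track_energy = FALSE) {
  assert_grid3d(I, "I")
  spacing <- check_spacing(spacing)
  if (is.null(init)) {
    phi0 <- init_z_threshold(I, t_top, t_bottom, clean = TRUE,
                             fill_below = fill_below, spacing = spacing)
  } else {
    assert_same_shape(I, init, "image and init mask")
    phi0 <- mask_signed_distance(init != 0, spacing)
  }
  if (!any(phi0 < 0)) stop("initialisation enclosed nothing")
  g <- edge_map(I, spec, spacing)
  res <- evolve(phi0, g, params, spacing, track_energy = track_energy)
  structure(list(phi = res$phi,
                 surface_mask = surface_shell(res$phi, shell_thickness),
                 interior_mask = res$phi < 0,
                 edge = g,
                 diagnostics = res$diagnostics),
            class = "surface_result")
}

#' @export
print.surface_result <- function(x, ...) {
  cat("tissue surface result\n")
  cat(sprintf("  interior voxels: %d\n", sum(x$interior_mask)))
  print(x$diagnostics)
  invisible(x)
}

#' Shell of voxels around the zero level
#'
#' Mask of voxels within `thickness / 2` (in `phi` units) of the contour.
#'
#' @param phi level-set function (3D numeric array).
#' @param thickness shell thickness (> 0).
#' @return 3D logical array.
#' @export
surface_shell <- function(phi, thickness) {
  assert_grid3d(phi, "phi")
  if (!is.numeric(thickness) || thickness <= 0) stop("'thickness' must be > 0")
  abs(phi) <= thickness / 2
}
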