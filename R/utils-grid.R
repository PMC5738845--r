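# Internal helpers on 3D numeric arrays (dim = c(n1, n2, n3), third axis = z).
# Boundary handling is replicate (Neumann) throughout.

assert_grid3d <- function(a, name = deparse(substitute(a))) {
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  invisible(a)
}

assert_same_shape <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  invisible(NULL)
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers", call. = FALSE)
  spacing
}

# shift a 3D array by d voxels along one axis, replicating edge values
shift_clamp <- function(a, axis, d) {
  if (d == 0L) return(a)
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + d, 1L), n)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

central_diff <- function(a, axis, h = 1) {
  (shift_clamp(a, axis, 1L) - shift_clamp(a, axis, -1L)) / (2 * h)
}

second_diff <- function(a, axis, h = 1) {
  (shift_clamp(a, axis, 1L) - 2 * a + shift_clamp(a, axis, -1L)) / (h * h)
}

# squared Euclidean distance to the TRUE voxels of `sites`, with nearest-site
# linear indices; exact, anisotropic spacing supported
edt3d <- function(sites, spacing = c(1, 1, 1)) {
  assert_grid3d(sites)
  spacing <- check_spacing(spacing)
  edt_cpp(as.logical(sites), dim(sites), spacing)
}

# signed distance to the boundary of a binary interior mask
# (negative inside); zero level sits half a voxel outside boundary voxels
mask_signed_distance <- function(interior, spacing = c(1, 1, 1)) {
  assert_grid3d(interior)
  interior <- interior != 0
  spacing <- check_spacing(spacing)
  d_out <- sqrt(edt_cpp(interior, dim(interior), spacing)$dist2)
  d_in <- sqrt(edt_cpp(!interior, dim(interior), spacing)$dist2)
  # an all-interior (or all-exterior) mask has no boundary: cap the distance
  # so phi stays finite
  cap <- sum(dim(interior) * spacing)
  d_out[!is.finite(d_out)] <- cap
  d_in[!is.finite(d_in)] <- cap
  phi <- ifelse(interior, -(d_in - 0.5), d_out - 0.5)
  array(phi, dim(interior))
}

# coordinates (voxel indices) of the centre of a grid
grid_centre <- function(shape) (shape + 1) / 2

# radial coordinate array around a centre, in voxel units (optionally scaled)
radius_grid <- function(shape, centre = grid_centre(shape), spacing = c(1, 1, 1)) {
  spacing <- check_spacing(spacing)
  x <- (seq_len(shape[1]) - centre[1]) * spacing[1]
  y <- (seq_len(shape[2]) - centre[2]) * spacing[2]
  z <- (seq_len(shape[3]) - centre[3]) * spacing[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  sqrt(r2)
}

# fill enclosed cavities: background components not touching any image border
fill_holes3d <- function(mask) {
  assert_grid3d(mask)
  mask <- mask != 0
  comp <- label_components_cpp(!mask, dim(mask))
  border <- unique(c(comp[1, , ], comp[dim(mask)[1], , ],
                     comp[, 1, ], comp[, dim(mask)[2], ],
                     comp[, , 1], comp[, , dim(mask)[3]]))
  border <- border[border > 0]
  filled <- mask | !(comp %in% c(0L, border))
  array(filled, dim(mask))
}

# keep only the largest connected component of a binary mask
largest_component <- function(mask) {
  assert_grid3d(mask)
  mask <- mask != 0
  if (!any(mask)) return(mask)
  comp <- label_components_cpp(mask, dim(mask))
  tab <- tabulate(comp[comp > 0L])
  keep <- which.max(tab)
  array(comp == keep, dim(mask))
}
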