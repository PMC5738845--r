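# shared helpers: analytic grids and measurement utilities for the synthetic
# fixtures; all expected values here are computed, not copied from results

radial_grid <- function(shape, centre = (shape + 1) / 2) {
  x2 <- (seq_len(shape[1]) - centre[1])^2
  y2 <- (seq_len(shape[2]) - centre[2])^2
  z2 <- (seq_len(shape[3]) - centre[3])^2
  sqrt(outer(outer(x2, y2, `+`), z2, `+`))
}

sphere_sdf <- function(shape, R, centre = (shape + 1) / 2) {
  radial_grid(shape, centre) - R
}

# sub-voxel radii of the zero level: linear interpolation across every
# sign-changing voxel pair along each axis
zero_crossing_radii <- function(phi, r) {
  out <- numeric(0)
  for (axis in 1:3) {
    n <- dim(phi)[axis]
    idx <- seq_len(n - 1)
    a <- switch(axis, phi[idx, , , drop = FALSE], phi[, idx, , drop = FALSE],
                phi[, , idx, drop = FALSE])
    b <- switch(axis, phi[idx + 1, , , drop = FALSE], phi[, idx + 1, , drop = FALSE],
                phi[, , idx + 1, drop = FALSE])
    ra <- switch(axis, r[idx, , , drop = FALSE], r[, idx, , drop = FALSE],
                 r[, , idx, drop = FALSE])
    rb <- switch(axis, r[idx + 1, , , drop = FALSE], r[, idx + 1, , drop = FALSE],
                 r[, , idx + 1, drop = FALSE])
    cross <- (a < 0) != (b < 0)
    if (any(cross)) {
      t <- a[cross] / (a[cross] - b[cross])
      out <- c(out, ra[cross] + t * (rb[cross] - ra[cross]))
    }
  }
  out
}

# effective radius from the interior volume
radius_from_volume <- function(phi) (3 * sum(phi < 0) / (4 * pi))^(1 / 3)

# per-column (x, y) depth of the first interior voxel from the top of the
# stack
first_interior_depth <- function(phi) {
  sh <- dim(phi)
  dep <- matrix(NA_real_, sh[1], sh[2])
  for (k in seq_len(sh[3])) {
    neg <- phi[, , k] < 0 & is.na(dep)
    dep[neg] <- k
  }
  dep
}

# number of interior local minima of a numeric profile
count_valleys <- function(v) {
  d <- diff(v)
  sum(d[-length(d)] < 0 & d[-1] > 0)
}

# mean |grad phi| deviation from 1 in the band |phi| < 3 (central differences)
band_slope_deviation <- function(phi) {
  shift1 <- function(a, axis, d) {
    n <- dim(a)[axis]
    idx <- pmin(pmax(seq_len(n) + d, 1L), n)
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  gx <- (shift1(phi, 1, 1) - shift1(phi, 1, -1)) / 2
  gy <- (shift1(phi, 2, 1) - shift1(phi, 2, -1)) / 2
  gz <- (shift1(phi, 3, 1) - shift1(phi, 3, -1)) / 2
  sn <- sqrt(gx^2 + gy^2 + gz^2)
  band <- abs(phi) < 3
  mean(abs(sn[band] - 1))
}

# seed label grid from the foam generator's seed points
foam_seed_grid <- function(tissue) {
  seeds <- array(0L, dim(tissue$image))
  co <- round(tissue$truth$seed_points)
  seeds[co] <- seq_len(nrow(co))
  seeds
}
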