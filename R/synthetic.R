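# Synthetic 3D fixtures with voxel-exact ground truth, emulating the imaging
# pathologies of confocal stacks of membrane-stained plant tissue: bright
# anticlinal walls with dim outer periclinal walls, loss of brightness along
# z, deep surface creases between organs, and a nuclear-reporter channel with
# one blob per cell.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_synthetic_tissue <- function(image, labels, surface, params, ...) {
  structure(c(list(image = image, truth_labels = labels,
                   truth_surface_mask = surface, params = params),
              list(...)),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("synthetic tissue (%s): %s voxels, %d cells\n",
              x$params$kind, paste(dim(x$image), collapse = "x"),
              length(setdiff(unique(as.integer(x$truth_labels)), 0L))))
  invisible(x)
}

atten_profile <- function(shape, atten_k) {
  z <- 1 - atten_k * (seq_len(shape[3]) - 1) / (shape[3] - 1)
  aperm(array(z, c(shape[3], shape[1], shape[2])), c(2, 3, 1))
}

add_noise_clip <- function(I, noise_sigma) {
  if (noise_sigma > 0) I <- I + array(rnorm(length(I), 0, noise_sigma), dim(I))
  I[I < 0] <- 0
  I
}

#' Synthetic spherical shell tissue (surface-detection fixture)
#'
#' A bright spherical wall of Gaussian cross-section around a dark interior:
#' intensity \eqn{A e^{-(r-R)^2/2\sigma^2}} times a linear z-attenuation
#' \eqn{1 - k(z-1)/(Z-1)}, plus clipped Gaussian noise. `bump_amp`/`bump_n`
#' superimpose a cell-scale sinusoidal relief on the radius (a "bumpy
#' sphere") for smoothing-term experiments. Ground truth: the (local) radius
#' surface and the enclosed interior as label 1.
#'
#' @param shape grid dimensions, default `c(96, 96, 96)`.
#' @param R sphere radius in voxels; must satisfy
#'   `R < min(shape)/2 - 3*wall_sigma`.
#' @param wall_sigma Gaussian half-thickness of the wall (voxels), default 1.
#' @param A_wall peak wall intensity, default 200.
#' @param noise_sigma additive Gaussian noise sd, default 0.
#' @param atten_k z-attenuation coefficient in `[0, 1)`, default 0.
#' @param bump_amp,bump_n amplitude (voxels) and angular frequency of the
#'   sinusoidal relief, defaults 0 (smooth sphere).
#' @param seed RNG seed (bit-reproducible output).
#' @return a `synthetic_tissue` object; `$truth` holds `R` and the local
#'   radius field.
#' @export
make_shell_sphere <- function(shape = c(96, 96, 96), R = 20, wall_sigma = 1,
                              A_wall = 200, noise_sigma = 0, atten_k = 0,
                              bump_amp = 0, bump_n = 0, seed = 1) {
  shape <- as.integer(shape)
  if (!(R < min(shape) / 2 - 3 * wall_sigma))
    stop("geometry violates R < min(shape)/2 - 3*wall_sigma")
  ctr <- grid_centre(shape)
  r <- radius_grid(shape, ctr)
  Rloc <- R
  if (bump_amp != 0 && bump_n > 0) {
    x <- slice.index(r, 1) - ctr[1]
    y <- slice.index(r, 2) - ctr[2]
    z <- slice.index(r, 3) - ctr[3]
    theta <- acos(pmin(pmax(z / pmax(r, 1e-9), -1), 1))
    phi_az <- atan2(y, x)
    Rloc <- R + bump_amp * sin(bump_n * theta) * cos(bump_n * phi_az)
  }
  I <- A_wall * exp(-(r - Rloc)^2 / (2 * wall_sigma^2)) * atten_profile(shape, atten_k)
  I <- with_seed(seed, add_noise_clip(I, noise_sigma))
  labels <- array(0L, shape)
  labels[r < Rloc] <- 1L
  surface <- abs(r - Rloc) <= 0.5
  new_synthetic_tissue(I, labels, surface,
                       params = list(kind = "shell_sphere", shape = shape, R = R,
                                     wall_sigma = wall_sigma, A_wall = A_wall,
                                     noise_sigma = noise_sigma, atten_k = atten_k,
                                     bump_amp = bump_amp, bump_n = bump_n,
                                     seed = seed),
                       truth = list(R = R, Rloc = Rloc, centre = ctr))
}

# Poisson-disk-ish seed sampling in a ball: candidates drawn uniformly,
# accepted if farther than dmin from all accepted seeds.
sample_seeds_ball <- function(n, centre, radius, dmin, max_tries = 20000L) {
  pts <- matrix(numeric(0), 0, 3)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1L
    p <- runif(3, -1, 1)
    if (sum(p^2) > 1) next
    cand <- centre + p * radius
    if (nrow(pts) == 0L || min(sqrt(colSums((t(pts) - cand)^2))) >= dmin)
      pts <- rbind(pts, cand)
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " cell seeds with the requested spacing")
  pts
}

#' Synthetic cellular foam (watershed / cellular-segmentation fixture)
#'
#' A ball-shaped tissue tessellated into `n_cells` convex cells (nearest-seed
#' Euclidean tessellation), with Gaussian-profile walls: inner (anticlinal)
#' walls between two cells at brightness `A_wall`, the outer (periclinal)
#' tissue surface at `rho_outer * A_wall` — dim outer walls being the classic
#' failure mode of watershed seeding at the tissue surface. z-attenuation and
#' clipped Gaussian noise as in [make_shell_sphere()]. Ground truth: the
#' tessellation labels (exterior 0) and the outer-surface voxel mask.
#'
#' @param shape grid dimensions, default `c(96, 96, 96)`.
#' @param n_cells number of cells (>= 2).
#' @param wall_width nominal wall thickness in voxels (Gaussian sigma =
#'   `wall_width / 2`), default 2.
#' @param A_wall inner-wall peak intensity, default 200.
#' @param rho_outer outer/inner wall brightness ratio, default 0.3.
#' @param noise_sigma additive Gaussian noise sd, default 4.
#' @param atten_k z-attenuation coefficient, default 0.4.
#' @param tissue_radius tissue ball radius (voxels); default `0.42 * min(shape)`.
#' @param min_cell_voxels reject seed layouts that produce a smaller cell.
#' @param seed RNG seed.
#' @return a `synthetic_tissue` object; `$truth` holds the seed points.
#' @export
make_foam <- function(shape = c(96, 96, 96), n_cells = 8, wall_width = 2,
                      A_wall = 200, rho_outer = 0.3, noise_sigma = 4,
                      atten_k = 0.4, tissue_radius = NULL,
                      min_cell_voxels = 100L, seed = 1) {
  shape <- as.integer(shape)
  if (n_cells < 2) stop("'n_cells' must be >= 2")
  if (is.null(tissue_radius)) tissue_radius <- 0.42 * min(shape)
  ctr <- grid_centre(shape)
  r <- radius_grid(shape, ctr)
  tissue <- r <= tissue_radius
  dmin <- 0.7 * (4 / 3 * pi * tissue_radius^3 / n_cells)^(1 / 3)

  res <- with_seed(seed, {
    for (attempt in 1:25) {
      pts <- sample_seeds_ball(n_cells, ctr, 0.82 * tissue_radius, dmin)
      sites <- array(FALSE, shape)
      site_lab <- integer(prod(shape))
      co <- round(pts)
      idx <- co[, 1] + shape[1] * (co[, 2] - 1 + shape[2] * (co[, 3] - 1))
      if (anyDuplicated(idx)) next
      sites[idx] <- TRUE
      site_lab[idx] <- seq_len(n_cells)
      near <- edt_cpp(sites, shape, c(1, 1, 1))$index
      labels <- array(site_lab[near], shape)
      labels[!tissue] <- 0L
      counts <- tabulate(labels[labels > 0L], nbins = n_cells)
      if (all(counts >= min_cell_voxels)) break
      labels <- NULL
    }
    if (is.null(labels)) stop("could not generate a foam with all cells >= ",
                              min_cell_voxels, " voxels")
    list(labels = labels, pts = pts)
  })
  labels <- res$labels

  # single-layer wall skeletons (one voxel layer per wall, the lower-label
  # side for inner walls), so inner and outer walls render with the same
  # per-sheet brightness and their mean ratio is rho_outer by construction
  different_neighbour <- array(FALSE, shape)
  outer_adj <- array(FALSE, shape)
  for (axis in 1:3) for (dd in c(-1L, 1L)) {
    nb <- shift_clamp(labels, axis, dd)
    different_neighbour <- different_neighbour | (labels > 0L & nb > labels)
    outer_adj <- outer_adj | (labels > 0L & nb == 0L)
  }
  # walls rendered by convolving the wall skeleton with a Gaussian of sigma
  # wall_width/2, normalised so an isolated flat wall peaks at A_wall;
  # contributions add where walls meet, giving the bright junction halos of
  # doubly-stained anticlinal wall crossings
  sw <- wall_width / 2
  r <- max(1L, ceiling(4 * sw))
  w0 <- {
    w <- exp(-(seq(-r, r))^2 / (2 * sw^2))
    max(w / sum(w))
  }
  I <- A_wall / w0 * (gaussian_smooth(different_neighbour * 1.0, sw) +
                      rho_outer * gaussian_smooth(outer_adj * 1.0, sw))
  I <- I * atten_profile(shape, atten_k)
  I <- with_seed(seed + 1L, add_noise_clip(I, noise_sigma))

  new_synthetic_tissue(I, labels, outer_adj,
                       params = list(kind = "foam", shape = shape,
                                     n_cells = n_cells, wall_width = wall_width,
                                     A_wall = A_wall, rho_outer = rho_outer,
                                     noise_sigma = noise_sigma, atten_k = atten_k,
                                     tissue_radius = tissue_radius, seed = seed),
                       truth = list(seed_points = res$pts,
                                    inner_wall_mask = different_neighbour,
                                    tissue_mask = tissue))
}

#' Synthetic folded tissue surface (crease-penetration fixture)
#'
#' A bright wall along a single-valued surface z = f(x, y): a smooth
#' paraboloid dome split into two lobes by a Gaussian groove of the given
#' depth and width — the deep, narrow crease that forms at the boundary
#' between growing organs. Beneath the groove the two lobes touch, so the
#' boundary wall continues downward as a bright septum plane (as the shared
#' anticlinal wall between two organs does). Intensity decays with exact
#' Euclidean distance to the rasterised surface + septum, so the steep groove
#' walls are rendered without gaps and the crease interior carries a bright
#' halo from the nearby walls. Ground truth: the depth map f.
#'
#' @param shape grid dimensions, default `c(96, 96, 48)`.
#' @param crease_depth groove depth in voxels, default 10.
#' @param crease_width groove width in voxels (>= 2; Gaussian sigma =
#'   `crease_width / 2`), default 3.
#' @param A_wall wall peak intensity, default 200.
#' @param wall_sigma wall Gaussian half-thickness (voxels), default 0.5 —
#'   the walls must be resolvable inside a crease of the default width for
#'   the crease floor to be imageable at all.
#' @param apex_z depth (z slice) of the dome apex, default 12.
#' @param dome_curv paraboloid curvature (voxels of extra depth per squared
#'   lateral voxel), default chosen so the dome drops ~12 voxels at the
#'   lateral border.
#' @param noise_sigma additive Gaussian noise sd, default 0.
#' @param seed RNG seed.
#' @return a `synthetic_tissue` object; `$truth$depth_map` is the `n1 x n2`
#'   matrix f, and `$truth$crease_cols` marks the columns inside the groove.
#' @export
make_folded_tissue <- function(shape = c(96, 96, 48), crease_depth = 10,
                               crease_width = 3, A_wall = 200, wall_sigma = 0.5,
                               apex_z = 12, dome_curv = NULL, noise_sigma = 0,
                               seed = 1) {
  shape <- as.integer(shape)
  if (crease_width < 2) stop("'crease_width' must be >= 2 voxels")
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  if (is.null(dome_curv)) dome_curv <- 12 / (min(shape[1], shape[2]) / 2)^2
  x <- seq_len(shape[1]); y <- seq_len(shape[2])
  lat2 <- outer((x - cx)^2, (y - cy)^2, `+`)
  # flat-bottomed channel profile (two organ surfaces pressed together leave
  # a near-parallel-walled gap, not a V): half-depth at half-width
  sc <- crease_width / 2
  groove <- crease_depth / (1 + ((x - cx) / sc)^8)
  zs <- apex_z + dome_curv * lat2 + matrix(groove, shape[1], shape[2])
  zs <- pmin(zs, shape[3] - 2)

  # rasterise the surface by supersampling the analytic depth map (4x per
  # axis), so steep groove walls become thin connected voxel staircases
  # instead of solid columns
  step <- 0.25
  xs <- seq(1, shape[1], by = step)
  ys <- seq(1, shape[2], by = step)
  lat2s <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  grooves <- crease_depth / (1 + ((xs - cx) / sc)^8)
  zss <- apex_z + dome_curv * lat2s + matrix(grooves, length(xs), length(ys))
  zss <- pmin(zss, shape[3] - 2)
  co <- cbind(rep(round(xs), times = length(ys)),
              rep(round(ys), each = length(xs)),
              as.vector(pmin(pmax(round(zss), 1), shape[3])))
  sheet <- array(FALSE, shape)
  sheet[co] <- TRUE
  zidx <- slice.index(sheet, 3)
  if (crease_depth > 0) {
    # septum: the shared wall between the two lobes, continuing below the
    # groove bottom
    xg <- slice.index(sheet, 1)
    zs3s <- array(rep(zs, shape[3]), shape)
    sheet <- sheet | (abs(xg - cx) <= 0.5 & zidx > zs3s)
  }
  d2 <- edt_cpp(sheet, shape, c(1, 1, 1))$dist2
  I <- A_wall * exp(-d2 / (2 * wall_sigma^2))
  I <- with_seed(seed, add_noise_clip(I, noise_sigma))

  labels <- array(0L, shape)
  zs3 <- array(rep(zs, shape[3]), shape)
  labels[zidx > zs3] <- 1L
  surface <- sheet & abs(zidx - zs3) <= 1
  crease_cols <- matrix(groove, shape[1], shape[2]) > crease_depth / 2
  new_synthetic_tissue(I, labels, surface,
                       params = list(kind = "folded_tissue", shape = shape,
                                     crease_depth = crease_depth,
                                     crease_width = crease_width, A_wall = A_wall,
                                     wall_sigma = wall_sigma, apex_z = apex_z,
                                     dome_curv = dome_curv,
                                     noise_sigma = noise_sigma, seed = seed),
                       truth = list(depth_map = zs, crease_cols = crease_cols))
}

#' Add a nuclear-reporter channel to a synthetic tissue
#'
#' One soft-edged blob per cell (except a random `missing_fraction` of
#' cells), centred at the cell's deepest interior voxel. Nucleus volumes are
#' drawn so that the nucleus:cell volume ratio has the requested mean and sd
#' and the (cell volume, nucleus volume) pairs have Pearson correlation close
#' to `target_corr` (the mixing weight between cell-size-linked and
#' independent ratio variation is calibrated on the drawn sample). The truth
#' nucleus mask is the drawn number of cell voxels nearest the centre — a
#' ball clipped to its cell, as nuclei deform against walls rather than
#' cross them — so the realised volume ratio equals the drawn one exactly.
#' The rendered blob is that mask convolved with a Gaussian edge
#' (`edge_sigma`): its half-maximum surface sits on the truth mask boundary.
#'
#' @param tissue a `synthetic_tissue` with cell labels (e.g. [make_foam()]).
#' @param ratio_mean,ratio_sd nucleus:cell volume ratio moments
#'   (0 < mean < 1), defaults 0.17 and 0.05.
#' @param target_corr target Pearson correlation between cell and nucleus
#'   volumes, default 0.6.
#' @param missing_fraction fraction of cells with no nucleus, in [0, 1).
#' @param A_nuc blob peak intensity, default 150.
#' @param edge_sigma Gaussian edge width of the blob (voxels), default 0.5
#'   (the nuclear envelope is sharp at sub-voxel scale in high-NA confocal).
#' @param noise_sigma additive Gaussian noise sd on the channel, default 2.
#' @param seed RNG seed.
#' @return the input `synthetic_tissue` with added elements `nuclear`
#'   (channel), `truth_nuclei` (label grid), and `truth$nuclei` (per-cell
#'   table with centre, radius, truth volumes, present flag).
#' @export
add_nuclei_channel <- function(tissue, ratio_mean = 0.17, ratio_sd = 0.05,
                               target_corr = 0.6, missing_fraction = 0,
                               A_nuc = 150, edge_sigma = 0.5, noise_sigma = 2,
                               seed = 1) {
  if (!inherits(tissue, "synthetic_tissue")) stop("'tissue' must be a synthetic_tissue")
  if (!(ratio_mean > 0 && ratio_mean < 1)) stop("'ratio_mean' must be in (0,1)")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("'missing_fraction' must be in [0,1)")
  L <- tissue$truth_labels
  shape <- dim(L)
  labs <- sort(setdiff(unique(as.integer(L)), 0L))
  n <- length(labs)
  if (n == 0L) stop("tissue has no cells")
  Vc <- tabulate(L[L > 0L], nbins = max(labs))[labs]

  gen <- with_seed(seed, {
    w <- rnorm(n)
    zc <- if (sd(Vc) > 0) (Vc - mean(Vc)) / sd(Vc) else rep(0, n)
    corr_for <- function(a) {
      ratio <- ratio_mean + ratio_sd * (a * zc + sqrt(1 - a^2) * w)
      vn <- pmax(ratio, 0.02) * Vc
      if (sd(vn) == 0 || sd(Vc) == 0) return(0)
      cor(Vc, vn)
    }
    a_star <- if (n >= 3 && ratio_sd > 0) {
      lo <- corr_for(-1); hi <- corr_for(1)
      if (target_corr <= lo) -1
      else if (target_corr >= hi) 1
      else uniroot(function(a) corr_for(a) - target_corr, c(-1, 1))$root
    } else 0
    ratio <- ratio_mean + ratio_sd * (a_star * zc + sqrt(1 - a_star^2) * w)
    ratio <- pmin(pmax(ratio, 0.02), 0.8)
    n_missing <- round(missing_fraction * n)
    missing <- if (n_missing > 0) sample(labs, n_missing) else integer(0)
    list(ratio = ratio, missing = missing)
  })

  chan <- array(0, shape)
  truth_nuc <- array(0L, shape)
  info <- data.frame(label = labs, cell_voxels = Vc,
                     ratio = gen$ratio, present = !(labs %in% gen$missing),
                     cx = NA_real_, cy = NA_real_, cz = NA_real_,
                     r_n = NA_real_)
  for (q in seq_len(n)) {
    k <- labs[q]
    w <- which(L == k)
    co <- arrayInd(w, shape)
    pad <- as.integer(ceiling(4 * edge_sigma + 1))
    bx <- clip_box(apply(co, 2, min) - pad, apply(co, 2, max) + pad, shape)
    pdim <- bx$hi - bx$lo + 1L
    ix <- lapply(1:3, function(a) seq(bx$lo[a], bx$hi[a]))
    cell <- array(L[ix[[1]], ix[[2]], ix[[3]]] == k, pdim)
    din <- sqrt(edt_cpp(!cell, pdim, c(1, 1, 1))$dist2)
    deep <- arrayInd(which(din == max(din))[1], pdim)
    centre <- as.numeric(deep + bx$lo - 1L)
    info[q, c("cx", "cy", "cz")] <- centre
    if (!info$present[q]) next
    # the nucleus is the Vn cell voxels nearest the centre: a ball clipped to
    # the cell (nuclei deform against walls rather than cross them), so the
    # realised nucleus:cell volume ratio equals the drawn one exactly
    vn <- max(1L, min(round(info$ratio[q] * Vc[q]), Vc[q] - 1L))
    # keep a cytoplasm rim: the nucleus sits in the cell voxels at least 2
    # voxels clear of the wall (falling back to the whole cell if too small)
    core <- cell & din > 2
    if (sum(core) < vn) core <- cell
    cw <- which(core)
    cco <- arrayInd(cw, pdim)
    dd <- sqrt((cco[, 1] - deep[1])^2 + (cco[, 2] - deep[2])^2 +
               (cco[, 3] - deep[3])^2)
    ord <- order(dd)
    nucmask <- array(FALSE, pdim)
    nucmask[cw[ord[seq_len(vn)]]] <- TRUE
    info$r_n[q] <- dd[ord[vn]]
    blob <- A_nuc * gaussian_smooth(nucmask * 1.0, edge_sigma)
    chan[ix[[1]], ix[[2]], ix[[3]]] <- chan[ix[[1]], ix[[2]], ix[[3]]] + blob
    tn <- truth_nuc[ix[[1]], ix[[2]], ix[[3]]]
    tn[nucmask & tn == 0L] <- k
    truth_nuc[ix[[1]], ix[[2]], ix[[3]]] <- tn
  }
  chan <- with_seed(seed + 1L, add_noise_clip(chan, noise_sigma))

  tissue$nuclear <- chan
  tissue$truth_nuclei <- truth_nuc
  tissue$truth$nuclei <- info
  tissue$params$nuclei <- list(ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                               target_corr = target_corr,
                               missing_fraction = missing_fraction,
                               A_nuc = A_nuc, edge_sigma = edge_sigma,
                               noise_sigma = noise_sigma, seed = seed)
  tissue
}
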