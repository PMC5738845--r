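# Multi-LSF cellular segmentation: one level-set function per cell, evolved
# independently in a shared edge map, then rasterised to a label image.
#
# Each LSF is stored as a patch: the field on a padded bounding box around
# the cell, plus its offset in the full grid. Evolution of one cell depends
# only on its own field, the edge map and the parameters (independence
# contract), so patches are exact as long as the front stays inside the
# patch; the margin controls that headroom.

new_lsf <- function(phi, offset, shape, label) {
  structure(list(phi = phi, offset = as.integer(offset),
                 shape = as.integer(shape), label = as.integer(label)),
            class = "lsf")
}

# clip a box [lo, hi] (3x2) to the grid
clip_box <- function(lo, hi, shape) {
  list(lo = pmax(lo, 1L), hi = pmin(hi, shape))
}

patch_index <- function(p) {
  lapply(1:3, function(a) seq(p$offset[a], p$offset[a] + dim(p$phi)[a] - 1L))
}

# full-grid expansion of a patch (exterior filled with a large positive value)
lsf_full <- function(p, fill = NULL) {
  if (is.null(fill)) fill <- max(p$phi) + 1
  out <- array(fill, p$shape)
  ix <- patch_index(p)
  out[ix[[1]], ix[[2]], ix[[3]]] <- p$phi
  out
}

seeds_to_list <- function(seeds, shape) {
  if (is.data.frame(seeds)) {
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(seeds)))
      stop("seed data frame needs columns label, x, y, z (1-based voxel indices)")
    labs <- sort(unique(seeds$label))
    split(seeds[c("x", "y", "z")], factor(seeds$label, levels = labs))
  } else {
    assert_grid3d(seeds, "seeds")
    labs <- sort(setdiff(unique(as.integer(seeds)), 0L))
    lapply(stats::setNames(labs, labs), function(l) {
      w <- which(seeds == l)
      arr <- arrayInd(w, dim(seeds))
      data.frame(x = arr[, 1], y = arr[, 2], z = arr[, 3])
    })
  }
}

#' Initialise one level-set function per seed
#'
#' Each seed's voxel set, dilated by a ball of radius `r0`, becomes the
#' initial interior of its LSF (signed distance, negative inside). The list
#' is ordered by ascending label. Fields are stored on padded bounding boxes
#' (see `margin`).
#'
#' @param seeds an integer 3D label array (0 = background) or a data frame
#'   with columns `label, x, y, z` (1-based voxel indices).
#' @param shape full grid dimensions (length 3); defaults to `dim(seeds)`
#'   when `seeds` is an array.
#' @param r0 dilation radius in voxels (>= 1).
#' @param margin patch padding in voxels beyond the dilated seed; must be at
#'   least the distance the front is expected to travel (about one cell
#'   radius for inflation pipelines).
#' @param spacing voxel spacing per axis.
#' @return list of `lsf` objects.
#' @export
init_from_seeds <- function(seeds, shape = NULL, r0 = 3, margin = 16,
                            spacing = c(1, 1, 1)) {
  if (is.null(shape)) {
    if (!is.array(seeds)) stop("'shape' required when seeds are a data frame")
    shape <- dim(seeds)
  }
  shape <- as.integer(shape)
  if (r0 < 1) stop("'r0' must be >= 1 voxel")
  spacing <- check_spacing(spacing)
  sl <- seeds_to_list(seeds, shape)
  lapply(names(sl), function(lab) {
    v <- sl[[lab]]
    if (nrow(v) == 0L) stop("empty seed voxel set for label ", lab)
    co <- as.matrix(v)
    if (any(co < 1) || any(t(co) > shape))
      stop("out-of-bounds seed voxel for label ", lab)
    pad <- ceiling(r0 + margin)
    bx <- clip_box(apply(co, 2, min) - pad, apply(co, 2, max) + pad, shape)
    pdim <- bx$hi - bx$lo + 1L
    sites <- array(FALSE, pdim)
    sites[cbind(co[, 1] - bx$lo[1] + 1L, co[, 2] - bx$lo[2] + 1L,
                co[, 3] - bx$lo[3] + 1L)] <- TRUE
    d <- sqrt(edt_cpp(sites, pdim, spacing)$dist2)
    new_lsf(d - r0, bx$lo, shape, as.integer(lab))
  })
}

#' Initialise one level-set function per labelled cell
#'
#' For every label `k >= 1`, the initial interior is the erosion of
#' `{L == k}` by a discrete Euclidean ball of radius `d`. A label whose
#' erosion would be empty keeps its single deepest voxel (maximum of the
#' internal distance transform, lowest linear index on ties), so no cell is
#' dropped from the initialisation.
#'
#' @param L integer 3D label array (0 = background), not all background.
#' @param d erosion radius in voxels (>= 0).
#' @param margin patch padding beyond the cell's bounding box.
#' @param spacing voxel spacing per axis.
#' @return list of `lsf` objects ordered by ascending label.
#' @export
init_from_labels <- function(L, d = 1, margin = 6, spacing = c(1, 1, 1)) {
  assert_grid3d(L, "L")
  if (d < 0) stop("'d' must be >= 0")
  spacing <- check_spacing(spacing)
  labs <- sort(setdiff(unique(as.integer(L)), 0L))
  if (length(labs) == 0L) stop("label image is all background")
  shape <- dim(L)
  lapply(labs, function(k) {
    w <- which(L == k)
    co <- arrayInd(w, shape)
    bx <- clip_box(apply(co, 2, min) - as.integer(ceiling(margin)),
                   apply(co, 2, max) + as.integer(ceiling(margin)), shape)
    pdim <- bx$hi - bx$lo + 1L
    ix <- lapply(1:3, function(a) seq(bx$lo[a], bx$hi[a]))
    cell <- array(L[ix[[1]], ix[[2]], ix[[3]]] == k, pdim)
    # internal distance: distance to the complement of the cell (patch border
    # padded as complement is conservative and correct here since the patch
    # extends beyond the cell)
    din <- sqrt(edt_cpp(!cell, pdim, spacing)$dist2)
    eroded <- din > d
    if (!any(eroded)) {
      deepest <- which(din == max(din))[1]
      eroded[deepest] <- TRUE
    }
    new_lsf(mask_signed_distance(array(eroded, pdim), spacing), bx$lo, shape, k)
  })
}

#' Evolve a list of level-set functions independently
#'
#' Runs [evolve()] on every LSF against the shared edge map (cropped to each
#' patch). Cellular pipelines use an outward balloon: the accelerating term
#' inflates each seed and pushes the cell contour out to the cell wall, where
#' the edge map halts it. The result for cell i depends only on its own
#' initial field, the edge map and the parameters.
#'
#' @param phis list of `lsf` objects (e.g. from [init_from_seeds()]).
#' @param g edge map over the full grid.
#' @param params an [evolve_params()]; cellular default `alpha = 1`,
#'   `beta = 0`, direction outward.
#' @param spacing voxel spacing per axis.
#' @return list of evolved `lsf` objects (order preserved), each with a
#'   `diagnostics` element attached.
#' @export
evolve_multi <- function(phis, g,
                         params = evolve_params(alpha = 1, beta = 0,
                                                direction = "outward"),
                         spacing = c(1, 1, 1)) {
  if (length(phis) == 0L) return(list())
  assert_grid3d(g, "g")
  spacing <- check_spacing(spacing)
  lapply(phis, function(p) {
    if (!inherits(p, "lsf")) stop("'phis' must be a list of lsf objects")
    if (!identical(as.integer(p$shape), as.integer(dim(g))))
      stop("edge map shape does not match LSF grid shape")
    ix <- patch_index(p)
    gp <- array(g[ix[[1]], ix[[2]], ix[[3]]], dim(p$phi))
    res <- evolve(p$phi, gp, params, spacing)
    out <- new_lsf(res$phi, p$offset, p$shape, p$label)
    out$diagnostics <- res$diagnostics
    out
  })
}

#' Rasterise per-cell level-set functions to a label image
#'
#' A voxel receives label i where \eqn{\phi_i < 0}; where several fields are
#' negative the most negative wins, exact ties go to the lowest label; voxels
#' with no negative field stay background (0).
#'
#' @param phis non-empty list of `lsf` objects on a common grid.
#' @param shape full grid dimensions; defaults to the patches' stored shape.
#' @return integer 3D label array.
#' @export
labels_from_lsfs <- function(phis, shape = NULL) {
  if (length(phis) == 0L) stop("empty LSF list")
  if (is.null(shape)) shape <- phis[[1]]$shape
  shape <- as.integer(shape)
  for (p in phis)
    if (!identical(as.integer(p$shape), shape))
      stop("inconsistent LSF grid shapes")
  best <- array(Inf, shape)
  lab <- array(0L, shape)
  ord <- order(vapply(phis, function(p) p$label, integer(1)))
  for (p in phis[ord]) {
    ix <- patch_index(p)
    cur <- best[ix[[1]], ix[[2]], ix[[3]]]
    upd <- p$phi < 0 & p$phi < cur   # strict: earlier (lower) label keeps ties
    if (any(upd)) {
      cur[upd] <- p$phi[upd]
      best[ix[[1]], ix[[2]], ix[[3]]] <- cur
      sub <- lab[ix[[1]], ix[[2]], ix[[3]]]
      sub[upd] <- p$label
      lab[ix[[1]], ix[[2]], ix[[3]]] <- sub
    }
  }
  lab
}

#' Assign unlabelled voxels to the nearest labelled object
#'
#' Cellular level-set contours stop short of the wall mid-plane (the gradient
#' indicator has a valley on each side of a wall), leaving inter-cell gaps.
#' This completes the segmentation by giving every unassigned voxel of the
#' domain the label of the nearest (Euclidean, physical spacing) labelled
#' voxel; ties go to the lowest label. Already-assigned voxels are unchanged;
#' the operation is idempotent.
#'
#' @param L integer 3D label array.
#' @param domain_mask 3D logical array of voxels that must end up labelled.
#' @param spacing voxel spacing per axis.
#' @return integer 3D label array.
#' @export
fill_unassigned_nearest <- function(L, domain_mask, spacing = c(1, 1, 1)) {
  assert_grid3d(L, "L")
  assert_same_shape(L, domain_mask, "labels and domain mask")
  spacing <- check_spacing(spacing)
  domain <- domain_mask != 0
  labs <- sort(setdiff(unique(as.integer(L[domain])), 0L))
  if (length(labs) == 0L) stop("no labelled voxels inside the domain")
  todo <- domain & L == 0L
  if (!any(todo)) return(L)
  best_d2 <- array(Inf, dim(L))
  best_lab <- array(0L, dim(L))
  for (k in labs) {
    d2 <- edt_cpp(L == k, dim(L), spacing)$dist2
    upd <- d2 < best_d2   # strict: lowest label keeps exact ties
    best_d2[upd] <- d2[upd]
    best_lab[upd] <- k
  }
  out <- L
  out[todo] <- best_lab[todo]
  out
}

#' Cellular segmentation pipeline
#'
#' Convenience wrapper: build the edge map, initialise one LSF per cell (from
#' seeds or from an existing segmentation eroded by `d`), evolve all LSFs
#' with an outward balloon, rasterise, and optionally assign the remaining
#' wall/gap voxels of `domain_mask` to the nearest cell.
#'
#' @param I 3D numeric array (membrane channel).
#' @param seeds seed labels (array or data frame), or `NULL` when
#'   `init_labels` is given.
#' @param init_labels existing label image to initialise from (eroded by `d`).
#' @param d erosion radius for `init_labels`.
#' @param r0 dilation radius for seed initialisation.
#' @param margin patch padding (see [init_from_seeds()]).
#' @param spec an [indicator_spec()]; default the Hessian wall indicator
#'   with image-scaled `gamma`.
#' @param params an [evolve_params()].
#' @param domain_mask if given, gap voxels inside it are filled by
#'   [fill_unassigned_nearest()].
#' @param spacing voxel spacing per axis.
#' @return list with `labels` (filled, if requested), `labels_prefill`, and
#'   `lsfs` (the evolved fields).
#' @export
segment_cells <- function(I, seeds = NULL, init_labels = NULL, d = 1, r0 = 3,
                          margin = 16, spec = indicator_spec("h", "auto"),
                          params = evolve_params(alpha = 1, beta = 0,
                                                 direction = "outward"),
                          domain_mask = NULL, spacing = c(1, 1, 1)) {
  assert_grid3d(I, "I")
  spacing <- check_spacing(spacing)
  if (is.null(seeds) && is.null(init_labels))
    stop("provide 'seeds' or 'init_labels'")
  phis <- if (!is.null(init_labels))
    init_from_labels(init_labels, d = d, margin = margin, spacing = spacing)
  else
    init_from_seeds(seeds, dim(I), r0 = r0, margin = margin, spacing = spacing)
  g <- edge_map(I, spec, spacing)
  ev <- evolve_multi(phis, g, params, spacing)
  pre <- labels_from_lsfs(ev, dim(I))
  out <- pre
  if (!is.null(domain_mask)) out <- fill_unassigned_nearest(pre, domain_mask, spacing)
  list(labels = out, labels_prefill = pre, lsfs = ev)
}
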