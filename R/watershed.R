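#' Most frequent intensity inside a mask
#'
#' Histogram mode of the interior voxels, used as a coarse estimate of the
#' typical intensity inside the cells. Integer-valued images use exact value
#' counts; floating-point images use 256 equal-width bins over the interior
#' range and report the centre of the modal bin. Ties go to the lowest value.
#'
#' @param I 3D numeric array.
#' @param interior_mask 3D logical (or 0/1) array, non-empty.
#' @return a single number.
#' @export
interior_mode <- function(I, interior_mask) {
  assert_grid3d(I, "I")
  assert_same_shape(I, interior_mask, "image and mask")
  v <- I[interior_mask != 0]
  if (length(v) == 0L) stop("empty interior mask")
  if (all(v == round(v))) {
    tab <- table(v)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), 256L),
                     nbins = 256L)
  k <- which.max(counts)
  (breaks[k] + breaks[k + 1L]) / 2
}

#' Reinforce the tissue surface for watershed segmentation
#'
#' Builds the modified image on which seeded watershed no longer trims or
#' loses outer-layer cells: the detected outer surface is set to white (the
#' image dtype's maximum), and the exterior background is set to the most
#' frequent intensity inside the tissue, so that outer cells are closed by a
#' bright cap and the background basin no longer swallows them.
#'
#' @param I 3D numeric array (raw image).
#' @param surface a `surface_result` from [detect_surface()] (same shape).
#' @param shell_thickness thickness of the white cap in `phi` units;
#'   default 2 (one voxel each side of the zero crossing).
#' @param white the "white" value; `NULL` picks the dtype maximum inferred
#'   from the data: 255 for integer-valued images within 8 bits, 65535 within
#'   16 bits, otherwise the image maximum.
#' @return modified 3D numeric array.
#' @export
enhance_image <- function(I, surface, shell_thickness = 2, white = NULL) {
  assert_grid3d(I, "I")
  if (!inherits(surface, "surface_result"))
    stop("'surface' must be a surface_result")
  assert_same_shape(I, surface$phi, "image and surface phi")
  if (is.null(white)) {
    mx <- max(I)
    white <- if (all(I == round(I)) && mx <= 255) 255
             else if (all(I == round(I)) && mx <= 65535) 65535
             else mx
  }
  mode_val <- interior_mode(I, surface$interior_mask)
  # the white cap must be watertight or the background basin floods back
  # into the outer cells: take the |phi| shell plus the zero-crossing faces
  # (voxels with a 6-neighbour of opposite sign), which is closed by
  # construction
  phi <- surface$phi
  inside <- phi < 0
  crossing <- array(FALSE, dim(phi))
  for (axis in 1:3) for (dd in c(-1L, 1L))
    crossing <- crossing | (inside != shift_clamp(inside, axis, dd))
  shell <- surface_shell(phi, shell_thickness) | crossing
  out <- I * 1.0
  out[phi > 0 & !shell] <- mode_val
  out[shell] <- white
  out
}

#' Watershed seeds from h-minima
#'
#' Suppresses all regional minima shallower than `h` (greyscale reconstruction
#' by erosion of `I + h` over `I`), then labels the connected components of
#' the remaining regional minima. Labelling is deterministic (components
#' ordered by their smallest linear index).
#'
#' @param I 3D numeric array.
#' @param h minimum basin depth (> 0); seeds are minima deeper than `h`.
#' @param mask optional 3D logical array restricting the search.
#' @return integer 3D array of seed labels (0 = no seed).
#' @export
detect_seeds_hminima <- function(I, h, mask = NULL) {
  assert_grid3d(I, "I")
  if (!is.numeric(h) || h <= 0) stop("'h' must be > 0")
  if (is.null(mask)) {
    mask <- array(TRUE, dim(I))
  } else {
    assert_same_shape(I, mask, "image and mask")
    mask <- mask != 0
  }
  # reconstruction by erosion of (I + h) above I, via its dilation dual
  filled <- -reconstruct_dilation_cpp(-(I + h), -(I * 1.0), dim(I))
  regional_minima_cpp(filled, dim(I), mask)
}

#' Seeded watershed segmentation
#'
#' Priority-flood watershed on raw intensity: flooding starts at the seeds and
#' proceeds in order of increasing intensity, so region boundaries settle on
#' the bright crests (cell walls) separating low-intensity basins. Every voxel
#' (within the mask, if given) receives the label of a seed. Deterministic:
#' ties in intensity are resolved first-in-first-out.
#'
#' @param I 3D numeric array.
#' @param seeds integer 3D array of seed labels (0 = unseeded), e.g. from
#'   [detect_seeds_hminima()].
#' @param mask optional 3D logical array restricting the flooding domain.
#' @return integer 3D array of labels.
#' @export
watershed_segment <- function(I, seeds, mask = NULL) {
  assert_grid3d(I, "I")
  assert_same_shape(I, seeds, "image and seeds")
  if (!any(seeds > 0)) stop("empty seed set")
  if (is.null(mask)) mask <- logical(0) else {
    assert_same_shape(I, mask, "image and mask")
    mask <- as.logical(mask)
  }
  watershed_cpp(I * 1.0, as.integer(seeds), dim(I), mask)
}

# overlap (contingency) matrix between two labellings (arrays or vectors),
# rows = labels of a, columns = labels of b, in sorted label order incl. 0
overlap_matrix <- function(a, b) {
  la <- sort(unique(as.integer(a)))
  lb <- sort(unique(as.integer(b)))
  ia <- match(as.integer(a), la)
  ib <- match(as.integer(b), lb)
  m <- matrix(0, length(la), length(lb), dimnames = list(la, lb))
  tab <- table(factor(ia, levels = seq_along(la)), factor(ib, levels = seq_along(lb)))
  m[] <- as.numeric(tab)
  m
}

# optimal injective matching maximising total overlap; returns for each row
# label the matched column label (NA if unmatched) and the total overlap
match_labels <- function(overlap) {
  res <- best_assignment_cpp(overlap)
  nr <- nrow(overlap); nc <- ncol(overlap)
  row_match <- rep(NA_integer_, nr)
  if (!res$transposed) {
    for (r in seq_len(nr)) if (res$row_match[r] > 0) row_match[r] <- res$row_match[r]
  } else {
    # res$row_match maps columns to rows
    for (cc in seq_len(nc)) {
      r <- res$row_match[cc]
      if (r > 0) row_match[r] <- cc
    }
  }
  list(total = res$total, row_match = row_match)
}

#' Compare a segmentation with ground truth
#'
#' Quantifies segmentation quality against a reference labelling:
#' * `lost_cells`: truth labels with no mutual-majority partner (a predicted
#'   label covering more than half the truth cell whose own majority truth
#'   label is that cell) — merged or missing cells count as lost;
#' * `agreement`: voxel-wise agreement under the optimal (maximum total
#'   overlap) injective matching of labels, background included;
#' * `volume_rel_error`: per-truth-cell relative volume error of the matched
#'   predicted label.
#'
#' If `surface_mask` is given, the same metrics restricted to the outer (L1)
#' layer — the truth cells touching the surface — are reported under `l1`.
#'
#' @param L integer 3D array, predicted labels.
#' @param truth integer 3D array, reference labels (same shape).
#' @param surface_mask optional 3D logical array marking the tissue surface.
#' @return an object of class `seg_metrics`.
#' @export
compare_segmentations <- function(L, truth, surface_mask = NULL) {
  assert_grid3d(L, "L")
  assert_same_shape(L, truth, "labels and truth")
  ov <- overlap_matrix(truth, L)
  truth_labels <- as.integer(rownames(ov))
  pred_labels <- as.integer(colnames(ov))

  core <- function(rows) {
    # rows: indices into truth_labels of the (non-zero) truth cells considered
    lost <- integer(0)
    vol_err <- numeric(0)
    for (r in rows) {
      t_size <- sum(ov[r, ])
      p <- which.max(ov[r, ])
      ok <- ov[r, p] > t_size / 2
      if (ok) {
        # mutual majority: the partner's own majority truth label must be r
        ok <- which.max(ov[, p]) == r
      }
      if (!ok || pred_labels[p] == 0L) {
        lost <- c(lost, truth_labels[r])
      } else {
        p_size <- sum(ov[, p])
        vol_err <- c(vol_err, (p_size - t_size) / t_size)
        names(vol_err)[length(vol_err)] <- truth_labels[r]
      }
    }
    m <- match_labels(ov)
    matched <- sum(vapply(seq_along(truth_labels), function(r) {
      if (is.na(m$row_match[r])) 0 else ov[r, m$row_match[r]]
    }, numeric(1)))
    list(lost_cells = length(lost), lost_labels = lost,
         agreement = matched / sum(ov), volume_rel_error = vol_err)
  }

  rows_all <- which(truth_labels != 0L)
  out <- core(rows_all)

  if (!is.null(surface_mask)) {
    assert_same_shape(L, surface_mask, "labels and surface mask")
    l1_labels <- setdiff(unique(as.integer(truth[surface_mask != 0])), 0L)
    rows_l1 <- which(truth_labels %in% l1_labels)
    l1 <- core(rows_l1)
    # agreement restricted to the voxels of L1 truth cells
    sel <- truth %in% l1_labels
    ov1 <- overlap_matrix(truth[sel], L[sel])
    m1 <- match_labels(ov1)
    l1$agreement <- m1$total / sum(ov1)
    out$l1 <- l1
  }
  structure(out, class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("segmentation metrics: %d lost cells, agreement %.3f\n",
              x$lost_cells, x$agreement))
  if (length(x$volume_rel_error))
    cat(sprintf("  mean |volume error|: %.3f\n", mean(abs(x$volume_rel_error))))
  if (!is.null(x$l1))
    cat(sprintf("  L1: %d lost, agreement %.3f, mean |volume error| %.3f\n",
                x$l1$lost_cells, x$l1$agreement,
                if (length(x$l1$volume_rel_error)) mean(abs(x$l1$volume_rel_error)) else NA))
  invisible(x)
}
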