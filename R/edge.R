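#' Indicator-function specification
#'
#' Chooses one of the three wall/object indicator functions `f` and the scale
#' of the Hill edge function built from it:
#' * `"g"` — gradient magnitude of the smoothed image, \eqn{f_1 = |\nabla \hat I|}:
#'   the classical edge indicator; shows a double valley across a bright wall.
#' * `"i"` — the smoothed intensity itself, \eqn{f_2 = \hat I}: a single
#'   valley per wall.
#' * `"h"` — the Hessian wall indicator \eqn{f_3 = \min(\lambda_3, 0)}, with
#'   \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3} the eigenvalues of the local
#'   Hessian of the smoothed image: a bright thin wall has one strongly
#'   negative eigenvalue across it, so this marks dim outer periclinal walls
#'   as sharply as bright anticlinal walls, with a single valley per wall.
#'
#' Default `gamma` values follow common choices for 8-bit-like intensity
#' ranges: 8 for `"g"`, 60 for `"i"`, 0.8 for `"h"`. `gamma` should be scaled
#' to the span of `f` values in the image at hand.
#'
#' @param kind one of `"g"`, `"i"`, `"h"`.
#' @param gamma Hill scale (> 0); `NULL` picks the per-kind default, and
#'   `"auto"` scales it to the span of indicator values in the image at hand
#'   (resolved when the edge map is built): a tenth of the 99.5th percentile
#'   of `|f|` for kinds `"g"` and `"h"`, a quarter of it for `"i"`.
#' @param s Gaussian smoothing standard deviation in voxel units (>= 0).
#' @return an object of class `indicator_spec`.
#' @export
indicator_spec <- function(kind = c("g", "i", "h"), gamma = NULL, s = 1) {
  kind <- match.arg(kind)
  if (is.null(gamma)) gamma <- c(g = 8, i = 60, h = 0.8)[[kind]]
  if (identical(gamma, "auto")) {
    return(structure(list(kind = kind, gamma = "auto", s = s),
                     class = "indicator_spec"))
  }
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  if (!is.numeric(s) || s < 0) stop("'s' must be >= 0")
  structure(list(kind = kind, gamma = gamma, s = s), class = "indicator_spec")
}

auto_gamma <- function(f, kind) {
  scale <- as.numeric(quantile(abs(f), 0.995))
  gam <- if (kind == "i") 0.25 * scale else 0.1 * scale
  if (!is.finite(gam) || gam <= 0) gam <- c(g = 8, i = 60, h = 0.8)[[kind]]
  gam
}

#' Gaussian smoothing of a 3D image
#'
#' Separable Gaussian filtering with standard deviation `s` (voxel units) per
#' axis; edge values are replicated. `s = 0` returns the input unchanged.
#' Intensities are promoted to double precision; no rescaling is applied.
#'
#' @param I 3D numeric array.
#' @param s standard deviation in voxel units (>= 0).
#' @return smoothed 3D numeric array.
#' @export
gaussian_smooth <- function(I, s = 1) {
  assert_grid3d(I, "I")
  if (!is.numeric(s) || length(s) != 1L || s < 0) stop("'s' must be >= 0")
  I <- I * 1.0
  if (s == 0) return(I)
  r <- max(1L, ceiling(4 * s))
  w <- exp(-(seq(-r, r))^2 / (2 * s^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    out <- array(0, dim(I))
    for (t in seq(-r, r)) out <- out + w[t + r + 1L] * shift_clamp(I, axis, t)
    I <- out
  }
  I
}

#' Indicator function of a smoothed image
#'
#' Computes the raw indicator `f` (before the Hill transform) from an already
#' smoothed image. For `kind = "g"` the central-difference gradient magnitude
#' (>= 0); for `kind = "i"` the image itself; for `kind = "h"` the most
#' negative local Hessian eigenvalue clipped at zero,
#' \eqn{f_3 = \min(\lambda_3, 0)} (<= 0).
#'
#' @param I_hat smoothed 3D numeric array.
#' @param kind `"g"`, `"i"` or `"h"`.
#' @param spacing voxel spacing per axis.
#' @return 3D numeric array `f`.
#' @export
indicator <- function(I_hat, kind = c("g", "i", "h"), spacing = c(1, 1, 1)) {
  assert_grid3d(I_hat, "I_hat")
  kind <- match.arg(kind)
  spacing <- check_spacing(spacing)
  if (kind == "i") return(I_hat * 1.0)
  if (kind == "g") {
    gx <- central_diff(I_hat, 1L, spacing[1])
    gy <- central_diff(I_hat, 2L, spacing[2])
    gz <- central_diff(I_hat, 3L, spacing[3])
    return(sqrt(gx^2 + gy^2 + gz^2))
  }
  ev <- hessian_eigen(I_hat, spacing)
  array(pmin(ev$l3, 0), dim(I_hat))
}

#' Eigenvalues of the local Hessian of a 3D image
#'
#' Second-order central finite differences (per-axis spacing respected)
#' followed by a per-voxel symmetric 3x3 eigendecomposition; eigenvalues are
#' sorted descending (`l1 >= l2 >= l3`).
#'
#' @param I_hat smoothed 3D numeric array.
#' @param spacing voxel spacing per axis.
#' @return list of three 3D arrays `l1`, `l2`, `l3`.
#' @export
hessian_eigen <- function(I_hat, spacing = c(1, 1, 1)) {
  assert_grid3d(I_hat, "I_hat")
  spacing <- check_spacing(spacing)
  I_hat <- I_hat * 1.0
  hxx <- second_diff(I_hat, 1L, spacing[1])
  hyy <- second_diff(I_hat, 2L, spacing[2])
  hzz <- second_diff(I_hat, 3L, spacing[3])
  hxy <- central_diff(central_diff(I_hat, 1L, spacing[1]), 2L, spacing[2])
  hxz <- central_diff(central_diff(I_hat, 1L, spacing[1]), 3L, spacing[3])
  hyz <- central_diff(central_diff(I_hat, 2L, spacing[2]), 3L, spacing[3])
  hessian_eigenvalues_cpp(hxx, hyy, hzz, hxy, hxz, hyz)
}

#' Hill edge function
#'
#' Maps an indicator `f` to the edge map
#' \deqn{g(x) = \frac{1}{1 + |f(x)/\gamma|^2},}
#' which is 1 where `f` is 0 and decreases towards 0 where `|f|` is large
#' (on the target walls/objects); `g(gamma) = 1/2`.
#'
#' @param f 3D numeric array.
#' @param gamma Hill scale (> 0).
#' @return 3D numeric array with values in (0, 1].
#' @export
hill_edge <- function(f, gamma) {
  assert_grid3d(f, "f")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be > 0")
  1 / (1 + (f / gamma)^2)
}

#' Edge map of an image
#'
#' Convenience pipeline: Gaussian smoothing, indicator function, Hill edge
#' function.
#'
#' @param I 3D numeric array (raw intensities).
#' @param spec an [indicator_spec()].
#' @param spacing voxel spacing per axis.
#' @return 3D numeric array `g` in (0, 1].
#' @export
edge_map <- function(I, spec = indicator_spec(), spacing = c(1, 1, 1)) {
  if (!inherits(spec, "indicator_spec"))
    stop("'spec' must be created by indicator_spec()")
  I_hat <- gaussian_smooth(I, spec$s)
  f <- indicator(I_hat, spec$kind, spacing)
  gam <- if (identical(spec$gamma, "auto")) auto_gamma(f, spec$kind) else spec$gamma
  hill_edge(f, gam)
}
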