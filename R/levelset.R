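#' Evolution parameters for a level-set run
#'
#' Bundles the weights of the four energy terms and the numerical controls of
#' the explicit gradient-flow scheme. The energy is
#' \deqn{E = \lambda L_g + \beta L_1 + \alpha A_g + \mu R_p,}
#' where \eqn{L_g} is the geodesic (image) term that attracts the contour to
#' valleys of the edge map, \eqn{L_1} is the contour-area (smoothing) term
#' whose flow is motion by mean curvature, \eqn{A_g} is the accelerating
#' (balloon) term producing normal motion at speed proportional to the edge
#' map, and \eqn{R_p} is a double-well distance regulariser that keeps the
#' level-set function close to a signed distance function so that no
#' re-initialisation is needed.
#'
#' `alpha` and `beta` are interpreted relative to `lam` and should be kept
#' small compared to it; both default to 0 so that the contour stays as
#' faithful as possible to the image.
#'
#' @param alpha weight of the accelerating (balloon) term; default 0.
#' @param beta weight (>= 0) of the smoothing (mean curvature) term; default 0.
#' @param lam weight (> 0) of the image term; default 5.
#' @param mu weight (> 0) of the distance regulariser; default 0.02. The
#'   explicit scheme requires `mu * dt < 0.25`.
#' @param dt explicit time step (> 0); default 0.2, which also respects the
#'   parabolic stability limit of the curvature terms at the default `lam`.
#' @param max_iter maximum number of iterations; default 1000.
#' @param conv_tol convergence tolerance in (0,1) on the mean fraction of
#'   voxels whose sign changed per iteration; default 2e-4.
#' @param conv_window number of trailing iterations averaged by the stop
#'   criterion; default 10.
#' @param direction `"inward"` or `"outward"`: the sense of the balloon
#'   motion (shrinking an enclosing contour onto a surface, or inflating a
#'   seed towards the cell wall).
#' @param eps half-width (voxel units) of the smoothed Heaviside/Dirac pair
#'   used in the energy diagnostic; default 1.5.
#' @return an object of class `evolution_params`.
#' @export
evolve_params <- function(alpha = 0, beta = 0, lam = 5, mu = 0.02, dt = 0.2,
                          max_iter = 1000L, conv_tol = 2e-4, conv_window = 10L,
                          direction = c("inward", "outward"), eps = 1.5) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(beta) || beta < 0) stop("'beta' must be >= 0")
  if (!is.numeric(lam) || lam <= 0) stop("'lam' must be > 0")
  if (!is.numeric(mu) || mu <= 0) stop("'mu' must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (mu * dt >= 0.25)
    stop("stability bound violated: mu * dt must be < 0.25")
  if (max_iter < 0) stop("'max_iter' must be >= 0")
  if (conv_tol <= 0 || conv_tol >= 1) stop("'conv_tol' must be in (0,1)")
  if (conv_window < 1) stop("'conv_window' must be >= 1")
  structure(list(alpha = alpha, beta = beta, lam = lam, mu = mu, dt = dt,
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 conv_window = as.integer(conv_window), direction = direction,
                 eps = eps),
            class = "evolution_params")
}

dir_sign <- function(params) if (params$direction == "outward") 1L else -1L

check_evolve_inputs <- function(phi, g, params) {
  assert_grid3d(phi, "phi")
  assert_grid3d(g, "g")
  assert_same_shape(phi, g, "phi and edge map")
  if (!inherits(params, "evolution_params"))
    stop("'params' must be created by evolve_params()")
  invisible(NULL)
}

#' Advance a level-set function by one explicit time step
#'
#' One step of the gradient flow of the level-set energy: the image term
#' attracts the zero level to valleys of the edge map `g`, the smoothing term
#' moves it by mean curvature, the balloon term moves it along its normal at
#' speed `alpha * g` (signed by `params$direction`), and the regulariser
#' drives \eqn{|\nabla\phi|} towards 1. The flow is applied to all level sets
#' (the \eqn{|\nabla\phi|} extension), so analytic front speeds hold: a planar
#' front in a uniform edge map advances by `alpha * g * dt` per step. The
#' balloon and edge-advection terms are discretised upwind, the curvature and
#' regulariser terms with central differences.
#'
#' @param phi 3D numeric array, the level-set function (negative inside).
#' @param g 3D numeric array, edge map in (0, 1], same shape as `phi`.
#' @param params an [evolve_params()] object.
#' @param spacing voxel spacing per axis (length 3).
#' @return the advanced `phi` (3D numeric array).
#' @export
evolve_step <- function(phi, g, params = evolve_params(), spacing = c(1, 1, 1)) {
  check_evolve_inputs(phi, g, params)
  spacing <- check_spacing(spacing)
  res <- ls_evolve_cpp(phi, g, dim(phi), spacing, params$lam, params$alpha,
                       dir_sign(params), params$beta, params$mu, params$dt,
                       params$eps, 1L, 0, .Machine$integer.max, FALSE)
  if (any(!is.finite(res$phi))) stop("evolve_step produced non-finite values")
  res$phi
}

#' Evolve a level-set function until convergence
#'
#' Iterates the explicit scheme of [evolve_step()] until the contour
#' decelerates (the mean fraction of sign-changing voxels over the last
#' `conv_window` iterations drops below `conv_tol`) or `max_iter` is reached.
#' Non-convergence is reported in the diagnostics, not raised as an error.
#'
#' @inheritParams evolve_step
#' @param phi0 initial level-set function.
#' @param track_energy if `TRUE`, record the (smoothed-Heaviside) approximate
#'   energy at every iteration.
#' @return a list with elements `phi` (the final field) and `diagnostics`, an
#'   `evolution_diagnostics` object with `iterations_run`,
#'   `sign_change_fraction` and `energy` series, and a `converged` flag.
#' @export
evolve <- function(phi0, g, params = evolve_params(), spacing = c(1, 1, 1),
                   track_energy = FALSE) {
  check_evolve_inputs(phi0, g, params)
  spacing <- check_spacing(spacing)
  res <- ls_evolve_cpp(phi0, g, dim(phi0), spacing, params$lam, params$alpha,
                       dir_sign(params), params$beta, params$mu, params$dt,
                       params$eps, params$max_iter, params$conv_tol,
                       params$conv_window, track_energy)
  diag <- structure(list(iterations_run = res$iterations_run,
                         sign_change_fraction = res$sign_change_fraction,
                         energy = res$energy,
                         converged = res$converged),
                    class = "evolution_diagnostics")
  list(phi = res$phi, diagnostics = diag)
}

#' Contour-deceleration stop criterion
#'
#' The evolution has converged when the fraction of voxels whose level-set
#' sign changed, averaged over the last `conv_window` iterations, is below
#' `conv_tol`. With fewer than `conv_window` recorded iterations the answer
#' is `FALSE`.
#'
#' @param diag an `evolution_diagnostics` object (or a numeric vector of
#'   per-iteration sign-change fractions).
#' @param conv_tol threshold on the trailing mean.
#' @param conv_window number of trailing iterations to average.
#' @return logical.
#' @export
has_converged <- function(diag, conv_tol = 2e-4, conv_window = 10L) {
  frac <- if (inherits(diag, "evolution_diagnostics")) diag$sign_change_fraction else diag
  n <- length(frac)
  if (n < conv_window) return(FALSE)
  mean(frac[(n - conv_window + 1L):n]) < conv_tol
}

#' @export
print.evolution_diagnostics <- function(x, ...) {
  cat(sprintf("level-set evolution: %d iterations, %s\n", x$iterations_run,
              if (x$converged) "converged" else "not converged"))
  if (x$iterations_run > 0)
    cat(sprintf("  final sign-change fraction: %.3g\n",
                x$sign_change_fraction[x$iterations_run]))
  invisible(x)
}
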