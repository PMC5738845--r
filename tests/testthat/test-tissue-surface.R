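test_that("z-linear threshold initialisation is exact on constant images", {
  sh <- c(10, 10, 11)
  I <- array(100, sh)
  phi <- init_z_threshold(I, 50, 50)
  expect_true(all(phi < 0))  # whole volume interior

  # thresholds 50 -> 150: t(z) < 100 exactly for the first half of the stack
  phi2 <- init_z_threshold(I, 50, 150)
  tz <- 50 + (150 - 50) * (seq_len(sh[3]) - 1) / (sh[3] - 1)
  inside <- apply(phi2 < 0, 3, all)
  outside <- apply(phi2 >= 0, 3, all)
  expect_identical(inside, tz < 100)
  expect_identical(outside, tz >= 100)
})

test_that("raising both thresholds never grows the initial interior", {
  set.seed(5)
  I <- gaussian_smooth(array(runif(32^3, 0, 200), c(32, 32, 32)), 2)
  lo <- init_z_threshold(I, 60, 90, clean = FALSE) < 0
  hi <- init_z_threshold(I, 80, 110, clean = FALSE) < 0
  expect_true(all(lo | !hi))  # hi interior is a subset of lo interior
})

test_that("threshold initialisation strictly encloses an attenuated shell", {
  tis <- make_shell_sphere(shape = c(64, 64, 64), R = 16, atten_k = 0.4)
  # thresholds at half the local shell brightness at top and bottom
  phi0 <- init_z_threshold(tis$image, 100, 60)
  expect_true(all(phi0[tis$truth_surface_mask] < 0))
})

test_that("surface detection recovers the shell sphere within 1.5 voxels RMS", {
  tis <- make_shell_sphere()  # 96^3, R = 20
  res <- detect_surface(tis$image, 100, 100)
  r <- radial_grid(dim(tis$image))
  rad <- zero_crossing_radii(res$phi, r)
  expect_lt(sqrt(mean((rad - 20)^2)), 1.5)
  expect_true(res$diagnostics$converged)
  # converged interior encloses the wall: volume within 5% of the ball out
  # to the outer wall surface (the gradient contour adheres to the outer
  # side of the wall, offset ~ the composed wall half-width)
  sigp <- sqrt(tis$params$wall_sigma^2 + 1)
  expect_equal(sum(res$interior_mask), 4 / 3 * pi * (20 + sigp)^3,
               tolerance = 0.05)
})

test_that("a contour initialised 10 voxels outside converges onto the shell", {
  tis <- make_shell_sphere()
  g <- edge_map(tis$image, indicator_spec("g", 8, 1))
  r <- radial_grid(dim(tis$image))
  res <- evolve(r - 30, g, evolve_params(alpha = 1, direction = "inward",
                                         conv_tol = 5e-6, max_iter = 1000))
  expect_true(res$diagnostics$converged)
  rad <- zero_crossing_radii(res$phi, r)
  expect_lt(sqrt(mean((rad - 20)^2)), 1.5)
})

test_that("detection is invariant under a joint intensity/parameter rescale", {
  tis <- make_shell_sphere(shape = c(64, 64, 64), R = 16, noise_sigma = 2)
  a <- detect_surface(tis$image, 100, 100, spec = indicator_spec("g", 8, 1))
  b <- detect_surface(tis$image * 4, 400, 400, spec = indicator_spec("g", 32, 1))
  expect_identical(a$interior_mask, b$interior_mask)
})

test_that("an initialisation that encloses nothing is an error", {
  I <- array(10, c(8, 8, 8))
  expect_error(detect_surface(I, 1000, 1000), "enclosed nothing")
})

test_that("the accelerating term pushes the contour into a deep crease", {
  ft <- make_folded_tissue(wall_sigma = 0.5)
  sh <- dim(ft$image)
  cx <- (sh[1] + 1) / 2
  strip <- abs(seq_len(sh[1]) - cx) <= 1   # crease floor columns
  err <- list()
  for (al in c(0, 1)) {
    rs <- detect_surface(ft$image, 40, 40, fill_below = TRUE,
                         spec = indicator_spec("g", 8, 0.5),
                         params = evolve_params(alpha = al, beta = 0,
                                                direction = "inward"))
    dep <- first_interior_depth(rs$phi)
    err[[as.character(al)]] <-
      abs(dep[strip, ] - ft$truth$depth_map[strip, ])
  }
  expect_lt(max(err[["1"]], na.rm = TRUE), 2)
  expect_gte(max(err[["0"]], na.rm = TRUE), ft$params$crease_depth / 2)
})

test_that("the smoothing term trades cell-scale relief for a smaller surface area", {
  bt <- make_shell_sphere(bump_amp = 2.5, bump_n = 5)
  truth_in <- bt$truth_labels > 0
  area <- c()
  for (be in c(0, 1)) {
    rs <- detect_surface(bt$image, 100, 100,
                         params = evolve_params(alpha = 1, beta = be,
                                                direction = "inward"))
    # smoothed-delta surface area estimate
    ph <- rs$phi
    shp <- function(a, ax, d) {
      n <- dim(a)[ax]; idx <- pmin(pmax(seq_len(n) + d, 1L), n)
      switch(ax, a[idx, , ], a[, idx, ], a[, , idx])
    }
    sn <- sqrt(((shp(ph, 1, 1) - shp(ph, 1, -1)) / 2)^2 +
               ((shp(ph, 2, 1) - shp(ph, 2, -1)) / 2)^2 +
               ((shp(ph, 3, 1) - shp(ph, 3, -1)) / 2)^2)
    de <- ifelse(abs(ph) <= 1.5, (1 + cos(pi * ph / 1.5)) / 3, 0)
    area[as.character(be)] <- sum(de * sn)
    expect_gte(sum(rs$interior_mask & truth_in) / sum(truth_in), 0.95)
  }
  expect_lt(area[["1"]], area[["0"]])
})

test_that("surface shells have the stated thickness and area scaling", {
  sh <- c(32, 32, 32)
  z <- slice.index(array(0, sh), 3)
  plane <- (z - 16.5) * 1.0   # exact signed distance to a plane
  shell <- surface_shell(plane, 2)
  expect_identical(sum(shell), 2L * 32L * 32L)
  expect_identical(sum(surface_shell(plane, 0.999)), 0L)

  sph <- sphere_sdf(c(64, 64, 64), 20)
  count <- sum(surface_shell(sph, 3))
  expect_equal(count, 4 * pi * 20^2 * 3, tolerance = 0.15)
  expect_error(surface_shell(plane, 0), "thickness")
})
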