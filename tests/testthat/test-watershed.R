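test_that("interior mode matches exact counting", {
  sh <- c(10, 10, 1)
  I <- array(c(rep(10, 5), rep(20, 80), rep(30, 15)), sh)
  mask <- array(TRUE, sh)
  expect_identical(interior_mode(I, mask), 20)
  expect_identical(interior_mode(array(42, sh), mask), 42)
  expect_error(interior_mode(I, array(FALSE, sh)), "empty")
})

test_that("interior mode of a continuous bimodal mixture matches a histogram oracle", {
  set.seed(21)
  v <- c(rnorm(5000, 20, 3), rnorm(1500, 120, 10))  # lumen majority, walls bright
  v <- v[v >= 0]
  n <- length(v)
  sh <- c(19, 19, 19)
  I <- array(c(v, rep(0, prod(sh) - n)), sh)
  mask <- array(c(rep(TRUE, n), rep(FALSE, prod(sh) - n)), sh)
  got <- interior_mode(I, mask)
  # brute-force oracle: 256 equal-width bins over the range, lowest-bin tie
  breaks <- seq(min(v), max(v), length.out = 257)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), 256),
                     nbins = 256)
  k <- which.max(counts)
  expect_identical(got, (breaks[k] + breaks[k + 1]) / 2)
  expect_lt(abs(got - 20), 5)  # it is the lumen mode, not the wall mode
})

test_that("image enhancement rewrites exactly the shell and the exterior", {
  tis <- make_shell_sphere(shape = c(48, 48, 48), R = 12, noise_sigma = 3)
  surf <- detect_surface(tis$image, 100, 100)
  enh <- enhance_image(tis$image, surf)
  white <- max(enh)
  expect_true(all(enh[abs(surf$phi) <= 1] == white))
  deep_in <- surf$phi < -3
  expect_identical(enh[deep_in], tis$image[deep_in])
  far_out <- surf$phi > 3
  expect_identical(unique(enh[far_out]), interior_mode(tis$image, surf$interior_mask))
  expect_error(enhance_image(tis$image[1:10, , ], surf), "3D|shape")
})

test_that("h-minima seeding counts basins against the ridge height", {
  I <- array(100, c(20, 20, 5))
  I[5, 10, 3] <- 10
  I[15, 10, 3] <- 20
  s2 <- detect_seeds_hminima(I, 30)
  expect_identical(max(s2), 2L)
  # with h above the basin depths the two minima merge into one marker
  s1 <- detect_seeds_hminima(I, 95)
  expect_identical(max(s1), 1L)
  # single dark basin
  I3 <- array(100, c(10, 10, 10)); I3[5, 5, 5] <- 0
  expect_identical(max(detect_seeds_hminima(I3, 50)), 1L)
  # deterministic labelling: lexicographically first component gets label 1
  expect_identical(unique(s2[s2 > 0][1]), 1L)
})

test_that("seeded watershed floods to wall crests", {
  I <- array(0, c(21, 9, 9))
  I[11, , ] <- 100
  I[10, , ] <- 40
  I[12, , ] <- 40
  seeds <- array(0L, dim(I)); seeds[3, 5, 5] <- 1L; seeds[19, 5, 5] <- 2L
  L <- watershed_segment(I, seeds)
  expect_true(all(L > 0))
  # 1D oracle along the inter-seed axis: the boundary must lie on the crest
  profile <- L[, 5, 5]
  boundary <- max(which(profile == 1))
  expect_lte(abs(boundary - 11), 1)

  expect_identical(unique(as.integer(watershed_segment(I, array(c(1L, rep(0L, prod(dim(I)) - 1)), dim(I))))), 1L)
  expect_error(watershed_segment(I, array(0L, dim(I))), "seed")
})

test_that("watershed from ground-truth seeds recovers the foam", {
  fm <- make_foam(shape = c(64, 64, 64), n_cells = 6, seed = 2)
  seeds <- foam_seed_grid(fm)
  L <- watershed_segment(fm$image, seeds, mask = fm$truth$tissue_mask)
  agree <- mean((L == fm$truth_labels)[fm$truth$tissue_mask])
  expect_gte(agree, 0.95)
})

test_that("segmentation comparison metrics match their definitions", {
  truth <- array(0L, c(8, 8, 2))
  truth[1:4, , ] <- 1L; truth[5:8, 1:4, ] <- 2L; truth[5:8, 5:8, ] <- 3L
  m <- compare_segmentations(truth, truth)
  expect_identical(m$lost_cells, 0L)
  expect_equal(m$agreement, 1)
  expect_true(all(m$volume_rel_error == 0))

  merged <- truth; merged[merged == 3L] <- 2L
  m2 <- compare_segmentations(merged, truth)
  expect_identical(m2$lost_cells, 1L)
  expect_identical(m2$lost_labels, 3L)
})

test_that("agreement equals the brute-force optimal assignment on toy grids", {
  set.seed(33)
  for (rep in 1:5) {
    truth <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
    L <- array(sample(0:3, 8^3, replace = TRUE), c(8, 8, 8))
    m <- compare_segmentations(L, truth)
    # brute force over all injective matchings of truth labels to predicted
    tl <- sort(unique(as.integer(truth))); pl <- sort(unique(as.integer(L)))
    ov <- table(factor(truth, tl), factor(L, pl))
    best <- 0
    perm_all <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm_all(v[-i]), function(p) c(v[i], p))))
    for (p in perm_all(seq_along(pl))) {
      tot <- sum(vapply(seq_along(tl), function(i)
        if (i <= length(p)) ov[i, p[i]] else 0, 0))
      best <- max(best, tot)
    }
    expect_equal(m$agreement, best / sum(ov))
  }
})

test_that("surface-enhanced watershed rescues outer-layer cells lost on the raw image", {
  fm <- make_foam(shape = c(96, 96, 96), n_cells = 8, seed = 4)
  I <- fm$image
  h <- 0.1 * diff(range(I))
  raw_seeds <- detect_seeds_hminima(I, h)
  L_raw <- watershed_segment(I, raw_seeds)
  m_raw <- compare_segmentations(L_raw, fm$truth_labels, fm$truth_surface_mask)

  surf <- detect_surface(I, 15, 9, spec = indicator_spec("g", 3, 1))
  enh <- enhance_image(I, surf)
  # enhancement never alters interior voxels outside the (watertight) cap:
  # the cap is the |phi| shell plus the sign-change faces
  inside <- surf$phi < 0
  crossing <- array(FALSE, dim(inside))
  for (axis in 1:3) for (dd in c(-1L, 1L))
    crossing <- crossing | (inside != levelset3d:::shift_clamp(inside, axis, dd))
  keep <- surf$phi < -1.5 & !crossing
  expect_identical(enh[keep], I[keep])

  enh_seeds <- detect_seeds_hminima(enh, 0.1 * diff(range(enh)))
  L_enh <- watershed_segment(enh, enh_seeds)
  m_enh <- compare_segmentations(L_enh, fm$truth_labels, fm$truth_surface_mask)

  raw_fails <- m_raw$l1$lost_cells >= 1 ||
    mean(abs(m_raw$l1$volume_rel_error)) > 0.2
  expect_true(raw_fails)
  expect_identical(m_enh$l1$lost_cells, 0L)
  # the outer-rim assignment bias scales with the cells' surface-to-volume
  # ratio; the < 10% bound at the 128^3 study scale is asserted in the
  # acceptance suite, this desk-size foam allows 15%
  expect_lt(mean(abs(m_enh$l1$volume_rel_error)), 0.15)
})
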