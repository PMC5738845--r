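test_that("shell-sphere fixture honours its stated construction", {
  tis <- make_shell_sphere(shape = c(64, 64, 64), R = 16)
  expect_equal(max(tis$image), 200, tolerance = 0.01)
  expect_identical(sort(unique(as.integer(tis$truth_labels))), c(0L, 1L))

  # z attenuation: noise-free intensity at (x, y, z) scales by 1 - k (z-1)/(Z-1)
  att <- make_shell_sphere(shape = c(64, 64, 64), R = 16, atten_k = 0.5)
  base <- make_shell_sphere(shape = c(64, 64, 64), R = 16, atten_k = 0)
  z <- slice.index(base$image, 3)
  sel <- base$image > 50
  expect_equal(att$image[sel],
               base$image[sel] * (1 - 0.5 * (z[sel] - 1) / 63),
               tolerance = 1e-12)

  expect_error(make_shell_sphere(shape = c(32, 32, 32), R = 15), "geometry")
  # bit-reproducible
  a <- make_shell_sphere(shape = c(32, 32, 32), R = 8, noise_sigma = 5, seed = 9)
  b <- make_shell_sphere(shape = c(32, 32, 32), R = 8, noise_sigma = 5, seed = 9)
  expect_identical(a$image, b$image)
})

test_that("foam fixture: wall contrast, cell counts, surface consistency", {
  fm <- make_foam(shape = c(64, 64, 64), n_cells = 6, noise_sigma = 0,
                  atten_k = 0, seed = 2)
  inner <- fm$truth$inner_wall_mask
  outer <- fm$truth_surface_mask
  # outer/inner mean brightness ratio ~ rho_outer, away from crossings
  d_in <- sqrt(levelset3d:::edt3d(inner)$dist2)
  d_out <- sqrt(levelset3d:::edt3d(outer)$dist2)
  ratio <- mean(fm$image[outer & d_in > 4]) / mean(fm$image[inner & d_out > 4])
  expect_equal(ratio, 0.3, tolerance = 0.05 / 0.3)

  fm8 <- make_foam(shape = c(96, 96, 96), n_cells = 8, seed = 1)
  counts <- tabulate(fm8$truth_labels[fm8$truth_labels > 0])
  expect_length(counts, 8)
  expect_true(all(counts >= 100))

  # every truth-surface voxel is adjacent to exterior background
  lab <- fm8$truth_labels
  adj0 <- array(FALSE, dim(lab))
  for (a in 1:3) for (d in c(-1L, 1L))
    adj0 <- adj0 | (levelset3d:::shift_clamp(lab, a, d) == 0L)
  expect_true(all(adj0[fm8$truth_surface_mask]))

  expect_error(make_foam(n_cells = 1), "n_cells")
  a <- make_foam(shape = c(48, 48, 48), n_cells = 3, seed = 4)
  b <- make_foam(shape = c(48, 48, 48), n_cells = 3, seed = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_labels, b$truth_labels)
})

test_that("folded-tissue fixture: dome, crease depth, halo", {
  flat <- make_folded_tissue(crease_depth = 0)
  # zero-depth crease reduces to the smooth dome
  sh <- dim(flat$image)
  cx <- (sh[1] + 1) / 2; cy <- (sh[2] + 1) / 2
  lat2 <- outer((seq_len(sh[1]) - cx)^2, (seq_len(sh[2]) - cy)^2, `+`)
  dome <- pmin(flat$params$apex_z + flat$params$dome_curv * lat2, sh[3] - 2)
  expect_equal(flat$truth$depth_map, dome, tolerance = 1e-12)

  ft <- make_folded_tissue()
  # stated depth recovered from the truth depth map at the groove centre
  centre_extra <- ft$truth$depth_map[round(cx), round(cy)] -
    dome[round(cx), round(cy)]
  expect_equal(centre_extra, ft$params$crease_depth, tolerance = 0.01)
  # bright voxels inside the crease reach the wall peak intensity
  crease3d <- array(rep(ft$truth$crease_cols, sh[3]), sh)
  expect_gte(max(ft$image[crease3d]), ft$params$A_wall * 0.99)
  expect_error(make_folded_tissue(crease_width = 1), "crease_width")
})

test_that("nuclear channel: presence, exact imposed ratios, calibrated correlation", {
  fm <- make_foam(shape = c(48, 48, 48), n_cells = 4, seed = 6)
  t0 <- add_nuclei_channel(fm, missing_fraction = 0, seed = 2)
  labs <- 1:4
  expect_true(all(labs %in% t0$truth_nuclei))

  # ratio_sd = 0: truth nucleus volumes are exactly ratio_mean * cell volume
  tr <- add_nuclei_channel(fm, ratio_mean = 0.2, ratio_sd = 0,
                           target_corr = 1, seed = 2)
  vc <- tabulate(tr$truth_labels[tr$truth_labels > 0], nbins = 4)
  vn <- tabulate(tr$truth_nuclei[tr$truth_nuclei > 0], nbins = 4)
  expect_equal(vn, round(0.2 * vc), tolerance = 1e-12)

  # large-n sampling check of the generator itself
  big <- make_foam(shape = c(128, 128, 128), n_cells = 200, seed = 7)
  big <- add_nuclei_channel(big, ratio_mean = 0.17, ratio_sd = 0.05,
                            target_corr = 0.6, seed = 7)
  info <- big$truth$nuclei
  vc <- tabulate(big$truth_labels[big$truth_labels > 0], nbins = 200)
  vn <- tabulate(big$truth_nuclei[big$truth_nuclei > 0], nbins = 200)
  sel <- info$present
  expect_equal(cor(vc[sel], vn[sel]), 0.6, tolerance = 0.1 / 0.6)
  expect_equal(mean(vn[sel] / vc[sel]), 0.17, tolerance = 0.02 / 0.17)
  expect_error(add_nuclei_channel(fm, ratio_mean = 1.2), "ratio_mean")
  expect_error(add_nuclei_channel(fm, missing_fraction = 1), "missing_fraction")
})

test_that("fixture parameters round-trip through JSON bit-exactly", {
  fm <- make_foam(shape = c(48, 48, 48), n_cells = 3, seed = 4)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(fm$params, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(as.numeric(back$seed), as.numeric(fm$params$seed))
  expect_identical(as.numeric(back$rho_outer), as.numeric(fm$params$rho_outer))
  expect_identical(as.numeric(back$atten_k), as.numeric(fm$params$atten_k))
  expect_identical(as.integer(back$shape), as.integer(fm$params$shape))
})
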