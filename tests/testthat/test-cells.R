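test_that("seed initialisation produces disjoint ball interiors", {
  seeds <- array(0L, c(32, 32, 32))
  seeds[10, 16, 16] <- 1L
  seeds[20, 16, 16] <- 2L
  phis <- init_from_seeds(seeds, r0 = 3, margin = 4)
  expect_length(phis, 2)
  vol1 <- sum(phis[[1]]$phi < 0)
  expect_equal(vol1, 4 / 3 * pi * 27, tolerance = 0.2)
  L <- labels_from_lsfs(phis)
  expect_identical(sort(unique(as.integer(L))), c(0L, 1L, 2L))
  # interiors disjoint: no voxel could get both labels
  expect_identical(sum(L == 1L) + sum(L == 2L), 2L * vol1)

  expect_identical(init_from_seeds(array(0L, c(8, 8, 8))), list())
  bad <- data.frame(label = 1, x = 50, y = 2, z = 2)
  expect_error(init_from_seeds(bad, shape = c(8, 8, 8)), "out-of-bounds")
})

test_that("label initialisation erodes by a Euclidean ball and never drops cells", {
  L <- array(0L, c(13, 13, 13))
  L[3:11, 3:11, 3:11] <- 1L          # 9^3 cube
  phis <- init_from_labels(L, d = 1)
  expect_equal(sum(phis[[1]]$phi < 0), 7^3)

  L2 <- array(0L, c(9, 9, 9)); L2[5, 5, 5] <- 1L
  phis2 <- init_from_labels(L2, d = 1)
  expect_identical(sum(phis2[[1]]$phi < 0), 1L)   # deepest-voxel fallback

  expect_error(init_from_labels(array(0L, c(4, 4, 4))), "background")
})

test_that("label round trip: d = 0 initialisation reproduces non-touching labels", {
  fm <- make_foam(shape = c(48, 48, 48), n_cells = 4, seed = 6)
  L <- fm$truth_labels
  # separate the cells so they do not touch
  L[fm$truth$inner_wall_mask] <- 0L
  phis <- init_from_labels(L, d = 0)
  back <- labels_from_lsfs(phis)
  expect_identical(back, L)
  # with d = 1 every interior is strictly inside its cell
  phis1 <- init_from_labels(fm$truth_labels, d = 1)
  L1 <- labels_from_lsfs(phis1)
  expect_true(all(fm$truth_labels[L1 > 0] == L1[L1 > 0]))
})

test_that("rasterisation resolves overlaps by depth with lowest-label ties", {
  sh <- c(8, 8, 8)
  p1 <- structure(list(phi = array(-2, sh), offset = c(1L, 1L, 1L),
                       shape = sh, label = 1L), class = "lsf")
  p2 <- structure(list(phi = array(-1, sh), offset = c(1L, 1L, 1L),
                       shape = sh, label = 2L), class = "lsf")
  expect_true(all(labels_from_lsfs(list(p1, p2)) == 1L))
  p3 <- structure(list(phi = array(-2, sh), offset = c(1L, 1L, 1L),
                       shape = sh, label = 3L), class = "lsf")
  expect_true(all(labels_from_lsfs(list(p1, p3)) == 1L))  # exact tie -> lowest
  p4 <- structure(list(phi = array(1, sh), offset = c(1L, 1L, 1L),
                       shape = sh, label = 1L), class = "lsf")
  expect_true(all(labels_from_lsfs(list(p4)) == 0L))
  expect_error(labels_from_lsfs(list()), "empty")
})

test_that("independent evolution inflates a seed to fill its cell", {
  fm <- make_foam(shape = c(64, 64, 64), n_cells = 6, seed = 2)
  seeds <- foam_seed_grid(fm)
  g <- edge_map(fm$image, indicator_spec("h", "auto", 1))
  phis <- init_from_seeds(seeds, r0 = 3, margin = 20)
  expect_identical(evolve_multi(list(), g), list())

  one <- evolve_multi(phis[1], g)
  lab <- labels_from_lsfs(one, dim(g))
  cell <- fm$truth_labels == 1L
  fill <- sum(lab == 1L & cell) / sum(cell)
  leak <- sum(lab == 1L & !cell & fm$truth_labels > 0L) / sum(lab == 1L)
  expect_gte(fill, 0.8)
  expect_lte(leak, 0.05)
})

test_that("gradient-indicator cells keep a gap at shared walls", {
  fm <- make_foam(shape = c(64, 64, 64), n_cells = 6, seed = 2)
  seeds <- foam_seed_grid(fm)
  res_g <- segment_cells(fm$image, seeds = seeds,
                         spec = indicator_spec("g", "auto"), margin = 20)
  pre <- res_g$labels_prefill
  # along the segment between two adjacent seed points there is >= 1
  # unlabelled voxel (the double valley keeps contours apart)
  pts <- fm$truth$seed_points
  # the closest pair of seeds belongs to adjacent cells
  dmat <- as.matrix(dist(pts))
  diag(dmat) <- Inf
  ab <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  a <- min(ab); b <- max(ab)
  line <- vapply(seq(0, 1, length.out = 96), function(t) {
    v <- round(pts[a, ] + t * (pts[b, ] - pts[a, ]))
    pre[v[1], v[2], v[3]]
  }, integer(1))
  expect_true(any(line == a) && any(line == b))
  la <- max(which(line == a))
  fb <- min(which(line == b))
  expect_lt(la, fb)
  expect_gte(sum(line[(la + 1):(fb - 1)] == 0), 1)
})

test_that("nearest-object gap filling matches a brute-force scan and is idempotent", {
  set.seed(9)
  L <- array(0L, c(10, 10, 10))
  sites <- sample(1000, 8)
  L[sites] <- sample(1:5, 8, replace = TRUE)
  domain <- array(TRUE, dim(L))
  filled <- fill_unassigned_nearest(L, domain)
  # brute force: nearest labelled voxel, lowest label on ties
  co <- arrayInd(sites, dim(L))
  labs <- L[sites]
  ref <- array(0L, dim(L))
  for (v in seq_len(1000)) {
    p <- arrayInd(v, dim(L))
    d2 <- colSums((t(co) - as.vector(p))^2)
    best <- min(d2)
    ref[v] <- min(labs[d2 == best])
  }
  ref[sites] <- labs
  expect_identical(filled, ref)
  expect_identical(fill_unassigned_nearest(filled, domain), filled)

  # two labels at opposite ends of a bar split at the midplane, lower label
  # keeps the equidistant plane
  bar <- array(0L, c(9, 3, 3)); bar[1, 2, 2] <- 1L; bar[9, 2, 2] <- 2L
  fb <- fill_unassigned_nearest(bar, array(TRUE, dim(bar)))
  expect_true(all(fb[1:5, , ] == 1L))
  expect_true(all(fb[6:9, , ] == 2L))
  expect_error(fill_unassigned_nearest(array(0L, c(4, 4, 4)),
                                       array(TRUE, c(4, 4, 4))), "no labelled")
})

test_that("the Hessian cellular pipeline reaches truth-level agreement after gap filling", {
  fm <- make_foam(shape = c(64, 64, 64), n_cells = 6, seed = 2)
  seeds <- foam_seed_grid(fm)
  res_h <- segment_cells(fm$image, seeds = seeds, margin = 20,
                         domain_mask = fm$truth$tissue_mask)
  m <- compare_segmentations(res_h$labels, fm$truth_labels)
  expect_gte(m$agreement, 0.95)
  expect_identical(m$lost_cells, 0L)

  res_g <- segment_cells(fm$image, seeds = seeds,
                         spec = indicator_spec("g", "auto"), margin = 20)
  # Hessian cells occupy more of the image before gap filling
  expect_gt(sum(res_h$labels_prefill > 0), sum(res_g$labels_prefill > 0))
})
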