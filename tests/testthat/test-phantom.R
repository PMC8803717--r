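test_that("degenerate spec without perivascular component is isotropic", {
  spec <- isotropic_spec(d = 0.9e-3, grid_shape = c(32L, 24L, 12L),
                         voxel_size_mm = c(1, 1, 1),
                         csf_halfwidth = 2, region_width = 7)
  field <- build_phantom(spec)
  te <- matrix(field$tensors, ncol = 6)
  expect_equal(max(abs(te[, 4:6])), 0)
  expect_equal(range(te[, 1:3]), c(0.9e-3, 0.9e-3))
})

test_that("fiber regions have the constructed principal axes", {
  field <- build_phantom(small_spec())
  te <- matrix(field$tensors, ncol = 6)
  lab <- as.vector(field$labels)
  for (vox in which(lab == 2L)[c(1, 50, 200)]) {  # projection
    D <- matrix(c(te[vox, 1], te[vox, 4], te[vox, 5],
                  te[vox, 4], te[vox, 2], te[vox, 6],
                  te[vox, 5], te[vox, 6], te[vox, 3]), 3, 3)
    ev <- eigen(D, symmetric = TRUE)
    expect_lt(sum(abs(abs(ev$vectors[, 1]) - c(0, 0, 1))), 1e-6)
  }
  for (vox in which(lab == 3L)[c(1, 50)]) {       # association
    D <- diag(3); D[1, 1] <- te[vox, 1]; D[2, 2] <- te[vox, 2]
    D[3, 3] <- te[vox, 3]
    ev <- eigen(D, symmetric = TRUE)
    expect_lt(sum(abs(abs(ev$vectors[, 1]) - c(0, 1, 0))), 1e-6)
  }
})

test_that("analytic index matches the ALPS module on the noiseless field", {
  spec <- small_spec()
  field <- build_phantom(spec)
  gs <- spec$grid_shape
  te <- matrix(field$tensors, ncol = 6)
  maps <- structure(list(
    dxx = array(te[, 1], gs), dyy = array(te[, 2], gs),
    dzz = array(te[, 3], gs), fa = NULL, md = NULL,
    fit_mask = array(TRUE, gs), source = "tensor", scheme_label = "truth",
    affine = field$affine, voxel_size_mm = spec$voxel_size_mm),
    class = "diffusivity_maps")
  res <- alps_index(maps, make_rois(spec))
  expect_equal(res$alps_bil, alps_truth(spec), tolerance = 1e-12)
  expect_equal(res$alps_r, res$alps_l, tolerance = 1e-12)
})

test_that("the ground-truth index is invariant to common diffusivity scaling", {
  base <- phantom_spec()
  scaled <- phantom_spec(compartment_diffusivities = lapply(
    base$compartment_diffusivities, function(d) d * 0.5))
  expect_equal(alps_truth(scaled), alps_truth(base), tolerance = 1e-12)
  # and decreases monotonically with diffusion time under the default decay
  tt <- sapply(c(29, 35.7, 40.7), function(t) alps_truth(base, t))
  expect_true(all(diff(tt) < 0))
})

test_that("invalid phantom geometry is rejected", {
  spec <- small_spec()
  bad <- spec$roi_centers
  bad$right_projection <- c(16.5, 12.5, 6.5)   # midline CSF
  bad$left_projection <- c(16.5, 12.5, 6.5)
  expect_error(build_phantom(small_spec(roi_centers = bad)),
               "outside its labeled region")
  expect_error(phantom_spec(grid_shape = c(16L, 24L, 12L)), "too small")
  asym <- spec$roi_centers
  asym$left_projection[1] <- asym$left_projection[1] + 1
  expect_error(small_spec(roi_centers = asym), "mirror-symmetric")
  expect_error(phantom_spec(compartment_diffusivities = list(
    projection = c(1e-3, 1e-3, 4e-3), association = c(0.5e-3, 1.4e-3, 0.5e-3),
    csf = rep(3e-3, 3), background = rep(0.8e-3, 3),
    pvs = c(1.5e-3, 0.4e-3, 0.4e-3))), "free water")
})

test_that("head rotation conjugates tensors and preserves eigenvalues", {
  spec <- small_spec()
  field <- build_phantom(spec)
  expect_identical(apply_head_rotation(field, 0), field)

  iso <- build_phantom(isotropic_spec(grid_shape = c(32L, 24L, 12L),
                                      voxel_size_mm = c(1, 1, 1),
                                      csf_halfwidth = 2, region_width = 7))
  rot_iso <- apply_head_rotation(iso, 17)
  expect_lt(max(abs(rot_iso$tensors - iso$tensors)), 1e-12)

  rot <- apply_head_rotation(field, 20)
  # voxel on the rotation axis keeps its (projection) label; compare with a
  # direct 3x3 conjugation of the region tensor
  ctr <- round(spec$roi_centers$right_projection)
  v6 <- field$tensors[ctr[1], ctr[2], ctr[3], ]
  th <- 20 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  D <- matrix(c(v6[1], v6[4], v6[5], v6[4], v6[2], v6[6],
                v6[5], v6[6], v6[3]), 3, 3)
  Dp <- R %*% D %*% t(R)
  got <- rot$tensors[ctr[1], ctr[2], ctr[3], ]
  expect_equal(got, c(Dp[1, 1], Dp[2, 2], Dp[3, 3], Dp[1, 2], Dp[1, 3],
                      Dp[2, 3]), tolerance = 1e-12, ignore_attr = TRUE)
  # Dyy/Dzz mix as cos^2/sin^2 of the originals (diagonal source tensor)
  expect_equal(got[2], cos(th)^2 * v6[2] + sin(th)^2 * v6[3],
               tolerance = 1e-12)

  # eigenvalues preserved for every rotated fiber voxel
  ev0 <- sort(v6[1:3])
  rlab <- as.vector(rot$labels)
  rte <- matrix(rot$tensors, ncol = 6)
  for (vox in which(rlab == 2L)[c(1, 100, 500)]) {
    D <- matrix(c(rte[vox, 1], rte[vox, 4], rte[vox, 5],
                  rte[vox, 4], rte[vox, 2], rte[vox, 6],
                  rte[vox, 5], rte[vox, 6], rte[vox, 3]), 3, 3)
    expect_equal(sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values),
                 ev0, tolerance = 1e-12)
  }
  expect_error(apply_head_rotation(field, 60), "45")
})

test_that("noiseless signals follow the closed-form decay", {
  spec <- small_spec()
  field <- build_phantom(spec)
  sch <- make_scheme(3, 1, 85)
  acq <- simulate_dwi(field, sch, snr_b0 = Inf)
  # b = 0 volume equals S0 exactly
  expect_identical(acq$signals[, , , 1], field$s0)
  # isotropic voxel: S = S0 exp(-b d) for any direction
  iso <- build_phantom(isotropic_spec(d = 1e-3, grid_shape = c(32L, 24L, 12L),
                                      voxel_size_mm = c(1, 1, 1),
                                      csf_halfwidth = 2, region_width = 7))
  a2 <- simulate_dwi(iso, make_scheme(12, 1, 85), snr_b0 = Inf)
  expected <- iso$s0 * exp(-1000 * 1e-3)
  for (v in 2:4)
    expect_equal(a2$signals[, , , v], expected, tolerance = 1e-12)
})

test_that("background magnitudes match the Rician zero-signal mean", {
  spec <- phantom_spec(csf_halfwidth = 2.5, region_width = 10)
  field <- build_phantom(spec)
  acq <- simulate_dwi(field, make_scheme(3, 1, 85), snr_b0 = 40, seed = 11)
  bg <- as.vector(field$labels) == 0L
  expect_gt(sum(bg), 10000)
  x <- matrix(acq$signals, ncol = dim(acq$signals)[4])[bg, 1]
  sigma <- 100 / 40
  expect_equal(mean(x), sigma * sqrt(pi / 2),
               tolerance = 3 * sd(x) / sqrt(length(x)) / (sigma * sqrt(pi / 2)))
})

test_that("simulation is seed-reproducible and seeds differ", {
  field <- build_phantom(small_spec())
  sch <- make_scheme(3, 2, 85)
  a <- simulate_dwi(field, sch, snr_b0 = 40, seed = 5)
  b <- simulate_dwi(field, sch, snr_b0 = 40, seed = 5)
  c_ <- simulate_dwi(field, sch, snr_b0 = 40, seed = 6)
  expect_identical(a$signals, b$signals)
  expect_false(identical(a$signals, c_$signals))
  # the caller's RNG stream is not disturbed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_dwi(field, sch, snr_b0 = 40, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("averaging reduces the spread of ROI-mean signals", {
  spec <- small_spec()
  field <- build_phantom(spec)
  roi <- roi_mask(make_rois(spec)[["right_projection"]], spec$grid_shape,
                  spec$voxel_size_mm)
  sds <- sapply(c(1L, 2L, 4L), function(av) {
    sch <- make_scheme(3, av, 85)
    means <- sapply(1:80, function(s) {
      a <- simulate_dwi(field, sch, snr_b0 = 20, seed = 1000 + s)
      mean(a$signals[, , , 2][roi])
    })
    sd(means)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("raw realizations keep one volume per average", {
  field <- build_phantom(small_spec())
  sch <- make_scheme(3, 3, 85)
  a <- simulate_dwi(field, sch, snr_b0 = 40, seed = 2, raw = TRUE)
  expect_equal(dim(a$signals)[4], length(sch$bvalues) * 3L)
  expect_false(a$averaged)
  expect_true(all(a$signals >= 0))
})
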