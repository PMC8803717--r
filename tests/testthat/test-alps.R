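test_that("ROI masks count voxels as the geometry dictates", {
  gs <- c(32L, 32L, 32L)
  one <- roi_mask(roi_spec("sphere", 1, c(16, 16, 16), "right", "projection"),
                  gs)
  expect_equal(sum(one), 1L)
  cube <- roi_mask(roi_spec("cube", 12, c(16.5, 16.5, 16.5), "right",
                            "projection"), gs)
  expect_equal(sum(cube), 12L^3)
  sq <- roi_mask(roi_spec("square", 8, c(16.5, 16.5, 16.5), "left",
                          "association"), gs)
  expect_equal(sum(sq), 8L^2)
  expect_equal(sum(apply(sq, 3, any)), 1L)  # single slice
})

test_that("sphere and cube masks match exhaustive enumeration", {
  gs <- c(24L, 24L, 16L)
  cases <- list(
    list(shape = "sphere", size = 12, ctr = c(12.5, 12.5, 8.5), vs = c(1, 1, 1)),
    list(shape = "sphere", size = 12, ctr = c(12.5, 12.5, 8.5),
         vs = c(0.78125, 0.78125, 3)),
    list(shape = "sphere", size = 8, ctr = c(10.5, 13.5, 8.5), vs = c(1, 1, 1)),
    list(shape = "cube", size = 8, ctr = c(12.5, 12.5, 8.5),
         vs = c(0.78125, 0.78125, 3)))
  for (cs in cases) {
    m <- roi_mask(roi_spec(cs$shape, cs$size, cs$ctr, "right", "projection"),
                  gs, cs$vs)
    want <- oracle_roi_enumeration(cs$shape, cs$size, cs$ctr, gs, cs$vs)
    lin <- function(v) (v[, 3] - 1) * gs[1] * gs[2] + (v[, 2] - 1) * gs[1] + v[, 1]
    expect_identical(sort(lin(which(m, arr.ind = TRUE))), sort(lin(want)))
  }
})

test_that("the six patterns share one exact center", {
  gs <- c(32L, 32L, 32L)
  ctr <- c(16.5, 16.5, 16.5)
  for (pat in roi_patterns()) {
    parts <- strsplit(pat, "_")[[1]]
    size <- if (parts[1] == "large") 12 else 8
    m <- roi_mask(roi_spec(parts[2], size, ctr, "right", "projection"), gs)
    idx <- which(m, arr.ind = TRUE)
    expect_equal(colMeans(idx)[1:2], ctr[1:2], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("truncated masks warn and are flagged", {
  gs <- c(16L, 16L, 16L)
  expect_warning(
    m <- roi_mask(roi_spec("sphere", 12, c(3.5, 8.5, 8.5), "left",
                           "projection"), gs),
    "truncated")
  expect_true(attr(m, "truncated"))
  expect_error(roi_mask(roi_spec("sphere", 4, c(20, 8, 8), "left",
                                 "projection"), gs), "outside grid")
})

test_that("ROI means equal the direct masked average", {
  spec <- small_spec()
  gs <- spec$grid_shape
  set.seed(3)
  vals <- array(runif(prod(gs)), gs)
  maps <- structure(list(dxx = vals, dyy = vals * 2, dzz = vals * 3,
                         fa = NULL, md = NULL,
                         fit_mask = array(TRUE, gs), source = "tensor",
                         scheme_label = "", affine = diag(4),
                         voxel_size_mm = spec$voxel_size_mm),
                    class = "diffusivity_maps")
  rois <- make_rois(spec)
  means <- measure_rois(maps, rois)
  for (i in seq_along(rois)) {
    m <- roi_mask(rois[[i]], gs, spec$voxel_size_mm)
    expect_equal(means$dxx[i], mean(vals[m]), tolerance = 1e-14)
    expect_equal(means$dyy[i], mean(vals[m]) * 2, tolerance = 1e-14)
  }
  # constant map: every ROI mean is that constant
  maps$dxx <- array(0.42, gs)
  expect_equal(unique(measure_rois(maps, rois)$dxx), 0.42)
  # map = x coordinate: left/right means mirror about the midline
  maps$dxx <- array(seq_len(gs[1]), gs)
  mm <- measure_rois(maps, rois)
  mid <- (gs[1] + 1) / 2
  expect_equal(mm$dxx[mm$hemisphere == "right"] - mid,
               mid - mm$dxx[mm$hemisphere == "left"], tolerance = 1e-12)
})

test_that("an ROI with no usable voxels is a named error", {
  spec <- small_spec()
  field <- build_phantom(spec)
  maps <- diffusivity_maps(fit_dti(simulate_dwi(field, make_scheme(12, 1, 85),
                                                snr_b0 = Inf)))
  maps$fit_mask[1:4, , ] <- FALSE  # e.g. a slab the fit rejected
  bad <- make_rois(spec)
  bad$right_projection <- roi_spec("sphere", 2, c(2, 12, 6), "right",
                                   "projection")
  expect_error(alps_index(maps, bad), "no usable voxels")
})

test_that("the index follows its defining ratio", {
  mk <- function(dxx_p, dxx_a, dyy_p, dzz_a) {
    rbind(
      data.frame(hemisphere = "right", region = "projection", shape = "sphere",
                 size_px = 12, n_voxels = 10, truncated = FALSE,
                 dxx = dxx_p, dyy = dyy_p, dzz = 1),
      data.frame(hemisphere = "right", region = "association", shape = "sphere",
                 size_px = 12, n_voxels = 10, truncated = FALSE,
                 dxx = dxx_a, dyy = 1, dzz = dzz_a))
  }
  expect_equal(compute_alps(mk(1e-3, 1e-3, 1e-3, 1e-3))$alps_r, 1.0)
  expect_equal(compute_alps(mk(2e-3, 2e-3, 1e-3, 1e-3))$alps_r, 2.0)
  expect_error(compute_alps(mk(2e-3, 2e-3, -1e-3, 1e-3)), "nonpositive")
})

test_that("pipeline index is scale-invariant and hemisphere-consistent", {
  spec <- small_spec()
  field <- build_phantom(spec)
  maps <- diffusivity_maps(fit_dti(simulate_dwi(field, make_scheme(12, 2, 85),
                                                snr_b0 = 30, seed = 9)))
  rois <- make_rois(spec)
  res <- alps_index(maps, rois)
  expect_equal(res$alps_bil, (res$alps_r + res$alps_l) / 2, tolerance = 1e-12)

  scaled <- maps
  for (nm in c("dxx", "dyy", "dzz")) scaled[[nm]] <- scaled[[nm]] * 3.7
  res_s <- alps_index(scaled, rois)
  expect_equal(res_s$alps_bil, res$alps_bil, tolerance = 1e-12)

  # relabeling hemispheres swaps the unilateral indices, bilateral unchanged
  swapped <- lapply(rois, function(r) {
    r$hemisphere <- if (r$hemisphere == "left") "right" else "left"
    r
  })
  res_w <- alps_index(maps, swapped)
  expect_equal(res_w$alps_r, res$alps_l, tolerance = 1e-12)
  expect_equal(res_w$alps_l, res$alps_r, tolerance = 1e-12)
  expect_equal(res_w$alps_bil, res$alps_bil, tolerance = 1e-12)
})

test_that("all six patterns agree on the homogeneous noiseless phantom", {
  spec <- phantom_spec()
  field <- build_phantom(spec)
  maps <- diffusivity_maps(fit_dti(simulate_dwi(field, make_scheme(12, 1, 85),
                                                snr_b0 = Inf)))
  idx <- sapply(roi_patterns(), function(p)
    alps_index(maps, default_rois(spec, p))$alps_bil)
  expect_lt(diff(range(idx)), 1e-9)
})

test_that("bilateral averaging does not inflate variance", {
  spec <- small_spec()
  field <- build_phantom(spec)
  rois <- make_rois(spec)
  sch <- make_scheme(3, 1, 85)
  res <- t(sapply(1:50, function(s) {
    m <- maps_from_three_axis(simulate_dwi(field, sch, snr_b0 = 25,
                                           seed = 400 + s))
    r <- alps_index(m, rois)
    c(r = r$alps_r, l = r$alps_l, bil = r$alps_bil)
  }))
  expect_lte(var(res[, "bil"]), var(res[, "r"]))
  expect_lte(var(res[, "bil"]), var(res[, "l"]))
})

test_that("pixel-size conversion gives the printed ROI diameters", {
  expect_equal(roi_physical_diameter(12), 9.375)
  expect_equal(roi_physical_diameter(8), 6.25)
})
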