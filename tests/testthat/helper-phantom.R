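# Small, fast phantom used by most unit tests: isotropic 1 mm voxels,
# 32 x 24 x 12 grid, 7-voxel fiber slabs (fits a 6-pixel ROI).
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 24L, 12L), voxel_size_mm = c(1, 1, 1),
               csf_halfwidth = 2, region_width = 7, ...)
}

# Four ROIs at the spec's centers with an arbitrary shape/size (the default
# study patterns are too large for the small test phantom).
make_rois <- function(spec, shape = "sphere", size_px = 6) {
  out <- list()
  for (hemi in c("right", "left")) for (reg in c("projection", "association")) {
    out[[paste(hemi, reg, sep = "_")]] <-
      roi_spec(shape, size_px, spec$roi_centers[[paste(hemi, reg, sep = "_")]],
               hemi, reg)
  }
  out
}

# a spec whose tissue is fully isotropic (the method's null)
isotropic_spec <- function(d = 0.8e-3, ...) {
  iso <- c(x = d, y = d, z = d)
  phantom_spec(compartment_diffusivities = list(
    projection = iso, association = iso, csf = iso, background = iso,
    pvs = iso), pvs_fraction = 0, ...)
}

# minimal hand-built acquisition for synthetic signal tests
fake_acquisition <- function(signals, scheme) {
  structure(list(signals = signals, scheme = scheme, snr_b0 = Inf,
                 rotation_deg = 0, scanner_profile = "centurian",
                 averaged = TRUE, affine = diag(4),
                 voxel_size_mm = c(1, 1, 1), seed = NA_integer_),
            class = "dwi_acquisition")
}

# noiseless signals for a set of tensors (rows of `tens6`, order
# xx,yy,zz,xy,xz,yz) under a scheme, arranged on an n x 1 x 1 grid
signals_from_tensors <- function(tens6, scheme, s0 = 100) {
  n <- nrow(tens6)
  nvol <- length(scheme$bvalues)
  S <- matrix(0, n, nvol)
  for (v in seq_len(nvol)) {
    g <- scheme$directions[v, ]
    b <- scheme$bvalues[v]
    q <- b * (g[1]^2 * tens6[, 1] + g[2]^2 * tens6[, 2] + g[3]^2 * tens6[, 3] +
                2 * g[1] * g[2] * tens6[, 4] + 2 * g[1] * g[3] * tens6[, 5] +
                2 * g[2] * g[3] * tens6[, 6])
    S[, v] <- s0 * exp(-q)
  }
  array(S, dim = c(n, 1, 1, nvol))
}

random_spd6 <- function(scale = 1e-3) {
  A <- matrix(rnorm(9, sd = 0.5), 3, 3)
  D <- (A %*% t(A) + diag(3) * 0.2) * scale / 3
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}
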