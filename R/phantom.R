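# Region label codes used throughout the phantom grids
.labels <- c(background = 0L, csf = 1L, projection = 2L, association = 3L)
.t_ref_ms <- 35.7  # reference diffusion time: compartment diffusivities hold here

#' Specify a corona-radiata diffusion phantom
#'
#' Defines the ground truth for the periventricular geometry the ALPS method
#' relies on: at the level of the lateral ventricle body, projection fibers
#' (principal axis z, inferior-superior) lie lateral to the ventricle and
#' association fibers (principal axis y, anterior-posterior) lateral to those,
#' while the perivascular space runs along x (right-left), perpendicular to
#' both fiber systems. Each fiber region is modeled as a two-compartment
#' mixture: an axis-aligned tissue tensor plus an x-aligned perivascular
#' tensor with weight `pvs_fraction`.
#'
#' Diffusion-time dependence is phenomenological, not biophysical: each
#' compartment carries a normalized monotone decay
#' `f(t) = d_inf + (d_0 - d_inf) * exp(-t / tau)` (tau in ms), applied as the
#' ratio `f(t) / f(35.7)` so that `compartment_diffusivities` are the
#' effective values at the standard diffusion time of 35.7 ms. The default
#' coefficients make the perivascular (x-aligned) compartment decay faster
#' than tissue, so the ALPS index falls as diffusion time grows.
#'
#' @param grid_shape integer length-3, voxels per axis (x right-left,
#'   y anterior-posterior, z inferior-superior). All even, so that the
#'   midsagittal plane and ROI centers fall on half-voxel coordinates.
#' @param voxel_size_mm numeric length-3 spacing in mm. Default matches a
#'   200 mm field of view on a 256 in-plane matrix with 3 mm slices.
#' @param compartment_diffusivities named list of length-3 principal
#'   diffusivities (mm^2/s, along x/y/z) for `projection`, `association`,
#'   `csf`, `background` and the perivascular compartment `pvs`.
#' @param pvs_fraction weight in `[0, 1)` of the perivascular compartment in
#'   the projection and association regions.
#' @param time_dependence named list of `c(d_inf, d_0, tau)` normalized decay
#'   coefficients per compartment (see Details).
#' @param csf_halfwidth half-width of the midline CSF slab, voxels.
#' @param region_width width of each fiber slab, voxels.
#' @param assoc_length_frac fraction of the y extent occupied by the
#'   association slab; values below 1 emulate a short superior longitudinal
#'   fasciculus so ROI overrun can be reproduced. Default 1 (off).
#' @param s0 named baseline (b = 0) signal per region, arbitrary units;
#'   background 0 represents air.
#' @param roi_centers optional named list overriding the derived ROI centers;
#'   names `right_projection`, `left_projection`, `right_association`,
#'   `left_association`, each a length-3 voxel coordinate (1-based,
#'   half-voxel values allowed).
#' @param seed integer seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 48L, 24L),
                         voxel_size_mm = c(200 / 256, 200 / 256, 3),
                         compartment_diffusivities = list(
                           projection  = c(x = 0.5e-3, y = 0.5e-3, z = 1.4e-3),
                           association = c(x = 0.5e-3, y = 1.4e-3, z = 0.5e-3),
                           csf         = c(x = 3.0e-3, y = 3.0e-3, z = 3.0e-3),
                           background  = c(x = 0.8e-3, y = 0.8e-3, z = 0.8e-3),
                           pvs         = c(x = 1.5e-3, y = 0.4e-3, z = 0.4e-3)),
                         pvs_fraction = 0.25,
                         time_dependence = list(
                           projection  = c(d_inf = 0.85, d_0 = 1.05, tau = 40),
                           association = c(d_inf = 0.85, d_0 = 1.05, tau = 40),
                           csf         = c(d_inf = 1, d_0 = 1, tau = 1),
                           background  = c(d_inf = 1, d_0 = 1, tau = 1),
                           pvs         = c(d_inf = 0.55, d_0 = 1.05, tau = 30)),
                         csf_halfwidth = 2.5, region_width = 13,
                         assoc_length_frac = 1,
                         s0 = c(background = 0, csf = 150,
                                projection = 100, association = 100),
                         roi_centers = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  if (any(grid_shape %% 2L != 0L))
    stop("`grid_shape` must be even along every axis (half-voxel symmetry)")
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  need <- c("projection", "association", "csf", "background", "pvs")
  if (!all(need %in% names(compartment_diffusivities)))
    stop("`compartment_diffusivities` must name: ", paste(need, collapse = ", "))
  for (nm in need) {
    d <- compartment_diffusivities[[nm]]
    if (length(d) != 3L || any(!is.finite(d)))
      stop("diffusivities for '", nm, "' must be three finite values")
    if (any(d <= 0) || any(d >= 3.2e-3))
      stop("diffusivities for '", nm,
           "' must lie in (0, 3.2e-3) mm^2/s (free water bound)")
  }
  cd <- compartment_diffusivities
  if (!(cd$projection[3] >= cd$projection[1] && cd$projection[3] >= cd$projection[2]))
    stop("projection compartment must have its principal axis along z")
  if (!(cd$association[2] >= cd$association[1] && cd$association[2] >= cd$association[3]))
    stop("association compartment must have its principal axis along y")
  if (!(cd$pvs[1] >= cd$pvs[2] && cd$pvs[1] >= cd$pvs[3]))
    stop("perivascular compartment must have its principal axis along x")
  if (pvs_fraction < 0 || pvs_fraction >= 1)
    stop("`pvs_fraction` must be in [0, 1)")
  if (!all(need %in% names(time_dependence)))
    stop("`time_dependence` must name: ", paste(need, collapse = ", "))
  if (assoc_length_frac <= 0 || assoc_length_frac > 1)
    stop("`assoc_length_frac` must be in (0, 1]")
  x_needed <- 2 * (csf_halfwidth + 2 * region_width)
  if (x_needed > grid_shape[1])
    stop("grid x extent ", grid_shape[1], " too small for geometry (needs >= ",
         ceiling(x_needed), ")")

  mid <- (grid_shape + 1) / 2
  if (is.null(roi_centers)) {
    # half-voxel centers so even-sized ROIs are symmetric; each 13-voxel-wide
    # slab contains a 12-pixel ROI centered half a voxel medial of the slab
    # center
    dproj <- floor(csf_halfwidth + region_width / 2) + 1
    dassoc <- floor(csf_halfwidth + 1.5 * region_width) + 1
    cyz <- c(mid[2], mid[3])
    roi_centers <- list(
      right_projection  = c(mid[1] + dproj, cyz),
      left_projection   = c(mid[1] - dproj, cyz),
      right_association = c(mid[1] + dassoc, cyz),
      left_association  = c(mid[1] - dassoc, cyz))
  }
  need_roi <- c("right_projection", "left_projection",
                "right_association", "left_association")
  if (!all(need_roi %in% names(roi_centers)))
    stop("`roi_centers` must name: ", paste(need_roi, collapse = ", "))
  for (side in c("projection", "association")) {
    r <- roi_centers[[paste0("right_", side)]]
    l <- roi_centers[[paste0("left_", side)]]
    if (abs((r[1] - mid[1]) + (l[1] - mid[1])) > 1e-9 ||
        any(abs(r[2:3] - l[2:3]) > 1e-9))
      stop("left/right ", side,
           " ROI centers are not mirror-symmetric about the midsagittal plane")
  }
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         compartment_diffusivities = cd, pvs_fraction = pvs_fraction,
         time_dependence = time_dependence, csf_halfwidth = csf_halfwidth,
         region_width = region_width, assoc_length_frac = assoc_length_frac,
         s0 = s0, roi_centers = roi_centers, seed = as.integer(seed)),
    class = "phantom_spec")
}

# normalized diffusion-time factor f(t)/f(t_ref)
.time_factor <- function(coefs, t_ms, t_ref = .t_ref_ms) {
  f <- function(t) coefs[["d_inf"]] + (coefs[["d_0"]] - coefs[["d_inf"]]) *
    exp(-t / coefs[["tau"]])
  f(t_ms) / f(t_ref)
}

#' Analytic ALPS index of a phantom specification
#'
#' Closed-form ground truth: the ALPS index
#' `mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)` evaluated directly
#' from the compartment table at the requested diffusion time, without
#' building a grid.
#'
#' @param spec a [phantom_spec()].
#' @param diffusion_time_ms diffusion time in ms (default 35.7, the
#'   reference).
#' @return The scalar index.
#' @export
alps_truth <- function(spec, diffusion_time_ms = .t_ref_ms) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$pvs_fraction
  cd <- spec$compartment_diffusivities
  td <- spec$time_dependence
  gp <- .time_factor(td$projection, diffusion_time_ms)
  ga <- .time_factor(td$association, diffusion_time_ms)
  gv <- .time_factor(td$pvs, diffusion_time_ms)
  dxx_proj  <- (1 - f) * cd$projection[1] * gp + f * cd$pvs[1] * gv
  dyy_proj  <- (1 - f) * cd$projection[2] * gp + f * cd$pvs[2] * gv
  dxx_assoc <- (1 - f) * cd$association[1] * ga + f * cd$pvs[1] * gv
  dzz_assoc <- (1 - f) * cd$association[3] * ga + f * cd$pvs[3] * gv
  unname(((dxx_proj + dxx_assoc) / 2) / ((dyy_proj + dzz_assoc) / 2))
}

# 6-vector order used for symmetric tensors everywhere: xx, yy, zz, xy, xz, yz
.diag6 <- function(d) c(d[1], d[2], d[3], 0, 0, 0)

# 6x6 matrix M such that vec6(R D R^T) = M %*% vec6(D), built by pushing the
# six symmetric basis tensors through the conjugation
.conj6_matrix <- function(R) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  M <- matrix(0, 6, 6)
  for (k in 1:6) {
    B <- matrix(0, 3, 3)
    B[idx[k, 1], idx[k, 2]] <- B[idx[k, 2], idx[k, 1]] <- 1
    Bp <- R %*% B %*% t(R)
    M[, k] <- Bp[cbind(idx[, 1], idx[, 2])]
  }
  M
}

#' Build the phantom tensor field
#'
#' Realizes a [phantom_spec()] on its voxel grid: a region label map
#' (background / CSF / projection / association) and, per voxel, the mixed
#' symmetric diffusion tensor `(1 - w) * D_tissue + w * D_pvs` where `w` is
#' `pvs_fraction` inside the fiber regions and 0 elsewhere. Both compartment
#' grids are retained so diffusion-time scaling and rotations act on each
#' compartment.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `tensor_field` with elements `tensors`
#'   (x,y,z,6 array in the order xx,yy,zz,xy,xz,yz, mm^2/s at the reference
#'   diffusion time), `labels`, `s0`, compartment grids, `affine`,
#'   `voxel_size_mm` and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  mid <- (gs + 1) / 2
  xi <- seq_len(gs[1]) - mid[1]
  yi <- seq_len(gs[2]) - mid[2]
  dx <- abs(array(xi, dim = gs))
  labels <- array(.labels[["background"]], dim = gs)
  labels[dx <= spec$csf_halfwidth] <- .labels[["csf"]]
  labels[dx > spec$csf_halfwidth &
         dx <= spec$csf_halfwidth + spec$region_width] <- .labels[["projection"]]
  assoc <- dx > spec$csf_halfwidth + spec$region_width &
    dx <= spec$csf_halfwidth + 2 * spec$region_width
  if (spec$assoc_length_frac < 1) {
    ylim <- spec$assoc_length_frac * gs[2] / 2
    dy <- abs(array(rep(yi, each = gs[1]), dim = gs))
    assoc <- assoc & dy <= ylim
  }
  labels[assoc] <- .labels[["association"]]

  cd <- spec$compartment_diffusivities
  nvox <- prod(gs)
  tissue <- matrix(0, nvox, 6)
  lab <- as.vector(labels)
  for (nm in c("background", "csf", "projection", "association")) {
    sel <- lab == .labels[[nm]]
    if (any(sel))
      tissue[sel, ] <- matrix(.diag6(cd[[nm]]), sum(sel), 6, byrow = TRUE)
  }
  w <- ifelse(lab %in% .labels[c("projection", "association")],
              spec$pvs_fraction, 0)
  pvs6 <- .diag6(cd$pvs)
  tensors <- (1 - w) * tissue + outer(w, pvs6)
  s0 <- array(spec$s0[names(.labels)[match(lab, .labels)]], dim = gs)

  field <- structure(
    list(tensors = array(tensors, dim = c(gs, 6)),
         labels = labels, s0 = s0,
         comp_tissue = array(tissue, dim = c(gs, 6)),
         pvs_tensor = pvs6,
         pvs_weight = array(w, dim = gs),
         affine = .phantom_affine(gs, spec$voxel_size_mm),
         voxel_size_mm = spec$voxel_size_mm,
         rotation_deg = 0, spec = spec),
    class = "tensor_field")

  for (nm in names(spec$roi_centers)) {
    ctr <- spec$roi_centers[[nm]]
    v <- pmin(pmax(round(ctr), 1), gs)
    want <- if (grepl("projection", nm)) .labels[["projection"]] else
      .labels[["association"]]
    if (labels[v[1], v[2], v[3]] != want)
      stop("ROI center '", nm, "' at (", paste(ctr, collapse = ", "),
           ") falls outside its labeled region")
  }
  field
}

# RAS+ voxel -> mm affine with the grid center at the origin
.phantom_affine <- function(grid_shape, voxel_size) {
  A <- diag(4)
  A[cbind(1:3, 1:3)] <- voxel_size
  A[1:3, 4] <- -voxel_size * (grid_shape + 1) / 2
  A
}

#' Effective tensors at a diffusion time
#'
#' Applies the per-compartment normalized diffusion-time decay to the tissue
#' and perivascular compartments and returns the mixed tensor grid.
#'
#' @param field a `tensor_field`.
#' @param diffusion_time_ms diffusion time in ms.
#' @return An (x,y,z,6) array, mm^2/s.
#' @export
effective_tensors <- function(field, diffusion_time_ms = .t_ref_ms) {
  stopifnot(inherits(field, "tensor_field"))
  td <- field$spec$time_dependence
  lab <- as.vector(field$labels)
  g <- numeric(length(lab))
  for (nm in names(.labels)) {
    sel <- lab == .labels[[nm]]
    if (any(sel)) g[sel] <- .time_factor(td[[nm]], diffusion_time_ms)
  }
  gv <- .time_factor(td$pvs, diffusion_time_ms)
  gs <- dim(field$labels)
  tissue <- matrix(field$comp_tissue, ncol = 6)
  w <- as.vector(field$pvs_weight)
  pvs <- if (is.matrix(field$pvs_tensor)) field$pvs_tensor else
    matrix(field$pvs_tensor, length(w), 6, byrow = TRUE)
  out <- (1 - w) * g * tissue + (w * gv) * pvs
  if (any(!is.finite(out)))
    stop("non-finite diffusivity after diffusion-time model at t = ",
         diffusion_time_ms, " ms")
  array(out, dim = c(gs, 6))
}

#' Pitch the phantom anatomy relative to the imaging frame
#'
#' Conjugates every tensor by a rotation about the x (right-left) axis,
#' `D' = R D R^T`, and resamples the label/compartment geometry under the
#' same rotation (nearest neighbor, in physical coordinates about the grid
#' center). This models both the chin-up head position and an imaging-plane
#' tilt (e.g. infra-orbital-meatal vs AC-PC line), since the motion-probing
#' gradients are aligned to the imaging plane: either way the anatomy is
#' pitched relative to the gradient frame.
#'
#' @param field a `tensor_field`.
#' @param pitch_deg pitch angle in degrees, `|pitch_deg| <= 45`. Positive =
#'   chin-up.
#' @return A rotated `tensor_field`; `rotation_deg` accumulates.
#' @export
apply_head_rotation <- function(field, pitch_deg) {
  stopifnot(inherits(field, "tensor_field"))
  if (abs(pitch_deg) > 45)
    stop("|pitch_deg| must be <= 45, got ", pitch_deg)
  if (pitch_deg == 0) return(field)
  th <- pitch_deg * pi / 180
  R <- rbind(c(1, 0, 0),
             c(0, cos(th), -sin(th)),
             c(0, sin(th), cos(th)))
  gs <- dim(field$labels)
  mid <- (gs + 1) / 2
  vs <- field$voxel_size_mm

  # nearest-neighbor pull-back: target voxel <- anatomy at R^{-1} offset
  ijk <- as.matrix(expand.grid(i = seq_len(gs[1]), j = seq_len(gs[2]),
                               k = seq_len(gs[3])))
  p <- sweep(ijk, 2, mid) * rep(vs, each = nrow(ijk))
  src <- p %*% R  # p %*% R == t(R^{-1} %*% t(p)) for rotation matrices
  srci <- round(sweep(src / rep(vs, each = nrow(src)), 2, mid, `+`))
  inside <- srci[, 1] >= 1 & srci[, 1] <= gs[1] &
    srci[, 2] >= 1 & srci[, 2] <= gs[2] &
    srci[, 3] >= 1 & srci[, 3] <= gs[3]
  srci[!inside, ] <- 1L
  lin <- (srci[, 3] - 1) * gs[1] * gs[2] + (srci[, 2] - 1) * gs[1] + srci[, 1]

  lab <- as.vector(field$labels)[lin]
  lab[!inside] <- .labels[["background"]]
  s0 <- as.vector(field$s0)[lin]
  s0[!inside] <- field$spec$s0[["background"]]
  w <- as.vector(field$pvs_weight)[lin]
  w[!inside] <- 0
  tissue <- matrix(field$comp_tissue, ncol = 6)[lin, , drop = FALSE]
  bg6 <- .diag6(field$spec$compartment_diffusivities$background)
  tissue[!inside, ] <- matrix(bg6, sum(!inside), 6, byrow = TRUE)

  M <- .conj6_matrix(R)
  tissue <- tissue %*% t(M)
  pvs6 <- as.vector(M %*% field$pvs_tensor)
  tensors <- (1 - w) * tissue + outer(w, pvs6)

  field$labels <- array(lab, dim = gs)
  field$s0 <- array(s0, dim = gs)
  field$pvs_weight <- array(w, dim = gs)
  field$comp_tissue <- array(tissue, dim = c(gs, 6))
  field$pvs_tensor <- pvs6
  field$tensors <- array(tensors, dim = c(gs, 6))
  field$rotation_deg <- field$rotation_deg + pitch_deg
  field
}

# evaluate b * g' D g for all voxels at once; tens is nvox x 6
.bquad <- function(tens, g, b) {
  b * (g[1]^2 * tens[, 1] + g[2]^2 * tens[, 2] + g[3]^2 * tens[, 3] +
         2 * g[1] * g[2] * tens[, 4] + 2 * g[1] * g[3] * tens[, 5] +
         2 * g[2] * g[3] * tens[, 6])
}

# scanner noise profiles: multiplicative factor on the b=0 SNR
.scanner_profiles <- c(centurian = 1.0, prisma = 0.9)

#' Simulate a diffusion-weighted acquisition
#'
#' Per voxel and volume the noiseless magnitude is
#' `S = S0 * exp(-b * g' D(t) g)` with `D(t)` the phantom's effective tensor
#' at the scheme's diffusion time. Rician noise at the stated b = 0
#' signal-to-noise ratio is added independently per average
#' (`M = sqrt((S + n1)^2 + n2^2)`, `n1, n2 ~ N(0, sigma^2)`), and magnitudes
#' are averaged before storage, matching scanner behavior. The scanner
#' profile rescales the SNR only; the signal model is shared.
#'
#' @param field a `tensor_field`.
#' @param scheme a [gradient_scheme()].
#' @param snr_b0 signal-to-noise ratio at b = 0 in tissue; `Inf` for a
#'   noiseless acquisition.
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @param scanner_profile `"centurian"` or `"prisma"`.
#' @param raw if `TRUE`, store every average as its own volume instead of
#'   averaging.
#' @return An object of class `dwi_acquisition`: `signals` (x,y,z,volume),
#'   the `scheme`, noise and geometry metadata.
#' @export
simulate_dwi <- function(field, scheme, snr_b0 = 40, seed = 1L,
                         scanner_profile = "centurian", raw = FALSE) {
  stopifnot(inherits(field, "tensor_field"), inherits(scheme, "gradient_scheme"))
  if (!is.infinite(snr_b0) && snr_b0 <= 0) stop("`snr_b0` must be positive")
  if (!scanner_profile %in% names(.scanner_profiles))
    stop("unknown scanner profile '", scanner_profile, "' (supported: ",
         paste(names(.scanner_profiles), collapse = ", "), ")")
  gs <- dim(field$labels)
  nvox <- prod(gs)
  tens <- matrix(effective_tensors(field, scheme$diffusion_time_ms), ncol = 6)
  s0 <- as.vector(field$s0)
  nvol <- length(scheme$bvalues)
  clean <- matrix(0, nvox, nvol)
  for (v in seq_len(nvol)) {
    bv <- scheme$bvalues[v]
    clean[, v] <- if (bv == 0) s0 else
      s0 * exp(-.bquad(tens, scheme$directions[v, ], bv))
  }
  navg <- scheme$averages
  if (is.infinite(snr_b0)) {
    signals <- if (raw) clean[, rep(seq_len(nvol), each = navg)] else clean
  } else {
    s0_ref <- field$spec$s0[["projection"]]
    sigma <- s0_ref / (snr_b0 * .scanner_profiles[[scanner_profile]])
    signals <- .with_seed(seed, {
      if (raw) {
        out <- matrix(0, nvox, nvol * navg)
        for (v in seq_len(nvol)) for (a in seq_len(navg)) {
          out[, (v - 1) * navg + a] <-
            sqrt((clean[, v] + stats::rnorm(nvox, sd = sigma))^2 +
                   stats::rnorm(nvox, sd = sigma)^2)
        }
        out
      } else {
        out <- matrix(0, nvox, nvol)
        for (v in seq_len(nvol)) {
          acc <- numeric(nvox)
          for (a in seq_len(navg)) {
            acc <- acc + sqrt((clean[, v] + stats::rnorm(nvox, sd = sigma))^2 +
                                stats::rnorm(nvox, sd = sigma)^2)
          }
          out[, v] <- acc / navg
        }
        out
      }
    })
  }
  structure(
    list(signals = array(signals, dim = c(gs, ncol(signals))),
         scheme = scheme, snr_b0 = snr_b0,
         rotation_deg = field$rotation_deg,
         scanner_profile = scanner_profile,
         averaged = !raw, affine = field$affine,
         voxel_size_mm = field$voxel_size_mm, seed = as.integer(seed)),
    class = "dwi_acquisition")
}

#' @rdname simulate_dwi
#' @param object a `tensor_field` (for the [stats::simulate()] generic).
#' @param nsim number of realizations.
#' @param ... passed on to [simulate_dwi()] (`scheme`, `snr_b0`,
#'   `scanner_profile`, `raw`).
#' @return `simulate()` returns a list of `nsim` acquisitions.
#' @export
simulate.tensor_field <- function(object, nsim = 1, seed = 1L, ...) {
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, nsim))
  lapply(seeds, function(s) simulate_dwi(object, seed = s, ...))
}

# run code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Corona-radiata phantom spec\n")
  cat(sprintf("  grid %s voxels, voxel size %s mm\n",
              paste(x$grid_shape, collapse = " x "),
              paste(signif(x$voxel_size_mm, 4), collapse = " x ")))
  cat(sprintf("  perivascular fraction %.2f; analytic ALPS index %.4f at %g ms\n",
              x$pvs_fraction, alps_truth(x), .t_ref_ms))
  invisible(x)
}

#' @export
print.tensor_field <- function(x, ...) {
  tab <- table(factor(names(.labels)[match(as.vector(x$labels), .labels)],
                      levels = names(.labels)))
  cat("Phantom tensor field:",
      paste(dim(x$labels), collapse = " x "), "voxels\n")
  cat("  voxels per region:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  if (x$rotation_deg != 0)
    cat(sprintf("  pitched %g degrees about x\n", x$rotation_deg))
  invisible(x)
}

#' @export
print.dwi_acquisition <- function(x, ...) {
  cat("Simulated DWI acquisition:", x$scheme$label, "\n")
  cat(sprintf("  %s voxels x %d volumes (%s), SNR(b0) = %g, scanner '%s'\n",
              paste(dim(x$signals)[1:3], collapse = " x "),
              dim(x$signals)[4],
              if (x$averaged) "magnitude-averaged" else "raw averages",
              x$snr_b0, x$scanner_profile))
  if (x$rotation_deg != 0)
    cat(sprintf("  anatomy pitched %g degrees\n", x$rotation_deg))
  invisible(x)
}
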