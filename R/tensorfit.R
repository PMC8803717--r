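#' Log-linear diffusion tensor fit
#'
#' Fits the single-tensor model `ln S = ln S0 - b g' D g` per voxel by
#' ordinary least squares over the six unique tensor elements plus `ln S0`.
#' Voxels containing any nonpositive signal are masked out rather than
#' clamped, and negative fitted diagonal elements are retained in the result
#' (downstream ROI statistics exclude them through the fit mask). No
#' weighting and no spatial smoothing are applied.
#'
#' @param acq a `dwi_acquisition` (simulated via [simulate_dwi()] or read via
#'   [read_dwi()]). Needs at least 6 distinct nonzero gradient directions and
#'   one b = 0 volume; 3-axis data must go through
#'   [maps_from_three_axis()] instead.
#' @return An object of class `dti_fit` with `tensor_elements`
#'   (x,y,z,6 array ordered xx,yy,zz,xy,xz,yz), `s0`, logical `fit_mask`,
#'   `residual_rms` (RMS log-signal residual) and the design metadata.
#' @seealso [diffusivity_maps()], [maps_from_three_axis()]
#' @export
fit_dti <- function(acq) {
  stopifnot(inherits(acq, "dwi_acquisition"))
  scheme <- acq$scheme
  if (scheme$n_axes < 6L)
    stop("tensor fit needs >= 6 distinct nonzero directions (got ",
         scheme$n_axes, "); use maps_from_three_axis() for the 3-axis path")
  if (!any(scheme$bvalues == 0))
    stop("tensor fit needs at least one b = 0 volume")
  B <- .dti_design(scheme)
  if (nrow(B) < 7L)
    stop("tensor fit needs >= 7 usable volumes, got ", nrow(B))
  gs <- dim(acq$signals)[1:3]
  nvol <- dim(acq$signals)[4]
  if (nvol != nrow(B))
    stop("volume count ", nvol, " does not match scheme (", nrow(B), ")")
  S <- matrix(acq$signals, ncol = nvol)
  ok <- rowSums(S <= 0 | !is.finite(S)) == 0
  qrB <- qr(B)
  if (qrB$rank < 7L) stop("rank-deficient gradient design matrix")
  coef <- matrix(NA_real_, 7, nrow(S))
  resid_rms <- rep(NA_real_, nrow(S))
  if (any(ok)) {
    Y <- t(log(S[ok, , drop = FALSE]))
    cf <- qr.coef(qrB, Y)
    coef[, ok] <- cf
    res <- Y - B %*% cf
    resid_rms[ok] <- sqrt(colMeans(res^2))
  }
  structure(
    list(tensor_elements = array(t(coef[2:7, , drop = FALSE]), dim = c(gs, 6)),
         s0 = array(exp(coef[1, ]), dim = gs),
         fit_mask = array(ok, dim = gs),
         residual_rms = array(resid_rms, dim = gs),
         scheme = scheme, affine = acq$affine,
         voxel_size_mm = acq$voxel_size_mm,
         n_volumes = nvol),
    class = "dti_fit")
}

# design matrix: columns (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
.dti_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Directional diffusivity maps from a tensor fit
#'
#' Extracts the tensor diagonal in the scanner frame — Dxx (right-left), Dyy
#' (anterior-posterior), Dzz (inferior-superior) — without any eigen-rotation,
#' plus fractional anisotropy and mean diffusivity from the tensor
#' invariants. The ROI mask excludes voxels where the fit failed or produced
#' a nonpositive diagonal element.
#'
#' @param fit a `dti_fit`.
#' @return An object of class `diffusivity_maps` (`source = "tensor"`).
#' @export
diffusivity_maps <- function(fit) {
  stopifnot(inherits(fit, "dti_fit"))
  te <- matrix(fit$tensor_elements, ncol = 6)
  dxx <- te[, 1]; dyy <- te[, 2]; dzz <- te[, 3]
  md <- (dxx + dyy + dzz) / 3
  # FA from rotation invariants: sum (lambda - md)^2 = ||D - md I||_F^2
  fro2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (te[, 4]^2 + te[, 5]^2 + te[, 6]^2)
  dev2 <- pmax(0, fro2 - 3 * md^2)
  fa <- sqrt(1.5 * dev2 / pmax(fro2, .Machine$double.xmin))
  gs <- dim(fit$fit_mask)
  mask <- fit$fit_mask & array(dxx > 0 & dyy > 0 & dzz > 0, dim = gs)
  mask[is.na(mask)] <- FALSE
  structure(
    list(dxx = array(dxx, gs), dyy = array(dyy, gs), dzz = array(dzz, gs),
         fa = array(fa, gs), md = array(md, gs),
         fit_mask = mask, source = "tensor",
         scheme_label = fit$scheme$label, affine = fit$affine,
         voxel_size_mm = fit$voxel_size_mm),
    class = "diffusivity_maps")
}

#' Per-axis ADC maps from a 3-axis acquisition
#'
#' The DWI path: for data acquired with exactly the orthogonal x, y, z
#' motion-probing gradients the per-axis apparent diffusion coefficient
#' `ADC_i = -ln(S_i / S0) / b` is computed from the averaged magnitude
#' images, with `S0` the mean of all b = 0 volumes. A tensor cannot be
#' estimated from three directions, so no FA is produced; the result is
#' labeled `source = "three_axis_adc"` so ADC-derived and tensor-derived
#' indices are never pooled unlabeled.
#'
#' @param acq a 3-axis `dwi_acquisition`.
#' @return A `diffusivity_maps` object with `fa = NULL`.
#' @export
maps_from_three_axis <- function(acq) {
  stopifnot(inherits(acq, "dwi_acquisition"))
  scheme <- acq$scheme
  if (scheme$n_axes != 3L)
    stop("three-axis path needs exactly 3 distinct directions, got ",
         scheme$n_axes)
  g <- scheme$directions
  b <- scheme$bvalues
  dwi <- which(b > 0)
  axes <- apply(abs(g[dwi, , drop = FALSE]), 1, which.max)
  aligned <- vapply(seq_along(dwi), function(r) {
    d <- abs(g[dwi[r], ]); d[axes[r]] > 1 - 1e-8 && sum(d) < 1 + 1e-8
  }, logical(1))
  if (!all(aligned) || length(unique(axes)) != 3L)
    stop("three-axis path needs the coordinate axes as gradient directions")
  gs <- dim(acq$signals)[1:3]
  nvol <- dim(acq$signals)[4]
  S <- matrix(acq$signals, ncol = nvol)
  s0 <- rowMeans(S[, b == 0, drop = FALSE])
  adc <- matrix(NA_real_, nrow(S), 3)
  for (ax in 1:3) {
    cols <- dwi[axes == ax]
    Si <- rowMeans(S[, cols, drop = FALSE])
    adc[, ax] <- -log(Si / s0) / b[cols[1]]
  }
  mask <- s0 > 0 & rowSums(S[, dwi, drop = FALSE] <= 0) == 0
  mask <- mask & is.finite(rowSums(adc))
  structure(
    list(dxx = array(adc[, 1], gs), dyy = array(adc[, 2], gs),
         dzz = array(adc[, 3], gs), fa = NULL,
         md = array(rowMeans(adc), gs),
         fit_mask = array(mask, gs), source = "three_axis_adc",
         scheme_label = scheme$label, affine = acq$affine,
         voxel_size_mm = acq$voxel_size_mm),
    class = "diffusivity_maps")
}

#' @export
coef.dti_fit <- function(object, ...) object$tensor_elements

#' @export
predict.dti_fit <- function(object, ...) {
  B <- .dti_design(object$scheme)
  te <- matrix(object$tensor_elements, ncol = 6)
  lnS <- cbind(log(as.vector(object$s0)), te) %*% t(B)
  array(exp(lnS), dim = c(dim(object$fit_mask), nrow(B)))
}

#' @export
residuals.dti_fit <- function(object, ...) object$residual_rms

#' @export
print.dti_fit <- function(x, ...) {
  cat("Log-linear diffusion tensor fit:", x$scheme$label, "\n")
  cat(sprintf("  %s voxels, %d volumes; %d voxels in fit mask (%.1f%%)\n",
              paste(dim(x$fit_mask), collapse = " x "), x$n_volumes,
              sum(x$fit_mask), 100 * mean(x$fit_mask)))
  cat(sprintf("  median RMS log-signal residual (in mask): %.3g\n",
              stats::median(x$residual_rms[x$fit_mask])))
  invisible(x)
}

#' @export
summary.dti_fit <- function(object, ...) {
  m <- diffusivity_maps(object)
  msk <- m$fit_mask
  out <- list(
    n_voxels = length(msk), n_in_mask = sum(msk),
    median_md = stats::median(m$md[msk]),
    median_fa = stats::median(m$fa[msk]),
    median_residual_rms = stats::median(object$residual_rms[msk]))
  class(out) <- "summary.dti_fit"
  out
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat("Tensor fit summary\n")
  cat(sprintf("  in-mask voxels: %d / %d\n", x$n_in_mask, x$n_voxels))
  cat(sprintf("  median MD: %.4g mm^2/s, median FA: %.3f\n",
              x$median_md, x$median_fa))
  cat(sprintf("  median RMS log residual: %.3g\n", x$median_residual_rms))
  invisible(x)
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  cat("Diffusivity maps (source:", x$source, ")\n")
  cat(sprintf("  %s voxels, %d in mask; FA %s\n",
              paste(dim(x$dxx), collapse = " x "), sum(x$fit_mask),
              if (is.null(x$fa)) "absent (3-axis ADC path)" else "present"))
  invisible(x)
}
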