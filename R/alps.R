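#' Measurement ROI specification
#'
#' One ALPS measurement ROI: a sphere or cube (3D) or a single-slice square,
#' sized in in-plane pixels, centered on a voxel coordinate (half-voxel
#' centers are the convention for even sizes so that all shapes sharing a
#' center are symmetric), in one hemisphere and fiber region.
#'
#' @param shape `"sphere"`, `"cube"` or `"square"`.
#' @param size_px diameter (sphere) or side (cube/square) in in-plane pixels;
#'   the study patterns use 12 and 8.
#' @param center length-3 voxel coordinate (1-based; may be half-integer).
#' @param hemisphere `"left"` or `"right"`.
#' @param region `"projection"` or `"association"`.
#' @param plane_index axial slice index for squares; defaults to the slice
#'   containing (or just below) the z center.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(shape, size_px, center, hemisphere, region,
                     plane_index = NULL) {
  shape <- match.arg(shape, c("sphere", "cube", "square"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  region <- match.arg(region, c("projection", "association"))
  stopifnot(length(center) == 3L, all(is.finite(center)), size_px > 0)
  if (shape == "square" && is.null(plane_index))
    plane_index <- as.integer(floor(center[3]))
  structure(list(shape = shape, size_px = size_px,
                 center = as.numeric(center), hemisphere = hemisphere,
                 region = region, plane_index = plane_index),
            class = "roi_spec")
}

#' Rasterize an ROI to a voxel mask
#'
#' Membership uses center-of-voxel distance in in-plane pixel units, with the
#' through-plane offset scaled by the spacing ratio so the ROI is isotropic
#' in physical space: a sphere keeps voxels with scaled Euclidean distance
#' `<= size_px / 2`, a cube bounds each scaled axis offset by `size_px / 2`,
#' and a square is the cube restricted to one axial slice. All shapes sharing
#' a center produce exactly co-centered masks.
#'
#' @param spec a [roi_spec()].
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_size_mm numeric length-3 spacing (mm); only the z/x ratio
#'   matters.
#' @return A logical (x,y,z) array with attribute `truncated` set (and a
#'   warning raised) if the ROI extent crosses the grid boundary.
#' @export
roi_mask <- function(spec, grid_shape, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(spec, "roi_spec"))
  gs <- as.integer(grid_shape)
  ctr <- spec$center
  if (any(ctr < 1) || any(ctr > gs))
    stop("ROI center (", paste(ctr, collapse = ", "), ") outside grid")
  r <- spec$size_px / 2
  zscale <- voxel_size_mm[3] / voxel_size_mm[1]
  dx <- seq_len(gs[1]) - ctr[1]
  dy <- seq_len(gs[2]) - ctr[2]
  dz <- (seq_len(gs[3]) - ctr[3]) * zscale
  DX <- array(dx, dim = gs)
  DY <- array(rep(dy, each = gs[1]), dim = gs)
  DZ <- array(rep(dz, each = gs[1] * gs[2]), dim = gs)
  mask <- switch(spec$shape,
    sphere = DX^2 + DY^2 + DZ^2 <= r^2,
    cube = abs(DX) <= r & abs(DY) <= r & abs(DZ) <= r,
    square = {
      m <- abs(DX) <= r & abs(DY) <= r
      sl <- array(FALSE, gs)
      sl[, , spec$plane_index] <- TRUE
      m & sl
    })
  truncated <- ctr[1] - r < 0.5 || ctr[1] + r > gs[1] + 0.5 ||
    ctr[2] - r < 0.5 || ctr[2] + r > gs[2] + 0.5 ||
    (spec$shape != "square" &&
       (ctr[3] - r / zscale < 0.5 || ctr[3] + r / zscale > gs[3] + 0.5))
  if (truncated)
    warning("ROI (", spec$hemisphere, " ", spec$region,
            ") truncated by the grid boundary")
  attr(mask, "truncated") <- truncated
  mask
}

#' The six study ROI patterns
#'
#' @return Character vector of pattern names: large/small x
#'   sphere/cube/square. "Large" is 12 in-plane pixels (about 9.4 mm at a
#'   200 mm FOV on a 256 matrix), "small" is 8 (about 6.3 mm).
#' @export
roi_patterns <- function() {
  c("large_sphere", "small_sphere", "large_cube", "small_cube",
    "large_square", "small_square")
}

.pattern_shape <- function(pattern) {
  parts <- strsplit(pattern, "_", fixed = TRUE)[[1]]
  list(size_px = if (parts[1] == "large") 12 else 8, shape = parts[2])
}

#' Default ROI set for a phantom
#'
#' Builds the four measurement ROIs (hemisphere x region) of one pattern at
#' the phantom's ROI centers. For real data, supply your own centers via
#' [roi_spec()].
#'
#' @param spec a [phantom_spec()] (or a `tensor_field`, whose spec is used).
#' @param pattern one of [roi_patterns()].
#' @return List of four [roi_spec()] objects.
#' @export
default_rois <- function(spec, pattern = "large_sphere") {
  if (inherits(spec, "tensor_field")) spec <- spec$spec
  stopifnot(inherits(spec, "phantom_spec"))
  pattern <- match.arg(pattern, roi_patterns())
  ps <- .pattern_shape(pattern)
  out <- list()
  for (hemi in c("right", "left")) for (reg in c("projection", "association")) {
    ctr <- spec$roi_centers[[paste(hemi, reg, sep = "_")]]
    out[[paste(hemi, reg, sep = "_")]] <-
      roi_spec(ps$shape, ps$size_px, ctr, hemi, reg)
  }
  out
}

#' ROI-mean diffusivities
#'
#' Means of Dxx/Dyy/Dzz over each ROI mask intersected with the fit mask.
#'
#' @param maps a `diffusivity_maps` object.
#' @param rois list of [roi_spec()] objects.
#' @return Data frame with one row per ROI: hemisphere, region, shape,
#'   size_px, n_voxels (in-mask), truncated flag, and mean dxx/dyy/dzz.
#' @export
measure_rois <- function(maps, rois) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  gs <- dim(maps$dxx)
  rows <- lapply(rois, function(spec) {
    m <- roi_mask(spec, gs, maps$voxel_size_mm)
    sel <- m & maps$fit_mask
    if (!any(sel))
      stop("ROI (", spec$hemisphere, " ", spec$region, ", ", spec$shape,
           " ", spec$size_px, "px) has no usable voxels after masking")
    data.frame(hemisphere = spec$hemisphere, region = spec$region,
               shape = spec$shape, size_px = spec$size_px,
               n_voxels = sum(sel),
               truncated = isTRUE(attr(m, "truncated")),
               dxx = mean(maps$dxx[sel]), dyy = mean(maps$dyy[sel]),
               dzz = mean(maps$dzz[sel]))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' ALPS index from ROI means
#'
#' Per hemisphere, `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj,
#' Dzz_assoc)`: diffusivity along the perivascular direction (x) in the
#' projection- and association-fiber areas over diffusivity perpendicular to
#' both the fibers and the perivascular space (y in the projection area, z in
#' the association area). The bilateral index is the mean of the two
#' unilateral indices.
#'
#' @param means data frame from [measure_rois()] containing, per evaluated
#'   hemisphere, one `projection` and one `association` row.
#' @param source label propagated from the maps (`"tensor"` or
#'   `"three_axis_adc"`), kept so indices from the two pipelines are never
#'   pooled unlabeled.
#' @param provenance optional free-text provenance label.
#' @return An object of class `alps_result` with per-hemisphere component
#'   diffusivities, `alps_r`, `alps_l`, `alps_bil` and voxel counts.
#' @export
compute_alps <- function(means, source = "tensor", provenance = "") {
  res <- list(source = source, provenance = provenance)
  counts <- list()
  for (hemi in c("right", "left")) {
    proj <- means[means$hemisphere == hemi & means$region == "projection", ]
    asso <- means[means$hemisphere == hemi & means$region == "association", ]
    if (nrow(proj) != 1L || nrow(asso) != 1L) {
      res[[paste0("alps_", substr(hemi, 1, 1))]] <- NA_real_
      next
    }
    comp <- c(dxx_proj = proj$dxx, dxx_assoc = asso$dxx,
              dyy_proj = proj$dyy, dzz_assoc = asso$dzz)
    if (any(comp <= 0))
      stop("nonpositive component diffusivity in ", hemi,
           " hemisphere; ALPS index undefined")
    res[[paste0("components_", hemi)]] <- comp
    res[[paste0("alps_", substr(hemi, 1, 1))]] <-
      ((comp[["dxx_proj"]] + comp[["dxx_assoc"]]) / 2) /
      ((comp[["dyy_proj"]] + comp[["dzz_assoc"]]) / 2)
    counts[[hemi]] <- c(projection = proj$n_voxels, association = asso$n_voxels)
  }
  if (is.null(res$alps_r)) res$alps_r <- NA_real_
  if (is.null(res$alps_l)) res$alps_l <- NA_real_
  res$alps_bil <- mean(c(res$alps_r, res$alps_l))
  res$roi_voxel_counts <- counts
  structure(res, class = "alps_result")
}

#' Compute the ALPS index from diffusivity maps
#'
#' Convenience wrapper: measures the ROI set on the maps and evaluates the
#' index.
#'
#' @param maps a `diffusivity_maps` object.
#' @param rois list of [roi_spec()] (e.g. [default_rois()]).
#' @return An `alps_result`.
#' @export
alps_index <- function(maps, rois) {
  means <- measure_rois(maps, rois)
  compute_alps(means, source = maps$source, provenance = maps$scheme_label)
}

#' Physical ROI diameter
#'
#' Converts an ROI size in pixels to millimetres for a given field of view
#' and reconstruction matrix (pixel spacing = FOV / matrix).
#'
#' @param size_px size in pixels.
#' @param fov_mm field of view in mm (default 200).
#' @param matrix_size in-plane matrix after interpolation (default 256).
#' @return Diameter in mm.
#' @examples
#' roi_physical_diameter(12)  # ~9.4 mm
#' roi_physical_diameter(8)   # ~6.3 mm
#' @export
roi_physical_diameter <- function(size_px, fov_mm = 200, matrix_size = 256) {
  size_px * fov_mm / matrix_size
}

#' @export
print.alps_result <- function(x, ...) {
  cat("ALPS index (", x$source, ")\n", sep = "")
  cat(sprintf("  right %.4f  left %.4f  bilateral %.4f\n",
              x$alps_r, x$alps_l, x$alps_bil))
  for (hemi in c("right", "left")) {
    comp <- x[[paste0("components_", hemi)]]
    if (!is.null(comp))
      cat(sprintf("  %s: Dxx(proj) %.4g  Dxx(assoc) %.4g  Dyy(proj) %.4g  Dzz(assoc) %.4g\n",
                  hemi, comp[["dxx_proj"]], comp[["dxx_assoc"]],
                  comp[["dyy_proj"]], comp[["dzz_assoc"]]))
  }
  invisible(x)
}
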