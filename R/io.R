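#' Read a diffusion acquisition from NIfTI + bval/bvec
#'
#' Reads a 4D NIfTI-1 volume together with FSL-dialect gradient tables
#' (`.bval`: one whitespace-separated row of b-values; `.bvec`: three rows of
#' x, y, z components). Volume counts must agree across the three files, and
#' every nonzero-b direction must be unit length within 1e-3 (it is then
#' renormalized exactly).
#'
#' @param nifti_path path to the 4D image.
#' @param bval_path,bvec_path paths to the gradient tables.
#' @param averages,te_ms,diffusion_time_ms scheme metadata not carried by
#'   the FSL dialect; supply if known.
#' @return A `dwi_acquisition`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, averages = 1L,
                     te_ms = NA_real_, diffusion_time_ms = NA_real_) {
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D volume in ", nifti_path, ", got ",
         length(dim(arr)), "D")
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L)
    stop("bvec file ", bvec_path, " must have 3 rows (x, y, z), has ",
         nrow(bvecs))
  nvol <- dim(arr)[4]
  if (length(bvals) != nvol)
    stop("volume count mismatch: ", nvol, " volumes in ", nifti_path,
         " vs ", length(bvals), " entries in ", bval_path)
  if (ncol(bvecs) != nvol)
    stop("volume count mismatch: ", nvol, " volumes in ", nifti_path,
         " vs ", ncol(bvecs), " entries in ", bvec_path)
  dirs <- t(bvecs)
  nrm <- sqrt(rowSums(dirs^2))
  dwi <- bvals > 0
  if (any(abs(nrm[dwi] - 1) > 1e-3))
    stop("non-unit gradient direction in ", bvec_path,
         " (tolerance 1e-3): norms ",
         paste(signif(nrm[dwi][abs(nrm[dwi] - 1) > 1e-3], 4), collapse = ", "))
  dirs[dwi, ] <- dirs[dwi, , drop = FALSE] / nrm[dwi]
  scheme <- gradient_scheme(dirs, bvals, averages = averages, te_ms = te_ms,
                            diffusion_time_ms = diffusion_time_ms,
                            label = basename(nifti_path))
  pd <- attr(img, "pixdim")
  vs <- if (!is.null(pd) && length(pd) >= 3) abs(pd[1:3]) else c(1, 1, 1)
  structure(
    list(signals = arr, scheme = scheme, snr_b0 = NA_real_,
         rotation_deg = 0, scanner_profile = NA_character_,
         averaged = TRUE, affine = structure(RNifti::xform(img),
                                             dimnames = NULL),
         voxel_size_mm = vs, seed = NA_integer_),
    class = "dwi_acquisition")
}

.write_nifti <- function(arr, path, affine, voxel_size) {
  img <- RNifti::asNifti(arr, reference = NULL)
  if (!is.null(affine)) {
    af <- structure(affine, code = 2L)
    img <- RNifti::`sform<-`(img, af)
    img <- RNifti::`qform<-`(img, af)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a diffusion acquisition as NIfTI + bval/bvec
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval` and `<prefix>.bvec` in the FSL
#' dialect (bvec rows = x, y, z). Existing files are never silently
#' overwritten.
#'
#' @param acq a `dwi_acquisition`.
#' @param prefix output path prefix.
#' @param overwrite allow replacing existing files.
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(acq, prefix, overwrite = FALSE) {
  stopifnot(inherits(acq, "dwi_acquisition"))
  paths <- paste0(prefix, c(".nii.gz", ".bval", ".bvec"))
  .check_overwrite(paths, overwrite)
  .write_nifti(acq$signals, paths[1], acq$affine, acq$voxel_size_mm)
  bv <- acq$scheme$bvalues
  writeLines(paste(format(bv, trim = TRUE), collapse = " "), paths[2])
  dirs <- t(acq$scheme$directions)
  writeLines(apply(dirs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), paths[3])
  invisible(prefix)
}

#' Write diffusivity maps as NIfTI volumes
#'
#' Writes dxx/dyy/dzz (plus fa/md when present) and the fit mask, each as
#' `<dir>/<prefix>_<name>.nii.gz` with the source affine.
#'
#' @param maps a `diffusivity_maps` object.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default the source label).
#' @param overwrite allow replacing existing files.
#' @return Named character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, dir, prefix = maps$source, overwrite = FALSE) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- list(dxx = maps$dxx, dyy = maps$dyy, dzz = maps$dzz)
  if (!is.null(maps$fa)) vols$fa <- maps$fa
  if (!is.null(maps$md)) vols$md <- maps$md
  vols$mask <- maps$fit_mask * 1
  paths <- file.path(dir, paste0(prefix, "_", names(vols), ".nii.gz"))
  .check_overwrite(paths, overwrite)
  for (i in seq_along(vols))
    .write_nifti(vols[[i]], paths[i], maps$affine, maps$voxel_size_mm)
  names(paths) <- names(vols)
  invisible(paths)
}

#' Write study results as CSV
#'
#' Index columns are rounded to 4 decimal places in the CSV (full precision
#' stays in the in-memory objects); a provenance comment records the package
#' version, seed and configuration hash.
#'
#' @param results an `alps_study` data frame (or any ALPS results table with
#'   an `alps` column).
#' @param path output CSV path.
#' @param seed seed to record (defaults to the table's).
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_alps_csv <- function(results, path, seed = attr(results, "seed"),
                           overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  out <- as.data.frame(results)
  for (nm in intersect(c("alps", "dxx_proj", "dxx_assoc", "dyy_proj",
                         "dzz_assoc"), names(out)))
    out[[nm]] <- round(out[[nm]], 4)
  prov <- provenance(seed = seed, config = list(columns = names(out)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dtialps %s seed=%s config=%s", prov$version,
                     prov$seed, prov$config_hash), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report with a provenance block
#'
#' @param report named list of results.
#' @param path output path.
#' @param seed seed to record.
#' @param config configuration object hashed into the provenance block.
#' @param overwrite allow replacing an existing file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, seed = NA_integer_,
                              config = list(), overwrite = FALSE) {
  .check_overwrite(path, overwrite)
  payload <- c(list(provenance = provenance(seed, config)), report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.check_overwrite <- function(paths, overwrite) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !overwrite)
    stop("refusing to overwrite existing output (pass overwrite = TRUE): ",
         paste(hit, collapse = ", "))
}

#' Provenance block
#'
#' @param seed RNG seed recorded with the output.
#' @param config configuration list; hashed via [config_hash()].
#' @return List with package, version, seed, config hash and timestamp.
#' @export
provenance <- function(seed = NA_integer_, config = list()) {
  list(package = "dtialps",
       version = as.character(utils::packageVersion("dtialps")),
       seed = if (is.null(seed)) NA_integer_ else seed,
       config_hash = config_hash(config),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Hash of a canonicalized configuration
#'
#' Recursively sorts names, renders to JSON at fixed precision, and returns
#' the MD5 of that canonical text, so the hash changes when (and only when)
#' a design field changes.
#'
#' @param config a (possibly nested) list.
#' @return 32-character hex string.
#' @export
config_hash <- function(config) {
  canon <- .canonicalize(config)
  txt <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = 12,
                          null = "null", force = TRUE)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

.canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    lapply(x, .canonicalize)
  } else if (is.function(x)) {
    paste(deparse(x), collapse = "\n")
  } else x
}
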