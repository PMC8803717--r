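#' Motion-probing gradient schemes
#'
#' A `gradient_scheme` bundles the acquisition contract of one diffusion
#' series: unit gradient directions in the imaging-plane frame, the b-value
#' per volume (0 marks non-diffusion-weighted volumes), the number of
#' magnitude averages, and the echo/diffusion-time pair.
#'
#' @param directions numeric matrix, one row per volume, columns x/y/z.
#'   Rows with `bvalues == 0` are ignored (conventionally all-zero).
#' @param bvalues numeric vector of b-values (s/mm^2), one per volume.
#' @param averages integer, number of magnitude averages (NEX).
#' @param te_ms echo time in ms.
#' @param diffusion_time_ms diffusion time in ms.
#' @param label free-text label carried into provenance.
#' @return An object of class `gradient_scheme`.
#' @seealso [make_scheme()] for the standard study schemes.
#' @export
gradient_scheme <- function(directions, bvalues, averages = 1L,
                            te_ms = NA_real_, diffusion_time_ms = NA_real_,
                            label = "") {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (ncol(directions) != 3L)
    stop("`directions` must have three columns (x, y, z)")
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("`directions` rows (", nrow(directions), ") and `bvalues` length (",
         length(bvalues), ") disagree")
  if (!any(bvalues == 0))
    stop("a gradient scheme needs at least one b = 0 volume")
  dwi <- bvalues > 0
  nrm <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("non-unit gradient direction (|norm - 1| > 1e-8) in diffusion-weighted volume")
  averages <- as.integer(averages)
  if (averages < 1L) stop("`averages` must be >= 1")
  ndir <- nrow(unique(round(directions[dwi, , drop = FALSE], 10)))
  structure(
    list(directions = directions, bvalues = bvalues,
         n_axes = ndir, averages = averages,
         te_ms = te_ms, diffusion_time_ms = diffusion_time_ms,
         label = label),
    class = "gradient_scheme")
}

# TE (ms) -> diffusion time (ms) pairing used throughout the study conditions
.te_diffusion_time <- c(`65` = 29, `85` = 35.7, `100` = 40.7)

#' Build a study-condition gradient scheme
#'
#' Constructs the scheme for one acquisition condition: 3, 12 or 30
#' motion-probing gradient (MPG) axes at a single b-value plus one b = 0
#' volume. The 3-axis set is exactly the orthogonal x, y, z axes (the
#' diffusion-weighted-image path). The 12- and 30-axis sets are a
#' deterministic generalized-spiral (golden-angle Fibonacci) hemisphere point
#' set, an approximately uniform spherical design that is reproducible from
#' code alone; see the methods vignette. Diffusion time is looked up from the
#' echo time via the fixed pairing TE 65/85/100 ms -> 29/35.7/40.7 ms.
#'
#' @param n_axes number of distinct MPG axes; one of 3, 12, 30.
#' @param averages number of magnitude averages.
#' @param te_ms echo time in ms; one of 65, 85, 100.
#' @param b diffusion weighting (s/mm^2), default 1000.
#' @param label optional label (defaults to a description of the scheme).
#' @return A [gradient_scheme()].
#' @examples
#' sch <- make_scheme(3, averages = 4, te_ms = 85)
#' sch$directions
#' @export
make_scheme <- function(n_axes, averages = 2L, te_ms = 85, b = 1000,
                        label = NULL) {
  if (!n_axes %in% c(3L, 12L, 30L))
    stop("`n_axes` must be 3, 12 or 30, got ", n_axes)
  key <- as.character(te_ms)
  if (!key %in% names(.te_diffusion_time))
    stop("no diffusion time paired with TE = ", te_ms,
         " ms (supported: 65, 85, 100)")
  if (b <= 0) stop("`b` must be positive")
  dirs <- if (n_axes == 3L) diag(3) else fibonacci_directions(n_axes)
  directions <- rbind(c(0, 0, 0), dirs)
  bvalues <- c(0, rep(b, n_axes))
  if (is.null(label))
    label <- sprintf("%d-axis b=%g avg=%d TE=%g", n_axes, b, averages, te_ms)
  gradient_scheme(directions, bvalues, averages = averages, te_ms = te_ms,
                  diffusion_time_ms = unname(.te_diffusion_time[key]),
                  label = label)
}

#' Deterministic near-uniform hemisphere directions
#'
#' Generalized-spiral (golden-angle) point set on the upper hemisphere,
#' the documented direction set used for the 12- and 30-axis schemes.
#' Antipodal symmetry of diffusion weighting makes a hemisphere sufficient.
#'
#' @param n number of directions.
#' @return `n` x 3 matrix of unit vectors with positive z.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", x$label, "\n")
  cat(sprintf("  %d volumes (%d b=0), %d distinct MPG axes, b = %g s/mm^2\n",
              length(x$bvalues), sum(x$bvalues == 0), x$n_axes,
              max(x$bvalues)))
  cat(sprintf("  averages = %d, TE = %g ms, diffusion time = %g ms\n",
              x$averages, x$te_ms, x$diffusion_time_ms))
  invisible(x)
}
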