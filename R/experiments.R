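#' The study's acquisition condition grid
#'
#' The twelve acquisition conditions varied by the multi-condition
#' experiment: a four-session test-retest block on the standard sequence
#' (12-axis MPG, 2 averages, TE 85 ms, AC-PC plane, neutral head position),
#' an imaging-plane tilt and a chin-up head position, altered averaging and
#' MPG axis counts (12/4, 30/1, 3/4 — the last being the orthogonal DWI
#' output), two altered echo/diffusion times, and a second scanner noise
#' profile.
#'
#' @param im_tilt_deg plane tilt for the infra-orbital-meatal condition,
#'   degrees (default 8.5, the midpoint of the reported 7-10 range).
#' @param chin_up_deg chin-up pitch, degrees (default 20).
#' @return Data frame, one row per condition.
#' @export
study_conditions <- function(im_tilt_deg = 8.5, chin_up_deg = 20) {
  data.frame(
    label = c("1a", "1b", "1c", "1d", "2a", "2b",
              "3a", "3b", "3c", "4a", "4b", "5"),
    schedule = c("day1", "day1", "day2", "day2", "day1", "day1",
                 "day2", "day2", "day2", "day2", "day2", "day2"),
    head_position = c(rep("neutral", 4), "neutral", "chin_up",
                      rep("neutral", 6)),
    plane = c(rep("acpc", 4), "im", rep("acpc", 7)),
    n_axes = c(12, 12, 12, 12, 12, 12, 12, 30, 3, 12, 12, 12),
    averages = c(2, 2, 2, 2, 2, 2, 4, 1, 4, 2, 2, 2),
    te_ms = c(rep(85, 9), 100, 65, 85),
    scanner = c(rep("centurian", 11), "prisma"),
    pitch_deg = c(0, 0, 0, 0, im_tilt_deg, chin_up_deg,
                  0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Design a simulated multi-condition ALPS study
#'
#' @param n_subjects number of simulated subjects (default 7).
#' @param conditions condition grid as from [study_conditions()].
#' @param base_spec the cohort-level [phantom_spec()]; per-subject anatomy is
#'   derived from it.
#' @param subject_sd SD of the lognormal multiplicative jitter applied per
#'   subject to each fiber/perivascular compartment diffusivity (default
#'   0.05). CSF and background are left unjittered.
#' @param snr_b0 b = 0 signal-to-noise ratio for every acquisition
#'   (default 40); `Inf` gives a noiseless study.
#' @param patterns ROI patterns to evaluate (default all six).
#' @param seed integer master seed; every RNG draw in the study derives from
#'   it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 7L, conditions = study_conditions(),
                         base_spec = phantom_spec(), subject_sd = 0.05,
                         snr_b0 = 40, patterns = roi_patterns(),
                         seed = 1L) {
  stopifnot(n_subjects >= 1L, inherits(base_spec, "phantom_spec"))
  if (anyDuplicated(conditions$label))
    stop("condition labels must be unique")
  need <- c("label", "n_axes", "averages", "te_ms", "scanner", "pitch_deg")
  if (!all(need %in% names(conditions)))
    stop("conditions must provide columns: ", paste(need, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions, base_spec = base_spec,
                 subject_sd = subject_sd, snr_b0 = snr_b0,
                 patterns = patterns, seed = as.integer(seed)),
            class = "study_design")
}

# per-subject anatomy: lognormal jitter on fiber/perivascular diffusivities,
# capped below the free-water bound
.subject_spec <- function(base_spec, subject_sd, seed) {
  if (subject_sd == 0) return(base_spec)
  cd <- base_spec$compartment_diffusivities
  jit <- .with_seed(seed, {
    lapply(c(projection = "projection", association = "association",
             pvs = "pvs"),
           function(nm) exp(stats::rnorm(3, sd = subject_sd)))
  })
  for (nm in names(jit))
    cd[[nm]] <- pmin(cd[[nm]] * jit[[nm]], 3.15e-3)
  spec <- base_spec
  spec$compartment_diffusivities <- cd
  spec
}

#' Run the simulated study end to end
#'
#' For every subject x condition: subject-jittered phantom, head/plane
#' rotation where the condition requires it, noisy acquisition, tensor fit
#' (or the 3-axis ADC path), and the ALPS index for every ROI pattern and
#' laterality. A failing cell is recorded and skipped; the run continues.
#'
#' @param design a [study_design()].
#' @param verbose print progress per subject.
#' @return Data frame (class `alps_study`), one row per subject x condition
#'   x pattern x laterality, with the index, its component diffusivities
#'   (unilateral rows), the map source, and the cell seed. Failed cells are
#'   listed in `attr(, "failures")`.
#' @export
run_study <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  conds <- design$conditions
  ns <- design$n_subjects
  nc <- nrow(conds)
  seeds <- .with_seed(design$seed, {
    list(subject = sample.int(.Machine$integer.max - 1L, ns),
         cell = matrix(sample.int(.Machine$integer.max - 1L, ns * nc),
                       nrow = ns))
  })
  rows <- vector("list", ns * nc)
  failures <- character(0)
  ri <- 0L
  for (s in seq_len(ns)) {
    sspec <- .subject_spec(design$base_spec, design$subject_sd,
                           seeds$subject[s])
    field0 <- build_phantom(sspec)
    if (verbose) message("subject ", s, "/", ns)
    for (ci in seq_len(nc)) {
      ri <- ri + 1L
      cond <- conds[ci, ]
      rows[[ri]] <- tryCatch({
        field <- if (cond$pitch_deg != 0)
          apply_head_rotation(field0, cond$pitch_deg) else field0
        scheme <- make_scheme(cond$n_axes, cond$averages, cond$te_ms,
                              label = cond$label)
        acq <- simulate_dwi(field, scheme, snr_b0 = design$snr_b0,
                            seed = seeds$cell[s, ci],
                            scanner_profile = cond$scanner)
        maps <- if (cond$n_axes == 3) maps_from_three_axis(acq) else
          diffusivity_maps(fit_dti(acq))
        pr <- lapply(design$patterns, function(pat) {
          res <- alps_index(maps, default_rois(sspec, pat))
          .alps_rows(res, s, cond, pat, seeds$cell[s, ci])
        })
        do.call(rbind, pr)
      }, error = function(e) {
        failures <<- c(failures, sprintf("subject %d condition %s: %s",
                                         s, cond$label, conditionMessage(e)))
        NULL
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  attr(out, "seed") <- design$seed
  class(out) <- c("alps_study", class(out))
  out
}

.alps_rows <- function(res, subject, cond, pattern, cell_seed) {
  side_row <- function(side, value, comp) {
    data.frame(subject = subject, condition = cond$label,
               schedule = cond$schedule, pattern = pattern,
               source = res$source, side = side, alps = value,
               dxx_proj = if (is.null(comp)) NA_real_ else comp[["dxx_proj"]],
               dxx_assoc = if (is.null(comp)) NA_real_ else comp[["dxx_assoc"]],
               dyy_proj = if (is.null(comp)) NA_real_ else comp[["dyy_proj"]],
               dzz_assoc = if (is.null(comp)) NA_real_ else comp[["dzz_assoc"]],
               seed = cell_seed, stringsAsFactors = FALSE)
  }
  rbind(side_row("R", res$alps_r, res$components_right),
        side_row("L", res$alps_l, res$components_left),
        side_row("Bil", res$alps_bil, NULL))
}

#' Subjects-by-conditions matrix of the index
#'
#' Pivots a [run_study()] table into the complete measurement matrix the
#' reliability statistics consume.
#'
#' @param results an `alps_study` table.
#' @param conditions condition labels, in column order.
#' @param pattern ROI pattern to extract.
#' @param side laterality (`"R"`, `"L"` or `"Bil"`).
#' @return Numeric matrix, one row per subject.
#' @export
study_matrix <- function(results, conditions, pattern = "large_sphere",
                         side = "Bil") {
  sub <- results[results$pattern == pattern & results$side == side &
                   results$condition %in% conditions, ]
  if (nrow(sub) == 0)
    stop("no study rows for conditions ", paste(conditions, collapse = ", "),
         " (pattern ", pattern, ", side ", side, ")")
  subjects <- sort(unique(sub$subject))
  cols <- lapply(conditions, function(cl) {
    rows <- sub[sub$condition == cl, ]
    rows$alps[match(subjects, rows$subject)]
  })
  m <- matrix(unlist(cols), nrow = length(subjects),
              dimnames = list(subjects, conditions))
  if (any(is.na(m)))
    stop("missing cells for conditions ", paste(conditions, collapse = ", "))
  m
}

# ICC that treats an all-identical matrix (zero-noise degenerate study) as
# perfect agreement
.icc_value <- function(m) {
  r <- icc21(m)
  if (r$degenerate) 1 else r$icc
}

#' Check the study's qualitative findings on simulated results
#'
#' Evaluates eight pass/fail findings on a completed [run_study()] table,
#' each with the numbers behind it: (a) test-retest ICC of the bilateral
#' index, large spherical ROI, is at least `icc_high`; (b) large ROIs give at
#' least the reliability of small ROIs (mean ICC over the three shapes);
#' (c) the bilateral index is at least as reliable as the weaker unilateral
#' index; (d) plane tilt and chin-up both degrade agreement with the matched
#' conditions below the test-retest ICC; (e) 30- vs 12-axis MPG indices
#' differ (paired t, `p < alpha`) yet correlate `r > 0.9`; (f) 3-axis DWI vs
#' 12-axis DTI indices differ yet correlate `r > 0.8`; (g) the index falls
#' monotonically as diffusion time grows 29 -> 35.7 -> 40.7 ms; (h) changing
#' only the scanner noise profile keeps ICC at least `icc_high`.
#'
#' @param results an `alps_study` table from [run_study()].
#' @param alpha significance level for the paired tests (default 0.05).
#' @param icc_high reliability threshold for checks a and h (default 0.8).
#' @return Data frame of class `alps_findings`: id, description, the one or
#'   two key numbers, and `pass`.
#' @export
check_findings <- function(results, alpha = 0.05, icc_high = 0.8) {
  retest <- c("1a", "1b", "1c", "1d")
  mat <- function(conds, pattern = "large_sphere", side = "Bil")
    study_matrix(results, conds, pattern, side)
  m_tr <- mat(retest)
  icc_tr <- .icc_value(m_tr)
  retest_mean <- rowMeans(m_tr)

  icc_pat <- vapply(roi_patterns(), function(p) .icc_value(mat(retest, p)),
                    numeric(1))
  large <- mean(icc_pat[grep("^large", names(icc_pat))])
  small <- mean(icc_pat[grep("^small", names(icc_pat))])

  icc_r <- .icc_value(mat(retest, side = "R"))
  icc_l <- .icc_value(mat(retest, side = "L"))

  icc_im <- .icc_value(cbind(retest_mean, mat("2a")[, 1]))
  icc_chin <- .icc_value(cbind(retest_mean, mat("2b")[, 1]))

  pc_axes30 <- paired_comparison(retest_mean, mat("3b")[, 1])
  pc_axes3 <- paired_comparison(retest_mean, mat("3c")[, 1])

  mean_t29 <- mean(mat("4b")[, 1])
  mean_t357 <- mean(retest_mean)
  mean_t407 <- mean(mat("4a")[, 1])

  same_day <- rowMeans(mat(c("1c", "1d")))
  icc_scanner <- .icc_value(cbind(same_day, mat("5")[, 1]))

  f <- function(id, description, value1, value2, pass)
    data.frame(id = id, description = description, value1 = value1,
               value2 = value2, pass = pass, stringsAsFactors = FALSE)
  out <- rbind(
    f("a", sprintf("test-retest ICC (bilateral, large sphere) >= %.2f",
                   icc_high), icc_tr, NA, icc_tr >= icc_high),
    f("b", "mean ICC of large ROI patterns >= small patterns",
      large, small, large >= small),
    f("c", "bilateral ICC >= min(unilateral ICCs)",
      .icc_value(mat(retest)), min(icc_r, icc_l),
      .icc_value(mat(retest)) >= min(icc_r, icc_l)),
    f("d", "plane tilt and chin-up degrade ICC below test-retest",
      icc_im, icc_chin,
      icc_im < icc_tr && icc_chin < icc_tr),
    f("e", sprintf("12- vs 30-axis: paired p < %.2f and r > 0.9", alpha),
      pc_axes30$t_p, pc_axes30$pearson_r,
      isTRUE(pc_axes30$t_p < alpha) && isTRUE(pc_axes30$pearson_r > 0.9)),
    f("f", sprintf("12- vs 3-axis DWI: paired p < %.2f and r > 0.8", alpha),
      pc_axes3$t_p, pc_axes3$pearson_r,
      isTRUE(pc_axes3$t_p < alpha) && isTRUE(pc_axes3$pearson_r > 0.8)),
    f("g", "index decreases with diffusion time 29 > 35.7 > 40.7 ms",
      mean_t29 - mean_t357, mean_t357 - mean_t407,
      mean_t29 > mean_t357 && mean_t357 > mean_t407),
    f("h", sprintf("scanner-profile swap keeps ICC >= %.2f", icc_high),
      icc_scanner, NA, icc_scanner >= icc_high))
  class(out) <- c("alps_findings", class(out))
  out
}

#' @export
print.alps_findings <- function(x, ...) {
  cat("Qualitative findings on the simulated cohort\n")
  for (i in seq_len(nrow(x))) {
    v2 <- if (is.na(x$value2[i])) "" else sprintf(" / %.4g", x$value2[i])
    cat(sprintf("  [%s] %-4s %s  (%.4g%s)\n", x$id[i],
                if (x$pass[i]) "PASS" else "FAIL",
                x$description[i], x$value1[i], v2))
  }
  cat(sprintf("%d of %d findings reproduced\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' @export
summary.alps_study <- function(object, ...) {
  agg <- stats::aggregate(alps ~ condition + side,
                          data = object[object$pattern == "large_sphere", ],
                          FUN = mean)
  cat("Simulated ALPS study:", length(unique(object$subject)), "subjects x",
      length(unique(object$condition)), "conditions x",
      length(unique(object$pattern)), "ROI patterns\n")
  if (length(attr(object, "failures")))
    cat("  failed cells:", length(attr(object, "failures")), "\n")
  cat("Mean index by condition (large sphere):\n")
  print(utils::head(stats::reshape(
    agg, direction = "wide", idvar = "condition", timevar = "side"), 12))
  invisible(object)
}
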