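#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Test-retest agreement of a single measurement: ICC(2,1) from the two-way
#' ANOVA mean squares of a complete subjects x sessions matrix,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the standard
#' F-based confidence interval (McGraw & Wong). Sensitive to systematic
#' session shifts, which is the property wanted for test-retest designs.
#'
#' @param m numeric matrix, subjects in rows, sessions/raters in columns;
#'   at least 2 x 2, no missing cells.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `icc`: `icc`, `ci` (length-2), `label`
#'   (Landis-Koch category), the mean squares, dimensions, and `degenerate`
#'   flag with an explanation when total variance is zero.
#' @export
icc21 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 sessions")
  if (any(!is.finite(m)))
    stop("measurement matrix has missing or non-finite cells")
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  tot <- sum((m - gm)^2)
  if (tot < .Machine$double.eps * max(1, gm^2) * n * k) {
    out <- list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                label = NA_character_, msr = msr, msc = msc, mse = mse,
                n = n, k = k, conf_level = conf_level, degenerate = TRUE,
                note = "zero total variance: ICC undefined (all measurements identical)")
    class(out) <- "icc"
    return(out)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F-based interval (McGraw & Wong 1996, ICC(A,1))
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  out <- list(icc = icc, ci = c(lower, upper), label = landis_koch(icc),
              msr = msr, msc = msc, mse = mse, n = n, k = k,
              conf_level = conf_level, degenerate = FALSE, note = NULL)
  class(out) <- "icc"
  out
}

#' Landis-Koch qualitative agreement label
#'
#' Maps an agreement coefficient to the conventional bands: below 0 "poor",
#' 0-0.20 "slight", 0.21-0.40 "fair", 0.41-0.60 "moderate", 0.61-0.80
#' "substantial", 0.81-1.00 "almost perfect" (band edges upper-inclusive).
#'
#' @param icc a coefficient `<= 1`.
#' @return Character label.
#' @export
landis_koch <- function(icc) {
  stopifnot(is.finite(icc), icc <= 1)
  if (icc < 0) return("poor")
  if (icc <= 0.20) return("slight")
  if (icc <= 0.40) return("fair")
  if (icc <= 0.60) return("moderate")
  if (icc <= 0.80) return("substantial")
  "almost perfect"
}

#' Paired comparison of two measurement sets
#'
#' Two-sided paired t test and Pearson correlation for subject-paired values
#' (e.g. an index under two acquisition conditions). When one input is a
#' multi-session mean, average before calling.
#'
#' @param a,b numeric vectors of equal length (>= 3), paired by subject.
#' @return List with `t_statistic`, `t_p`, `pearson_r`, `mean_difference`
#'   (`a - b`), `n`, and a `degenerate` flag when the differences have zero
#'   variance.
#' @export
paired_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    return(list(t_statistic = if (all(d == 0)) 0 else NA_real_,
                t_p = NA_real_, pearson_r = r, mean_difference = mean(d),
                n = length(a), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_statistic = unname(tt$statistic), t_p = tt$p.value,
       pearson_r = r, mean_difference = mean(d), n = length(a),
       degenerate = FALSE)
}

#' One-within-factor repeated-measures ANOVA
#'
#' Two-way repeated-measures decomposition with subject as the random block
#' and the acquisition condition as the within-subject factor, fit via
#' [stats::aov()] with an `Error(subject)` stratum. Requires a complete
#' design with at least three condition levels.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns
#'   (>= 3 columns).
#' @return List with the ANOVA `table` (term, df, ss, ms, f, p), and the
#'   condition-effect `f` and `p` pulled out for convenience.
#' @export
rm_anova_ws <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 3L)
    stop("repeated-measures ANOVA here needs >= 3 condition levels")
  if (nrow(values) < 2L) stop("need >= 2 subjects")
  if (any(!is.finite(values))) stop("incomplete design: missing cells")
  n <- nrow(values); k <- ncol(values)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = long)
  s <- summary(fit)
  betw <- s[["Error: subject"]][[1]]
  with_ <- s[["Error: Within"]][[1]]
  tab <- data.frame(
    term = c("subject", "condition", "residual"),
    df = c(betw["Residuals", "Df"], with_["condition", "Df"],
           with_["Residuals", "Df"]),
    ss = c(betw["Residuals", "Sum Sq"], with_["condition", "Sum Sq"],
           with_["Residuals", "Sum Sq"]),
    ms = c(betw["Residuals", "Mean Sq"], with_["condition", "Mean Sq"],
           with_["Residuals", "Mean Sq"]))
  f <- with_["condition", "F value"]
  p <- with_["condition", "Pr(>F)"]
  if (tab$ss[2] <= .Machine$double.eps * max(1, sum(tab$ss))) {
    f <- 0; p <- 1  # no condition effect at all
  }
  tab$f <- c(NA, f, NA)
  tab$p <- c(NA, p, NA)
  list(table = tab, f = f, p = p, n = n, k = k)
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1), absolute agreement (%d subjects x %d sessions)\n",
              x$n, x$k))
  if (x$degenerate) {
    cat("  degenerate:", x$note, "\n")
  } else {
    cat(sprintf("  ICC = %.3f  %g%% CI [%.3f, %.3f]  (%s)\n",
                x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$label))
  }
  invisible(x)
}
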