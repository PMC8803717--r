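# Independent oracles kept deliberately separate from the package internals.

# normal-equations pseudoinverse tensor fit: ln S = X beta, beta via
# solve(X'X) X' y
oracle_tensor_fit <- function(signals2d, scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  XtXi <- solve(t(X) %*% X)
  t(XtXi %*% t(X) %*% t(log(signals2d)))[, 2:7, drop = FALSE]
}

# ICC(2,1) from aov() mean squares (independent of the package's hand-rolled
# two-way decomposition)
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     sess = factor(rep(seq_len(k), each = n)))
  tab <- anova(lm(y ~ subj + sess, data = long))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["sess", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# brute-force sums-of-squares decomposition for the one-within-factor
# repeated-measures design
oracle_rm_ss <- function(values) {
  n <- nrow(values); k <- ncol(values)
  gm <- mean(values)
  ss_subj <- k * sum((rowMeans(values) - gm)^2)
  ss_cond <- n * sum((colMeans(values) - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  ms_cond <- ss_cond / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  list(ss_subj = ss_subj, ss_cond = ss_cond, ss_err = ss_err,
       ms_cond = ms_cond, ms_err = ms_err, f = ms_cond / ms_err,
       p = pf(ms_cond / ms_err, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# exhaustive voxel-by-voxel ROI membership over the bounding box
oracle_roi_enumeration <- function(shape, size_px, center, grid_shape,
                                   voxel_size = c(1, 1, 1)) {
  r <- size_px / 2
  zs <- voxel_size[3] / voxel_size[1]
  keep <- matrix(0, 0, 3)
  for (i in seq_len(grid_shape[1])) for (j in seq_len(grid_shape[2]))
    for (k in seq_len(grid_shape[3])) {
      dx <- i - center[1]; dy <- j - center[2]; dz <- (k - center[3]) * zs
      inside <- switch(shape,
        sphere = dx^2 + dy^2 + dz^2 <= r^2,
        cube = abs(dx) <= r && abs(dy) <= r && abs(dz) <= r)
      if (inside) keep <- rbind(keep, c(i, j, k))
    }
  keep
}
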