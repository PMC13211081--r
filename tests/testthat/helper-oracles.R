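# Independent oracles and small fixture builders shared across tests.

# Brute-force ICC(2,k) through R's linear-model machinery (QR-based ANOVA),
# an implementation path fully independent of kyphofat::icc2k().
oracle_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     case = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # perfect fits (MSE = 0) make anova() warn about F tests; only the mean
  # squares are used here
  an <- suppressWarnings(stats::anova(stats::lm(y ~ case + rater,
                                                data = long)))
  msr <- an["case", "Mean Sq"]
  msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Tiny phantom spec that keeps unit tests fast (~200k voxels).
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 64, 64), ...)
}

# Rater matrix with exact per-column means (two symmetric cases per mean).
matrix_with_column_means <- function(col_means, half_spread = 1) {
  m <- rbind(col_means - half_spread, col_means + half_spread)
  colnames(m) <- paste0("rater_", seq_along(col_means))
  m
}
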