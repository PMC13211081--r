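#' Intraclass correlation ICC(2,k): two-way random effects, absolute
#' agreement, reliability of the k-rater mean
#'
#' Computed from the two-way ANOVA decomposition with rows = cases and
#' columns = raters (Shrout-Fleiss A,k form):
#' `ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#'
#' @param m numeric n x k matrix of measurements (cases x raters), no
#'   missing entries, n >= 2 and k >= 2.
#' @return list of class `icc_result` with `icc2k`, `ms_rows`, `ms_cols`,
#'   `ms_error`, `n`, `k` (CI fields are filled by [bootstrap_ci()]).
#' @export
icc2k <- function(m) {
  m <- .check_rater_matrix(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (ssr <= 1e-12 * max(sst, 1))
    stop("zero between-case variance: ICC(2,k) is undefined")
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  structure(list(icc2k = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, ci_low = NA_real_, ci_high = NA_real_,
                 n_bootstrap = NA_integer_, seed = NA_integer_),
            class = "icc_result")
}

.check_rater_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("rater matrix must be numeric with no missing entries")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("rater matrix needs at least 2 cases and 2 raters")
  m
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,k): %.4f  (n = %d cases, k = %d raters)\n",
              x$icc2k, x$n, x$k))
  if (!is.na(x$ci_low))
    cat(sprintf("  bootstrap %s CI: [%.4f, %.4f]  (B = %d)\n",
                "95%", x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}

#' Percentile bootstrap confidence interval for ICC(2,k)
#'
#' Cases are resampled with replacement (raters fixed); ICC(2,k) is
#' recomputed per replicate and the percentile interval taken. Degenerate
#' replicates (zero between-case variance) are skipped and counted.
#'
#' @param m n x k rater matrix.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed; the interval is reproducible given it.
#' @return an `icc_result` (as [icc2k()]) with `ci_low`, `ci_high`,
#'   `n_bootstrap`, `seed` filled in and an attribute `n_degenerate`.
#' @export
bootstrap_ci <- function(m, B = 2000, level = 0.95, seed = 1L) {
  m <- .check_rater_matrix(m)
  if (B < 100) stop("B must be at least 100")
  point <- icc2k(m)
  n <- nrow(m)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(icc2k(m[idx, , drop = FALSE])$icc2k,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_deg <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  if (length(reps) < 2L) stop("all bootstrap replicates were degenerate")
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  point$ci_low <- min(ci[1], point$icc2k)
  point$ci_high <- max(ci[2], point$icc2k)
  point$n_bootstrap <- as.integer(B)
  point$seed <- as.integer(seed)
  attr(point, "n_degenerate") <- n_deg
  point
}

#' Bland-Altman analysis against the k-rater per-case mean
#'
#' Each of the n x k observations contributes one point: x = the case's
#' k-rater mean, y = observation minus that mean. By construction the mean
#' bias is exactly zero (deviations from an own-case mean sum to zero);
#' the 95% limits of agreement are bias +/- 1.96 x SD of the pooled
#' differences (one pair of limits pooled over all raters and cases).
#'
#' @param m n x k rater matrix.
#' @return list of class `bland_altman_result` with `case_mean` and
#'   `difference` vectors (length n x k), `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`.
#' @export
bland_altman <- function(m) {
  m <- .check_rater_matrix(m)
  cm <- rowMeans(m)
  diffs <- m - cm
  bias <- mean(diffs)
  s <- stats::sd(as.vector(diffs))
  structure(list(case_mean = rep(cm, times = ncol(m)),
                 difference = as.vector(diffs),
                 bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s),
            class = "bland_altman_result")
}

#' Per-case across-rater standard deviation
#'
#' Sample SD (denominator k - 1) across the k raters of each case,
#' summarized as mean and SD over cases.
#'
#' @param m n x k rater matrix.
#' @return list with `per_case` (length n), `mean_sd`, `sd_of_sd`.
#' @export
per_case_sd <- function(m) {
  m <- .check_rater_matrix(m)
  s <- apply(m, 1, stats::sd)
  list(per_case = s, mean_sd = mean(s), sd_of_sd = stats::sd(s))
}

#' Per-rater and grand summary of a rater matrix
#'
#' @param m n x k rater matrix.
#' @return list with `per_rater` (data.frame rater/mean/sd) and
#'   `grand_mean` (mean over all n x k entries).
#' @export
rater_summary <- function(m) {
  m <- .check_rater_matrix(m)
  per <- data.frame(rater = colnames(m) %||% paste0("rater_", seq_len(ncol(m))),
                    mean = colMeans(m),
                    sd = apply(m, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_rater = per, grand_mean = mean(m))
}
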