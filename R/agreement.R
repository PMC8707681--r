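#' Bland-Altman agreement between paired measurements
#'
#' Differences are oriented invasive minus noninvasive throughout. Limits of
#' agreement are bias +/- 1.96 sample SDs of the differences (n - 1
#' denominator), the conventional 95\% band.
#'
#' @param invasive,noninvasive equal-length paired measurements; pairs with
#'   any `NA` are dropped.
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `outlier_fraction` (fraction of differences strictly outside
#'   the limits), `n`.
#' @examples
#' bland_altman(c(1.1, 1.2, 1.3), c(1.0, 1.0, 1.0))
#' @export
bland_altman <- function(invasive, noninvasive) {
  if (length(invasive) != length(noninvasive)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(invasive, noninvasive)
  d <- invasive[ok] - noninvasive[ok]
  n <- length(d)
  if (n < 3) stop("insufficient data: need >= 3 pairs", call. = FALSE)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_d
  loa_high <- bias + 1.96 * sd_d
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_low = loa_low, loa_high = loa_high,
                 outlier_fraction = mean(d < loa_low | d > loa_high),
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (differences: invasive - noninvasive)\n")
  cat(sprintf("  n = %d, bias = %.4g, SD(diff) = %.4g\n", x$n, x$bias,
              x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.4g, %.4g]  (bias +/- 1.96 SD)\n",
              x$loa_low, x$loa_high))
  cat(sprintf("  outliers beyond limits: %.1f%%\n", 100 * x$outlier_fraction))
  invisible(x)
}

#' Pearson correlation with percentile-bootstrap confidence interval
#'
#' Product-moment correlation of the paired series with a 95\% percentile
#' bootstrap CI (pairs resampled with replacement), deterministic given
#' `seed`.
#'
#' @param x,y equal-length paired series (NA pairs dropped, n >= 3, both with
#'   positive variance).
#' @param n_boot bootstrap replicates (default 2000, >= 100).
#' @param seed integer seed.
#' @return Object of class `cor_boot`: `r`, `ci_low`, `ci_high`, `n`,
#'   `n_boot`, `seed`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 2000L, seed = 1L) {
  if (length(x) != length(y)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: need >= 3 pairs", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(r = r, ci_low = max(-1, min(ci[1], r)),
                 ci_high = min(1, max(ci[2], r)),
                 n = n, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "cor_boot")
}

#' @export
print.cor_boot <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.3f (95%% bootstrap CI %.3f to %.3f; n = %d, %d resamples)\n",
    x$r, x$ci_low, x$ci_high, x$n, x$n_boot))
  invisible(x)
}

#' Ordinary least-squares fit of noninvasive on invasive
#'
#' @param invasive predictor series (positive variance required).
#' @param noninvasive response series.
#' @return List `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(invasive, noninvasive) {
  if (length(invasive) != length(noninvasive)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(invasive, noninvasive)
  invasive <- invasive[ok]; noninvasive <- noninvasive[ok]
  if (length(invasive) < 3) {
    stop("insufficient data: need >= 3 pairs", call. = FALSE)
  }
  if (stats::sd(invasive) == 0) {
    stop("zero variance in predictor", call. = FALSE)
  }
  fit <- stats::lm(noninvasive ~ invasive)
  sst <- sum((noninvasive - mean(noninvasive))^2)
  r2 <- if (sst == 0) NA_real_ else
    1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(invasive))
}
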