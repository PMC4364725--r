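# Cross-platform agreement between array betas and bisulfite pyrosequencing.

new_concordance_result <- function(n, pearson_r = NA_real_, p_value = NA_real_,
                                   bias = NA_real_, sd_diff = NA_real_,
                                   loa_low = NA_real_, loa_high = NA_real_) {
  structure(list(n = n, pearson_r = pearson_r, p_value = p_value,
                 bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result (n = %d)\n", x$n))
  if (!is.na(x$pearson_r))
    cat(sprintf("  Pearson r = %.4f, p = %.3g\n", x$pearson_r, x$p_value))
  if (!is.na(x$bias))
    cat(sprintf("  Bland-Altman bias = %.3f, limits of agreement [%.3f, %.3f]\n",
                x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Correlation of paired delta values across platforms
#'
#' Pearson correlation of array-derived and pyrosequencing-derived delta
#' values with a two-sided p-value from the t transform on n - 2 degrees of
#' freedom. Pairs with a missing value in either vector are dropped.
#'
#' @param array_delta,pyro_delta Equal-length numeric vectors of per-pair
#'   delta values on a common scale (fraction or percent; r is
#'   scale-invariant).
#' @return A `concordance_result` with `pearson_r` and `p_value` filled.
#' @export
delta_concordance <- function(array_delta, pyro_delta) {
  if (length(array_delta) != length(pyro_delta))
    stop_deltabeta("validation_error", "vectors must have equal length")
  ok <- !is.na(array_delta) & !is.na(pyro_delta)
  x <- array_delta[ok]; y <- pyro_delta[ok]
  if (length(x) < 3)
    stop_deltabeta("validation_error", "need >= 3 paired measurements")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_deltabeta("degenerate_error", "zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new_concordance_result(length(x), pearson_r = unname(ct$estimate),
                         p_value = ct$p.value)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Per-measurement differences `d = method1 - method2`; bias is their mean
#' and the limits of agreement are bias plus/minus exactly 2 sample standard
#' deviations of the differences (n - 1 denominator), the 95% range of
#' agreement. Inputs are expected on the percent scale so both platforms
#' share a common range.
#'
#' @param method1,method2 Equal-length numeric vectors (percent scale).
#' @return A `concordance_result` with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high` filled.
#' @export
bland_altman <- function(method1, method2) {
  if (length(method1) != length(method2))
    stop_deltabeta("validation_error", "vectors must have equal length")
  ok <- !is.na(method1) & !is.na(method2)
  d <- method1[ok] - method2[ok]
  if (length(d) < 2)
    stop_deltabeta("validation_error", "need >= 2 paired measurements")
  bias <- mean(d)
  s <- stats::sd(d)
  new_concordance_result(length(d), bias = bias, sd_diff = s,
                         loa_low = bias - 2 * s, loa_high = bias + 2 * s)
}
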