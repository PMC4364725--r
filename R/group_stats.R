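# Variance filtering, PCA, and per-probe differential tests.
#
# Per-probe t statistics are computed with vectorized closed forms (a call to
# t.test per probe does not scale to array size); the closed forms agree with
# stats::t.test, which serves as the oracle in the test suite.

row_n <- function(x) rowSums(!is.na(x))
row_mean <- function(x) {
  n <- row_n(x)
  out <- rowSums(x, na.rm = TRUE) / n
  out[n == 0] <- NA_real_
  out
}
row_var <- function(x) {
  n <- row_n(x)
  m <- row_mean(x)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2] <- NA_real_
  out
}

# constant rows leave ~1e-33 rounding residue in the centered sum of squares;
# anything below this is a degenerate (zero-variance) row, far under any real
# beta-scale variance
.zero_var_tol <- 1e-24

#' Filter probes by relative standard deviation
#'
#' Computes each probe's standard deviation across samples and retains probes
#' with `sigma / sigma_max > tau` (strict), where `sigma_max` is the largest
#' per-probe standard deviation in the matrix. This is the variance filter
#' used before unsupervised analyses of beta matrices.
#'
#' @param bm A [beta_matrix()] with at least 2 samples.
#' @param tau Relative-sd threshold in \[0,1) (the cohort analysis uses
#'   0.275).
#' @return The filtered [beta_matrix()], with attributes `tau` and
#'   `sigma_max`.
#' @export
variance_filter <- function(bm, tau) {
  if (ncol(bm$beta) < 2)
    stop_deltabeta("validation_error", "variance filter needs >= 2 samples")
  sds <- sqrt(row_var(bm$beta))
  smax <- max(sds, na.rm = TRUE)
  if (!is.finite(smax) || smax == 0)
    stop_deltabeta("degenerate_error", "constant matrix: sigma_max = 0")
  keep <- !is.na(sds) & sds / smax > tau
  out <- subset_beta_matrix(bm, probes = which(keep))
  attr(out, "tau") <- tau
  attr(out, "sigma_max") <- smax
  out
}

#' Principal component embedding of samples
#'
#' Projects samples onto principal components of the probe space. Probes are
#' mean-centered; no unit-variance rescaling is applied (beta values share a
#' common scale).
#'
#' @param bm A [beta_matrix()] with at least 2 samples and no missing beta
#'   values (impute or drop probes first).
#' @param n_components Number of components to keep; capped at the matrix
#'   rank with a warning. Default: all.
#' @param tau Optional record of the variance-filter threshold that produced
#'   `bm` (bookkeeping only).
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `explained_variance` (proportions, non-increasing), `n_loci` and `tau`.
#' @export
pca_embed <- function(bm, n_components = NULL, tau = NA_real_) {
  x <- t(bm$beta)
  if (nrow(x) < 2)
    stop_deltabeta("validation_error", "PCA needs >= 2 samples")
  if (anyNA(x))
    stop_deltabeta("validation_error", "PCA input has missing beta values; impute or drop probes first")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  rank <- max(rank, 1L)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds rank %d; capped", n_components, rank))
    n_components <- rank
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    explained_variance = ev[seq_len(n_components)],
    n_loci = nrow(bm$beta),
    tau = if (is.na(tau) && !is.null(attr(bm, "tau"))) attr(bm, "tau") else tau
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components on %d loci; PC1 %.1f%% of variance\n",
              nrow(x$scores), ncol(x$scores), x$n_loci, 100 * x$explained_variance[1]))
  invisible(x)
}

new_test_result <- function(probe_id, statistic, raw_p, mean_diff, n_used, flag) {
  structure(data.frame(probe_id = probe_id, statistic = statistic,
                       raw_p = raw_p, q = adjust_bh(raw_p),
                       mean_diff = mean_diff, n_used = n_used,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("test_result", "data.frame"))
}

# two-sided one-sample t on the rows of a difference matrix; shared by the
# paired probe test and the clinical IGF1 summary
row_paired_t <- function(d) {
  n <- row_n(d)
  m <- row_mean(d)
  v <- row_var(d)
  t <- m / sqrt(v / n)
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  flag <- rep("", nrow(d))
  flag[n < 2] <- "insufficient_pairs"
  flag[n >= 2 & !is.na(v) & v < .zero_var_tol] <- "zero_variance"
  bad <- flag != ""
  t[bad] <- NA_real_; p[bad] <- NA_real_
  list(statistic = t, raw_p = p, mean_diff = m, n_used = n, flag = flag)
}

#' Per-probe paired t-test
#'
#' Two-sided paired t-test of stimulated minus baseline beta values for every
#' probe, with Benjamini-Hochberg q-values over all tested probes.
#' `mean_diff` is the mean paired difference (stimulated - baseline). Probes
#' with fewer than 2 complete pairs or zero-variance differences are flagged
#' and get missing p.
#'
#' @param x A [beta_matrix()] or a plain numeric matrix (rows = variables,
#'   columns = samples named in the design).
#' @param design A `paired_design`.
#' @return A `test_result` data frame with columns `probe_id`, `statistic`,
#'   `raw_p`, `q`, `mean_diff`, `n_used`, `flag`.
#' @export
paired_test <- function(x, design) {
  d <- paired_differences(x, design)
  r <- row_paired_t(d)
  new_test_result(rownames(d), r$statistic, r$raw_p, r$mean_diff, r$n_used, r$flag)
}

paired_differences <- function(x, design) {
  m <- if (inherits(x, "beta_matrix")) x$beta else x
  missing_samples <- setdiff(design$sample_id, colnames(m))
  if (length(missing_samples))
    stop_deltabeta("design_error", "design sample not in matrix: %s", missing_samples[1])
  ind <- unique(design$individual_id)
  base <- design$sample_id[match(paste(ind, "baseline"),
                                 paste(design$individual_id, design$timepoint))]
  stim <- design$sample_id[match(paste(ind, "stimulated"),
                                 paste(design$individual_id, design$timepoint))]
  d <- m[, stim, drop = FALSE] - m[, base, drop = FALSE]
  colnames(d) <- ind
  d
}

#' Per-probe unpaired two-sample t-test
#'
#' Two-sided two-sample t-test of treated versus untreated samples per probe
#' (pooled-variance Student by default), with Benjamini-Hochberg q-values.
#' `mean_diff` is mean(treated) - mean(untreated). Probes with zero variance
#' in both groups are flagged with missing p.
#'
#' @param bm A [beta_matrix()].
#' @param design A `cohort_design`; both groups need at least 2 samples.
#' @param var_equal Use the pooled-variance statistic (default `TRUE`); set
#'   `FALSE` for Welch.
#' @return A `test_result` data frame.
#' @export
unpaired_test <- function(bm, design, var_equal = TRUE) {
  m <- bm$beta
  missing_samples <- setdiff(design$sample_id, colnames(m))
  if (length(missing_samples))
    stop_deltabeta("design_error", "design sample not in matrix: %s", missing_samples[1])
  g1 <- design$sample_id[design$group == "treated"]
  g2 <- design$sample_id[design$group == "untreated"]
  if (length(g1) < 2 || length(g2) < 2)
    stop_deltabeta("design_error", "both groups need >= 2 samples (treated %d, untreated %d)",
                   length(g1), length(g2))
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, g2, drop = FALSE]
  n1 <- row_n(x1); n2 <- row_n(x2)
  m1 <- row_mean(x1); m2 <- row_mean(x2)
  v1 <- row_var(x1); v2 <- row_var(x2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = df)
  flag <- rep("", nrow(m))
  flag[n1 < 2 | n2 < 2] <- "insufficient_samples"
  zero_both <- !is.na(v1) & !is.na(v2) & v1 < .zero_var_tol & v2 < .zero_var_tol
  flag[zero_both] <- "zero_variance"
  bad <- flag != ""
  t[bad] <- NA_real_; p[bad] <- NA_real_
  new_test_result(rownames(m), t, p, m1 - m2, n1 + n2, flag)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1 and returned in input
#' order. Missing p-values pass through as missing and do not count toward
#' `m`.
#'
#' @param raw_p Numeric vector of p-values in \[0,1\] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_bh <- function(raw_p) {
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE))
    stop_deltabeta("validation_error", "p-value outside [0,1]")
  q <- rep(NA_real_, length(raw_p))
  obs <- !is.na(raw_p)
  q[obs] <- stats::p.adjust(raw_p[obs], method = "BH")
  q
}

#' Select significant probes
#'
#' Returns the probes satisfying every supplied strict-inequality criterion
#' (`raw_p < raw_p_max`, `q < q_max`), in input order. Probes with missing
#' values for a requested criterion are excluded.
#'
#' @param tr A `test_result`.
#' @param raw_p_max Optional raw p-value cutoff in (0,1\].
#' @param q_max Optional q-value cutoff in (0,1\].
#' @return Character vector of probe ids.
#' @export
select_significant <- function(tr, raw_p_max = NULL, q_max = NULL) {
  if (is.null(raw_p_max) && is.null(q_max))
    stop_deltabeta("usage_error", "supply raw_p_max and/or q_max")
  for (thr in c(raw_p_max, q_max)) {
    if (thr <= 0 || thr > 1)
      stop_deltabeta("validation_error", "threshold must be in (0,1]")
  }
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(raw_p_max)) keep <- keep & !is.na(tr$raw_p) & tr$raw_p < raw_p_max
  if (!is.null(q_max)) keep <- keep & !is.na(tr$q) & tr$q < q_max
  tr$probe_id[keep]
}
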