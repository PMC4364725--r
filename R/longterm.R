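# Cross-sectional treated-versus-untreated analysis: per-probe regression of
# methylation on treatment duration, and targeted re-testing of candidate
# probes found in the paired arm.

#' Per-probe regression of beta on treatment duration
#'
#' Ordinary least squares of each probe's beta values on treatment months,
#' with a two-sided slope p-value and Benjamini-Hochberg q over all probes.
#' By default only treated samples enter the fit (untreated carry duration 0,
#' which would otherwise re-encode group membership). An absence of
#' duration-associated methylation is read as zero probes at q < 0.05.
#'
#' @param bm A [beta_matrix()].
#' @param design A `cohort_design`.
#' @param scope `"treated_only"` (default) or `"all"`.
#' @return A `regression_result` data frame: `probe_id`, `slope` (delta-beta
#'   per month), `intercept`, `raw_p`, `q`, `n_used`, `flag`.
#' @export
duration_regression <- function(bm, design, scope = c("treated_only", "all")) {
  scope <- match.arg(scope)
  keep <- if (scope == "treated_only") design$group == "treated" else rep(TRUE, nrow(design))
  ids <- design$sample_id[keep]
  missing_samples <- setdiff(ids, colnames(bm$beta))
  if (length(missing_samples))
    stop_deltabeta("design_error", "design sample not in matrix: %s", missing_samples[1])
  x <- design$treatment_months[keep]
  if (length(x) < 3 || length(unique(x)) < 2)
    stop_deltabeta("degenerate_error",
                   "regression needs >= 3 samples with >= 2 distinct treatment_months")
  y <- bm$beta[, ids, drop = FALSE]
  M <- !is.na(y)
  n <- rowSums(M)
  sx <- M %*% x
  sxx <- M %*% x^2
  xbar <- as.vector(sx / n)
  ybar <- row_mean(y)
  y0 <- y; y0[!M] <- 0
  sxy <- as.vector(y0 %*% x) - n * xbar * ybar
  Sxx <- as.vector(sxx) - n * xbar^2
  Syy <- rowSums((y - ybar)^2, na.rm = TRUE)
  slope <- sxy / Sxx
  intercept <- ybar - slope * xbar
  rss <- pmax(Syy - slope * sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  flag <- rep("", nrow(y))
  flag[n < 3 | Sxx == 0] <- "insufficient_samples"
  flag[Syy < .zero_var_tol & flag == ""] <- "zero_variance"
  bad <- flag != ""
  slope[flag == "zero_variance"] <- 0
  p[bad] <- NA_real_
  structure(data.frame(probe_id = rownames(y), slope = slope,
                       intercept = intercept, raw_p = p, q = adjust_bh(p),
                       n_used = n, flag = flag, stringsAsFactors = FALSE),
            class = c("regression_result", "data.frame"))
}

#' Targeted re-testing of candidate probes in a cross-sectional cohort
#'
#' Intersects a candidate probe list (e.g. hits from the paired short-term
#' arm) with the probes surviving QC in the cross-sectional matrix, then runs
#' the treated-versus-untreated test and the duration regression on that
#' subset only, with Benjamini-Hochberg adjustment within the subset.
#'
#' @param bm A post-QC [beta_matrix()].
#' @param design A `cohort_design`.
#' @param candidates Nonempty character vector of candidate probe ids.
#' @return List with `test` (a `test_result`), `regression` (a
#'   `regression_result`) and `n_matched` (candidates present in `bm`).
#' @export
targeted_subset_test <- function(bm, design, candidates) {
  if (length(candidates) == 0L)
    stop_deltabeta("usage_error", "candidate list is empty")
  matched <- intersect(candidates, probe_ids(bm))
  if (length(matched) == 0L) {
    warning("no candidate probe matches the matrix; returning empty results")
    empty_tr <- new_test_result(character(), numeric(), numeric(), numeric(),
                                integer(), character())
    empty_rr <- structure(data.frame(probe_id = character(), slope = numeric(),
                                     intercept = numeric(), raw_p = numeric(),
                                     q = numeric(), n_used = integer(),
                                     flag = character(), stringsAsFactors = FALSE),
                          class = c("regression_result", "data.frame"))
    return(list(test = empty_tr, regression = empty_rr, n_matched = 0L))
  }
  sub <- subset_beta_matrix(bm, probes = matched)
  list(test = unpaired_test(sub, design),
       regression = duration_regression(sub, design),
       n_matched = length(matched))
}
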