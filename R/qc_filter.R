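# Sample- and probe-level quality filtering.
#
# Filter order is fixed: samples first (call rate), then probes (detection
# p-value in every retained sample). The cross-sectional arm additionally
# restricts probes to autosomal non-SNP assays.

#' Per-sample call rates
#'
#' The call rate of a sample is the fraction of its probes whose detection
#' p-value is strictly below `detection_p_max`. Missing detection entries
#' count as failed calls.
#'
#' @param bm A [beta_matrix()].
#' @param detection_p_max Detection p-value threshold (default 0.01).
#' @return Named numeric vector of call rates in \[0,1\], one per sample.
#' @export
compute_call_rates <- function(bm, detection_p_max = 0.01) {
  if (nrow(bm$beta) == 0L || ncol(bm$beta) == 0L)
    stop_deltabeta("validation_error", "empty matrix: no probes or no samples")
  pass <- !is.na(bm$detection_p) & bm$detection_p < detection_p_max
  colMeans(pass)
}

#' Apply sample and probe quality filters
#'
#' Drops samples whose call rate does not exceed `call_rate_min`, then drops
#' probes whose detection p-value is `>= detection_p_max` (or missing) in any
#' retained sample. The default boundary is strict: a call rate exactly equal
#' to `call_rate_min` fails ("above 98%").
#'
#' @param bm A [beta_matrix()].
#' @param call_rate_min Minimum per-sample call rate (default 0.98).
#' @param detection_p_max Per-call detection p-value threshold (default 0.01).
#' @param probe_rule Probe retention rule; only `"all_samples"` is
#'   implemented: a probe is kept only if it passes in every retained sample.
#' @param call_rate_boundary `"strict"` (rate must exceed the minimum,
#'   default) or `"inclusive"` (rate equal to the minimum passes).
#' @return List with elements `bm` (the filtered [beta_matrix()]) and
#'   `report` (a `qc_report`).
#' @export
apply_qc <- function(bm, call_rate_min = 0.98, detection_p_max = 0.01,
                     probe_rule = "all_samples",
                     call_rate_boundary = c("strict", "inclusive")) {
  call_rate_boundary <- match.arg(call_rate_boundary)
  probe_rule <- match.arg(probe_rule, "all_samples")
  rates <- compute_call_rates(bm, detection_p_max)
  keep_s <- if (call_rate_boundary == "strict") rates > call_rate_min else rates >= call_rate_min
  if (!any(keep_s))
    stop_deltabeta("qc_error", "empty cohort after QC: every sample has call rate <= %g",
                   call_rate_min)
  bm2 <- subset_beta_matrix(bm, samples = which(keep_s))
  pass <- !is.na(bm2$detection_p) & bm2$detection_p < detection_p_max
  keep_p <- rowSums(pass) == ncol(bm2$beta)
  out <- subset_beta_matrix(bm2, probes = which(keep_p))
  report <- structure(list(
    call_rate = rates,
    kept_samples = sample_ids(out),
    kept_probes = probe_ids(out),
    n_samples_before = ncol(bm$beta), n_samples_after = ncol(out$beta),
    n_probes_before = nrow(bm$beta), n_probes_after = nrow(out$beta),
    call_rate_min = call_rate_min, detection_p_max = detection_p_max,
    probe_rule = probe_rule, call_rate_boundary = call_rate_boundary
  ), class = "qc_report")
  list(bm = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d/%d samples kept (call rate %s %g at detection p < %g); %d/%d probes kept (%s)\n",
    x$n_samples_after, x$n_samples_before,
    if (x$call_rate_boundary == "strict") ">" else ">=",
    x$call_rate_min, x$detection_p_max,
    x$n_probes_after, x$n_probes_before, x$probe_rule))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(sample_id = names(x$call_rate),
             call_rate = unname(x$call_rate),
             kept = names(x$call_rate) %in% x$kept_samples,
             stringsAsFactors = FALSE)
}

#' Restrict to autosomal non-SNP probes
#'
#' Keeps probes of class `cg` or `ch` located on autosomes (chromosome not X
#' or Y), the additional filter applied to the cross-sectional cohort. Probe
#' order is preserved.
#'
#' @param bm A [beta_matrix()].
#' @param ann A `probe_annotation` covering every probe in `bm`.
#' @return The filtered [beta_matrix()].
#' @export
subset_autosomal_non_snp <- function(bm, ann) {
  ids <- probe_ids(bm)
  if (length(ids) == 0L) return(bm)
  idx <- match(ids, ann$probe_id)
  if (anyNA(idx))
    stop_deltabeta("key_mismatch_error", "probe not in annotation: %s", ids[is.na(idx)][1])
  chr <- sub("^chr", "", ann$chromosome[idx])
  keep <- ann$probe_class[idx] %in% c("cg", "ch") & !(chr %in% c("X", "Y"))
  subset_beta_matrix(bm, probes = which(keep))
}
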