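# End-to-end drivers wiring the modules into the two analysis arms. These
# are the programmatic entry points; a thin command-line wrapper over them
# ships in inst/scripts/deltabeta-cli.R.

write_config_echo <- function(params, path) {
  df <- data.frame(parameter = names(params),
                   value = vapply(params, function(v) as.character(v)[1], ""),
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Run the paired short-term analysis arm
#'
#' QC (call rate, detection p) -> variance filter + PCA -> per-probe paired
#' t-test with BH adjustment -> selection at the raw-p cutoff -> per-pair
#' delta-beta, trinary classification, recurrence filtering -> gene-level
#' aggregation (when an annotation is given) and overlap of the two gene
#' lists.
#'
#' @param bm A [beta_matrix()].
#' @param design A `paired_design`.
#' @param ann Optional `probe_annotation` (enables gene aggregation).
#' @param detection_p_max,call_rate_min QC thresholds (defaults 0.01, 0.98).
#' @param variance_tau Relative-sd threshold for the PCA input (default
#'   0.275).
#' @param raw_p_max Paired-test selection cutoff (default 1e-4).
#' @param delta_threshold,min_pairs,min_cpgs Individualized-evaluation
#'   thresholds (defaults 0.1, 3, 3).
#' @param out_dir Optional directory; when given, all result tables and a
#'   config echo are written there as TSV.
#' @return List with `qc_report`, `pca`, `paired` (test_result),
#'   `significant` (probe ids at `raw_p_max`), `delta`
#'   (delta_beta_result), `recurrent` (probe ids), and when annotated
#'   `genes_significant`, `genes_recurrent`, `genes_overlap`.
#' @export
run_short_term <- function(bm, design, ann = NULL,
                           detection_p_max = 0.01, call_rate_min = 0.98,
                           variance_tau = 0.275, raw_p_max = 1e-4,
                           delta_threshold = 0.1, min_pairs = 3, min_cpgs = 3,
                           out_dir = NULL) {
  qc <- apply_qc(bm, call_rate_min = call_rate_min, detection_p_max = detection_p_max)
  kept <- qc$bm
  design_kept <- design[design$sample_id %in% sample_ids(kept), , drop = FALSE]
  design_kept <- paired_design(complete_pairs_only(design_kept))
  pca <- pca_embed(variance_filter(kept, variance_tau))
  paired <- paired_test(kept, design_kept)
  sig <- select_significant(paired, raw_p_max = raw_p_max)
  dr <- classify_trinary(compute_delta_beta(kept, design_kept), delta_threshold)
  rec <- recurrent_targets(dr, min_pairs = min_pairs)
  res <- list(qc_report = qc$report, pca = pca, paired = paired,
              significant = sig, delta = dr, recurrent = rec)
  if (!is.null(ann)) {
    probe_genes <- function(ids) sort(unique(unlist(gene_sets(ann)[intersect(ids, ann$probe_id)])))
    res$genes_significant <- probe_genes(sig)
    gr <- gene_recurrence_filter(rec, ann, min_cpgs = min_cpgs)
    res$genes_recurrent_all <- probe_genes(rec)
    res$genes_recurrent <- gr$genes
    res$genes_overlap <- overlap_gene_lists(res$genes_significant, res$genes_recurrent_all)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(as.data.frame(qc$report), file.path(out_dir, "qc_report.tsv"))
    write_table(paired, file.path(out_dir, "paired_test.tsv"))
    write_table(dr$delta, file.path(out_dir, "delta_matrix.tsv"))
    codes <- dr$codes; storage.mode(codes) <- "integer"
    write_table(codes, file.path(out_dir, "code_matrix.tsv"))
    write_table(data.frame(probe_id = rownames(dr$delta),
                           recurrence_count = dr$recurrence_count),
                file.path(out_dir, "recurrence_counts.tsv"))
    write_table(data.frame(probe_id = rec), file.path(out_dir, "recurrent_targets.tsv"))
    write_config_echo(list(detection_p_max = detection_p_max,
                           call_rate_min = call_rate_min,
                           variance_tau = variance_tau, raw_p_max = raw_p_max,
                           delta_threshold = delta_threshold,
                           min_pairs = min_pairs, min_cpgs = min_cpgs),
                      file.path(out_dir, "config_echo.tsv"))
  }
  res
}

# after sample-level QC some individuals may have lost one member; keep only
# complete pairs
complete_pairs_only <- function(design) {
  tab <- table(design$individual_id)
  design[design$individual_id %in% names(tab)[tab == 2], , drop = FALSE]
}

#' Run the cross-sectional long-term analysis arm
#'
#' QC -> autosomal non-SNP subset -> treated-vs-untreated pooled t-test with
#' BH adjustment -> per-probe regression of beta on treatment months ->
#' optional targeted re-test of a candidate probe list.
#'
#' @param bm A [beta_matrix()].
#' @param design A `cohort_design`.
#' @param ann A `probe_annotation` (required for the autosome/SNP filter).
#' @param candidates Optional candidate probe ids from the paired arm.
#' @param detection_p_max,call_rate_min QC thresholds.
#' @param q_max Discovery threshold on BH q (default 0.05).
#' @param regression_scope Passed to [duration_regression()].
#' @param out_dir Optional output directory for TSV results.
#' @return List with `qc_report`, `unpaired` (test_result), `regression`
#'   (regression_result), `n_discoveries` (probes at q < `q_max` in the
#'   group test), and when candidates are given `targeted` (see
#'   [targeted_subset_test()]).
#' @export
run_long_term <- function(bm, design, ann, candidates = NULL,
                          detection_p_max = 0.01, call_rate_min = 0.98,
                          q_max = 0.05, regression_scope = "treated_only",
                          out_dir = NULL) {
  qc <- apply_qc(bm, call_rate_min = call_rate_min, detection_p_max = detection_p_max)
  kept <- subset_autosomal_non_snp(qc$bm, ann)
  design_kept <- design[design$sample_id %in% sample_ids(kept), , drop = FALSE]
  design_kept <- cohort_design(design_kept)
  unp <- unpaired_test(kept, design_kept)
  reg <- duration_regression(kept, design_kept, scope = regression_scope)
  res <- list(qc_report = qc$report, unpaired = unp, regression = reg,
              n_discoveries = length(select_significant(unp, q_max = q_max)))
  if (!is.null(candidates))
    res$targeted <- targeted_subset_test(kept, design_kept, candidates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(as.data.frame(qc$report), file.path(out_dir, "qc_report.tsv"))
    write_table(unp, file.path(out_dir, "unpaired_test.tsv"))
    write_table(reg, file.path(out_dir, "duration_regression.tsv"))
    write_config_echo(list(detection_p_max = detection_p_max,
                           call_rate_min = call_rate_min, q_max = q_max,
                           regression_scope = regression_scope),
                      file.path(out_dir, "config_echo.tsv"))
  }
  res
}
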