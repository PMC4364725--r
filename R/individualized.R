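# Individualized per-pair evaluation: delta-beta, trinary classification,
# recurrence filtering, gene aggregation and cluster ordering.
#
# Sign convention: delta = beta(stimulated) - beta(baseline), so a code of +1
# means methylation gained under treatment.

#' Per-pair delta-beta values
#'
#' Computes, for every probe and every individual, the within-pair
#' difference of beta values, stimulated minus baseline. A missing beta in
#' either member of the pair yields a missing delta.
#'
#' @param bm A [beta_matrix()] (or plain matrix) containing both samples of
#'   every pair.
#' @param design A `paired_design`.
#' @return A `delta_beta_result`: list with `delta` (probes x individuals
#'   matrix), and placeholders `codes`, `recurrence_count`, `threshold`
#'   filled by [classify_trinary()].
#' @export
compute_delta_beta <- function(bm, design) {
  d <- paired_differences(bm, design)
  structure(list(delta = d, codes = NULL, recurrence_count = NULL,
                 threshold = NA_real_), class = "delta_beta_result")
}

#' @export
print.delta_beta_result <- function(x, ...) {
  cat(sprintf("delta_beta_result: %d probes x %d pairs%s\n",
              nrow(x$delta), ncol(x$delta),
              if (is.null(x$codes)) " (codes not yet classified)"
              else sprintf("; threshold %g, %d recurrent-capable probes",
                           x$threshold, sum(x$recurrence_count > 0))))
  invisible(x)
}

#' Trinary classification of delta-beta values
#'
#' Labels each probe-pair as gained methylation (+1, delta strictly above the
#' threshold), lost methylation (-1, delta strictly below minus the
#' threshold) or unchanged (0). Missing deltas give missing codes, excluded
#' from recurrence counts.
#'
#' @param dr A `delta_beta_result` from [compute_delta_beta()].
#' @param threshold Absolute delta-beta cutoff, strictly between 0 and 1
#'   (default 0.1, i.e. a ten-percentage-point methylation difference).
#' @return The `delta_beta_result` with `codes` (same shape as `delta`,
#'   values -1/0/+1), `recurrence_count` (per-probe count of nonzero codes)
#'   and `threshold` filled.
#' @export
classify_trinary <- function(dr, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_deltabeta("validation_error", "threshold must be in (0,1)")
  codes <- sign(dr$delta) * (abs(dr$delta) > threshold)
  dr$codes <- codes
  dr$recurrence_count <- rowSums(abs(codes), na.rm = TRUE)
  dr$threshold <- threshold
  dr
}

#' Recurrently differentially methylated targets
#'
#' Probes whose delta-beta exceeds the classification threshold (in either
#' direction) in at least `min_pairs` pairs, in input order. The absolute
#' count can alternatively be derived from a fraction of pairs
#' (`min_fraction`), read as "strictly more than" that fraction; with 24
#' pairs, `min_fraction = 0.1` reproduces the 3-of-24 rule.
#'
#' @param dr A classified `delta_beta_result` (see [classify_trinary()]).
#' @param min_pairs Minimum number of exceeding pairs (default 3).
#' @param min_fraction Optional fraction of pairs overriding `min_pairs`.
#' @return Character vector of probe ids.
#' @export
recurrent_targets <- function(dr, min_pairs = 3, min_fraction = NULL) {
  if (is.null(dr$codes))
    stop_deltabeta("usage_error", "codes not computed; call classify_trinary() first")
  n_pairs <- ncol(dr$delta)
  if (!is.null(min_fraction)) min_pairs <- floor(min_fraction * n_pairs) + 1
  if (min_pairs < 1 || min_pairs > n_pairs)
    stop_deltabeta("validation_error", "min_pairs must be in [1, %d]", n_pairs)
  rownames(dr$delta)[dr$recurrence_count >= min_pairs]
}

#' Genes recurrently affected by multiple target probes
#'
#' Aggregates a recurrent-target probe list to genes: a gene is kept when at
#' least `min_cpgs` distinct target probes map to it. A probe annotated to
#' several genes counts once toward each of them; unannotated probes
#' contribute to no gene.
#'
#' @param targets Character vector of target probe ids.
#' @param ann A `probe_annotation`.
#' @param min_cpgs Minimum distinct target probes per gene (default 3).
#' @return List with `genes` (sorted) and `probes` (the subset of `targets`
#'   mapping to a kept gene, input order).
#' @export
gene_recurrence_filter <- function(targets, ann, min_cpgs = 3) {
  if (length(targets) == 0L) return(list(genes = character(), probes = character()))
  sets <- gene_sets(ann)[intersect(targets, ann$probe_id)]
  genes_per_probe <- sets[match(targets, names(sets))]
  genes_per_probe[is.na(names(genes_per_probe))] <- list(character())
  counts <- table(unlist(lapply(genes_per_probe, unique)))
  genes <- sort(names(counts)[counts >= min_cpgs])
  hit <- vapply(genes_per_probe, function(g) any(g %in% genes), logical(1))
  list(genes = genes, probes = targets[hit])
}

#' Intersection of two gene lists
#'
#' Case-sensitive set intersection, sorted lexicographically.
#'
#' @param a,b Character vectors of gene symbols.
#' @return Sorted character vector of shared genes.
#' @export
overlap_gene_lists <- function(a, b) sort(intersect(unique(a), unique(b)))

#' Hierarchical cluster ordering of a delta or code matrix
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) of the rows and columns, as used to order heatmaps of delta-beta
#' values or trinary codes. Missing entries are imputed before clustering:
#' 0 for code matrices, the row mean for delta matrices.
#'
#' @param m Numeric matrix with at least 2 rows and 2 columns.
#' @param type `"delta"` or `"codes"`; `"auto"` (default) treats a matrix
#'   whose values are all in \{-1, 0, 1\} as codes.
#' @return List with `row_order` and `col_order` (leaf index orders) and the
#'   two `hclust` objects (`row_hclust`, `col_hclust`, NULL when degenerate).
#' @export
cluster_order <- function(m, type = c("auto", "delta", "codes")) {
  type <- match.arg(type)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_deltabeta("validation_error", "cluster_order needs >= 2 rows and columns")
  if (type == "auto") {
    vals <- m[!is.na(m)]
    type <- if (length(vals) && all(vals %in% c(-1, 0, 1))) "codes" else "delta"
  }
  if (anyNA(m)) {
    if (type == "codes") {
      m[is.na(m)] <- 0
    } else {
      rm <- row_mean(m)
      rm[is.na(rm)] <- 0
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- rm[idx[, 1]]
    }
  }
  if (max(m) == min(m)) {
    warning("degenerate all-equal matrix: input order returned")
    return(list(row_order = seq_len(nrow(m)), col_order = seq_len(ncol(m)),
                row_hclust = NULL, col_hclust = NULL))
  }
  hr <- stats::hclust(stats::dist(m), method = "complete")
  hc <- stats::hclust(stats::dist(t(m)), method = "complete")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc)
}
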