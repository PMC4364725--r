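# Shared fixtures and independent oracles, built in code.

make_bm <- function(beta, detection_p = NULL,
                    probes = sprintf("cg%03d", seq_len(nrow(beta))),
                    samples = sprintf("s%d", seq_len(ncol(beta)))) {
  dimnames(beta) <- list(probes, samples)
  if (!is.null(detection_p)) dimnames(detection_p) <- dimnames(beta)
  beta_matrix(beta, detection_p)
}

make_paired_design <- function(n) {
  inds <- sprintf("I%02d", seq_len(n))
  paired_design(data.frame(
    sample_id = c(paste0(inds, "_base"), paste0(inds, "_stim")),
    individual_id = rep(inds, 2),
    timepoint = rep(c("baseline", "stimulated"), each = n),
    stringsAsFactors = FALSE))
}

random_paired_bm <- function(n_probes, n_pairs) {
  design <- make_paired_design(n_pairs)
  beta <- matrix(runif(n_probes * 2 * n_pairs), n_probes, 2 * n_pairs)
  dimnames(beta) <- list(sprintf("cg%05d", seq_len(n_probes)), design$sample_id)
  list(bm = beta_matrix(beta), design = design)
}

make_annotation <- function(probe_id, probe_class, chromosome,
                            gene_symbols = rep("", length(probe_id))) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(probe_id = probe_id, probe_class = probe_class,
               chromosome = chromosome, position = seq_along(probe_id),
               gene_symbols = gene_symbols, stringsAsFactors = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_annotation(f)
}

# O(m^2) Benjamini-Hochberg straight from the step-up definition
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# single-pass scan of the raw matrix: recurrent targets without going
# through the delta/classify pipeline
recurrence_brute_force <- function(bm, design, threshold, min_pairs) {
  inds <- unique(design$individual_id)
  hits <- character()
  for (g in rownames(bm$beta)) {
    count <- 0L
    for (i in inds) {
      b <- bm$beta[g, design$sample_id[design$individual_id == i & design$timepoint == "baseline"]]
      s <- bm$beta[g, design$sample_id[design$individual_id == i & design$timepoint == "stimulated"]]
      if (!is.na(b) && !is.na(s) && abs(s - b) > threshold) count <- count + 1L
    }
    if (count >= min_pairs) hits <- c(hits, g)
  }
  hits
}

# fraction of samples whose nearest neighbour in PCA score space is the
# other sample of the same individual
pca_pairing_fraction <- function(scores) {
  D <- as.matrix(dist(scores))
  diag(D) <- Inf
  nn <- rownames(D)[apply(D, 1, which.min)]
  ind <- function(x) sub("_(base|stim)$", "", x)
  mean(ind(rownames(D)) == ind(nn))
}

write_tsv_file <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  f
}
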