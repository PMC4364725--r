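# Core data model and tabular IO.
#
# The pipeline's central object is the beta matrix: probes x samples average
# beta values in [0,1] with a parallel matrix of per-call detection p-values.
# All files are tab-delimited text with a single header row, "." as decimal
# point and "NA" for missing cells.

#' Construct a beta matrix
#'
#' Bundles a probes x samples matrix of average beta values (methylation
#' fractions in \[0,1\]) with a same-shaped matrix of detection p-values.
#' Row names are probe ids, column names are sample ids; both must be unique.
#'
#' @param beta Numeric matrix of beta values with probe row names and sample
#'   column names. Missing entries are allowed and kept as `NA`.
#' @param detection_p Numeric matrix of detection p-values with identical
#'   dimnames, or `NULL` to fill with 0 (every call passes).
#' @return An object of class `beta_matrix`: a list with elements `beta` and
#'   `detection_p`.
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop_deltabeta("validation_error", "beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop_deltabeta("validation_error", "beta must have probe row names and sample column names")
  if (anyDuplicated(rownames(beta)))
    stop_deltabeta("validation_error", "duplicate probe id: %s",
                   rownames(beta)[duplicated(rownames(beta))][1])
  if (anyDuplicated(colnames(beta)))
    stop_deltabeta("validation_error", "duplicate sample id: %s",
                   colnames(beta)[duplicated(colnames(beta))][1])
  check_unit_interval(beta, "beta")
  if (is.null(detection_p)) {
    detection_p <- array(0, dim(beta), dimnames = dimnames(beta))
  } else {
    if (!identical(dim(beta), dim(detection_p)))
      stop_deltabeta("key_mismatch_error", "beta and detection_p dimensions differ")
    key_diff <- function(a, b, what) {
      if (!identical(a, b))
        stop_deltabeta("key_mismatch_error", "%s keys differ: only-beta {%s} vs only-detection {%s}",
                       what, paste(setdiff(a, b), collapse = ","),
                       paste(setdiff(b, a), collapse = ","))
    }
    key_diff(rownames(beta), rownames(detection_p), "probe")
    key_diff(colnames(beta), colnames(detection_p), "sample")
    check_unit_interval(detection_p, "detection_p")
  }
  structure(list(beta = beta, detection_p = detection_p), class = "beta_matrix")
}

check_unit_interval <- function(m, what) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_deltabeta("validation_error", "%s value %g outside [0,1] at probe %s, sample %s",
                   what, m[bad[1, 1], bad[1, 2]],
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  }
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing beta calls)\n",
              nrow(x$beta), ncol(x$beta), sum(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

probe_ids <- function(bm) rownames(bm$beta)
sample_ids <- function(bm) colnames(bm$beta)

subset_beta_matrix <- function(bm, probes = NULL, samples = NULL) {
  b <- bm$beta; d <- bm$detection_p
  if (!is.null(probes)) { b <- b[probes, , drop = FALSE]; d <- d[probes, , drop = FALSE] }
  if (!is.null(samples)) { b <- b[, samples, drop = FALSE]; d <- d[, samples, drop = FALSE] }
  structure(list(beta = b, detection_p = d), class = "beta_matrix")
}

read_numeric_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop_deltabeta("validation_error", "%s: expected probe_id column plus sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Load a beta-value dataset from delimited text
#'
#' Reads a probes x samples table of average beta values (first column probe
#' id, one header row of sample ids) and, optionally, a detection p-value
#' table with identical row and column keys.
#'
#' @param beta_path Path to the tab-delimited beta table.
#' @param detection_path Optional path to the matching detection p-value
#'   table. When omitted, detection p-values are filled with 0 so every call
#'   passes QC.
#' @return A [beta_matrix()].
#' @export
load_dataset <- function(beta_path, detection_path = NULL) {
  beta <- read_numeric_table(beta_path)
  det <- NULL
  if (!is.null(detection_path)) {
    det <- read_numeric_table(detection_path)
    # align only when the key sets agree; otherwise let the constructor name
    # the difference
    if (setequal(rownames(beta), rownames(det)) && setequal(colnames(beta), colnames(det)))
      det <- det[rownames(beta), colnames(beta), drop = FALSE]
  }
  beta_matrix(beta, det)
}

#' Load a probe annotation table
#'
#' Reads a tab-delimited manifest with columns `probe_id`, `probe_class`
#' (one of `cg`, `ch`, `rs`: CpG assay, non-CpG cytosine assay, SNP identity
#' assay), `chromosome`, `position` and semicolon-separated `gene_symbols`.
#'
#' @param path Path to the annotation file.
#' @return A data frame of class `probe_annotation` with an attached
#'   `class_counts` attribute (assays per probe class).
#' @export
load_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "NA", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("probe_id", "probe_class", "chromosome", "position", "gene_symbols")
  if (!all(need %in% names(df)))
    stop_deltabeta("validation_error", "annotation must have columns: %s",
                   paste(need, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop_deltabeta("validation_error", "duplicate probe_id in annotation: %s",
                   df$probe_id[duplicated(df$probe_id)][1])
  bad <- setdiff(unique(df$probe_class), c("cg", "ch", "rs"))
  if (length(bad))
    stop_deltabeta("validation_error", "unknown probe_class token: %s", bad[1])
  df$position <- suppressWarnings(as.numeric(df$position))
  if (any(!is.na(df$position) & df$position < 1))
    stop_deltabeta("validation_error", "position must be >= 1")
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  counts <- table(factor(df$probe_class, levels = c("cg", "ch", "rs")))
  structure(df, class = c("probe_annotation", "data.frame"),
            class_counts = as.integer(counts))
}

#' Per-class assay counts of an annotation
#'
#' @param ann A `probe_annotation`.
#' @return Named integer vector with counts for `cg`, `ch`, `rs` and `total`.
#' @export
annotation_class_counts <- function(ann) {
  n <- attr(ann, "class_counts")
  c(cg = n[1], ch = n[2], rs = n[3], total = sum(n))
}

# probe id -> character vector of gene symbols (possibly empty)
gene_sets <- function(ann) {
  sets <- strsplit(ann$gene_symbols, ";", fixed = TRUE)
  sets <- lapply(sets, function(g) g[nzchar(g)])
  names(sets) <- ann$probe_id
  sets
}

#' Load a sample design sheet
#'
#' In `paired` mode the sheet must have columns `sample_id`, `individual_id`
#' and `timepoint` (`baseline` or `stimulated`), with exactly one sample per
#' individual and timepoint. In `cohort` mode it must have `sample_id`,
#' `group` (`treated` or `untreated`) and `treatment_months` (required and
#' positive-or-zero for treated samples; untreated default to 0).
#'
#' @param path Path to the tab-delimited sample sheet.
#' @param mode `"paired"` or `"cohort"`.
#' @return A data frame of class `paired_design` or `cohort_design`.
#' @export
load_design <- function(path, mode = c("paired", "cohort")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  if (mode == "paired") paired_design(df) else cohort_design(df)
}

#' Construct a paired baseline/stimulated design
#'
#' @param df Data frame with columns `sample_id`, `individual_id`,
#'   `timepoint`.
#' @return A `paired_design` data frame.
#' @export
paired_design <- function(df) {
  need <- c("sample_id", "individual_id", "timepoint")
  if (!all(need %in% names(df)))
    stop_deltabeta("design_error", "paired design needs columns: %s", paste(need, collapse = ", "))
  if (!all(df$timepoint %in% c("baseline", "stimulated")))
    stop_deltabeta("design_error", "timepoint must be baseline or stimulated")
  if (anyDuplicated(df$sample_id))
    stop_deltabeta("design_error", "duplicate sample_id in design")
  tab <- table(df$individual_id, factor(df$timepoint, c("baseline", "stimulated")))
  bad <- rownames(tab)[tab[, 1] != 1 | tab[, 2] != 1]
  if (length(bad))
    stop_deltabeta("design_error",
                   "individual %s does not have exactly one baseline and one stimulated sample", bad[1])
  structure(as.data.frame(df)[need], class = c("paired_design", "data.frame"))
}

#' Construct a treated/untreated cohort design
#'
#' @param df Data frame with columns `sample_id`, `group`,
#'   `treatment_months`.
#' @return A `cohort_design` data frame.
#' @export
cohort_design <- function(df) {
  need <- c("sample_id", "group", "treatment_months")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_deltabeta("design_error", "cohort design needs columns sample_id and group")
  if (!all(df$group %in% c("treated", "untreated")))
    stop_deltabeta("design_error", "group must be treated or untreated")
  if (anyDuplicated(df$sample_id))
    stop_deltabeta("design_error", "duplicate sample_id in design")
  if (is.null(df$treatment_months)) df$treatment_months <- NA_real_
  df$treatment_months[df$group == "untreated" & is.na(df$treatment_months)] <- 0
  if (any(df$group == "treated" & is.na(df$treatment_months)))
    stop_deltabeta("design_error", "treated sample without treatment_months: %s",
                   df$sample_id[df$group == "treated" & is.na(df$treatment_months)][1])
  if (any(df$treatment_months < 0, na.rm = TRUE))
    stop_deltabeta("design_error", "treatment_months must be >= 0")
  structure(as.data.frame(df)[need], class = c("cohort_design", "data.frame"))
}

#' Write a result table as tab-delimited text
#'
#' Writes any tabular result with a header row, "NA" for missing values and
#' numeric values rendered with enough significant digits to re-read
#' bit-for-bit. Row order is the input order.
#'
#' @param result A data frame, matrix, or `beta_matrix`.
#' @param path Output file path.
#' @param what For a `beta_matrix`: which slot to write (`"beta"` or
#'   `"detection_p"`).
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path, what = "beta") {
  UseMethod("write_table")
}

#' @export
write_table.beta_matrix <- function(result, path, what = c("beta", "detection_p")) {
  what <- match.arg(what)
  write_table(result[[what]], path)
}

#' @export
write_table.matrix <- function(result, path, what = "beta") {
  df <- data.frame(probe_id = rownames(result), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(result))) df[[colnames(result)[j]]] <- result[, j]
  write_table(df, path)
}

#' @export
write_table.data.frame <- function(result, path, what = "beta") {
  out <- result
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop_deltabeta("io_error", "cannot write %s: %s", path,
                                       conditionMessage(e))
  )
  invisible(path)
}
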