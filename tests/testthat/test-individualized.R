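test_that("delta-beta is stimulated minus baseline, per pair", {
  design <- make_paired_design(2)
  beta <- matrix(c(0.30, 0.20,   # baselines I01, I02
                   0.45, 0.20),  # stimulated I01, I02
                 1, 4, dimnames = list("cgA", design$sample_id))
  dr <- compute_delta_beta(beta_matrix(beta), design)
  expect_equal(dr$delta["cgA", "I01"], 0.15)
  expect_equal(dr$delta["cgA", "I02"], 0)
  # identical timepoints give all-zero deltas
  b0 <- matrix(0.4, 3, 4, dimnames = list(c("a", "b", "c"), design$sample_id))
  expect_true(all(compute_delta_beta(beta_matrix(b0), design)$delta == 0))
  # swapping labels negates every delta
  swapped <- design
  swapped$timepoint <- ifelse(swapped$timepoint == "baseline", "stimulated", "baseline")
  dr2 <- compute_delta_beta(beta_matrix(beta), paired_design(swapped))
  expect_equal(dr2$delta, -dr$delta)
  # missing member gives missing delta
  beta[1, 1] <- NA
  drna <- compute_delta_beta(beta_matrix(beta), design)
  expect_true(is.na(drna$delta["cgA", "I01"]))
})

test_that("trinary classification uses strict inequalities at the threshold", {
  design <- make_paired_design(3)
  base <- matrix(0.4, 1, 3)
  stim <- base + c(0.15, -0.15, 0.05)
  beta <- cbind(base, stim)
  dimnames(beta) <- list("cgA", design$sample_id)
  dr <- classify_trinary(compute_delta_beta(beta_matrix(beta), design))
  expect_equal(unname(dr$codes["cgA", ]), c(1, -1, 0))
  expect_equal(unname(dr$recurrence_count), 2)

  # exactly +/-0.1 codes 0 (strict inequality); inject exact deltas to avoid
  # floating-point subtraction artefacts
  dr2 <- dr
  dr2$delta["cgA", ] <- c(0.1, -0.1, 0.10000001)
  dr2 <- classify_trinary(dr2)
  expect_equal(unname(dr2$codes["cgA", ]), c(0, 0, 1))

  expect_error(classify_trinary(dr, threshold = 0), class = "deltabeta_validation_error")
  expect_error(classify_trinary(dr, threshold = 1), class = "deltabeta_validation_error")
})

test_that("recurrent targets respect the min-pairs cutoff and fraction form", {
  set.seed(5)
  rp <- random_paired_bm(50, 24)
  dr <- classify_trinary(compute_delta_beta(rp$bm, rp$design))
  rt3 <- recurrent_targets(dr, 3)
  expect_setequal(rt3, rownames(dr$delta)[dr$recurrence_count >= 3])
  # fraction form: strictly more than 10% of 24 pairs = 3
  expect_equal(recurrent_targets(dr, min_fraction = 0.1), rt3)
  expect_error(recurrent_targets(dr, 0), class = "deltabeta_validation_error")
  expect_error(recurrent_targets(dr, 25), class = "deltabeta_validation_error")
  expect_error(recurrent_targets(compute_delta_beta(rp$bm, rp$design), 3),
               class = "deltabeta_usage_error")
})

test_that("recurrence pipeline agrees exactly with the brute-force scan", {
  set.seed(20)
  for (rep in 1:10) {
    np <- sample(10:120, 1)
    npairs <- sample(2:24, 1)
    rp <- random_paired_bm(np, npairs)
    thr <- runif(1, 0.05, 0.3)
    mp <- sample(seq_len(npairs), 1)
    fast <- recurrent_targets(classify_trinary(compute_delta_beta(rp$bm, rp$design), thr), mp)
    slow <- recurrence_brute_force(rp$bm, rp$design, thr, mp)
    expect_identical(fast, slow)
  }
})

test_that("recurrent sets shrink monotonically and ignore global sign", {
  set.seed(8)
  rp <- random_paired_bm(200, 12)
  dr1 <- classify_trinary(compute_delta_beta(rp$bm, rp$design), 0.1)
  dr2 <- classify_trinary(compute_delta_beta(rp$bm, rp$design), 0.2)
  expect_true(all(recurrent_targets(dr2, 3) %in% recurrent_targets(dr1, 3)))
  expect_true(all(recurrent_targets(dr1, 5) %in% recurrent_targets(dr1, 3)))
  # negating deltas leaves the set unchanged
  neg <- dr1
  neg$delta <- -neg$delta
  neg <- classify_trinary(neg, 0.1)
  expect_identical(recurrent_targets(neg, 3), recurrent_targets(dr1, 3))
})

test_that("gene aggregation counts distinct target probes per gene", {
  ann <- make_annotation(sprintf("cg%d", 1:5),
                         rep("cg", 5), rep("1", 5),
                         gene_symbols = c("geneA", "geneA", "geneA;geneB", "geneB", ""))
  out <- gene_recurrence_filter(sprintf("cg%d", 1:4), ann, min_cpgs = 3)
  expect_equal(out$genes, "geneA")
  expect_equal(out$probes, c("cg1", "cg2", "cg3"))
  # min_cpgs = 1 keeps every touched gene
  out1 <- gene_recurrence_filter(sprintf("cg%d", 1:5), ann, min_cpgs = 1)
  expect_equal(out1$genes, c("geneA", "geneB"))
  expect_equal(gene_recurrence_filter(character(), ann)$genes, character())
})

test_that("gene-list overlap is a sorted case-sensitive intersection", {
  expect_equal(overlap_gene_lists(c("A", "B", "C"), c("C", "B", "D")), c("B", "C"))
  expect_equal(overlap_gene_lists(c("a"), c("A")), character())
  expect_equal(overlap_gene_lists(character(), c("A")), character())
})

test_that("cluster ordering separates obvious blocks and handles degeneracy", {
  m <- rbind(c(0, 0, 1, 1), c(0.1, 0, 1, 0.9),
             c(1, 1, 0, 0), c(0.9, 1, 0.1, 0))
  rownames(m) <- paste0("r", 1:4)
  ord <- cluster_order(m, type = "delta")
  pos <- match(1:4, ord$row_order)
  expect_true(abs(pos[1] - pos[2]) == 1 && abs(pos[3] - pos[4]) == 1)
  # identical rows are adjacent leaves
  m2 <- rbind(m, r5 = m[1, ])
  ord2 <- cluster_order(m2, type = "delta")
  expect_equal(abs(match(1, ord2$row_order) - match(5, ord2$row_order)), 1)
  # permuting rows preserves merge heights
  perm <- c(3, 1, 4, 2)
  h1 <- sort(cluster_order(m, type = "delta")$row_hclust$height)
  h2 <- sort(cluster_order(m[perm, ], type = "delta")$row_hclust$height)
  expect_equal(h1, h2)
  expect_warning(ordd <- cluster_order(matrix(0.5, 3, 3)), "degenerate")
  expect_equal(ordd$row_order, 1:3)
  # missing codes impute to 0, missing deltas to the row mean
  mc <- rbind(c(1, NA, -1), c(0, 0, 1), c(1, 0, -1))
  expect_silent(cluster_order(mc))
})
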