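test_that("variance filter keeps probes above the relative-sd threshold, strictly", {
  # probes engineered with sd ratios 1, 0.5, 0
  beta <- rbind(c(0.2, 0.4), c(0.3, 0.4), c(0.5, 0.5))
  bm <- make_bm(beta)
  out <- variance_filter(bm, 0.6)
  expect_equal(rownames(out$beta), "cg001")
  # tau = 0 keeps every probe with sd > 0
  expect_equal(nrow(variance_filter(bm, 0)$beta), 2)
  # a constant probe is excluded at any tau >= 0
  expect_false("cg003" %in% rownames(variance_filter(bm, 0)$beta))
  # exact boundary is excluded (strict >)
  expect_equal(nrow(variance_filter(bm, 0.5)$beta), 1)
  # constant matrix is degenerate
  expect_error(variance_filter(make_bm(matrix(0.5, 3, 3)), 0.1),
               class = "deltabeta_degenerate_error")
})

test_that("PCA embedding handles identity and rank-1 cases and caps components", {
  b <- matrix(runif(10), 5, 2)
  b[, 2] <- b[, 1]
  pr <- pca_embed(make_bm(b))
  expect_equal(dist(pr$scores)[1], 0)

  b2 <- matrix(runif(10), 5, 2)
  pr2 <- pca_embed(make_bm(b2))
  expect_equal(pr2$explained_variance[1], 1)

  b3 <- matrix(runif(40), 10, 4)
  expect_warning(pr3 <- pca_embed(make_bm(b3), n_components = 10), "capped")
  expect_lte(ncol(pr3$scores), 3)
  expect_true(all(diff(pr3$explained_variance) <= 1e-12))
})

test_that("unpaired pooled t matches stats::t.test probe by probe", {
  design <- cohort_design(data.frame(
    sample_id = sprintf("s%d", 1:10),
    group = rep(c("treated", "untreated"), each = 5),
    treatment_months = c(runif(5, 10, 60), rep(0, 5))))
  set.seed(42)
  beta <- matrix(runif(200), 20, 10, dimnames = list(sprintf("cg%03d", 1:20), design$sample_id))
  tr <- unpaired_test(beta_matrix(beta), design)
  for (g in c(1, 7, 20)) {
    o <- t.test(beta[g, 1:5], beta[g, 6:10], var.equal = TRUE)
    expect_equal(tr$statistic[g], unname(o$statistic))
    expect_equal(tr$raw_p[g], o$p.value)
    expect_equal(tr$mean_diff[g], unname(o$estimate[1] - o$estimate[2]))
  }
  # textbook two-point example
  b2 <- matrix(c(0.1, 0.2, 0.7, 0.8), 1, 4,
               dimnames = list("cg1", c("a1", "a2", "b1", "b2")))
  d2 <- cohort_design(data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                                 group = c("treated", "treated", "untreated", "untreated"),
                                 treatment_months = c(1, 1, 0, 0)))
  tr2 <- unpaired_test(beta_matrix(b2), d2)
  o2 <- t.test(c(0.1, 0.2), c(0.7, 0.8), var.equal = TRUE)
  expect_equal(tr2$statistic, unname(o2$statistic))
  expect_equal(tr2$raw_p, o2$p.value)
  # symmetric data give t = 0, p = 1
  b3 <- matrix(c(0.1, 0.3, 0.1, 0.3), 1, 4, dimnames = dimnames(b2))
  tr3 <- unpaired_test(beta_matrix(b3), d2)
  expect_equal(tr3$statistic, 0)
  expect_equal(tr3$raw_p, 1)
  # group with < 2 samples is a design error
  expect_error(unpaired_test(beta_matrix(b2),
                             cohort_design(data.frame(sample_id = c("a1", "b1", "b2"),
                                                      group = c("treated", "untreated", "untreated"),
                                                      treatment_months = c(1, 0, 0)))),
               class = "deltabeta_design_error")
})

test_that("paired t matches stats::t.test and its closed form", {
  design <- make_paired_design(4)
  base <- matrix(0.3, 2, 4)
  stim <- base + rbind(c(0.01, 0.02, 0.03, 0.04), c(0.05, -0.05, 0.05, -0.05))
  beta <- cbind(base, stim)
  dimnames(beta) <- list(c("cgA", "cgB"), design$sample_id)
  tr <- paired_test(beta_matrix(beta), design)
  o <- t.test(stim[1, ], base[1, ], paired = TRUE)
  expect_equal(tr$statistic[1], unname(o$statistic))
  expect_equal(tr$raw_p[1], o$p.value)
  expect_equal(tr$statistic[1], mean(1:4) / (sd(1:4) / 2), tolerance = 1e-12)
  # antisymmetric differences: t = 0, p = 1
  expect_equal(tr$statistic[2], 0)
  expect_equal(tr$raw_p[2], 1)
})

test_that("swapping timepoint labels negates t and mean_diff, keeps p", {
  set.seed(7)
  rp <- random_paired_bm(30, 6)
  swapped <- rp$design
  swapped$timepoint <- ifelse(swapped$timepoint == "baseline", "stimulated", "baseline")
  a <- paired_test(rp$bm, rp$design)
  b <- paired_test(rp$bm, paired_design(swapped))
  expect_equal(b$statistic, -a$statistic)
  expect_equal(b$mean_diff, -a$mean_diff)
  expect_equal(b$raw_p, a$raw_p)
})

test_that("BH adjustment equals the O(m^2) step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (m in c(1, 2, 17, 200)) {
    p <- runif(m)^2
    expect_equal(adjust_bh(p), bh_brute_force(p))
  }
  # missing p-values pass through without inflating m
  p <- c(0.01, NA, 0.04)
  q <- adjust_bh(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_brute_force(p[c(1, 3)]))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "deltabeta_validation_error")
})

test_that("q-values are monotone in the rank of raw p", {
  set.seed(3)
  p <- runif(100)
  q <- adjust_bh(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("select_significant applies strict-inequality criteria", {
  tr <- structure(data.frame(probe_id = c("a", "b", "c"),
                             statistic = 1:3,
                             raw_p = c(0.00005, 0.0001, 0.5),
                             q = c(0.03, 0.2, 0.9),
                             mean_diff = 0, n_used = 4, flag = ""),
                  class = c("test_result", "data.frame"))
  expect_equal(select_significant(tr, raw_p_max = 0.0001), "a")
  expect_equal(select_significant(tr, q_max = 0.05), "a")
  expect_equal(select_significant(tr, raw_p_max = 0.0001, q_max = 0.05),
               intersect(select_significant(tr, raw_p_max = 0.0001),
                         select_significant(tr, q_max = 0.05)))
  expect_error(select_significant(tr), class = "deltabeta_usage_error")
})

test_that("unpaired test is calibrated under a two-group null", {
  set.seed(101)
  n <- 10000
  beta <- matrix(runif(n * 10), n, 10,
                 dimnames = list(sprintf("cg%05d", 1:n), sprintf("s%d", 1:10)))
  design <- cohort_design(data.frame(sample_id = sprintf("s%d", 1:10),
                                     group = rep(c("treated", "untreated"), each = 5),
                                     treatment_months = c(rep(12, 5), rep(0, 5))))
  tr <- unpaired_test(beta_matrix(beta), design)
  frac <- mean(tr$raw_p < 0.05, na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})
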