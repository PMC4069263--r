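test_that("expression reader validates ids, metadata and cell types", {
  m <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("g1", "g2"),
                              sprintf("%s_t02_r%d", rep(c("CF", "RF", "SF"), 2),
                                      rep(1:2, each = 3))))
  meta <- data.frame(sample_id = colnames(m),
                     cohort = rep(c("CF", "RF", "SF"), 2),
                     time_h = 2, replicate = rep(1:2, each = 3))
  x <- expression_matrix(m, meta)
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, mp, sp)
  back <- read_expression(mp, sp)
  expect_equal(back$values, x$values, tolerance = 1e-9)

  expect_error(expression_matrix(m, meta[-2, ]), meta$sample_id[2])
  m2 <- m; rownames(m2) <- c("g1", "g1")
  expect_error(expression_matrix(m2, meta), "duplicate gene ids: g1")
  m3 <- m; m3[1, 1] <- NA
  expect_error(expression_matrix(m3, meta), "non-finite")
})

test_that("quantile normalization: worked example, identical-column fixpoint, defining property", {
  m <- cbind(a = c(1, 2), b = c(3, 4))
  rownames(m) <- c("g1", "g2")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2, 3), c(2, 3)))

  same <- matrix(rep(c(5, 1, 3), 4), nrow = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(quantile_normalize(same), same)

  set.seed(7)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("paired t matches the closed form and the one-sample oracle", {
  # differences 1,2,3,4: t = 2.5 / (sd/2), p from t with 3 df
  a <- c(t2 = 2, t4 = 4, t6 = 6, t8 = 8)
  b <- c(t2 = 1, t4 = 2, t6 = 3, t8 = 4)
  got <- paired_t(a, b)
  expect_equal(got$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(got$t, 3.872983, tolerance = 1e-6)
  expect_equal(got$p, 2 * pt(-got$t, 3), tolerance = 1e-12)
  expect_equal(got$p, 0.03046629, tolerance = 1e-6)  # 2 * pt(-3.872983, 3)
  # equals one-sample t.test on the differences
  tt <- t.test(a - b)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
})

test_that("paired t conventions: antisymmetry, zero variance, short input", {
  a <- c(t2 = 2, t4 = 4, t6 = 6); b <- c(t2 = 1, t4 = 5, t6 = 2)
  f <- paired_t(a, b); r <- paired_t(b, a)
  expect_equal(f$t, -r$t)
  expect_equal(f$mean_diff, -r$mean_diff)
  expect_equal(f$p, r$p)

  same <- paired_t(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  expect_true(same$zero_variance)

  shifted <- paired_t(a + 1, a)
  expect_equal(shifted$p, 0)
  expect_true(shifted$zero_variance)

  expect_error(paired_t(a[1], b[1]), ">= 2 matched")
  expect_error(paired_t(c(t2 = 1, t4 = 2), c(t2 = 1, t9 = 2)), "time points")
})

test_that("BH worked examples and brute-force step-up equivalence", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:25) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # monotone: p_i <= p_j implies q_i <= q_j
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("run_comparisons matches per-gene paired_t and pools the correction", {
  cfg <- expr_sim_config(n_genes = 25, seed = 3)
  sim <- simulate_expression(cfg)
  comp <- run_comparisons(sim$expr)
  expect_equal(nrow(comp), 25 * 3)
  expect_true(all(comp$q >= comp$p - 1e-12))
  expect_true(all(comp$fold_change > 0))
  # oracle: recompute one comparison per gene with the scalar paired_t
  meta <- sim$expr$metadata
  tmean <- function(co, g) {
    keep <- meta$cohort == co
    tapply(sim$expr$values[g, keep], meta$time_h[keep], mean)
  }
  for (g in c("g0001", "g0013", "g0025")) {
    one <- paired_t(tmean("SF", g), tmean("CF", g))
    row <- comp[comp$gene_id == g & comp$comparison == "SF_vs_CF", ]
    expect_equal(row$t, one$t, tolerance = 1e-9)
    expect_equal(row$p, one$p, tolerance = 1e-9)
    expect_equal(row$mean_diff_log2, one$mean_diff, tolerance = 1e-9)
  }
  # pooled correction: q equals BH over the full 3 x n_genes p vector
  expect_equal(comp$q, bh_fdr(comp$p), tolerance = 1e-12)
  # missing cohort errors by name
  sub <- sim$expr
  keep <- sub$metadata$cohort != "SF"
  sub$values <- sub$values[, keep]
  sub$metadata <- sub$metadata[keep, ]
  expect_error(run_comparisons(sub), "SF")
})

test_that("gene order permutation permutes comparison rows identically", {
  cfg <- expr_sim_config(n_genes = 12, seed = 6)
  sim <- simulate_expression(cfg)
  comp1 <- run_comparisons(sim$expr)
  perm <- rev(seq_len(12))
  x2 <- sim$expr
  x2$values <- x2$values[perm, ]
  comp2 <- run_comparisons(x2)
  for (cm in unique(comp1$comparison)) {
    a <- comp1[comp1$comparison == cm, ]
    b <- comp2[comp2$comparison == cm, ]
    b <- b[match(a$gene_id, b$gene_id), ]
    expect_equal(a$t, b$t)
    expect_equal(a$q, b$q)
  }
})

test_that("under the all-null design raw p-values are uniform at the 5% level", {
  cfg <- expr_sim_config(n_genes = 400, archetype_mix = c(null = 1),
                         sigma = 0.25, seed = 19)
  comp <- run_comparisons(simulate_expression(cfg)$expr)
  frac <- mean(comp$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(comp))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)  # tests share samples, allow slack
  expect_equal(sum(comp$q < 0.05), 0)
})
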