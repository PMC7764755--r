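toy_pool_table <- function(values, groups) {
  structure(list(values = values,
                 samples = tibble::tibble(
                   sample_id = rownames(values),
                   group = groups)),
            class = "pool_table")
}

test_that("pool normalization divides by norvaline and protein", {
  tab <- tibble::tibble(
    sample_id = "s1", tissue = "brain", time_min = 15, group = "WT",
    metabolite_id = "lactate", mass_shift = 0:3,
    raw_abundance = c(400, 300, 200, 100),
    norvaline = 10, protein_mg = 2
  )
  pt <- normalize_pools(tab, value_col = "raw_abundance")
  expect_equal(unname(pt$values["s1", "lactate"]), 1000 / 10 / 2)
  # common scaling of counts and internal standard cancels
  tab2 <- dplyr::mutate(tab, raw_abundance = raw_abundance * 7,
                        norvaline = norvaline * 7)
  pt2 <- normalize_pools(tab2, value_col = "raw_abundance")
  expect_equal(pt2$values, pt$values)
  tab3 <- dplyr::mutate(tab, protein_mg = 0)
  expect_error(normalize_pools(tab3, value_col = "raw_abundance"), "s1")
})

test_that("IQR filtering drops the flattest metabolites first", {
  set.seed(31)
  x <- matrix(stats::rnorm(60, sd = rep(1:10, each = 6)), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("met", 1:10)))
  x[, "met3"] <- 5  # constant: IQR zero, dropped first
  expect_identical(iqr_filter(x, 0), x)
  kept <- iqr_filter(x, 0.2)
  expect_equal(ncol(kept), 8)
  expect_false("met3" %in% colnames(kept))
})

test_that("auto-scaling is exact and idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- autoscale(x)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(s)) < 1e-12))
  expect_equal(apply(s, 2, stats::sd), c(a = 1, b = 1))
  expect_equal(autoscale(s), s, tolerance = 1e-12)
  x[, "b"] <- 4
  expect_error(autoscale(x), "zero-variance")
})

test_that("two-stage BKY reproduces the hand-computed fixture", {
  # q' = 0.05/1.05 = 0.047619; stage 1 rejects 3; stage 2 level
  # 0.047619 * 4 / 1 = 0.190476 confirms the same 3
  flags <- two_stage_bky(c(0.001, 0.01, 0.02, 0.8), Q = 0.05)
  expect_equal(flags, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(two_stage_bky(rep(1, 10), Q = 0.05)), 0)
  expect_error(two_stage_bky(c(0.5, 1.2)), "0, 1")
  expect_error(two_stage_bky(0.5, Q = 0), "Q")
})

test_that("BKY rejections are monotone in Q and dominate plain BH", {
  set.seed(32)
  for (i in 1:40) {
    p <- c(stats::runif(30), stats::rbeta(10, 0.2, 4))
    r_lo <- two_stage_bky(p, Q = 0.01)
    r_hi <- two_stage_bky(p, Q = 0.10)
    expect_true(all(r_hi[r_lo]))  # nested discovery sets
    bh <- stats::p.adjust(p, "BH") <= 0.05
    expect_gte(sum(two_stage_bky(p, Q = 0.05)), sum(bh))
  }
})

test_that("BKY keeps the realized FDR at or below Q in simulation", {
  set.seed(33)
  n_rep <- 500; m <- 80; q <- 0.05
  fdp_null <- numeric(n_rep); fdp_mix <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    a <- matrix(stats::rnorm(m * 5), m); b <- matrix(stats::rnorm(m * 5), m)
    rej <- two_stage_bky(welch_p(a, b), q)
    fdp_null[r] <- if (any(rej)) 1 else 0  # all nulls: any rejection is false
    shift <- c(rep(2.5, 20), rep(0, m - 20))
    rej2 <- two_stage_bky(welch_p(a, b + shift), q)
    fdp_mix[r] <- if (any(rej2)) sum(rej2[21:m]) / sum(rej2) else 0
  }
  mc_tol <- 3 * stats::sd(fdp_mix) / sqrt(n_rep)
  expect_lte(mean(fdp_null), q + 3 * stats::sd(fdp_null) / sqrt(n_rep))
  expect_lte(mean(fdp_mix), q + mc_tol)
})

test_that("group comparison flags a strong shift and not identical groups", {
  set.seed(34)
  x <- matrix(stats::rnorm(200), nrow = 20,
              dimnames = list(NULL, paste0("met", 1:10)))
  x[11:20, "met1"] <- x[11:20, "met1"] + 5
  groups <- rep(c("WT", "KO"), each = 10)
  res <- group_compare(x, reference = "WT", groups = groups, Q = 0.01)
  expect_true(res$discovery[res$variable == "met1"])
  expect_lt(res$p[res$variable == "met1"], 1e-4)
  # identical groups: t = 0, p = 1, nothing discovered
  y <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  res0 <- group_compare(y, reference = "A", groups = c("A", "A", "B", "B"))
  expect_equal(res0$t, rep(0, 3))
  expect_equal(res0$p, rep(1, 3))
  expect_false(any(res0$discovery))
  expect_error(group_compare(x[1:3, ], reference = "WT",
                             groups = c("WT", "KO", "KO")), "at least 2")
  expect_error(group_compare(x, reference = "nope", groups = groups),
               "reference")
})

test_that("log2 fold changes point from the reference to the other group", {
  pt <- toy_pool_table(
    cbind(met1 = c(1, 1, 2, 2), met2 = c(4, 4, 1, 1)) *
      matrix(1 + 1e-3 * stats::rnorm(8), 4),
    groups = c("WT", "WT", "KO", "KO"))
  rownames(pt$values) <- paste0("s", 1:4)
  res <- group_compare(pt, reference = "WT")
  expect_equal(res$log2fc[res$variable == "met1"], 1, tolerance = 0.05)
  expect_equal(res$log2fc[res$variable == "met2"], -2, tolerance = 0.05)
  expect_equal(res$neg_log10_p, -log10(res$p))
})

test_that("PCA scores separate structure and respect permutations", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  r1 <- pca_scores(u %o% v, k = 1)
  expect_equal(r1$explained_variance[1], 1, tolerance = 1e-12)
  set.seed(35)
  x <- matrix(stats::rnorm(80), nrow = 8)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  a <- pca_scores(x, k = 2); b <- pca_scores(x[perm, ], k = 2)
  expect_equal(unname(b$scores), unname(a$scores[perm, ]), tolerance = 1e-10)
  # two groups shifted by 3 sd on 20 autoscaled metabolites separate on PC1
  g <- rep(c(0, 1), each = 10)
  y <- matrix(stats::rnorm(20 * 20), 20) + 3 * g
  sc <- pca_scores(autoscale(y), k = 2)$scores[, 1]
  agree <- max(mean((sc > 0) == (g == 1)), mean((sc > 0) == (g == 0)))
  expect_gte(agree, 0.95)
  expect_error(pca_scores(y, k = 50), "invalid number")
})
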