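test_that("pearson_r matches hand-computed values and is symmetric", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x + 5)$r, -1)
  y <- c(2, 1, 4, 3)
  expect_equal(pearson_r(x, y)$r, 0.6, tolerance = 1e-12)
  expect_equal(pearson_r(x, y)$r, pearson_r(y, x)$r)
  expect_equal(pearson_r(x, y)$p, pearson_r(2 + 3 * x, y)$p)
  expect_error(pearson_r(x, rep(1, 4)), "constant input")
  expect_error(pearson_r(x, y[1:3]), "lengths differ")
})

test_that("simple_linear_fit solves the normal equations", {
  x <- c(0, 1, 2)
  expect_equal(simple_linear_fit(x, 3 * x + 1),
               list(intercept = 1, slope = 3))
  f <- simple_linear_fit(x, c(0, 0, 3))
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, -0.5)
  set.seed(61)
  y <- rnorm(10); xx <- rnorm(10)
  expect_equal(simple_linear_fit(xx, 7 * y)$slope,
               7 * simple_linear_fit(xx, y)$slope)
  expect_error(simple_linear_fit(rep(2, 5), rnorm(5)), "constant x")
})

test_that("bh_fdr reproduces the step-up recursion", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(62)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_manual(p))
  }
  # permutation invariance up to reordering
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("genotype-dependent screen applies its rules in order", {
  set.seed(63)
  n <- 60
  genotype <- rep(c("WT", "Heter"), each = n / 2)
  lnc <- rnorm(n, 5, 1)
  wt <- genotype == "WT"; het <- !wt
  g_const <- ifelse(het, 1, 2 + 0.5 * lnc + rnorm(n, 0, 0.1))[seq_len(n)]
  g_ratio <- ifelse(het, 0.3 * lnc, 0.2 * lnc) + 2 + rnorm(n, 0, 0.02)
  g_good <- ifelse(het, 0.9 * lnc, 0.05 * lnc) + 2 + rnorm(n, 0, 0.3)
  g_null <- 2 + rnorm(n)
  panel <- list(genotype = genotype, lnc_expr = lnc,
                gene_expr = cbind(const = g_const, ratio = g_ratio,
                                  good = g_good, null = g_null))
  res <- genotype_dependent_screen(panel)
  expect_identical(res$fail_reason[res$gene_id == "const"], "constant")
  expect_identical(res$fail_reason[res$gene_id == "ratio"], "beta_ratio")
  expect_true(res$passed[res$gene_id == "good"])
  expect_false(res$passed[res$gene_id == "null"])

  # fully relaxed thresholds pass every non-degenerate gene
  th0 <- screen_thresholds(r_het_min = 0, fdr_max = 1, beta_ratio_min = 0,
                           r_wt_max = 1)
  res0 <- genotype_dependent_screen(panel, th0)
  expect_true(all(res0$passed[res0$gene_id != "const"]))
  expect_false(res0$passed[res0$gene_id == "const"])

  small <- list(genotype = c("WT", "WT", "Heter"), lnc_expr = rnorm(3),
                gene_expr = matrix(rnorm(3), 3, 1))
  expect_error(genotype_dependent_screen(small), "at least 3")
})

test_that("positive-correlation screen keeps signed positive hits only", {
  set.seed(64)
  n <- 80
  lnc <- rnorm(n, 5, 1)
  panel <- list(
    genotype = rep(c("WT", "Heter"), n / 2), lnc_expr = lnc,
    gene_expr = cbind(pos = lnc + rnorm(n, 0, 0.5),
                      neg = -lnc + rnorm(n, 0, 0.5),
                      noise = rnorm(n)))
  got <- positive_correlation_screen(panel, r_min = 0.3, p_max = 1e-5)
  expect_identical(got, "pos")
  # oracle: direct cor.test filtering agrees on every gene
  for (g in colnames(panel$gene_expr)) {
    ct <- cor.test(lnc, panel$gene_expr[, g])
    expect_identical(g %in% got,
                     unname(ct$estimate > 0.3 & ct$p.value < 1e-5))
  }
})

test_that("overlap enrichment reproduces the 2x2 arithmetic and the
           hypergeometric tail", {
  bg <- sprintf("g%04d", 1:1000)
  a <- bg[1:100]
  b <- bg[c(1:20, 101:110)]      # k = 20, |A| = 100, |B| = 30
  enr <- overlap_enrichment(a, b, 1000)
  expect_identical(enr$overlap, 20L)
  expect_equal(enr$odds_ratio, 22.25)  # (20 * 890) / (80 * 10)
  expect_equal(enr$p, sum(dhyper(20:30, 100, 900, 30)))

  # overlap at expectation with integral cells: OR = 1
  bg2 <- sprintf("x%02d", 1:20)
  e <- overlap_enrichment(bg2[1:10], bg2[c(1:4, 11:14)], 20)
  expect_equal(e$odds_ratio, 1)

  expect_error(overlap_enrichment(bg, b, 50), "background")
})

test_that("hypergeometric p equals exhaustive pmf summation for N <= 50", {
  set.seed(65)
  for (rep in 1:25) {
    N <- sample(10:50, 1)
    na <- sample(1:(N - 1), 1)
    nb <- sample(1:(N - 1), 1)
    bg <- sprintf("u%03d", seq_len(N))
    a <- sample(bg, na)
    b <- sample(bg, nb)
    k <- length(intersect(a, b))
    brute <- sum(vapply(k:min(na, nb), function(x)
      choose(na, x) * choose(N - na, nb - x) / choose(N, nb), numeric(1)))
    expect_equal(overlap_enrichment(a, b, N)$p, brute, tolerance = 1e-10)
  }
})

test_that("the synthetic panel screen recovers genotype-dependent genes", {
  pan <- simulate_expression_panel(
    coexpr_panel_config(n_samples = 150, n_genes = 120,
                        frac_genotype_dependent = 0.1, seed = 66L))
  res <- genotype_dependent_screen(pan)
  truth <- pan$truth$label == "dependent"
  recall <- mean(res$passed[truth])
  expect_gt(recall, 0.6)
  if (any(res$passed)) {
    fdp <- mean(!truth[res$passed])
    expect_lt(fdp, 0.3)
  }
})
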