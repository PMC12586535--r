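test_that("identical config yields an identical cohort", {
  cfg <- cohort_config(n_snps = 40, seed = 3L)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("truth bookkeeping is exact and count records are het-only", {
  cfg <- cohort_config(n_snps = 97, frac_true_discordant = 0.13, seed = 2L)
  co <- simulate_cohort(cfg)
  expect_identical(sum(co$truth$label == "discordant"),
                   as.integer(round(0.13 * 97)))

  key_counts <- unique(paste(co$counts$snp_id, co$counts$pair_id))
  gt <- setNames(co$genotypes$genotype,
                 paste(co$genotypes$snp_id, co$genotypes$pair_id))
  expect_true(all(gt[key_counts] == "het"))
  expect_true(all(co$counts$alt_count >= 0 & co$counts$ref_count >= 0))
})

test_that("fixed-depth records sum to the drawn depth", {
  co <- simulate_cohort(cohort_config(n_snps = 30, depth_mean = 80,
                                      depth_model = "fixed", seed = 4L))
  expect_true(all(co$counts$alt_count + co$counts$ref_count == 80))
})

test_that("null configuration pools to alt fraction 1/2", {
  cfg <- cohort_config(n_pairs = 9, n_snps = 200, frac_true_discordant = 0,
                       beta0_sd = 0, betas_true = 0, sigma_gamma = 0, rho = 0,
                       depth_mean = 100, depth_model = "fixed", het_rate = 1,
                       seed = 11L)
  co <- simulate_cohort(cfg)
  n_reads <- sum(co$counts$alt_count + co$counts$ref_count)
  frac <- sum(co$counts$alt_count) / n_reads
  mc_sd <- sqrt(0.25 / n_reads)
  expect_lt(abs(frac - 0.5), 3 * mc_sd)
})

test_that("injected phenotype effect shifts the affected co-twin only", {
  cfg <- cohort_config(n_pairs = 9, n_snps = 200, frac_true_discordant = 1,
                       beta0_sd = 0, betas_true = 2, sigma_gamma = 0, rho = 0,
                       depth_mean = 100, depth_model = "fixed", het_rate = 1,
                       seed = 12L)
  co <- simulate_cohort(cfg)
  for (mem in c("affected", "unaffected")) {
    sub <- co$counts[co$counts$member == mem, ]
    n_reads <- sum(sub$alt_count + sub$ref_count)
    frac <- sum(sub$alt_count) / n_reads
    p <- if (mem == "affected") plogis(2) else 0.5
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n_reads))
  }
})

test_that("counts match binomial moments, inflated under overdispersion", {
  base <- list(n_pairs = 9, n_snps = 600, frac_true_discordant = 0,
               beta0_sd = 0, betas_true = 0, sigma_gamma = 0,
               depth_mean = 50, depth_model = "fixed", het_rate = 1,
               seed = 13L)
  co0 <- simulate_cohort(do.call(cohort_config, c(base, rho = 0)))
  a0 <- co0$counts$alt_count
  expect_gt(length(a0), 1e4)
  expect_lt(abs(mean(a0) - 25), 3 * sqrt(12.5 / length(a0)))
  expect_lt(abs(var(a0) / 12.5 - 1), 0.1)

  co1 <- simulate_cohort(do.call(cohort_config, c(base, rho = 0.1)))
  infl <- var(co1$counts$alt_count) / 12.5
  expect_lt(abs(infl / (1 + 49 * 0.1) - 1), 0.15)
})

test_that("invalid configs and uninformative cohorts error", {
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(het_rate = 1.2), "het_rate")
  expect_error(cohort_config(depth_mean = 0), "depth_mean")
  expect_error(cohort_config(frac_true_discordant = -0.1), "frac")
  cfg <- cohort_config(n_snps = 5, het_rate = 0, discordant_hom_rate = 0,
                       seed = 1L)
  expect_error(simulate_cohort(cfg), "uninformative cohort")
})

test_that("expression panel is reproducible with exact truth bookkeeping", {
  cfg <- coexpr_panel_config(n_samples = 60, n_genes = 50, seed = 8L)
  expect_identical(simulate_expression_panel(cfg),
                   simulate_expression_panel(cfg))
  p0 <- simulate_expression_panel(
    coexpr_panel_config(n_samples = 60, n_genes = 50,
                        frac_genotype_dependent = 0, seed = 8L))
  expect_identical(sum(p0$truth$label == "dependent"), 0L)
})

test_that("per-group OLS slope ratio recovers the generative multiplier", {
  cfg <- coexpr_panel_config(n_samples = 200, n_genes = 100,
                             frac_genotype_dependent = 0.2,
                             beta_het_multiplier = 3, noise_sd = 0.2,
                             seed = 9L)
  pan <- simulate_expression_panel(cfg)
  wt <- pan$genotype == "WT"; het <- pan$genotype == "Heter"
  truth_genes <- which(pan$truth$label == "dependent")
  ratios <- vapply(truth_genes, function(g) {
    simple_linear_fit(pan$lnc_expr[het], pan$gene_expr[het, g])$slope /
      simple_linear_fit(pan$lnc_expr[wt], pan$gene_expr[wt, g])$slope
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.2 * 3)
})

test_that("an empty genotype group is an error, not a silent panel", {
  cfg <- coexpr_panel_config(n_samples = 10, maf = 0.001, seed = 1L)
  expect_error(simulate_expression_panel(cfg), "n_samples or maf")
})
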