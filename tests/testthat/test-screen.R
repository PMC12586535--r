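toy_variants <- function(pos, ids = sprintf("s%d", seq_along(pos))) {
  data.frame(snp_id = ids, chrom = "chr1", pos = pos,
             ref_allele = "C", alt_allele = "G", stringsAsFactors = FALSE)
}

test_that("SNP-transcript pairing respects 1-based inclusive exon bounds", {
  ann <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                    start = 50, end = 150)
  got <- pair_snps_to_transcripts(toy_variants(c(49, 50, 100, 150, 151)), ann)
  expect_setequal(got$snp_id, c("s2", "s3", "s4"))
})

test_that("a SNP in exons of two transcripts yields two pairs", {
  ann <- data.frame(
    transcript_id = c("t1", "t2", "t3"), gene_id = c("g1", "g1", "g2"),
    chrom = "chr1", start = c(100, 150, 400), end = c(200, 260, 500))
  got <- pair_snps_to_transcripts(toy_variants(c(120, 180, 450)), ann)
  # s1 -> t1; s2 -> t1 and t2; s3 -> t3: four pairs in total
  expect_identical(nrow(got), 4L)
  expect_setequal(got$transcript_id[got$snp_id == "s2"], c("t1", "t2"))
})

test_that("multi-exon transcripts pair a SNP once and bad intervals error", {
  ann2 <- data.frame(transcript_id = c("t1", "t1"), gene_id = "g1",
                     chrom = "chr1", start = c(10, 100), end = c(20, 120))
  got <- pair_snps_to_transcripts(toy_variants(110), ann2)
  expect_identical(nrow(got), 1L)
  bad <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                    start = 200, end = 100)
  expect_error(pair_snps_to_transcripts(toy_variants(150), bad), "malformed")
})

test_that("heterozygous-informative filter keeps >=1-het SNPs only", {
  m <- rbind(
    s1 = c("hom_ref", "hom_ref", "hom_ref"),
    s2 = c("het",     "hom_ref", "hom_ref"),
    s3 = c("hom_alt", "hom_alt", "hom_alt"),
    s4 = c("het",     "het",     "het"),
    s5 = c("hom_ref", NA,        "hom_alt")
  )
  colnames(m) <- sprintf("p%d", 1:3)
  gt <- geno_table(m)
  pairs <- data.frame(snp_id = rownames(m), transcript_id = "t1",
                      stringsAsFactors = FALSE)
  expect_setequal(filter_informative(pairs, gt)$snp_id, c("s2", "s4"))
})

test_that("discordant-homozygote filter drops hom_ref-vs-hom_alt SNPs", {
  m <- rbind(
    s1 = c("hom_ref", "het",     "hom_alt"),  # excluded
    s2 = c("hom_ref", "het",     "het"),      # retained
    s3 = c("hom_alt", "hom_alt", "het"),      # retained (no hom_ref)
    s4 = c("hom_ref", "hom_ref", "hom_ref"),  # retained here
    s5 = c("hom_alt", "hom_ref", "hom_ref"),  # excluded
    s6 = c("het",     "het",     "het")       # retained
  )
  colnames(m) <- sprintf("p%d", 1:3)
  gt <- geno_table(m)
  pairs <- data.frame(snp_id = rownames(m), transcript_id = "t1",
                      stringsAsFactors = FALSE)
  expect_setequal(filter_discordant_homozygous(pairs, gt)$snp_id,
                  c("s2", "s3", "s4", "s6"))
})

test_that("the two genotype filters commute, are idempotent and monotone", {
  set.seed(51)
  for (rep in 1:30) {
    m <- matrix(sample(c("hom_ref", "het", "hom_alt", NA), 8 * 4,
                       replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
                nrow = 8, dimnames = list(sprintf("s%d", 1:8),
                                          sprintf("p%d", 1:4)))
    gt <- geno_table(m)
    pairs <- data.frame(snp_id = rownames(m), transcript_id = "t1",
                        stringsAsFactors = FALSE)
    ab <- filter_discordant_homozygous(filter_informative(pairs, gt), gt)
    ba <- filter_informative(filter_discordant_homozygous(pairs, gt), gt)
    expect_setequal(ab$snp_id, ba$snp_id)
    expect_setequal(filter_informative(ab, gt)$snp_id, ab$snp_id)
    expect_lte(nrow(ab), nrow(filter_informative(pairs, gt)))
    expect_lte(nrow(filter_informative(pairs, gt)), nrow(pairs))
  }
})

test_that("AAF is the signed allelic imbalance on [-1, 1]", {
  expect_identical(compute_aaf(5, 5), 0)
  expect_identical(compute_aaf(30, 10), 0.5)
  expect_identical(compute_aaf(0, 7), -1)
  expect_error(compute_aaf(0, 0), "zero total depth")
  expect_error(compute_aaf(-1, 2), "negative")
})

test_that("the end-to-end screen is deterministic and internally consistent", {
  cfg <- cohort_config(n_snps = 30, n_transcripts = 15,
                       frac_true_discordant = 0.2, betas_true = 2,
                       depth_mean = 300, depth_model = "fixed",
                       het_rate = 0.6, seed = 52L)
  co <- simulate_cohort(cfg)
  r1 <- run_ase_screen(co, bf_threshold = 5)
  r2 <- run_ase_screen(co, bf_threshold = 5)
  expect_identical(r1$bf_records, r2$bf_records)

  s <- r1$summary
  expect_lte(s$n_pairs_het_informative, s$n_pairs_annotated)
  expect_lte(s$n_pairs_after_hom_filter, s$n_pairs_het_informative)
  expect_lte(s$n_hits, s$n_pairs_tested)
  expect_true(all(r1$hits$log_bf %in% r1$bf_records$log_bf))
  expect_true(all(r1$hits$bf > 5))
  expect_true(all(r1$aaf_table$aaf >= -1 & r1$aaf_table$aaf <= 1))

  empty <- co
  empty$counts <- co$counts[0, ]
  expect_error(run_ase_screen(empty), "uninformative cohort")
})

test_that("hit summaries count distinct SNPs, transcripts and genes", {
  fake <- list(
    hits = data.frame(
      snp_id = c("s1", "s2", "s3", "s4", "s4"),
      transcript_id = c("t1", "t1", "t2", "t3", "t2")),
    retained_pairs = data.frame(
      snp_id = c("s1", "s2", "s3", "s4", "s4"),
      transcript_id = c("t1", "t1", "t2", "t3", "t2"),
      gene_id = c("g1", "g1", "g1", "g2", "g1")),
    summary = list(n_pairs_annotated = 10, n_pairs_het_informative = 8,
                   n_pairs_after_hom_filter = 7, n_pairs_tested = 7,
                   n_hits = 5)
  )
  got <- summarize_hits(fake)
  expect_identical(got$n_hit_snps, 4L)
  expect_identical(got$n_hit_transcripts, 3L)
  expect_identical(got$n_hit_genes, 2L)

  fake$hits <- fake$hits[0, ]
  got0 <- summarize_hits(fake)
  expect_identical(c(got0$n_hit_snps, got0$n_hit_transcripts,
                     got0$n_hit_genes), c(0L, 0L, 0L))
})
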