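# Synthetic twin-cohort and expression-panel generators.
#
# The cohort generator forward-simulates the logit mixed model the Bayes-factor
# machinery assumes: for twin pair i and disease status s (affected = 1),
#   logit(p_is) = beta0 + betas * s * [SNP is truth-discordant] + gamma_i,
# with gamma_i ~ N(0, sigma_gamma^2) per pair, and alternative-allele counts
# drawn Binomial(depth, p_is), or beta-binomial when rho > 0. Allelic counts
# are emitted only for heterozygous pairs: homozygotes carry no allelic signal.

#' Configuration for a synthetic discordant-twin ASE cohort
#'
#' Defaults emulate the study design the package targets: nine monozygotic
#' twin pairs discordant for a psychiatric phenotype, a minority of SNPs with
#' a genuine disease-associated allelic shift, and sequencing depths typical
#' of transcript-level allelic quantification.
#'
#' @param n_pairs Number of twin pairs (one affected, one unaffected member).
#' @param n_snps Number of SNPs.
#' @param n_transcripts Number of lncRNA transcripts SNPs are assigned to;
#'   defaults to roughly one transcript per two SNPs.
#' @param frac_true_discordant Fraction of SNPs given a nonzero phenotype
#'   effect `betas_true`. Exactly `round(frac_true_discordant * n_snps)` SNPs
#'   (the first indices) are labelled `discordant` in the truth table. A
#'   discordant SNP is always testable: it is guaranteed at least one
#'   heterozygous pair (the phenotype effect exists only in heterozygous
#'   carriers) and never carries the excluded hom_ref-vs-hom_alt pattern.
#' @param beta0_sd SD of the per-SNP baseline allelic bias `beta0` (logit
#'   scale).
#' @param betas_true Phenotype fixed effect injected into discordant SNPs
#'   (logit scale, applied to the affected co-twin).
#' @param sigma_gamma SD of the per-pair random intercept `gamma_i`.
#' @param rho Beta-binomial overdispersion (intra-class correlation) in
#'   `[0, 1)`; 0 gives pure binomial counts.
#' @param depth_mean Mean total read depth per (SNP, individual) observation.
#' @param depth_model One of `"fixed"`, `"poisson"`, `"negative_binomial"`
#'   (the latter with size 10, i.e. variance `mu + mu^2/10`). Draws are
#'   truncated below at 1 read.
#' @param het_rate Per-pair probability a SNP is heterozygous.
#' @param discordant_hom_rate Probability a SNP carries the excluded
#'   hom-ref-in-one-pair / hom-alt-in-another genotype pattern.
#' @param seed Integer seed; identical config implies byte-identical output.
#' @return A validated `cohort_config` object (a list).
#' @export
cohort_config <- function(n_pairs = 9L,
                          n_snps = 200L,
                          n_transcripts = NULL,
                          frac_true_discordant = 0.1,
                          beta0_sd = 0.25,
                          betas_true = 2,
                          sigma_gamma = 0.3,
                          rho = 0,
                          depth_mean = 200,
                          depth_model = c("poisson", "fixed", "negative_binomial"),
                          het_rate = 0.35,
                          discordant_hom_rate = 0.05,
                          seed = 1L) {
  depth_model <- match.arg(depth_model)
  if (is.null(n_transcripts)) n_transcripts <- max(1L, ceiling(n_snps / 2))
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_snps = as.integer(n_snps),
    n_transcripts = as.integer(n_transcripts),
    frac_true_discordant = frac_true_discordant,
    beta0_sd = beta0_sd, betas_true = betas_true,
    sigma_gamma = sigma_gamma, rho = rho,
    depth_mean = depth_mean, depth_model = depth_model,
    het_rate = het_rate, discordant_hom_rate = discordant_hom_rate,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 1L, cfg$n_snps >= 1L, cfg$n_transcripts >= 1L)
  if (cfg$frac_true_discordant < 0 || cfg$frac_true_discordant > 1)
    stop("frac_true_discordant must be in [0, 1]", call. = FALSE)
  if (cfg$het_rate < 0 || cfg$het_rate > 1)
    stop("het_rate must be in [0, 1]", call. = FALSE)
  if (cfg$discordant_hom_rate < 0 || cfg$discordant_hom_rate > 1)
    stop("discordant_hom_rate must be in [0, 1]", call. = FALSE)
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop("rho must be in [0, 1)", call. = FALSE)
  if (cfg$beta0_sd < 0) stop("beta0_sd must be >= 0", call. = FALSE)
  if (cfg$sigma_gamma < 0) stop("sigma_gamma must be >= 0", call. = FALSE)
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0", call. = FALSE)
  invisible(cfg)
}

# Deterministic per-(snp, pair) sub-stream seeds: a small LCG-style mix kept
# below 2^31 so adding SNPs never perturbs the draws of earlier ones.
mix_seed <- function(seed, i, j) {
  m <- 2147483647
  h <- seed %% m
  h <- (h * 48271 + i * 1009 + 1) %% m
  h <- (h * 48271 + j * 9176 + 1) %% m
  as.integer(h)
}

rdepth <- function(n, cfg) {
  d <- switch(cfg$depth_model,
    fixed = rep(round(cfg$depth_mean), n),
    poisson = stats::rpois(n, cfg$depth_mean),
    negative_binomial = stats::rnbinom(n, mu = cfg$depth_mean, size = 10)
  )
  pmax(as.integer(d), 1L)
}

# Beta-binomial with mean p and intra-class correlation rho:
# alpha = p(1-rho)/rho, beta = (1-p)(1-rho)/rho; rho -> 0 limit is binomial.
rbetabinom <- function(n_draws, size, p, rho) {
  if (rho <= 0) return(stats::rbinom(n_draws, size, p))
  al <- p * (1 - rho) / rho
  be <- (1 - p) * (1 - rho) / rho
  stats::rbinom(n_draws, size, stats::rbeta(n_draws, al, be))
}

#' Simulate a discordant monozygotic twin ASE cohort
#'
#' Draws genotypes, per-SNP baseline biases, per-pair random effects and
#' allelic read counts under the binomial (or beta-binomial) logit mixed
#' model. Counts are emitted only for heterozygous pairs. Each SNP is placed
#' in one exon of one transcript; the matching exon annotation is returned so
#' the downstream screen can run end to end.
#'
#' @param config A [cohort_config()].
#' @return An `ase_cohort` list with elements `genotypes` (snp_id, pair_id,
#'   genotype), `counts` (snp_id, transcript_id, pair_id, member, alt_count,
#'   ref_count), `truth` (per-SNP label and generative effects), `truth_gamma`
#'   (per het pair random effect), `snps` (positions/alleles), `annotation`
#'   (1-based inclusive exons with gene ids), and the `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  validate_cohort_config(cfg)
  n_disc <- round(cfg$frac_true_discordant * cfg$n_snps)
  tr_of_snp <- ((seq_len(cfg$n_snps) - 1L) %% cfg$n_transcripts) + 1L

  # transcript geometry: disjoint 1 kb single-exon transcripts on chr1;
  # ~10% of genes carry two transcripts (gene index = ceiling(0.9 * t))
  tr_ids <- sprintf("tx_%04d", seq_len(cfg$n_transcripts))
  gene_ids <- sprintf("gene_%04d", ceiling(seq_len(cfg$n_transcripts) * 0.9))
  tr_start <- (seq_len(cfg$n_transcripts) - 1L) * 2000L + 1L
  annotation <- data.frame(
    transcript_id = tr_ids, gene_id = gene_ids, chrom = "chr1",
    start = tr_start, end = tr_start + 999L, stringsAsFactors = FALSE
  )
  snp_pos <- tr_start[tr_of_snp] +
    (((seq_len(cfg$n_snps) - 1L) %/% cfg$n_transcripts) * 13L + 7L) %% 1000L

  snp_ids <- sprintf("snp_%05d", seq_len(cfg$n_snps))
  pair_ids <- sprintf("pair_%02d", seq_len(cfg$n_pairs))

  geno <- matrix("hom_ref", nrow = cfg$n_snps, ncol = cfg$n_pairs)
  beta0 <- numeric(cfg$n_snps)
  disc_hom <- logical(cfg$n_snps)

  counts_list <- vector("list", cfg$n_snps)
  gamma_list <- vector("list", cfg$n_snps)

  for (j in seq_len(cfg$n_snps)) {
    set.seed(mix_seed(cfg$seed, j, 0L))
    het <- stats::runif(cfg$n_pairs) < cfg$het_rate
    disc_hom[j] <- stats::runif(1) < cfg$discordant_hom_rate
    if (j <= n_disc) {
      # an injected discordant-ASE label is only meaningful on a testable
      # SNP: the phenotype effect exists in heterozygous carriers, and the
      # excluded hom_ref-vs-hom_alt pattern would remove the SNP upstream
      disc_hom[j] <- FALSE
      if (!any(het)) het[1L + (j %% cfg$n_pairs)] <- TRUE
    }
    if (disc_hom[j]) {
      # force the excluded pattern: >=1 hom_ref and >=1 hom_alt pair
      if (sum(!het) < 2L) het[order(het)[1:2]] <- FALSE
      geno[j, which(!het)[1L]] <- "hom_alt"
    }
    geno[j, het] <- "het"
    beta0[j] <- stats::rnorm(1, 0, cfg$beta0_sd)
    betas_j <- if (j <= n_disc) cfg$betas_true else 0

    het_idx <- which(het)
    if (!length(het_idx)) next
    rec <- vector("list", length(het_idx))
    gam <- numeric(length(het_idx))
    for (u in seq_along(het_idx)) {
      i <- het_idx[u]
      set.seed(mix_seed(cfg$seed, j, i))
      g <- stats::rnorm(1, 0, cfg$sigma_gamma)
      gam[u] <- g
      depth <- rdepth(2L, cfg)  # affected, unaffected
      p_aff <- stats::plogis(beta0[j] + betas_j + g)
      p_unf <- stats::plogis(beta0[j] + g)
      alt <- c(
        rbetabinom(1L, depth[1], p_aff, cfg$rho),
        rbetabinom(1L, depth[2], p_unf, cfg$rho)
      )
      rec[[u]] <- data.frame(
        snp_id = snp_ids[j], transcript_id = tr_ids[tr_of_snp[j]],
        pair_id = pair_ids[i], member = c("affected", "unaffected"),
        alt_count = alt, ref_count = depth - alt, stringsAsFactors = FALSE
      )
    }
    counts_list[[j]] <- do.call(rbind, rec)
    gamma_list[[j]] <- data.frame(
      snp_id = snp_ids[j], pair_id = pair_ids[het_idx], gamma = gam,
      stringsAsFactors = FALSE
    )
  }

  counts <- do.call(rbind, counts_list[!vapply(counts_list, is.null, TRUE)])
  if (is.null(counts) || nrow(counts) == 0L)
    stop("uninformative cohort: no SNP has a heterozygous twin pair",
         call. = FALSE)
  rownames(counts) <- NULL

  genotypes <- data.frame(
    snp_id = rep(snp_ids, each = cfg$n_pairs),
    pair_id = rep(pair_ids, times = cfg$n_snps),
    genotype = as.vector(t(geno)), stringsAsFactors = FALSE
  )
  truth <- data.frame(
    snp_id = snp_ids, transcript_id = tr_ids[tr_of_snp],
    label = ifelse(seq_len(cfg$n_snps) <= n_disc, "discordant", "null"),
    beta0 = beta0,
    betas = ifelse(seq_len(cfg$n_snps) <= n_disc, cfg$betas_true, 0),
    stringsAsFactors = FALSE
  )
  truth_gamma <- do.call(rbind, gamma_list[!vapply(gamma_list, is.null, TRUE)])
  rownames(truth_gamma) <- NULL
  snps <- data.frame(
    snp_id = snp_ids, chrom = "chr1", pos = snp_pos,
    ref_allele = "C", alt_allele = "G",
    stringsAsFactors = FALSE
  )

  structure(
    list(genotypes = genotypes, counts = counts, truth = truth,
         truth_gamma = truth_gamma, snps = snps, annotation = annotation,
         config = cfg),
    class = "ase_cohort"
  )
}

#' @export
print.ase_cohort <- function(x, ...) {
  cat("ASE twin cohort:", x$config$n_pairs, "pairs,", x$config$n_snps,
      "SNPs,", nrow(x$counts), "count records,",
      sum(x$truth$label == "discordant"), "truth-discordant SNPs\n")
  invisible(x)
}

#' Configuration for a synthetic genotype-stratified expression panel
#'
#' Emulates a population expression panel (samples by genes, plus a focal
#' lncRNA) split by genotype at a focal regulatory SNP into homozygous
#' reference (WT) and heterozygous (Heter) groups. A fraction of genes track
#' the lncRNA with a genotype-dependent slope.
#'
#' @param n_samples Number of samples (>= 10).
#' @param maf Minor-allele frequency in (0, 0.5]; samples are drawn from the
#'   WT/Heter classes with Hardy-Weinberg probabilities renormalized over
#'   those two classes (hom-alt carriers are outside the two-group design).
#' @param n_genes Number of genes screened against the focal lncRNA.
#' @param frac_genotype_dependent Fraction of genes with a Heter-specific
#'   slope; exactly `round(frac * n_genes)` (first indices) are labelled true.
#' @param beta_wt Regression slope of each tracking gene on the lncRNA in WT.
#' @param beta_het_multiplier True Heter/WT slope ratio for dependent genes
#'   (>= 2 marks a gene the screen is meant to recover).
#' @param noise_sd Residual SD of gene expression.
#' @param seed Integer seed.
#' @return A validated `coexpr_panel_config` object.
#' @export
coexpr_panel_config <- function(n_samples = 200L,
                                maf = 0.25,
                                n_genes = 500L,
                                frac_genotype_dependent = 0.1,
                                beta_wt = 0.2,
                                beta_het_multiplier = 3,
                                noise_sd = 0.6,
                                seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), maf = maf,
    n_genes = as.integer(n_genes),
    frac_genotype_dependent = frac_genotype_dependent,
    beta_wt = beta_wt, beta_het_multiplier = beta_het_multiplier,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_samples < 10L) stop("n_samples must be >= 10", call. = FALSE)
  if (cfg$maf <= 0 || cfg$maf > 0.5) stop("maf must be in (0, 0.5]",
                                          call. = FALSE)
  if (cfg$frac_genotype_dependent < 0 || cfg$frac_genotype_dependent > 1)
    stop("frac_genotype_dependent must be in [0, 1]", call. = FALSE)
  if (cfg$beta_het_multiplier < 0)
    stop("beta_het_multiplier must be >= 0", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(cfg, class = "coexpr_panel_config")
}

#' Simulate a genotype-stratified co-expression panel
#'
#' @param config A [coexpr_panel_config()].
#' @return An `expression_panel` list: `sample_ids`, `genotype` (`"WT"` /
#'   `"Heter"` per sample), `lnc_expr` (focal lncRNA), `gene_expr` (samples x
#'   genes matrix), `truth` (per-gene label and true slopes), `config`.
#' @export
simulate_expression_panel <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  p_wt <- (1 - cfg$maf)^2
  p_het <- 2 * cfg$maf * (1 - cfg$maf)
  genotype <- sample(c("WT", "Heter"), cfg$n_samples, replace = TRUE,
                     prob = c(p_wt, p_het) / (p_wt + p_het))
  if (!all(c("WT", "Heter") %in% genotype))
    stop("empty genotype group after draw: increase n_samples or maf",
         call. = FALSE)

  n_dep <- round(cfg$frac_genotype_dependent * cfg$n_genes)
  lnc <- stats::rnorm(cfg$n_samples, 5, 1)
  slope_wt <- rep(cfg$beta_wt, cfg$n_genes)
  slope_het <- ifelse(seq_len(cfg$n_genes) <= n_dep,
                      cfg$beta_wt * cfg$beta_het_multiplier, cfg$beta_wt)
  slope <- outer(genotype == "Heter", slope_het) +
    outer(genotype == "WT", slope_wt)  # samples x genes
  expr <- 2 + slope * lnc +
    matrix(stats::rnorm(cfg$n_samples * cfg$n_genes, 0, cfg$noise_sd),
           cfg$n_samples, cfg$n_genes)
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  colnames(expr) <- gene_ids

  structure(
    list(
      sample_ids = sprintf("s_%04d", seq_len(cfg$n_samples)),
      genotype = genotype, lnc_expr = lnc, gene_expr = expr,
      truth = data.frame(
        gene_id = gene_ids,
        label = ifelse(seq_len(cfg$n_genes) <= n_dep, "dependent", "null"),
        slope_wt = slope_wt, slope_het = slope_het, stringsAsFactors = FALSE
      ),
      config = cfg
    ),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("Expression panel:", length(x$sample_ids), "samples (",
      sum(x$genotype == "WT"), "WT /", sum(x$genotype == "Heter"),
      "Heter ),", ncol(x$gene_expr), "genes,",
      sum(x$truth$label == "dependent"), "genotype-dependent\n")
  invisible(x)
}
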