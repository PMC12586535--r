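# Demo configuration: nine discordant MZ twin pairs, 500 SNPs of which 20
# carry a true phenotype-associated allelic shift (betas = 2 on the logit
# scale) at 500x coverage.
cohort:
  n_pairs: 9
  n_snps: 500
  n_transcripts: 250
  frac_true_discordant: 0.04
  beta0_sd: 0.25
  betas_true: 2.0
  sigma_gamma: 0.3
  rho: 0.0
  depth_mean: 500
  depth_model: fixed
  het_rate: 0.35
  discordant_hom_rate: 0.05
  seed: 20260101
panel:
  n_samples: 200
  maf: 0.25
  n_genes: 500
  frac_genotype_dependent: 0.1
  beta_wt: 0.2
  beta_het_multiplier: 3.0
  noise_sd: 0.6
  seed: 20260102
priors:
  beta_sd: 3.0
  sigma_gamma_scale: 1.0
  rho_mode: fixed_zero
bf_threshold: 5.0
method: laplace_aghq
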