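# twinase

Screening for phenotype-associated allele-specific expression (ASE) of
lncRNA transcripts in **phenotype-discordant monozygotic twins**.

MZ co-twins share a genome, so when the affected member of a discordant pair
systematically over-expresses one allele of a heterozygous SNP relative to
the unaffected member, that allelic shift — not a genotype difference — is a
candidate regulatory correlate of the phenotype. twinase implements the full
screen: the genotype/annotation filtering cascade, a Bayesian model
comparison on allelic read counts, per-individual allelic-imbalance
summaries, and the downstream genotype-dependent co-expression screen used
to nominate target genes of a hit lncRNA. A synthetic cohort generator
reproduces the statistical structure of the twin design so every stage is
testable without controlled-access data.

## The model

For twin pair $i$ and disease status $s$ (affected $= 1$), the proportion
$p_{is}$ of reads supporting the alternative allele follows a binomial (or
beta-binomial) logit mixed model, and two nested models are compared:

    M1: logit(p_is) = beta0 + betas * s + gamma_i
    M0: logit(p_is) = beta0 + gamma_i,      gamma_i ~ N(0, sigma_gamma^2)

Evidence for a phenotype-associated allelic shift is the Bayes factor
`BF = m1(y) / m0(y)`, the ratio of fully marginalized likelihoods under
documented weakly-informative priors (Normal(0, 3^2) on fixed effects,
half-Normal(1) on `sigma_gamma`); the screen calls hits at the stringent
`BF > 5`. Marginal likelihoods are computed by adaptive Gauss–Hermite
quadrature for the per-pair random intercepts, Laplace for the fixed
effects, and 1-D quadrature for the random-effect scale, and are validated
against a brute-force tensor-grid integrator and an importance-sampling
oracle (agreement within 0.1 nats on all small test instances).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the bundled
demo configuration (9 twin pairs, 500 SNPs with 20 injected discordant-ASE
SNPs at `betas = 2`, 500x coverage) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_ase_screen.R
Rscript analysis/03_coexpr_screen.R
Rscript analysis/04_operating_characteristics.R
```

which prints, in order:

```
Simulated 9 twin pairs x 500 SNPs (250 transcripts); 20 truth-discordant
Count records: 3146 (het pairs only); median het pairs/SNP: 3
Mean |AAF| among truth-discordant affected members: 0.758

ASE screen: 500 SNP-transcript pairs -> 489 het-informative -> 472 after hom filter -> 472 tested -> 21 hits (BF > 5)
Hits: 21 SNPs in 21 transcripts (19 genes)
Recovered 20 / 20 injected discordant SNPs; 1 other calls

Screen: 52 / 500 genes pass; recall 0.98, observed FDP 0.06
Positive-correlation set: 269 genes; overlap 24; OR = 0.71, P = 9.06e-01

 betas depth   n mean_log_bf call_rate_bf5
   0.0   200 200   -3.359913             0
   0.5   200 200   22.958818             1
   1.0   200 200   97.108837             1
   2.0   200 200  311.719738             1
   2.0   500 200  782.899321             1
```

Reading these: the injected allelic shift (`betas = 2`, i.e. the affected
co-twin's alternative-allele fraction moves from ~0.5 to ~0.88) produces a
mean AAF of 0.76 in affected members; the cascade keeps 472 of 500
SNP–transcript pairs after the heterozygosity and discordant-homozygote
filters; all 20 injected SNPs are called at `BF > 5` with one false call
among the 452 tested nulls (0.2%, against the 5% nominal bound); and the
co-expression screen recovers 49 of 50 genotype-dependent genes with 3
false discoveries. The negative log Bayes factor at `betas = 0` is the
Occam penalty M1 pays for its unused parameter. The co-expression passed
set is *not* enriched in the pooled positive-correlation set (OR < 1) —
expected here, because the synthetic genotype-dependent genes are built
with weak wild-type coupling.

Same pipeline as one call, writing every artifact plus a resolved config
snapshot:

```r
library(twinase)
run_pipeline(system.file("extdata", "demo_config.yaml", package = "twinase"),
             out_dir = "results/pipeline")
```

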