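---
title: "Screening for phenotype-associated allele-specific expression in discordant monozygotic twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for phenotype-associated allele-specific expression in discordant monozygotic twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinase)
```

## The design and the model

Monozygotic (MZ) twins discordant for a psychiatric phenotype are a natural
control for genetic background: both co-twins carry the same genome, so a
systematic difference in *allele-specific expression* (ASE) between the
affected and unaffected member points at a regulatory event associated with
the phenotype rather than at a genotype difference. twinase screens
SNP–lncRNA transcript pairs for exactly this signature.

At a SNP heterozygous in twin pair $i$, let $p_{is}$ be the proportion of
reads supporting the alternative allele in the member with disease status
$s$ ($s = 1$ affected, $s = 0$ unaffected). Two binomial logit models are
compared:

$$
\mathrm{M1}: \operatorname{logit}(p_{is}) = \beta_0 + \beta_s s + \gamma_i,
\qquad
\mathrm{M0}: \operatorname{logit}(p_{is}) = \beta_0 + \gamma_i,
$$

where $\beta_0$ is the baseline allelic bias of the SNP–transcript pair,
$\beta_s$ the phenotype effect, and $\gamma_i \sim N(0, \sigma_\gamma^2)$ a
random intercept shared by the two co-twins of pair $i$ (pairs differ in
haplotype context, so their baseline imbalance varies). The alternative
count is $\mathrm{Binomial}(n, p_{is})$, or beta-binomial with intra-class
correlation $\rho$ when allelic counts are overdispersed
(variance inflation $\approx 1 + (n-1)\rho$).

Evidence is summarized by the Bayes factor
$\mathrm{BF} = m_1(y) / m_0(y)$, the ratio of *fully marginalized*
likelihoods (fixed effects, random intercepts and $\sigma_\gamma$ all
integrated). BF $> 3$ conventionally favors M1; the screen calls hits at the
stringent BF $> 5$. Because marginal likelihoods depend on priors, the
priors are explicit and config-exposed rather than implicit tool defaults:
$\beta_0, \beta_s \sim N(0, 3^2)$ (weakly informative on the logit scale:
effects beyond $\pm 6$ are already near-saturating) and
$\sigma_\gamma \sim$ half-Normal(1), generous for between-pair spread of
allelic bias. A BIC-style approximation is available for comparison only.

## Computing the marginal likelihood

The integrals are low-dimensional (at most 2 fixed effects + 9 intercepts +
1 scale) but must be cheap — a screen evaluates thousands of SNP–transcript
pairs — and accurate to a fraction of a nat, since calls sit at a fixed BF
threshold. One pitfall shapes the whole implementation: the joint posterior
density over $(\beta, \gamma, \log\sigma_\gamma)$ is unbounded along the
$\sigma_\gamma \to 0$ funnel (pin $\gamma = 0$ and the density grows like
$-k\log\sigma_\gamma$), so a "joint mode plus Laplace" recipe is ill-posed.
All methods in twinase therefore marginalize $\gamma$ *first*:

* **Per-pair integrals.** Given $(\beta, \sigma_\gamma)$, the likelihood
  factorizes over pairs; each 1-D $\gamma_i$ integral is computed by
  adaptive Gauss–Hermite quadrature around its conditional mode (15 nodes by
  default; `method = "laplace"` is the same backbone with a single node,
  i.e. a pure Laplace approximation of each $\gamma$ integral).
* **Fixed effects.** Integrated by Laplace. Along the $\log\sigma_\gamma$
  direction the fixed-effect mode and curvature drift, so the Laplace
  determinant is tracked with an analytic Schur complement of the joint
  information at each evaluation point rather than frozen at the mode.
* **The random-effect scale.** The marginal posterior of
  $\log\sigma_\gamma$ is strongly right-skewed when only a handful of pairs
  are informative; a Gaussian approximation there costs up to 0.2 nats. It
  is instead integrated by a 1-D trapezoid rule on an adaptive grid
  (spacing half its posterior SD, half-width at least 2.5), following the
  conditional ridge of the fixed effects.

`fit_mode()` reports the posterior mode in the same spirit:
$\log\sigma_\gamma$ is profiled on the $\gamma$-marginalized posterior, then
the concave posterior over $(\beta, \gamma)$ is maximized at that scale by
damped Newton iteration from a zero start (gradient tolerance $10^{-6}$).

Two independent oracles guard these approximations. A brute-force
tensor-grid integrator (`brute_force_log_marginal()`, refused above six
dimensions) uses non-uniform trapezoid grids: a fine core (spacing 0.1)
centered by a penalized-profile pilot scan, united with coarser nodes
covering the prior bulk out to 3.5 prior SDs — a uniform grid either
truncates weak-likelihood instances or becomes unaffordably dense. Below
$\sigma_\gamma = 0.35$ the $\gamma$ integrals switch to a prior-standardized
substitution $\gamma = \sigma_\gamma z$ so that arbitrarily narrow priors
remain resolved. An importance sampler (`is_log_marginal()`, multivariate-t
proposal centered at the posterior mode) provides a second, Monte-Carlo
route. On randomized instances with up to 3 pairs and 5–50 reads per record
the adaptive-quadrature marginal likelihood stays within 0.1 nats of the
grid oracle (the test suite checks 25 such instances per run); accuracy
degrades below roughly 5 reads per record, where the fixed-effect posterior
is prior-dominated and visibly skewed.

Numerical conventions worth knowing: Bayes factors are reported as
`log_bf` alongside `bf` (the latter overflows past ~709 nats); counts are
canonicalized to the pooled minor orientation before fitting, which makes
the mathematical invariance of the BF under a global alt/ref swap exact in
floating point; records with zero total depth are dropped with a warning
when other records remain; non-converged fits are flagged and excluded from
calls, never silently reported.

## The screening cascade

`run_ase_screen()` reproduces the screen stage by stage, with per-stage
retention counts kept for audit:

1. **Pairing.** SNPs are paired to every transcript whose exon contains
   them (1-based inclusive input coordinates, converted internally to
   0-based half-open; `GenomicRanges` does the interval work). A SNP may
   map to several transcripts.
2. **Heterozygous-informative filter.** A SNP is retained iff at least one
   twin pair is heterozygous — homozygotes carry no allelic signal. Missing
   genotypes count as non-het and are tallied, never silently dropped.
3. **Discordant-homozygote filter.** A SNP is excluded iff one pair is
   hom-ref and another hom-alt: such sites reflect genotype differences,
   not ASE. The two filters are logically independent and commute (a
   property the tests check on random genotype tables).
4. **Bayes-factor calling** per surviving SNP–transcript pair, BF > 5.
5. **AAF summaries.** Per individual, the signed allelic imbalance
   $\mathrm{AAF} = (a - r)/(a + r) \in [-1, 1]$, positive when the
   alternative haplotype dominates. The field convention fixes only the
   sign semantics; this package uses the symmetric ratio above, computed
   from each individual's summed counts.

`summarize_hits()` reports hits at three levels — distinct SNPs, transcripts
and genes — matching how such screens are conventionally tallied.

## The synthetic cohort

Because the original twin WGS/RNA-seq data are controlled-access, the
package ships a generator (`simulate_cohort()`) that emulates the cohort's
statistical structure rather than its sequences: 9 twin pairs by default,
per-SNP baseline bias $\beta_0 \sim N(0, 0.25^2)$, per-pair intercepts
$\gamma_i \sim N(0, 0.3^2)$, a configurable fraction of truth-discordant
SNPs with $\beta_s = 2$ injected in the affected member, per-pair
heterozygosity 0.35, and read depths fixed, Poisson or negative-binomial
(size 10) around a mean of 200. These defaults are the conditions the rest
of the package is tested under; the depth distribution behind the original
TPM-derived proportions is not documented anywhere, so the choice of depth
model is the package's own and Poisson is the default for counts of this
kind. Counts are emitted only for heterozygous pairs, and an injected
discordant label is guaranteed testable (at least one het pair, never the
excluded hom/hom pattern) — the phenotype effect exists only in
heterozygous carriers, so the label would otherwise be vacuous. Sub-stream
seeding by (SNP, pair) index keeps earlier draws invariant when SNPs are
added, and identical configs are byte-identical.

The generator produces integer read counts directly — the natural support
of the binomial likelihood — while haplotype quantifications in practice
arrive as TPM pairs; `tpm_to_effective_counts()` bridges the two by a
library-scale multiplication and round-half-even, erroring on zero
effective depth rather than emitting empty records.

What the generator does *not* emulate: read-level artifacts (mapping bias,
phasing errors), LD structure between SNPs, shared random effects across
transcripts of one gene, or depth–imbalance coupling. Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to those artifacts.

## The co-expression screen

`genotype_dependent_screen()` implements the downstream nomination of
genes whose coupling to a focal lncRNA depends on genotype at a regulatory
SNP. Samples split into WT (hom-ref) and Heter groups; per gene and group,
Pearson correlation and OLS slope against the lncRNA are computed, and a
gene passes iff $|r_{het}| > 0.5$, BH-FDR $< 0.05$ (computed over
Heter-group p-values only — the rule set ties the FDR to that group),
$|\beta_{het}| \ge 2\,|\beta_{wt}|$, and $|r_{wt}| \le 0.5$. Slopes are
compared on absolute values: a sign flip with doubled magnitude still
indicates genotype dependence. `fail_reason` records the first violated
rule, with genes constant in either group excluded explicitly. The pooled
positive-correlation screen ($r > 0.3$, $p < 10^{-5}$, signed) and the
overlap-enrichment statistic (odds ratio with Haldane correction iff any
cell is zero; one-sided hypergeometric $P(X \ge k)$ — the test itself is
unnamed in common usage, so Fisher's one-sided choice is documented here)
complete the module. The synthetic panel
(`simulate_expression_panel()`, 200 samples, MAF 0.25 renormalized over the
two modelled genotype classes, WT slope 0.2, Heter multiplier 3, residual SD
0.6) is calibrated so that true genes clear the $r$ thresholds with margin
while null genes sit well below them; at these defaults the screen attains
recall $\ge 0.8$ at observed false-discovery proportion $\le 0.2$, which
the acceptance suite verifies.

## Problem sizes, runtime, and reproducibility

The analysis scripts and acceptance checks run at desk scale, chosen to
keep a full run in minutes on one CPU: 1,000 SNPs for null calibration,
200 SNPs per effect-size setting for the power curve, 200 replicates for
mode recovery, a 500-SNP demo cohort with 20 injected discordant SNPs, and
a 500-gene expression panel. All stochastic steps take explicit integer
seeds; there is no wall-clock seeding anywhere. The interchange formats are
plain TSV (tab, UTF-8, header, `.` for missing) plus optional VCF 4.2
(GT-only) genotype input and output, and every pipeline run writes its
fully resolved configuration next to its outputs so the run can be
reproduced from that snapshot alone.

## Known limitations

* The headline tallies of the motivating twin study (20,811 tagging SNPs,
  124 ASE-SNPs, the GTEx/LIBD overlaps) require its controlled-access
  cohort and external consortium panels; this package reproduces the
  method, not those numbers.
* The marginal-likelihood approximations are validated against brute-force
  quadrature only up to 3 pairs (the oracle's tractable range) and degrade
  below ~5 reads per record.
* The beta-binomial path profiles $\rho$ on a small fixed grid against the
  null model's marginal likelihood rather than treating it as a free
  parameter with a prior.
* The written model is linear on the logit scale; no spline terms are
  provided even where the source material's terminology gestures at
  additivity, and no MCMC fallback exists — the quadrature oracles are the
  accuracy reference.
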