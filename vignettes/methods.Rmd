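---
title: "Models and methods in pneumogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pneumogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pneumogwas implements the statistical machinery of a two-cohort
case-control GWAS and its downstream analyses — meta-analysis,
heritability, finemapping, gene and gene-set association, Mendelian
randomisation, and pathway-partitioned polygenic scoring — together with
a synthetic-data generator that produces every input with known ground
truth. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the design was
genuinely open.

## The synthetic-data generator

All simulations flow from `sim_config()`, which fixes the panel
structure, the disease model and the cohort sizes.

**LD panel.** `simulate_reference_panel()` draws two latent haplotype
Gaussians per individual; within an LD block the latent series follows
an AR(1) process with parameter `block_rho` (default 0.8), and each
latent value is thresholded at its variant's MAF quantile to produce an
allele. The dosage is the sum of the two haplotypes, so Hardy-Weinberg
proportions hold marginally and dosage correlation decays roughly as
`block_rho^(2|i-j|)` within a block and is zero across blocks. This
gives tunable r² structure without phased-haplotype machinery; it does
not reproduce human LD maps, variable block lengths, or
frequency-dependent LD, so tests passing here say nothing about those
features of real data.

**Disease model.** Liability is the additive genetic score plus
independent normal noise scaled so the total liability variance is 1;
an individual is a case when liability exceeds `qnorm(1 - K)`. Defaults
mirror a pneumonia-style trait: prevalence `K = 0.1296` and liability
heritability `h2 = 0.0269`. Desk-scale tests pass explicit, stronger
configurations (documented below) because a realistic per-variant
signal at a few thousand simulated variants requires either a large
`h2/M` ratio or enormous sample sizes.

**Effect architecture.** `simulate_true_effects()` draws effects with
equal variance per *standardized* variant (the model LD score
regression assumes), multiplies the variance of variants inside
designated gene sets by `pathway_enrichment`, and rescales so
`sum(2 p (1-p) beta^2)` equals `h2` exactly. An earlier per-allele
parameterisation was rejected because it couples per-variant signal to
heterozygosity and hence biases the LD-score slope — a MAF-dependent
architecture the downstream regression is not built for.

**Summary statistics.** The analytic mode draws effect estimates
directly from their sampling distribution: `se = 1/sqrt(2 p (1-p)
N_eff)` on the log-odds scale with `N_eff = 4/(1/n_cases +
1/n_controls)`, mean equal to the LD-convolved marginal effect
(block-wise product with the panel's empirical dosage correlation),
re-expressed on the observed scale of a balanced design so that the
liability transform at sample prevalence 0.5 returns the configured
`h2`. Between-cohort heterogeneity adds a per-cohort normal deviation
(`heterogeneity_sd`, log-odds units) to every variant's effect.
Imputation INFO is drawn on Uniform(0.3, 1) *independently* of the
effects so the INFO ≥ 0.6 filter can be exercised without confounding
the architecture. The individual mode simulates a cohort by rejection
sampling and runs a per-variant logistic score test; it is reserved for
the polygenic-scoring tests that need genotypes, because it is two
orders of magnitude slower.

Because the marginal effects and the LD scores are computed from the
same finite panel, their shared estimation noise leaks a small upward
bias into heritability recovery (a few percent of the estimate at
panel size 1000–1500). The recovery tests therefore check coverage at
two jackknife standard errors rather than exact agreement.

## Meta-analysis and loci

`ivw_meta()` is the fixed-effects inverse-variance-weighted estimator:
weights `1/se²`, pooled `se = 1/sqrt(sum w)`, Cochran's Q on k−1
degrees of freedom. Effective sample size uses `4/(1/a + 1/b)`, the
balanced-design equivalent. `intercept_correct()` conservatively
divides every χ² statistic by an LD-score-regression intercept, which
preserves variant ranking. `define_loci()` reproduces the standard
two-stage clumping convention — independent significant variants at
r² ≤ 0.6, lead variants at r² ≤ 0.1, LD blocks within 250 kb merged —
with p-ties broken by genomic position for determinism.

## Heritability and genetic correlation

`ldsc_h2()` fits `E[chi²] = 1 + N a + (N h²/M) ℓ` by two-step weighted
least squares: initial weights `1/max(ℓ,1)`, one reweighting by the
fitted heteroscedastic variance. Full iteration to convergence adds
nothing measurable at desk scale and the two-step fit is exactly
recoverable on noiseless inputs, which gives a sharp test. Standard
errors come from a 200-block delete-one jackknife (reduced with a
warning when variants are scarce; estimates below ~2000 variants are
approximate). `M` defaults to the regression variants — there is no
external reference-panel M here, a deliberate divergence from
munging-based conventions, which are out of scope. The
observed/liability conversion is `h2_lia = h2_obs K²(1−K)²/(P(1−P)z²)`;
with analytic-mode statistics built on `N_eff`, the appropriate sample
prevalence is 0.5. `ldsc_rg()` regresses the z-score product on ℓ and
normalises by the two heritabilities, jackknifing the whole ratio;
estimates are clipped to [−1.25, 1.25] with a warning outside [−1, 1].

## Finemapping, colocalisation, gene finemapping

`wakefield_abf()` computes the closed-form approximate Bayes factor
with prior variance `W = 0.2² = 0.04` by default, which encodes a 95%
prior odds-ratio interval of (0.68, 1.48). The ABF is oriented *in
favour of* association (the reciprocal of the null-favouring form) so
posterior probabilities are directly proportional to it; everything is
computed on the log scale. `credible_set()` assumes a single causal
variant and a flat prior over variants, sorts by posterior with
position as the deterministic tie-break, and accumulates to the nominal
mass. `coloc_abf()` evaluates the five single-causal-variant hypotheses
from per-variant log-ABF sums with priors `p1 = p2 = 1e-4`,
`p12 = 1e-5`; `coloc_sensitivity()` re-evaluates the posterior over a
log-spaced `p12` grid spanning 1e-8 to 1e-4 (the grid endpoints are a
package choice). Trait-specific prior variances default to 0.04 for
case-control traits and 0.0225 for quantitative traits, the
conventional values. `twas_finemap()` enumerates causal-gene
configurations up to `max_causal = 3` with a Bernoulli prior
(`p = 1e-3`) and non-centrality prior variance `nsigma2 = 40`; the
empty configuration is the null model representing potentially untyped
genes and competes for credible-set mass on equal terms. The
configuration covariance `Omega + nsigma2 * Omega[,c] Omega[c,]` is
ridge-stabilised at 1e-6 when needed. This is a simplified re-derivation
of configuration-enumeration TWAS finemapping, not a reproduction of
any specific tool's internals.

## Gene and gene-set association

`gene_test()` aggregates variant z-scores as `T = sum(z²)` and
moment-matches the null under the LD matrix R (mean `m = n_snps`,
variance `2 sum(R²)`, so `T/c ~ chi²_f` with `c = Var/2m`,
`f = 2m²/Var`). Moment matching was chosen over exact
quadratic-form inversion because it is standard, LD-aware, cheap, and
collapses to the right answers in the two verifiable limits
(independent SNPs; perfect LD). The competitive `geneset_test()`
regresses gene Z (upper-tail probit of the gene p) on set membership
plus `log(n_snps)` and `log(gene length)`, one-sided for enrichment,
and requires at least five overlapping genes. `acat_combine()` is the
Cauchy combination with inputs clipped to [1e-300, 1 − 1e-16],
equal weights by default; it is used to meta-analyse the same test
across annotation windows, where dependence is arbitrary. The window
presets are gene-body only, 5/1.5 kb, and 35/10 kb, applied
strand-aware and clipped at position 1.

## Mendelian randomisation

The estimator suite comprises the Wald ratio (first-order delta SE by
default; second-order behind a flag), IVW with fixed or multiplicative
random effects (the MRE inflation floored at 1), MR-Egger with
instruments oriented to positive exposure effect, and weighted median
and weighted mode with parametric-bootstrap standard errors (seeds are
mandatory arguments). `cluster_instruments()` fits, by EM, a mixture
over Wald ratios with known sampling variances: a null component fixed
at zero, K free normal components, and a uniform junk component over
the observed ratio range; K is selected by BIC over 0..`K_max`
(including the null+junk-only model, without which all-null data would
be forced into a spurious cluster), and assignments below an 80%
posterior inclusion threshold are reported unassigned. This is a
simplified EM+BIC re-derivation of mixture-model instrument clustering,
not the cited algorithm itself.

## Pharmagenic enrichment scores

`pes_enrichment_scan()` runs the competitive gene-set test for every
druggable set at the inclusion thresholds {0.005, 0.05, 0.5, 1} and
both extended annotation windows, with Benjamini-Hochberg FDR applied
jointly across all tests. `clump_and_threshold()` builds C+T weights at
r² = 0.1 within 250 kb (matching the locus conventions; the scoring
parameters are a package default, configurable). `score_individuals()`
standardises the weighted dosage sum over the cohort, mean-imputing
missing dosages by default. `pes_association()` fits logistic
regressions with and without the pathway score — both containing the
genome-wide PRS when `adjust_prs` — and reports the χ²(1) test of
residual deviance alongside the Wald odds ratio per SD.
`atc_overrepresentation()` is Fisher's exact test per ATC code with
Bonferroni correction across codes.

## Desk-scale study designs used by the tests

Problem sizes are chosen so each statistical property is testable in
seconds to minutes on one core:

* *Heritability recovery*: 3000 variants in 150 blocks, panel of 1200,
  fully polygenic `h2 = 0.1`, `N_eff = 50000`, checked within two
  jackknife SEs across seeds.
* *Genetic correlation*: 2500 variants, architectures sharing effects
  with weight 0.7, mean over seeds within 0.1 of the target.
* *Credible-set coverage*: 2000 replicates of a correctly specified
  single-causal locus of 200 variants with the effect drawn from the
  ABF prior, so nominal 95% coverage is the exact benchmark.
* *PES end-to-end*: 1200 variants, one druggable pathway with 15-fold
  effect-variance enrichment on a 0.3-causal background at `h2 = 0.4`,
  two discovery cohorts of 8,000/8,000 and an independently simulated
  target cohort of 2,000/2,000, scored at the lenient threshold
  `P_T = 1`. Modest discovery cohorts are deliberate: they keep the
  per-variant weights noisy enough that the genome-wide PRS does not
  already absorb the pathway signal, which is the regime in which a
  pathway-partitioned score is informative at all. With precisely
  estimated weights the PRS is near-sufficient and the residual-deviance
  test has, correctly, little to find.

These generated data are idealised in ways real GWAS are not: no
population stratification, no sample overlap between cohorts, no
allele-frequency mismatch against the LD panel, no genotyping batch
structure. Green tests demonstrate the estimators' internal
correctness and calibration under their stated models, not robustness
to those real-world violations.

## Numerical choices and degenerate inputs

Posterior normalisations use log-sum-exp throughout. ACAT inputs are
clipped as above; p-values of exactly 1 are accepted and clipped.
Zero-variance scores return zeros with a warning rather than 0/0.
Logistic separation raises an error recommending penalisation instead
of silently applying one. EM non-convergence returns the best fit with
a warning flag. Clumping and credible-set ties break by genomic
position; variants absent from the LD panel are excluded with a
message, never silently.
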