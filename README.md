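# pneumogwas

An R toolkit for the statistical genetics of a two-cohort case-control
GWAS — built for settings like pneumonia susceptibility, where one
large self-reported cohort and one registry-ascertained cohort are
meta-analysed and then pushed through the full downstream stack:

* **Harmonisation and meta-analysis** — allele alignment across
  cohorts, strand-ambiguity and INFO ≥ 0.6 filtering, fixed-effects
  inverse-variance-weighted meta-analysis (β̂ = Σwᵢβᵢ/Σwᵢ, w = 1/se²)
  with Cochran's Q heterogeneity, effective sample size
  N_eff = 4/(1/N_cases + 1/N_controls), LDSC-intercept p-value
  correction, and FUMA-style locus definition (r² ≤ 0.6 / r² ≤ 0.1
  clumping, 250 kb merging).
* **Heritability** — LD score regression
  E[χ²] = 1 + Na + (Nh²/M)ℓ with block-jackknife SEs, the
  observed↔liability conversion h²_lia = h²_obs·K²(1−K)²/(P(1−P)z²),
  and cross-trait genetic correlation.
* **Finemapping** — Wakefield approximate Bayes factors
  (prior variance 0.2², i.e. a 95% prior OR interval of 0.68–1.48),
  95% credible sets, single-causal-variant colocalisation (PP.H0–H4)
  with p12 prior sensitivity, configuration-enumeration TWAS gene
  finemapping with a null model, and criterion-count gene
  prioritisation.
* **Gene and gene-set association** — LD-aware Σz² gene statistic with
  Brown moment matching, three strand-aware annotation windows,
  competitive gene-set regression, ACAT (Cauchy) combination across
  windows, Bonferroni/BH adjustment.
* **Mendelian randomisation** — Wald ratio, IVW-FE/IVW-MRE, MR-Egger,
  weighted median, weighted mode, Cochran's Q, and EM mixture-model
  clustering of instrument-level causal estimates with null and junk
  components and an 80% inclusion threshold.
* **Pharmagenic enrichment scores (PES)** — pathway-restricted
  clumping+thresholding polygenic scores over druggable gene sets
  discovered at multiple inclusion thresholds with FDR control,
  genome-wide-PRS-adjusted residual-deviance association tests, and
  ATC drug-class overrepresentation.
* **Synthetic data** — a liability-threshold generator (AR(1)-block LD
  panels, two-cohort summary statistics in a fast analytic mode or an
  individual-level mode, MR instrument sets, gene models/GMT/ATC
  tables) with known ground truth, so every stage is testable with no
  external downloads.

## Worked example

```r
library(pneumogwas)

cfg <- sim_config(seed = 42, n_variants = 2000, n_blocks = 100, block_rho = 0.8,
                  h2_liability = 0.1, prevalence = 0.13, causal_fraction = 1,
                  n_cases = c(25000, 25000), n_controls = c(25000, 25000))
panel   <- simulate_reference_panel(cfg, n_individuals = 1000)
effects <- simulate_true_effects(panel, cfg)
ss      <- simulate_sumstats(panel, effects, cfg)

h <- harmonise_pair(ss[[1]], ss[[2]])
#> Harmonised cohort pair: 645 common + 0 rare variants (1355 dropped)
meta <- ivw_meta(h)
loci <- define_loci(meta, panel, p_threshold = 5e-8)
nrow(loci)
#> 15

ell <- ld_scores(panel)[match(meta$SNP, panel$variants$id)]
fit <- ldsc_h2(meta, ell, n = meta$N_EFF[1], M = cfg$n_variants)
fit
#> LD score regression
#>   h2 (observed scale): 0.0789 (SE 0.0382)
#>   intercept: 2.3505 (SE 3.8318); mean chi2 = 10.5800; ratio = 0.141
#>   645 variants, M = 2000, N = 100000, 200 jackknife blocks
liability_transform(fit$h2_observed, P_sample = 0.5, K_population = 0.13)
#> 0.0903

iv <- simulate_instruments(60, theta = 0.2, se_y = 0.008, seed = 1)
mr_all(iv, n_boot = 200, seed = 2)$ivw_mre
#> IVW-MRE: theta = 0.2015 (SE 0.0070), OR = 1.223 [1.207, 1.240], p = 9.08e-183
#>   Q = 77.55 on 59 df, p = 0.0531
```

Reading the output: 1355 of 2000 simulated variants fall to the
INFO ≥ 0.6 filter (INFO is drawn on Uniform(0.3, 1) in both cohorts);
15 loci clear genome-wide significance; LD score regression on the
surviving 645 variants puts the observed-scale SNP heritability at
0.079, which the liability transform at prevalence 13% (sample
prevalence 0.5 for an effective-N analysis) maps to 0.090 — within a
jackknife SE of the simulated 0.1. The MR suite, given 60 valid
instruments simulated with causal effect θ = 0.2, returns an OR per
exposure SD of 1.22 with θ̂ = 0.2015.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
their assumptions, the default parameters, and the desk-scale study
designs the tests use.

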