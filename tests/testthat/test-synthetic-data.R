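test_that("panel generation is deterministic and validates parameters", {
  cfg <- tiny_config(seed = 7)
  p1 <- simulate_reference_panel(cfg, n_individuals = 200)
  p2 <- simulate_reference_panel(cfg, n_individuals = 200)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$variants, p2$variants)

  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(sim_config(n_variants = 10, n_blocks = 3), "divisible")
})

test_that("block_rho = 0 gives independent dosages", {
  cfg <- tiny_config(block_rho = 0, n_variants = 60, n_blocks = 3)
  panel <- simulate_reference_panel(cfg, n_individuals = 4000)
  r <- cor(panel$genotypes)
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 0.02)
})

test_that("adjacent-pair r2 matches a brute-force latent-Gaussian oracle", {
  rho <- 0.9
  cfg <- tiny_config(block_rho = rho, n_variants = 2, n_blocks = 1,
                     maf_range = c(0.3, 0.3))
  panel <- simulate_reference_panel(cfg, n_individuals = 10000)
  r2_obs <- cor(panel$genotypes[, 1], panel$genotypes[, 2])^2

  # independent Monte-Carlo oracle of the same thresholding process
  set.seed(42)
  n <- 200000
  thr <- qnorm(1 - 0.3)
  dose <- function() {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1 > thr, z2 > thr)
  }
  d <- dose() + dose()
  r2_mc <- cor(d[, 1], d[, 2])^2
  expect_lt(abs(r2_obs - r2_mc), 0.05)
})

test_that("unselected population prevalence approaches K", {
  cfg <- tiny_config(prevalence = 0.2, h2_liability = 0.3)
  panel <- simulate_reference_panel(cfg, n_individuals = 300)
  eff <- simulate_true_effects(panel, cfg)
  pop <- simulate_population(panel, eff, cfg, n = 8000)
  prev <- mean(pop$phenotype)
  ci_half <- 3 * sqrt(0.2 * 0.8 / 8000)
  expect_lt(abs(prev - 0.2), ci_half)
})

test_that("h2 = 0 gives case status independent of genotype", {
  cfg <- tiny_config(h2_liability = 0, prevalence = 0.3)
  panel <- simulate_reference_panel(cfg, n_individuals = 300)
  eff <- simulate_true_effects(panel, cfg)
  expect_true(all(eff$beta_liability == 0))
  coh <- simulate_cohort(panel, eff, cfg, n_cases = 1500,
                         n_controls = 1500)
  ps <- vapply(c(1, 100, 250), function(j)
    summary(glm(coh$phenotype ~ coh$genotypes[, j],
                family = binomial()))$coefficients[2, 4], numeric(1))
  expect_gt(min(ps), 1e-4)
})

test_that("single-causal observed-scale effect matches threshold-model integration", {
  # K = 0.5, h2 = 0.5, one causal SNP at maf 0.3: compare the logistic
  # score-test estimate against brute-force numerical integration of the
  # liability-threshold model over the three genotype classes
  maf <- 0.3
  cfg <- sim_config(seed = 5, n_variants = 4, n_blocks = 4, block_rho = 0,
                    maf_range = c(maf, maf), h2_liability = 0.5,
                    prevalence = 0.5, causal_fraction = 0.25,
                    n_cases = c(5000L, 100L), n_controls = c(5000L, 100L))
  panel <- simulate_reference_panel(cfg, n_individuals = 200)
  eff <- simulate_true_effects(panel, cfg, rng = 5)
  j <- which(eff$causal)
  beta <- eff$beta_liability[j]

  # oracle: P(case | dosage d) = Phi((beta*(d - 2p) ) / sqrt(1 - h2*... )
  # liability = beta*d - mean + e, e ~ N(0, 1 - h2); threshold at qnorm(1-K)
  mu <- 2 * maf * beta
  sd_e <- sqrt(1 - cfg$h2_liability)
  pcase <- function(d) pnorm((beta * d - mu - qnorm(0.5)) / sd_e)
  pgen <- dbinom(0:2, 2, maf)
  # expected log-odds per allele in a 50/50 case-control sample via the
  # prospective likelihood at the population-ascertained approximation:
  # fit weighted logistic regression on the three genotype classes
  pc <- pcase(0:2)
  wcase <- pgen * pc / sum(pgen * pc)
  wctrl <- pgen * (1 - pc) / sum(pgen * (1 - pc))
  df <- data.frame(d = rep(0:2, 2), y = rep(c(1, 0), each = 3),
                   w = c(wcase, wctrl) / 2)
  oracle <- coef(suppressWarnings(
    glm(y ~ d, family = binomial(), weights = w, data = df)))[2]

  coh <- simulate_cohort(panel, eff, cfg, n_cases = 5000,
                         n_controls = 5000)
  fit <- glm(coh$phenotype ~ coh$genotypes[, j], family = binomial())
  est <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - oracle), 4 * se)
})

test_that("analytic null sumstats are calibrated", {
  cfg <- tiny_config(h2_liability = 0, n_variants = 2000, n_blocks = 100)
  panel <- simulate_reference_panel(cfg, n_individuals = 400)
  eff <- simulate_true_effects(panel, cfg)
  ss <- simulate_sumstats(panel, eff, cfg)
  z <- ss[[1]]$BETA / ss[[1]]$SE
  expect_lt(abs(mean(z^2) - 1), 0.1)
  expect_gt(ks.test(ss[[1]]$P, "punif")$p.value, 0.01)
})

test_that("analytic se follows the 1/sqrt(2 p (1-p) N_eff) formula", {
  cfg <- sim_config(seed = 1, n_variants = 1, n_blocks = 1,
                    maf_range = c(0.5, 0.5), h2_liability = 0,
                    n_cases = c(5000L), n_controls = c(5000L))
  panel <- simulate_reference_panel(cfg, n_individuals = 100)
  eff <- simulate_true_effects(panel, cfg)
  ss <- simulate_sumstats(panel, eff, cfg)
  expect_equal(ss[[1]]$SE, 1 / sqrt(2 * 0.25 * 10000), tolerance = 1e-12)
  expect_equal(ss[[1]]$SE, 0.01414, tolerance = 1e-3)
})

test_that("between-cohort heterogeneity drives Cochran's Q power", {
  base <- tiny_config(seed = 3, n_variants = 2000, n_blocks = 100,
                      h2_liability = 0.02)
  panel <- simulate_reference_panel(base, n_individuals = 400)
  frac_sig <- function(het) {
    cfg <- tiny_config(seed = 3, n_variants = 2000, n_blocks = 100,
                       h2_liability = 0.02, heterogeneity_sd = het)
    eff <- simulate_true_effects(panel, cfg)
    ss <- simulate_sumstats(panel, eff, cfg)
    m <- ivw_meta(harmonise_pair(ss[[1]], ss[[2]], info_min = 0))
    mean(m$P_HET < 0.05)
  }
  f0 <- frac_sig(0)
  f1 <- frac_sig(0.05)
  expect_lt(abs(f0 - 0.05), 0.02)
  expect_gt(f1, 0.10)
})

test_that("instrument generator recovers its own ground truth", {
  iv0 <- simulate_instruments(40, theta = 0, se_y = 0.005, seed = 2)
  est <- mr_ivw(iv0)
  expect_lt(abs(est$theta), 3 * est$se)

  iv2 <- simulate_instruments(60, theta = c(0.2, -0.1), se_x = 0.002,
                              se_y = 0.002, seed = 3)
  means <- sapply(split(iv2$beta_y / iv2$beta_x, iv2$cluster), mean)
  expect_lt(abs(means[["1"]] - 0.2), 0.02)
  expect_lt(abs(means[["2"]] + 0.1), 0.02)

  ivp <- simulate_instruments(150, theta = 0.1,
                              pleiotropy_intercept = 0.04,
                              se_y = 0.004, seed = 4)
  eg <- mr_egger(ivp)
  expect_lt(abs(eg$intercept - 0.04), 3 * eg$intercept_se)

  expect_error(simulate_instruments(10, theta = numeric(0)), "cluster")
})

test_that("annotation generator obeys its contracts", {
  cfg <- tiny_config()
  panel <- simulate_reference_panel(cfg, n_individuals = 100)
  ann <- simulate_annotations(panel, n_genes = 40, n_sets = 10,
                              druggable_fraction = 1, seed = 9)
  expect_true(all(ann$druggable))
  expect_true(all(vapply(ann$sets, length, integer(1)) >= 5))
  # every druggable set has >= 1 ATC-coded drug-target gene
  for (s in names(ann$sets)[ann$druggable])
    expect_gt(length(intersect(ann$sets[[s]], ann$atc$GENE)), 0)
  # gene intervals non-overlapping
  g <- ann$genes[order(ann$genes$START), ]
  expect_true(all(g$START[-1] > g$END[-nrow(g)]))

  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(ann$sets, f1)
  write_gmt(simulate_annotations(panel, n_genes = 40, n_sets = 10,
                                 druggable_fraction = 1, seed = 9)$sets, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(simulate_annotations(panel, n_genes = 1000), "exceeds")
})

test_that("cohort sampling fails loudly when the attempt cap is hit", {
  cfg <- tiny_config(prevalence = 0.001, h2_liability = 0.1)
  panel <- simulate_reference_panel(cfg, n_individuals = 100)
  eff <- simulate_true_effects(panel, cfg)
  expect_error(simulate_cohort(panel, eff, cfg, n_cases = 500,
                               n_controls = 10, max_attempts = 2000),
               "attempt cap")
})
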