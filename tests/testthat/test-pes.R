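# one shared design for the heavier end-to-end checks
design <- pes_design(101)

test_that("enrichment scan finds the planted druggable pathway", {
  scan <- pes_enrichment_scan(design$meta, design$panel,
                              design$ann$genes, design$ann$sets,
                              design$ann$druggable)
  expect_s3_class(scan, "pes_scan")
  expect_true(any(scan$CANDIDATE & scan$SET == design$target_set))
  expect_true(all(scan$SET %in%
                    names(design$ann$druggable)[design$ann$druggable]))
  expect_error(pes_enrichment_scan(design$meta, design$panel,
                                   design$ann$genes, design$ann$sets,
                                   setNames(rep(FALSE, 20),
                                            names(design$ann$sets))),
               "druggable")
})

test_that("a sub-threshold-only enrichment appears only at lenient P_T", {
  # constructed: pathway variants carry modest z (never significant),
  # so the set enriches at P_T = 1 but cannot at P_T = 0.005
  cfg <- tiny_config(seed = 55, n_variants = 1200, n_blocks = 60,
                     block_rho = 0.5)
  panel <- simulate_reference_panel(cfg, n_individuals = 400)
  ann <- simulate_annotations(panel, n_genes = 60, n_sets = 15,
                              set_size_range = c(6, 10),
                              druggable_fraction = 1, seed = 55)
  target <- names(ann$sets)[1]
  vars <- data.frame(SNP = panel$variants$id, CHR = panel$variants$chrom,
                     BP = panel$variants$pos)
  mapping <- annotate_snps(vars, ann$genes, "conservative")
  inset <- panel$variants$id %in% unlist(mapping[ann$sets[[target]]])
  set.seed(55)
  z <- rnorm(nrow(panel$variants))
  z[inset] <- rnorm(sum(inset), mean = 1.3)   # modest, sub-threshold
  m <- manual_meta(panel, z)
  scan <- pes_enrichment_scan(m, panel, ann$genes, ann$sets,
                              ann$druggable,
                              p_thresholds = c(0.005, 1),
                              windows = "conservative")
  hit_lenient <- scan$P[scan$SET == target & scan$P_T == 1]
  expect_lt(hit_lenient, 0.01)
  strict <- scan$P[scan$SET == target & scan$P_T == 0.005]
  expect_true(length(strict) == 0 || strict > 0.01)
})

test_that("clumping and thresholding keep the right variants", {
  # independent variants at P_T = 1: everything is its own index
  cfg <- tiny_config(seed = 12, block_rho = 0, n_variants = 50,
                     n_blocks = 50)
  panel <- simulate_reference_panel(cfg, n_individuals = 2000)
  set.seed(12)
  z <- rnorm(50, 0, 2)
  m <- manual_meta(panel, z)
  wt <- clump_and_threshold(m, panel, p_t = 1)
  expect_equal(nrow(wt), 50)

  # duplicate variant pair: the smaller p survives
  g <- matrix(rbinom(3000, 2, 0.3), ncol = 1)
  pan2 <- manual_panel(cbind(g, g))
  m2 <- manual_meta(pan2, c(2, 3))
  wt2 <- clump_and_threshold(m2, pan2, p_t = 1)
  expect_equal(wt2$SNP, "snp002")

  # threshold filters exactly on the clump indices
  wt3 <- clump_and_threshold(m, panel, p_t = 0.005)
  expect_setequal(wt3$SNP, m$SNP[m$P <= 0.005])
  expect_error(clump_and_threshold(m, panel, p_t = 1e-30), "empty score")
})

test_that("scoring is linear, standardised, and restriction-consistent", {
  cfg <- tiny_config(seed = 14, n_variants = 100, n_blocks = 10)
  panel <- simulate_reference_panel(cfg, n_individuals = 400)
  set.seed(14)
  m <- manual_meta(panel, rnorm(100, 0, 1.5))
  wt <- clump_and_threshold(m, panel, p_t = 1)
  prs <- score_individuals(panel, wt)
  expect_equal(mean(prs), 0, tolerance = 1e-12)
  expect_equal(sd(prs), 1, tolerance = 1e-12)

  # restriction to all scored variants is the identity
  pes_all <- score_individuals(panel, wt, restrict_to = wt$SNP)
  expect_equal(pes_all, prs, tolerance = 1e-12, ignore_attr = TRUE)

  # oracle: standardised weighted dosage sum
  raw <- as.numeric(panel$genotypes[, wt$SNP] %*% wt$BETA)
  expect_equal(prs, (raw - mean(raw)) / sd(raw), tolerance = 1e-12,
               ignore_attr = TRUE)

  # correlation between nested scores matches the brute-force value
  sub <- wt$SNP[1:10]
  pes <- score_individuals(panel, wt, restrict_to = sub)
  raw_sub <- as.numeric(panel$genotypes[, sub] %*%
                          wt$BETA[match(sub, wt$SNP)])
  expect_equal(pes_prs_correlation(pes, prs)$r, cor(raw_sub, raw),
               tolerance = 1e-12)

  # all-zero weights: warning and zero scores
  wt0 <- wt; wt0$BETA <- 0
  expect_warning(s0 <- score_individuals(panel, wt0), "zero-variance")
  expect_true(all(s0 == 0))

  # an individual homozygous for every risk allele attains the max score
  wpos <- wt; wpos$BETA <- abs(wpos$BETA)
  g2 <- panel$genotypes
  g2[1, wpos$SNP] <- 2L
  s2 <- score_individuals(g2, wpos)
  expect_equal(which.max(s2), 1L)
})

test_that("mean imputation fills missing dosages", {
  g <- matrix(rbinom(600, 2, 0.4), ncol = 3,
              dimnames = list(NULL, c("snp001", "snp002", "snp003")))
  gna <- g; gna[1:5, 2] <- NA
  wt <- data.frame(SNP = colnames(g), A1 = "A", A2 = "G",
                   BETA = c(0.1, 0.2, -0.1), P = 0.01)
  s_mean <- score_individuals(gna, wt)
  expect_false(anyNA(s_mean))
  s_drop <- score_individuals(gna, wt, missing = "drop")
  expect_equal(attr(s_drop, "n_snps"), 2)
})

test_that("PES association isolates pathway signal above the PRS", {
  wt <- clump_and_threshold(design$meta, design$panel, p_t = 1)
  coh <- simulate_cohort(design$panel, design$effects, design$cfg,
                         n_cases = 2000, n_controls = 2000, rng = 9101)
  prs <- score_individuals(coh, wt)
  pes <- score_individuals(coh, wt, restrict_to = design$enriched)
  res <- pes_association(coh$phenotype, pes, prs)
  expect_lt(res$p_deviance, 0.05)
  expect_gt(res$or_per_sd, 1)

  # collinearity limit: PES identical to PRS adds no deviance
  res_same <- pes_association(coh$phenotype, prs, prs)
  expect_gt(res_same$p_deviance, 0.99)

  # PRS is required when adjusting
  expect_error(pes_association(coh$phenotype, pes, adjust_prs = TRUE),
               "prs")
  expect_error(pes_association(c(0, 1, 2), rnorm(3), rnorm(3)),
               "binary")
})

test_that("PES deviance test is calibrated under the null", {
  set.seed(71)
  n <- 400
  ps <- replicate(300, {
    y <- rbinom(n, 1, 0.3)
    pes_association(y, rnorm(n), rnorm(n))$p_deviance
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("PES distribution over a null cohort is near-normal", {
  cfg <- tiny_config(seed = 88, n_variants = 200, n_blocks = 20,
                     h2_liability = 0)
  panel <- simulate_reference_panel(cfg, n_individuals = 5000)
  set.seed(88)
  m <- manual_meta(panel, rnorm(200))
  wt <- clump_and_threshold(m, panel, p_t = 1)
  s <- score_individuals(panel, wt)
  expect_gt(shapiro.test(sample(s, 3000))$p.value, 1e-4)
})

test_that("ATC overrepresentation matches the hypergeometric oracle", {
  # extreme table: all set genes target one code
  universe <- sprintf("G%03d", 1:100)
  atc <- data.frame(DRUG = "D1", ATC_CODE = "X01", GENE = universe[1:10])
  out <- atc_overrepresentation(universe[1:10], universe, atc)
  expect_lt(out$P, 1e-10)

  # 2x2 table (5,5,5,985): equals hypergeometric enumeration
  uni2 <- sprintf("H%04d", 1:1000)
  set_g <- uni2[1:10]
  targets <- c(uni2[1:5], uni2[11:15])
  atc2 <- data.frame(DRUG = "D2", ATC_CODE = "X02", GENE = targets)
  out2 <- atc_overrepresentation(set_g, uni2, atc2)
  oracle <- sum(dhyper(5:10, 10, 990, 10))
  expect_equal(out2$P, oracle, tolerance = 1e-10)

  # Bonferroni across codes
  atc3 <- rbind(atc2, data.frame(DRUG = "D3", ATC_CODE = "X03",
                                 GENE = uni2[500:520]))
  out3 <- atc_overrepresentation(set_g, uni2, atc3)
  expect_equal(out3$P_BONF, pmin(out3$P * 2, 1))
  expect_equal(0.05 / 85, 5.882353e-4, tolerance = 1e-6)
})

test_that("the scan -> score -> associate path detects the planted pathway in most seeds", {
  seeds <- c(101, 202, 303, 404, 505)
  sig <- vapply(seeds, function(s) {
    d <- if (s == 101) design else pes_design(s)
    wt <- clump_and_threshold(d$meta, d$panel, p_t = 1)
    coh <- simulate_cohort(d$panel, d$effects, d$cfg, n_cases = 2000,
                           n_controls = 2000, rng = s + 3000)
    prs <- score_individuals(coh, wt)
    pes <- score_individuals(coh, wt, restrict_to = d$enriched)
    pes_association(coh$phenotype, pes, prs)$p_deviance < 0.05
  }, logical(1))
  expect_gte(sum(sig), 3)
})
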