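# Shared fixtures, all generated in code.

# small default config for module tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_variants = 400L, n_blocks = 20L,
               block_rho = 0.8, h2_liability = 0.1, prevalence = 0.13,
               n_cases = c(10000L, 10000L),
               n_controls = c(10000L, 10000L), causal_fraction = 1)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# hand-built panel with fully specified dosage matrix (for exact-LD cases)
manual_panel <- function(genotypes, pos = NULL, maf = NULL) {
  m <- ncol(genotypes)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(maf)) maf <- colMeans(genotypes) / 2
  ids <- sprintf("snp%03d", seq_len(m))
  colnames(genotypes) <- ids
  structure(list(
    variants = data.frame(id = ids, chrom = 1L, pos = pos, a1 = "A",
                          a2 = "G", maf = maf, block = 1L,
                          stringsAsFactors = FALSE),
    genotypes = genotypes, block_rho = NA_real_),
    class = "reference_panel")
}

# a meta_result built directly from z-scores (for locus/clumping tests)
manual_meta <- function(panel, z, n_eff = 10000) {
  v <- panel$variants
  se <- 1 / sqrt(2 * v$maf * (1 - v$maf) * n_eff)
  structure(data.frame(SNP = v$id, CHR = v$chrom, BP = v$pos,
                       A1 = v$a1, A2 = v$a2, FRQ = v$maf,
                       BETA = z * se, SE = se, Z = z,
                       P = 2 * pnorm(abs(z), lower.tail = FALSE),
                       Q = 0, Q_DF = 1L, P_HET = 1, N_EFF = n_eff,
                       stringsAsFactors = FALSE),
            class = c("meta_result", "data.frame"))
}

# the desk-scale pathway-enrichment study design used by the PES
# end-to-end checks: modest discovery cohorts (noisy per-SNP weights),
# one strongly enriched druggable pathway
pes_design <- function(seed) {
  cfg <- sim_config(seed = seed, n_variants = 1200L, n_blocks = 60L,
                    block_rho = 0.8, h2_liability = 0.4, prevalence = 0.2,
                    causal_fraction = 0.3, pathway_enrichment = 15,
                    n_cases = c(8000L, 8000L),
                    n_controls = c(8000L, 8000L))
  panel <- simulate_reference_panel(cfg, n_individuals = 1000L)
  ann <- simulate_annotations(panel, n_genes = 60L, n_sets = 20L,
                              set_size_range = c(5L, 8L),
                              druggable_fraction = 0.5, seed = seed)
  target_set <- names(ann$sets)[ann$druggable][1]
  vars <- data.frame(SNP = panel$variants$id, CHR = panel$variants$chrom,
                     BP = panel$variants$pos, stringsAsFactors = FALSE)
  mapping <- annotate_snps(vars, ann$genes, "conservative")
  enriched <- unique(unlist(mapping[ann$sets[[target_set]]]))
  eff <- simulate_true_effects(panel, cfg, enriched_ids = enriched)
  ss <- simulate_sumstats(panel, eff, cfg)
  meta <- ivw_meta(harmonise_pair(ss[[1]], ss[[2]], info_min = 0))
  list(cfg = cfg, panel = panel, ann = ann, target_set = target_set,
       enriched = enriched, effects = eff, meta = meta)
}
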