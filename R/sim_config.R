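#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: the LD panel
#' (variant count, AR(1) block structure, allele-frequency range), the
#' liability-threshold disease model (SNP heritability on the liability
#' scale, population prevalence), per-cohort case/control counts, optional
#' between-cohort effect heterogeneity, and the sparsity/pathway-enrichment
#' structure of the true effects.
#'
#' Defaults mirror a two-cohort pneumonia-style meta-analysis: liability
#' heritability 0.0269, population prevalence 0.1296, and the case/control
#' counts of a large self-reported cohort plus a registry-based cohort.
#' Tests and examples pass smaller explicit values.
#'
#' @param seed Integer seed; the same seed reproduces every generated object
#'   byte for byte.
#' @param n_variants Total number of variants in the panel.
#' @param n_blocks Number of LD blocks; must divide \code{n_variants}.
#' @param block_rho AR(1) latent correlation within a block, in [0, 1).
#' @param maf_range Length-2 numeric, lower/upper minor-allele frequency in
#'   (0, 0.5].
#' @param h2_liability SNP heritability on the liability scale, in [0, 1].
#' @param prevalence Population prevalence K of the binary trait, in (0, 1).
#' @param n_cases,n_controls Integer vectors (one entry per cohort) of case
#'   and control counts.
#' @param heterogeneity_sd SD (log-odds units) of per-cohort deviations
#'   added to each variant's effect; 0 means perfectly shared effects.
#' @param causal_fraction Proportion of variants with nonzero liability
#'   effect.
#' @param pathway_enrichment Multiplier (>= 1) applied to the per-SNP effect
#'   variance of variants annotated to designated enriched gene sets.
#' @param pos_spacing_bp Base-pair spacing between adjacent variants (one
#'   chromosome, positions \code{1, 1 + s, 1 + 2s, ...}).
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_variants = 100, n_blocks = 10,
#'                   h2_liability = 0.1, n_cases = c(500, 500),
#'                   n_controls = c(500, 500))
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 1000L,
                       n_blocks = 50L,
                       block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       h2_liability = 0.0269,
                       prevalence = 0.1296,
                       n_cases = c(40600L, 33723L),
                       n_controls = c(90039L, 226682L),
                       heterogeneity_sd = 0,
                       causal_fraction = 0.2,
                       pathway_enrichment = 1,
                       pos_spacing_bp = 5000L) {
  seed <- check_count(seed, "seed", min = 0L)
  n_variants <- check_count(n_variants, "n_variants")
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (n_variants %% n_blocks != 0L)
    stop_param("'n_variants' (%d) must be divisible by 'n_blocks' (%d)",
               n_variants, n_blocks)
  if (length(block_rho) != 1L || !is.finite(block_rho) ||
      block_rho < 0 || block_rho >= 1)
    stop_param("'block_rho' must be in [0,1) (got %s)", format(block_rho))
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_param("'maf_range' must be an increasing pair in (0, 0.5]")
  check_prob(h2_liability, "h2_liability", open_lower = FALSE,
             open_upper = FALSE)
  check_prob(prevalence, "prevalence")
  if (length(n_cases) != length(n_controls))
    stop_param("'n_cases' and 'n_controls' must have one entry per cohort")
  n_cases <- vapply(seq_along(n_cases), function(i)
    check_count(n_cases[i], "n_cases"), integer(1))
  n_controls <- vapply(seq_along(n_controls), function(i)
    check_count(n_controls[i], "n_controls"), integer(1))
  if (heterogeneity_sd < 0)
    stop_param("'heterogeneity_sd' must be >= 0")
  check_prob(causal_fraction, "causal_fraction", open_lower = FALSE,
             open_upper = FALSE)
  if (pathway_enrichment < 1)
    stop_param("'pathway_enrichment' must be >= 1")

  structure(list(seed = seed, n_variants = n_variants, n_blocks = n_blocks,
                 block_rho = block_rho, maf_range = as.numeric(maf_range),
                 h2_liability = h2_liability, prevalence = prevalence,
                 n_cases = n_cases, n_controls = n_controls,
                 heterogeneity_sd = heterogeneity_sd,
                 causal_fraction = causal_fraction,
                 pathway_enrichment = pathway_enrichment,
                 pos_spacing_bp = as.integer(pos_spacing_bp)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  variants: %d in %d AR(1) blocks (rho = %.2f), MAF %.3f-%.3f\n",
              x$n_variants, x$n_blocks, x$block_rho,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  liability model: h2 = %.4f, prevalence K = %.4f\n",
              x$h2_liability, x$prevalence))
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%d/%d", x$n_cases, x$n_controls),
                    collapse = ", ")))
  cat(sprintf("  heterogeneity SD = %g, causal fraction = %g, enrichment = %g\n",
              x$heterogeneity_sd, x$causal_fraction, x$pathway_enrichment))
  invisible(x)
}
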