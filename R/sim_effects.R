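#' Simulate true per-variant liability effects
#'
#' Draws a sparse additive genetic architecture on the liability scale.
#' A fraction \code{causal_fraction} of variants receive effects drawn from
#' a normal distribution; variants listed in \code{enriched_ids} have their
#' per-SNP effect variance multiplied by \code{pathway_enrichment} before
#' the draw. Effects are rescaled so that the total additive variance
#' \eqn{\sum_j 2 p_j (1-p_j) \beta_j^2} equals \code{h2_liability} exactly.
#'
#' @param panel A \code{reference_panel} giving allele frequencies.
#' @param config A \code{\link{sim_config}}.
#' @param enriched_ids Character vector of variant ids whose effect variance
#'   is multiplied by \code{config$pathway_enrichment}.
#' @param rng Optional seed override (default \code{config$seed}).
#' @return Object of class \code{true_effects}: data.frame with id, maf,
#'   \code{beta_liability} (liability SD per effect allele), and logical
#'   \code{causal}; attribute \code{h2_liability}.
#' @export
simulate_true_effects <- function(panel, config, enriched_ids = character(),
                                  rng = NULL) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(config, "sim_config"))
  seed <- if (is.null(rng)) config$seed else check_count(rng, "rng", 0L)
  gen <- local_rng(seed, stream = 2L)

  v <- panel$variants
  m <- nrow(v)
  n_causal <- max(if (config$h2_liability > 0) 1L else 0L,
                  round(config$causal_fraction * m))
  beta <- numeric(m)
  causal <- rep(FALSE, m)
  if (n_causal > 0L && config$h2_liability > 0) {
    idx <- sort(gen$sample(m, n_causal))
    causal[idx] <- TRUE
    relvar <- rep(1, n_causal)
    relvar[v$id[idx] %in% enriched_ids] <- config$pathway_enrichment
    # equal variance per *standardized* variant (the LDSC model), so the
    # per-allele scale is 1/sqrt(2p(1-p))
    het <- 2 * v$maf[idx] * (1 - v$maf[idx])
    beta[idx] <- gen$rnorm(n_causal, sd = sqrt(relvar / het))
    vg <- sum(2 * v$maf * (1 - v$maf) * beta^2)
    beta <- beta * sqrt(config$h2_liability / vg)
  }
  structure(data.frame(id = v$id, maf = v$maf, beta_liability = beta,
                       causal = causal, stringsAsFactors = FALSE),
            h2_liability = config$h2_liability, class = c("true_effects",
                                                          "data.frame"))
}

#' Simulate a labelled case-control cohort under the liability-threshold model
#'
#' Each individual's liability is the additive genetic score plus standard
#' normal environmental noise scaled so total liability variance is 1; an
#' individual is a case iff liability exceeds \eqn{\Phi^{-1}(1-K)}. Sampling
#' continues (in batches of fresh panel-like genotype draws) until exactly
#' \code{n_cases} cases and \code{n_controls} controls are collected.
#'
#' @param panel A \code{reference_panel}; genotypes are drawn from the same
#'   generative process (not resampled rows), keeping LD structure.
#' @param effects A \code{true_effects} aligned to the panel.
#' @param config A \code{\link{sim_config}}; uses \code{prevalence} and
#'   \code{h2_liability}.
#' @param n_cases,n_controls Target counts (scalars; default first cohort of
#'   the config).
#' @param max_attempts Cap on generated individuals before failing; guards
#'   against prevalences so small that case sampling cannot finish.
#' @param rng Optional seed override.
#' @return List of class \code{sim_cohort}: \code{genotypes} (dosage matrix),
#'   \code{phenotype} (0/1), \code{liability}, and counts.
#' @export
simulate_cohort <- function(panel, effects, config,
                            n_cases = config$n_cases[1],
                            n_controls = config$n_controls[1],
                            max_attempts = 50L * (n_cases + n_controls),
                            rng = NULL) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(effects, "true_effects"))
  if (!identical(effects$id, panel$variants$id))
    stop_param("'effects' must be aligned to the panel variants")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  seed <- if (is.null(rng)) config$seed else check_count(rng, "rng", 0L)

  K <- config$prevalence
  thr <- stats::qnorm(1 - K)
  sd_env <- sqrt(max(0, 1 - config$h2_liability))
  beta <- effects$beta_liability
  mu_g <- sum(2 * effects$maf * beta)  # centre so liability has mean 0

  geno_case <- matrix(NA_integer_, 0L, config$n_variants)
  geno_ctrl <- matrix(NA_integer_, 0L, config$n_variants)
  lia_case <- numeric(0); lia_ctrl <- numeric(0)
  attempts <- 0L
  batch <- max(1000L, n_cases + n_controls)
  draw_seed <- seed
  while (nrow(geno_case) < n_cases || nrow(geno_ctrl) < n_controls) {
    if (attempts >= max_attempts)
      stop_param(paste0("case/control sampling exceeded the attempt cap of ",
                        "%d individuals (prevalence K = %g too extreme?)"),
                 max_attempts, K)
    # fresh individuals from the panel's latent process at the panel's MAFs
    g <- regenerate_dosages(config, panel$variants$maf, batch,
                            seed = draw_seed + 7L)
    gen <- local_rng(draw_seed + 13L, stream = 3L)
    lia <- as.numeric(g %*% beta) - mu_g + sd_env * gen$rnorm(batch)
    is_case <- lia > thr
    need_ca <- n_cases - nrow(geno_case)
    need_co <- n_controls - nrow(geno_ctrl)
    if (need_ca > 0L && any(is_case)) {
      take <- which(is_case)[seq_len(min(need_ca, sum(is_case)))]
      geno_case <- rbind(geno_case, g[take, , drop = FALSE])
      lia_case <- c(lia_case, lia[take])
    }
    if (need_co > 0L && any(!is_case)) {
      take <- which(!is_case)[seq_len(min(need_co, sum(!is_case)))]
      geno_ctrl <- rbind(geno_ctrl, g[take, , drop = FALSE])
      lia_ctrl <- c(lia_ctrl, lia[take])
    }
    attempts <- attempts + batch
    draw_seed <- draw_seed + 101L
  }
  g <- rbind(geno_case, geno_ctrl)
  colnames(g) <- panel$variants$id
  structure(list(genotypes = g,
                 phenotype = c(rep(1L, n_cases), rep(0L, n_controls)),
                 liability = c(lia_case, lia_ctrl),
                 n_cases = n_cases, n_controls = n_controls),
            class = "sim_cohort")
}

# fresh dosage draws from the same latent AR(1)/threshold process at given
# MAFs (helper for cohort sampling; keeps the panel's LD structure)
regenerate_dosages <- function(config, maf, n_individuals, seed) {
  m <- config$n_variants
  block_size <- m %/% config$n_blocks
  rho <- config$block_rho
  thr <- stats::qnorm(1 - maf)
  gen <- local_rng(seed, stream = 4L)
  dose <- matrix(0L, n_individuals, m)
  for (hap in 1:2) {
    for (b in seq_len(config$n_blocks)) {
      cols <- ((b - 1L) * block_size + 1L):(b * block_size)
      z <- gen$rnorm(n_individuals)
      lat <- matrix(NA_real_, n_individuals, block_size)
      lat[, 1] <- z
      if (block_size > 1L) {
        sd_innov <- sqrt(1 - rho^2)
        for (j in 2:block_size) {
          z <- rho * z + sd_innov * gen$rnorm(n_individuals)
          lat[, j] <- z
        }
      }
      dose[, cols] <- dose[, cols] +
        (lat > rep(thr[cols], each = n_individuals))
    }
  }
  storage.mode(dose) <- "integer"
  dose
}

#' Simulate an unselected population under the liability-threshold model
#'
#' Draws \code{n} individuals from the same generative process as
#' \code{\link{simulate_cohort}} without case/control ascertainment, so the
#' empirical case prevalence estimates the population prevalence K.
#'
#' @param panel A \code{reference_panel}.
#' @param effects A \code{true_effects} aligned to the panel.
#' @param config A \code{\link{sim_config}}.
#' @param n Number of individuals.
#' @param rng Optional seed override.
#' @return List of class \code{sim_cohort} with \code{genotypes},
#'   \code{phenotype}, \code{liability}.
#' @export
simulate_population <- function(panel, effects, config, n = 1000L,
                                rng = NULL) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(effects, "true_effects"))
  if (!identical(effects$id, panel$variants$id))
    stop_param("'effects' must be aligned to the panel variants")
  n <- check_count(n, "n")
  seed <- if (is.null(rng)) config$seed else check_count(rng, "rng", 0L)
  beta <- effects$beta_liability
  g <- regenerate_dosages(config, panel$variants$maf, n, seed = seed + 7L)
  gen <- local_rng(seed + 13L, stream = 3L)
  lia <- as.numeric(g %*% beta) - sum(2 * effects$maf * beta) +
    sqrt(max(0, 1 - config$h2_liability)) * gen$rnorm(n)
  colnames(g) <- panel$variants$id
  phen <- as.integer(lia > stats::qnorm(1 - config$prevalence))
  structure(list(genotypes = g, phenotype = phen, liability = lia,
                 n_cases = sum(phen), n_controls = n - sum(phen)),
            class = "sim_cohort")
}
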