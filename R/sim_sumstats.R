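#' Simulate per-cohort GWAS summary statistics
#'
#' Produces one summary-statistics table per cohort in the configuration,
#' in either of two modes:
#' \describe{
#'   \item{analytic}{Effect estimates are drawn directly from their sampling
#'     distribution: on the log-odds scale,
#'     \eqn{se_j = 1/\sqrt{2 p_j (1-p_j) N_{eff}}} with
#'     \eqn{N_{eff} = 4/(1/n_{cases} + 1/n_{controls})}, and
#'     \eqn{\hat\beta_j \sim N(\beta_j + \delta_{cj}, se_j^2)} where
#'     \eqn{\beta_j} is the LD-convolved marginal effect implied by the true
#'     liability architecture (re-expressed on the observed scale of a
#'     balanced design) and \eqn{\delta_{cj} \sim N(0,
#'     heterogeneity\_sd^2)} is the cohort-specific deviation. Fast; used
#'     for everything that does not need genotypes.}
#'   \item{individual}{A case-control cohort is simulated under the
#'     liability-threshold model and each variant is tested with a logistic
#'     score test; beta/se are the one-step score-test estimates.}
#' }
#' Imputation INFO is simulated independently of the effects on
#' Uniform(0.3, 1) so downstream INFO filtering can be exercised without
#' confounding. Monomorphic variants (individual mode) are dropped with a
#' message; their count is in attribute \code{n_dropped}.
#'
#' @param panel A \code{reference_panel}.
#' @param effects A \code{true_effects} aligned to the panel.
#' @param config A \code{\link{sim_config}} (cohort sizes, prevalence,
#'   heterogeneity SD).
#' @param mode \code{"analytic"} (default) or \code{"individual"}.
#' @param rng Optional seed override.
#' @return A list with one data.frame per cohort, columns
#'   \code{SNP, CHR, BP, A1, A2, FRQ, BETA, SE, P, N_CASES, N_CONTROLS,
#'   INFO}. Attribute \code{true_marginal} holds the marginal log-odds
#'   effects used (analytic mode).
#' @export
simulate_sumstats <- function(panel, effects, config,
                              mode = c("analytic", "individual"),
                              rng = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "reference_panel"),
            inherits(effects, "true_effects"))
  if (!identical(effects$id, panel$variants$id))
    stop_param("'effects' must be aligned to the panel variants")
  seed <- if (is.null(rng)) config$seed else check_count(rng, "rng", 0L)

  v <- panel$variants
  p <- v$maf
  het <- 2 * p * (1 - p)
  n_coh <- length(config$n_cases)

  if (mode == "analytic") {
    # marginal standardized effects: blockwise LD convolution of the true
    # standardized liability effects, moved to the observed scale of a
    # balanced (N_eff, P = 0.5) design so the liability transform at
    # P = 0.5 maps heritability back to config$h2_liability.
    b_std <- effects$beta_liability * sqrt(het)
    K <- config$prevalence
    cfac <- K^2 * (1 - K)^2 /
      (0.25 * stats::dnorm(stats::qnorm(1 - K))^2)
    b_obs <- b_std / sqrt(cfac)
    marg <- numeric(length(b_obs))
    for (b in unique(v$block)) {
      idx <- which(v$block == b)
      r <- suppressWarnings(stats::cor(panel$genotypes[, idx, drop = FALSE]))
      r[!is.finite(r)] <- 0; diag(r) <- 1
      marg[idx] <- as.numeric(r %*% b_obs[idx])
    }
    beta_marg <- marg / sqrt(het)  # back to per-allele log-odds

    gen <- local_rng(seed, stream = 5L)
    out <- vector("list", n_coh)
    for (ci in seq_len(n_coh)) {
      nca <- config$n_cases[ci]; nco <- config$n_controls[ci]
      neff <- effective_n(nca, nco, rounded = FALSE)
      se <- 1 / sqrt(het * neff)
      delta <- if (config$heterogeneity_sd > 0)
        gen$rnorm(length(p), sd = config$heterogeneity_sd) else 0
      beta_hat <- beta_marg + delta + se * gen$rnorm(length(p))
      info <- gen$runif(length(p), 0.3, 1)
      out[[ci]] <- data.frame(
        SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$a1, A2 = v$a2,
        FRQ = p, BETA = beta_hat, SE = se,
        P = z_to_p(beta_hat / se),
        N_CASES = nca, N_CONTROLS = nco, INFO = info,
        stringsAsFactors = FALSE)
    }
    attr(out, "true_marginal") <- beta_marg
    return(out)
  }

  # individual mode: simulate each cohort and run a per-variant logistic
  # score test (one-step estimate beta = U/V, se = V^{-1/2})
  out <- vector("list", n_coh)
  for (ci in seq_len(n_coh)) {
    coh <- simulate_cohort(panel, effects, config,
                           n_cases = config$n_cases[ci],
                           n_controls = config$n_controls[ci],
                           rng = seed + 977L * ci)
    y <- coh$phenotype
    g <- coh$genotypes
    ybar <- mean(y)
    gbar <- colMeans(g)
    U <- as.numeric(crossprod(g, y - ybar))
    Vv <- ybar * (1 - ybar) *
      (colSums(g^2) - nrow(g) * gbar^2)
    mono <- Vv <= 0
    if (any(mono))
      message(sum(mono), " monomorphic variant(s) dropped from cohort ", ci)
    beta_hat <- U / Vv
    se <- 1 / sqrt(Vv)
    gen <- local_rng(seed + 31L * ci, stream = 6L)
    info <- gen$runif(length(gbar), 0.3, 1)
    df <- data.frame(
      SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$a1, A2 = v$a2,
      FRQ = gbar / 2, BETA = beta_hat, SE = se,
      P = z_to_p(beta_hat / se),
      N_CASES = coh$n_cases, N_CONTROLS = coh$n_controls, INFO = info,
      stringsAsFactors = FALSE)
    df <- df[!mono, , drop = FALSE]
    attr(df, "n_dropped") <- sum(mono)
    out[[ci]] <- df
  }
  out
}
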