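#' Wakefield approximate Bayes factor
#'
#' Closed-form Bayes factor in favour of association for a variant with
#' estimate \code{beta} and standard error \code{se}, under a normal
#' effect-size prior with variance \code{W}:
#' \deqn{ABF = \sqrt{V/(V+W)} \exp\{W \beta^2 / (2 V (V+W))\}, \quad V = se^2.}
#' Computed on the log scale. The default \code{W = 0.2^2 = 0.04} encodes a
#' 95\% prior odds-ratio interval of roughly (0.68, 1.48) for a log-odds
#' effect. Note the orientation: this is the reciprocal of the
#' null-favouring Bayes factor, so posterior causality probabilities are
#' proportional to it.
#'
#' @param beta Effect estimates (log-odds).
#' @param se Standard errors (> 0).
#' @param W Prior variance of the effect (default 0.04).
#' @param log Return log ABF instead.
#' @return Numeric vector of (log) ABFs.
#' @export
wakefield_abf <- function(beta, se, W = 0.04, log = FALSE) {
  if (W < 0) stop_param("prior variance 'W' must be >= 0")
  if (any(se <= 0)) stop_param("all 'se' must be positive")
  V <- se^2
  labf <- 0.5 * base::log(V / (V + W)) + W * beta^2 / (2 * V * (V + W))
  if (log) labf else exp(labf)
}

#' The central prior odds-ratio interval implied by an ABF prior variance
#' @param W Prior variance on the log-odds scale.
#' @param level Central mass (default 0.95).
#' @return Length-2 vector of odds ratios.
#' @examples abf_prior_or_interval(0.04)  # ~ (0.68, 1.48)
#' @export
abf_prior_or_interval <- function(W, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  exp(c(-1, 1) * q * sqrt(W))
}

#' Posterior probabilities and credible set from ABFs
#'
#' Normalises per-variant ABFs to posterior probabilities (flat prior over
#' variants, single causal variant assumed) and accumulates variants in
#' descending posterior order (ties by position) until the nominal mass
#' \code{rho} is reached.
#'
#' @param abf Numeric vector of ABFs (or log ABFs with \code{log = TRUE}).
#' @param snp Variant ids (default index labels).
#' @param pos Positions used only for deterministic tie-breaking.
#' @param rho Nominal credible mass (default 0.95).
#' @param log Interpret \code{abf} as log ABFs.
#' @return Object of class \code{credible_set}: list with \code{pp}
#'   (posterior probabilities, named, input order), \code{set} (ids in the
#'   credible set), \code{mass} (attained mass), \code{rho}.
#' @export
credible_set <- function(abf, snp = NULL, pos = NULL, rho = 0.95,
                         log = FALSE) {
  if (!length(abf)) stop_param("empty ABF vector")
  check_prob(rho, "rho")
  labf <- if (log) abf else base::log(abf)
  pp <- exp(labf - logsumexp(labf))
  if (is.null(snp)) snp <- as.character(seq_along(abf))
  if (is.null(pos)) pos <- seq_along(abf)
  names(pp) <- snp
  ord <- order(-pp, pos)
  cum <- cumsum(pp[ord])
  k <- which(cum >= rho)[1]
  if (is.na(k)) k <- length(pp)   # numeric slack: take everything
  structure(list(pp = pp, set = snp[ord[seq_len(k)]],
                 mass = unname(cum[k]), rho = rho),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%g%% credible set: %d of %d variants (mass %.4f)\n",
              100 * x$rho, length(x$set), length(x$pp), x$mass))
  invisible(x)
}

#' Single-causal-variant colocalisation of two traits
#'
#' Enumerates the five hypotheses of the standard ABF colocalisation model
#' over a shared variant list: no association (H0), trait-1-only (H1),
#' trait-2-only (H2), two distinct causal variants (H3), one shared causal
#' variant (H4). With per-variant ABFs \eqn{A_{1j}, A_{2j}} and priors
#' \code{p1, p2, p12}, the unnormalised masses are
#' 1, \eqn{p_1 \sum_j A_{1j}}, \eqn{p_2 \sum_j A_{2j}},
#' \eqn{p_1 p_2 (\sum_j A_{1j} \sum_k A_{2k} - \sum_j A_{1j} A_{2j})},
#' \eqn{p_{12} \sum_j A_{1j} A_{2j}}; all sums on the log scale.
#'
#' @param beta1,se1 Trait 1 effect estimates and SEs.
#' @param beta2,se2 Trait 2 effect estimates and SEs (same variants, same
#'   order).
#' @param W1,W2 Trait-specific ABF prior variances: 0.04 suits a
#'   case-control log-odds scale, 0.0225 a standardised quantitative trait.
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both.
#' @return Object of class \code{coloc_result}: list with \code{pp} (named
#'   PP.H0..PP.H4), \code{priors}, \code{labf1}, \code{labf2},
#'   \code{n_variants}.
#' @export
coloc_abf <- function(beta1, se1, beta2, se2, W1 = 0.04, W2 = 0.04,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(beta1)
  if (m < 2L) stop_param("colocalisation needs >= 2 shared variants")
  if (length(beta2) != m || length(se1) != m || length(se2) != m)
    stop_param("trait vectors must be aligned")
  l1 <- wakefield_abf(beta1, se1, W1, log = TRUE)
  l2 <- wakefield_abf(beta2, se2, W2, log = TRUE)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh <- c(H0 = 0,
          H1 = base::log(p1) + ls1,
          H2 = base::log(p2) + ls2,
          H3 = base::log(p1) + base::log(p2) +
            ls1 + ls2 + base::log1p(-exp(ls12 - ls1 - ls2)),
          H4 = base::log(p12) + ls12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  structure(list(pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
                 labf1 = l1, labf2 = l2, n_variants = m),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation over %d variants (p1=%g, p2=%g, p12=%g)\n",
              x$n_variants, x$priors["p1"], x$priors["p2"],
              x$priors["p12"]))
  print(round(x$pp, 4))
  invisible(x)
}

#' Sensitivity of the shared-causal-variant posterior to the p12 prior
#'
#' Re-evaluates the colocalisation posterior over a log-spaced grid of
#' \code{p12} values, holding p1 and p2 fixed, to show how the evidence for
#' a shared causal variant depends on that prior.
#'
#' @param coloc A \code{coloc_result}.
#' @param p12_grid Grid of p12 values (default 30 log-spaced points in
#'   [1e-8, 1e-4]).
#' @return data.frame with p12 and the five posterior probabilities.
#' @export
coloc_sensitivity <- function(coloc,
                              p12_grid = 10^seq(-8, -4, length.out = 30)) {
  stopifnot(inherits(coloc, "coloc_result"))
  ls1 <- logsumexp(coloc$labf1)
  ls2 <- logsumexp(coloc$labf2)
  ls12 <- logsumexp(coloc$labf1 + coloc$labf2)
  p1 <- coloc$priors["p1"]; p2 <- coloc$priors["p2"]
  rows <- lapply(p12_grid, function(p12) {
    lh <- c(0, base::log(p1) + ls1, base::log(p2) + ls2,
            base::log(p1) + base::log(p2) + ls1 + ls2 +
              base::log1p(-exp(ls12 - ls1 - ls2)),
            base::log(p12) + ls12)
    pp <- exp(lh - logsumexp(lh))
    data.frame(p12 = p12, PP.H0 = pp[1], PP.H1 = pp[2], PP.H2 = pp[3],
               PP.H3 = pp[4], PP.H4 = pp[5])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-level finemapping from TWAS z-scores
#'
#' Enumerates causal-gene configurations (all subsets up to
#' \code{max_causal} genes, plus the empty configuration, which acts as the
#' null model representing potentially untyped genes). For configuration c
#' the marginal likelihood is the multivariate normal density of the TWAS
#' z-vector with covariance \eqn{\Omega + n\sigma^2 \,
#' \Omega_{\cdot c} \Omega_{c \cdot}}, where \eqn{\Omega} is the predicted-
#' expression correlation among genes; the prior is Bernoulli,
#' \eqn{p^{|c|} (1-p)^{m-|c|}}. Per-gene posterior inclusion probabilities
#' (PIP) sum configuration posteriors containing the gene, and the credible
#' gene set accumulates genes (and possibly the null model) in descending
#' posterior order to mass \code{rho}.
#'
#' @param z TWAS z-scores (one per gene).
#' @param omega Gene-gene predicted-expression correlation matrix
#'   (symmetric, unit diagonal); stabilised with a 1e-6 ridge if needed.
#' @param p Bernoulli prior inclusion probability (default 1e-3).
#' @param nsigma2 Prior variance of the non-centrality (chi-square prior
#'   variance, default 40).
#' @param max_causal Maximum genes per configuration (default 3).
#' @param rho Credible-set mass (default 0.90).
#' @return Object of class \code{twas_finemap}: list with \code{pip}
#'   (named per-gene), \code{null_pp} (posterior of the empty
#'   configuration), \code{credible_set} (character vector, possibly
#'   containing \code{"NULL.MODEL"}), \code{rho}, and the configuration
#'   table \code{configs}.
#' @export
twas_finemap <- function(z, omega, p = 1e-3, nsigma2 = 40, max_causal = 3L,
                         rho = 0.90) {
  m <- length(z)
  if (!all(is.finite(z))) stop_param("TWAS z-scores must be finite")
  if (!isTRUE(all.equal(omega, t(omega))) ||
      any(abs(diag(omega) - 1) > 1e-8))
    stop_param("'omega' must be symmetric with unit diagonal")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) {
    omega <- omega + diag(1e-6, m)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop_param("'omega' is not positive semi-definite")
  } else if (min(ev) <= 0) omega <- omega + diag(1e-6, m)
  max_causal <- min(max_causal, m)

  ldmvnorm <- function(sigma) {
    ch <- chol(sigma)
    -0.5 * (m * base::log(2 * pi)) - sum(base::log(diag(ch))) -
      0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
  }
  configs <- list(integer(0))
  for (k in seq_len(max_causal))
    configs <- c(configs, utils::combn(m, k, simplify = FALSE))
  logpost <- vapply(configs, function(cfg) {
    k <- length(cfg)
    sigma <- omega
    if (k) sigma <- sigma + nsigma2 *
        omega[, cfg, drop = FALSE] %*% omega[cfg, , drop = FALSE]
    ldmvnorm(sigma) + k * base::log(p) + (m - k) * base::log1p(-p)
  }, numeric(1))
  post <- exp(logpost - logsumexp(logpost))

  gene_names <- if (!is.null(names(z))) names(z) else
    sprintf("gene%02d", seq_len(m))
  pip <- vapply(seq_len(m), function(g)
    sum(post[vapply(configs, function(cfg) g %in% cfg, logical(1))]),
    numeric(1))
  names(pip) <- gene_names
  null_pp <- post[1]

  # credible gene set: rank genes by PIP, include the null model as a
  # candidate at its posterior, accumulate to rho
  cand <- c(pip, NULL.MODEL = unname(null_pp))
  ord <- order(-cand)
  mass <- cand[ord] / sum(cand)
  k <- which(cumsum(mass) >= rho)[1]
  if (is.na(k)) k <- length(cand)
  cs <- names(cand)[ord[seq_len(k)]]

  cfg_tab <- data.frame(
    config = vapply(configs, function(cfg)
      if (!length(cfg)) "NULL" else paste(gene_names[cfg], collapse = "+"),
      character(1)),
    size = vapply(configs, length, integer(1)),
    posterior = post, stringsAsFactors = FALSE)
  structure(list(pip = pip, null_pp = unname(null_pp), credible_set = cs,
                 rho = rho, configs = cfg_tab,
                 p = p, nsigma2 = nsigma2),
            class = "twas_finemap")
}

#' @export
print.twas_finemap <- function(x, ...) {
  cat(sprintf("TWAS gene finemapping (p = %g, n*sigma2 = %g)\n", x$p,
              x$nsigma2))
  cat("  PIP:", paste(sprintf("%s=%.3f", names(x$pip), x$pip),
                      collapse = ", "), "\n")
  cat(sprintf("  null-model posterior: %.3f\n", x$null_pp))
  cat(sprintf("  %g%% credible set: %s\n", 100 * x$rho,
              paste(x$credible_set, collapse = ", ")))
  invisible(x)
}

#' Rank genes by satisfied prioritisation criteria
#'
#' Takes a gene-by-criterion logical table (criteria such as: closest gene
#' to the lead variant, membership of the ABF credible set, TWAS-finemap
#' prioritisation, top eQTL/pQTL gene, top variant-to-gene score, top CADD
#' variant, nonsynonymous variant, best regulatory rank - supplied as input
#' annotations) and ranks genes by the number of satisfied criteria,
#' descending. Ties share a rank and are reported, never broken
#' arbitrarily.
#'
#' @param criteria data.frame or matrix of logicals, rownames = gene ids.
#' @return data.frame: GENE, N_SATISFIED, RANK (min rank for ties),
#'   TIED (logical), ordered by rank.
#' @export
prioritise_genes <- function(criteria) {
  mat <- as.matrix(criteria)
  if (!is.logical(mat)) {
    if (all(mat %in% c(0, 1))) mat <- mat == 1
    else stop_param("criterion table must be boolean (TRUE/FALSE or 0/1)")
  }
  counts <- rowSums(mat)
  genes <- rownames(mat)
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(nrow(mat)))
  ord <- order(-counts)
  rk <- rank(-counts, ties.method = "min")
  out <- data.frame(GENE = genes[ord], N_SATISFIED = counts[ord],
                    RANK = rk[ord],
                    TIED = (table(counts)[as.character(counts)] > 1)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
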