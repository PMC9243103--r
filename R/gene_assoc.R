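#' Gene-boundary window presets
#'
#' The three SNP-to-gene annotation windows: \code{none} (gene body only),
#' \code{conservative} (5 kb upstream, 1.5 kb downstream) and
#' \code{liberal} (35 kb upstream, 10 kb downstream). Upstream means 5' of
#' the gene respecting strand.
#'
#' @param preset One of \code{"none"}, \code{"conservative"},
#'   \code{"liberal"}, or \code{"custom"}.
#' @param upstream_kb,downstream_kb Extents for \code{"custom"}.
#' @return List with \code{upstream_kb}, \code{downstream_kb},
#'   \code{preset}.
#' @export
gene_window <- function(preset = c("none", "conservative", "liberal",
                                   "custom"),
                        upstream_kb = 0, downstream_kb = 0) {
  preset <- match.arg(preset)
  ext <- switch(preset,
                none = c(0, 0),
                conservative = c(5, 1.5),
                liberal = c(35, 10),
                custom = c(upstream_kb, downstream_kb))
  if (any(ext < 0)) stop_param("window extents must be non-negative")
  list(upstream_kb = ext[1], downstream_kb = ext[2], preset = preset)
}

#' Annotate variants to genes under a boundary window
#'
#' Assigns each variant to every gene whose strand-aware extended interval
#' contains it: for a + strand gene the interval is
#' [start - upstream, end + downstream]; for a - strand gene
#' [start - downstream, end + upstream]. Coordinates are 1-based inclusive
#' and extensions are clipped at position 1.
#'
#' @param variants data.frame with columns SNP, CHR, BP.
#' @param genes data.frame with columns GENE, CHR, START, END, STRAND.
#' @param window A \code{\link{gene_window}} (or preset name).
#' @return Named list (one entry per gene with >= 1 variant) of variant-id
#'   character vectors.
#' @export
annotate_snps <- function(variants, genes, window = "none") {
  if (is.character(window)) window <- gene_window(window)
  if (!all(genes$STRAND %in% c("+", "-")))
    stop_param("unknown strand symbol (must be + or -)")
  up <- window$upstream_kb * 1000
  down <- window$downstream_kb * 1000
  lo <- ifelse(genes$STRAND == "+", genes$START - up, genes$START - down)
  hi <- ifelse(genes$STRAND == "+", genes$END + down, genes$END + up)
  lo <- pmax(lo, 1)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- variants$CHR == genes$CHR[i] &
      variants$BP >= lo[i] & variants$BP <= hi[i]
    variants$SNP[hit]
  })
  names(out) <- genes$GENE
  out[vapply(out, length, integer(1)) > 0L]
}

#' LD-aware gene-based association test
#'
#' Aggregates variant z-scores into the gene statistic \eqn{T = \sum_j
#' z_j^2} and evaluates it against its null distribution under the LD
#' matrix R by Brown/Satterthwaite moment matching: under the null T has
#' mean \eqn{m = n_{snps}} and variance \eqn{2 \sum_{ij} R_{ij}^2}, so
#' \eqn{T/c \sim \chi^2_f} with \eqn{c = Var/(2m)} and
#' \eqn{f = 2 m^2 / Var}.
#'
#' @param z Variant z-scores in the gene.
#' @param R LD (correlation) submatrix for those variants; symmetric, unit
#'   diagonal.
#' @return List of class \code{gene_test}: \code{stat}, \code{p}, \code{Z}
#'   (upper-tail probit of p), \code{n_snps}, \code{c}, \code{f}.
#' @export
gene_test <- function(z, R = NULL) {
  k <- length(z)
  if (k == 0L) return(NULL)
  if (is.null(R)) R <- diag(k)
  R <- as.matrix(R)
  if (nrow(R) != k || !isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8))
    stop_param("'R' must be a symmetric unit-diagonal matrix matching z")
  T_stat <- sum(z^2)
  mu <- k
  v2 <- 2 * sum(R^2)
  cc <- v2 / (2 * mu)
  f <- 2 * mu^2 / v2
  p <- stats::pchisq(T_stat / cc, df = f, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1)
  structure(list(stat = T_stat, p = p, Z = p_to_z(p), n_snps = k,
                 c = cc, f = f), class = "gene_test")
}

#' Gene-based association across all genes
#'
#' Runs \code{\link{gene_test}} for every gene in an annotation mapping,
#' pulling z-scores from a \code{meta_result} and LD from the panel.
#'
#' @param meta A \code{meta_result} (needs SNP and Z columns).
#' @param mapping Gene-to-variant mapping from \code{\link{annotate_snps}}.
#' @param panel A \code{reference_panel} for LD.
#' @param genes Optional gene model data.frame to attach gene length.
#' @return data.frame: GENE, N_SNPS, STAT, P, Z, LENGTH (bp, NA without
#'   \code{genes}).
#' @export
gene_assoc <- function(meta, mapping, panel, genes = NULL) {
  rows <- lapply(names(mapping), function(gid) {
    ids <- intersect(mapping[[gid]], meta$SNP)
    ids <- intersect(ids, colnames(panel$genotypes))
    if (!length(ids)) return(NULL)
    z <- meta$Z[match(ids, meta$SNP)]
    R <- stats::cov2cor(stats::cov(
      panel$genotypes[, ids, drop = FALSE]))
    R[!is.finite(R)] <- 0; diag(R) <- 1
    gt <- gene_test(z, R)
    data.frame(GENE = gid, N_SNPS = gt$n_snps, STAT = gt$stat, P = gt$p,
               Z = gt$Z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$LENGTH <- if (!is.null(genes))
    (genes$END - genes$START + 1L)[match(out$GENE, genes$GENE)]
  else NA_real_
  rownames(out) <- NULL
  out
}

#' Competitive gene-set association test
#'
#' Ordinary least squares of gene Z on set membership plus the nuisance
#' covariates log(number of SNPs) and log(gene length), one-sided p for a
#' positive membership coefficient (enrichment relative to all other
#' genes). Sets with fewer than \code{min_genes} member genes present in
#' the results are rejected.
#'
#' @param gene_results data.frame from \code{\link{gene_assoc}} (GENE, Z,
#'   N_SNPS, LENGTH).
#' @param set_genes Character vector of member gene ids.
#' @param covariates Optional numeric matrix of extra covariates (rows
#'   aligned to \code{gene_results}).
#' @param min_genes Minimum overlapping genes (default 5).
#' @return List of class \code{geneset_test}: \code{beta}, \code{se},
#'   \code{p} (one-sided), \code{n_set}, \code{n_genes}.
#' @export
geneset_test <- function(gene_results, set_genes, covariates = NULL,
                         min_genes = 5L) {
  member <- gene_results$GENE %in% set_genes
  if (sum(member) < min_genes)
    stop_param("gene set has %d overlapping genes (< %d required)",
               sum(member), min_genes)
  if (all(member))
    stop_param("degenerate design: every gene is in the set")
  X <- cbind(member = as.numeric(member),
             log_nsnps = base::log(gene_results$N_SNPS),
             log_len = if (all(is.finite(gene_results$LENGTH)))
               base::log(gene_results$LENGTH) else NULL)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  fit <- stats::lm(gene_results$Z ~ X)
  smf <- suppressWarnings(summary(fit))  # degenerate fits handled below
  sm <- smf$coefficients
  row <- grep("member", rownames(sm))
  beta <- sm[row, 1]; se <- sm[row, 2]
  tval <- sm[row, 3]
  # degenerate fit (e.g. all gene Z identical): no enrichment, not an error
  if ((!is.finite(tval) || smf$sigma < 1e-10) && abs(beta) < 1e-8) {
    beta <- 0; tval <- 0
  }
  p <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
  structure(list(beta = beta, se = se, p = p, n_set = sum(member),
                 n_genes = nrow(gene_results)),
            class = "geneset_test")
}

#' Cauchy combination (ACAT) of p-values
#'
#' \eqn{T = \sum_i w_i \tan\{(0.5 - p_i)\pi\}}, combined
#' \eqn{p = 0.5 - \arctan(T)/\pi}. Heavy Cauchy tails make the statistic
#' robust to dependence between the inputs, which is why it is used to
#' meta-analyse the same test run under different annotation windows.
#' Inputs are clipped to [1e-300, 1 - 1e-16].
#'
#' @param p Vector of p-values in (0, 1).
#' @param weights Non-negative weights (default equal); normalised to sum
#'   to 1.
#' @return Combined p-value.
#' @examples acat_combine(c(0.01, 0.5))   # ~ 0.0199
#' @export
acat_combine <- function(p, weights = NULL) {
  if (!length(p)) stop_param("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p >= 1 + 1e-15))
    stop_param("p-values must lie in (0, 1)")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  if (is.null(weights)) weights <- rep(1, length(p))
  if (any(weights < 0)) stop_param("weights must be non-negative")
  weights <- weights / sum(weights)
  T_stat <- sum(weights * tan((0.5 - p) * pi))
  0.5 - atan(T_stat) / pi
}

#' Multiple-testing adjustment with decisions
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment with reject flags at
#' level \code{alpha}.
#'
#' @param p Vector of p-values.
#' @param method \code{"bonferroni"} or \code{"bh_fdr"}.
#' @param alpha Decision level in (0, 1).
#' @return data.frame: p, q (adjusted), reject.
#' @export
multiple_testing <- function(p, method = c("bonferroni", "bh_fdr"),
                             alpha = 0.05) {
  method <- match.arg(method)
  check_prob(alpha, "alpha")
  q <- stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni"
                       else "BH")
  data.frame(p = p, q = q, reject = q < alpha)
}
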