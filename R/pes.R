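# Pharmagenic enrichment scores: druggable gene-set discovery across
# P-value inclusion thresholds, pathway-restricted clumping+thresholding
# scores, genome-wide-PRS-adjusted association, and ATC overrepresentation.

#' Scan druggable gene sets for enrichment across P thresholds and windows
#'
#' For every combination of druggable gene set, variant-inclusion P
#' threshold and annotation window, runs the LD-aware gene test on the
#' variants passing the threshold and a competitive gene-set test of the
#' resulting gene Z-scores, then applies Benjamini-Hochberg FDR jointly
#' across all tests. Survivors at \code{fdr_alpha} are the candidate sets
#' a pathway score can be built for; sets at least nominally significant
#' (p < 0.05) in both annotation windows are flagged \code{both_windows}.
#'
#' @param meta A \code{meta_result}.
#' @param panel A \code{reference_panel}.
#' @param genes Gene model data.frame (GENE CHR START END STRAND).
#' @param sets Named list of gene sets (from \code{\link{read_gmt}} or
#'   \code{\link{simulate_annotations}}).
#' @param druggable Logical vector (named by set) flagging druggable sets;
#'   only those are tested.
#' @param p_thresholds Variant-inclusion thresholds (default
#'   0.005, 0.05, 0.5, 1).
#' @param windows Character vector of window presets (default
#'   conservative + liberal).
#' @param fdr_alpha FDR level (default 0.05).
#' @param min_genes Minimum overlapping genes per set (default 5).
#' @return data.frame of class \code{pes_scan}: SET, WINDOW, P_T, BETA, P,
#'   Q, CANDIDATE, BOTH_WINDOWS.
#' @export
pes_enrichment_scan <- function(meta, panel, genes, sets, druggable,
                                p_thresholds = c(0.005, 0.05, 0.5, 1),
                                windows = c("conservative", "liberal"),
                                fdr_alpha = 0.05, min_genes = 5L) {
  drug_sets <- sets[names(sets) %in% names(druggable)[druggable]]
  if (!length(drug_sets)) stop_param("no druggable gene sets supplied")
  variants <- data.frame(SNP = meta$SNP, CHR = meta$CHR, BP = meta$BP,
                         stringsAsFactors = FALSE)
  rows <- list()
  for (w in windows) {
    mapping <- annotate_snps(variants, genes, w)
    for (pt in p_thresholds) {
      sub <- meta[is.finite(meta$P) & meta$P <= pt, , drop = FALSE]
      if (nrow(sub) < 10L) next
      map_pt <- lapply(mapping, intersect, sub$SNP)
      map_pt <- map_pt[vapply(map_pt, length, integer(1)) > 0L]
      gr <- gene_assoc(sub, map_pt, panel, genes)
      if (is.null(gr) || nrow(gr) < 2L * min_genes) next
      for (s in names(drug_sets)) {
        res <- tryCatch(geneset_test(gr, drug_sets[[s]],
                                     min_genes = min_genes),
                        error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          SET = s, WINDOW = w, P_T = pt, BETA = res$beta, P = res$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    stop_param("no testable (set, threshold, window) combinations")
  out <- do.call(rbind, rows)
  out$Q <- stats::p.adjust(out$P, method = "BH")
  out$CANDIDATE <- out$Q < fdr_alpha
  nominal <- stats::aggregate(P ~ SET + WINDOW, out, min)
  both <- vapply(out$SET, function(s) {
    ps <- nominal$P[nominal$SET == s]
    length(ps) >= 2L && sum(ps < 0.05) >= 2L
  }, logical(1))
  out$BOTH_WINDOWS <- both
  rownames(out) <- NULL
  structure(out, class = c("pes_scan", "data.frame"))
}

#' Clumping + thresholding weight table
#'
#' Greedy p-ascending clumping at the scoring r-squared (clump indices
#' absorb neighbours with r2 above \code{r2} within the panel), then
#' retention of index variants with p <= \code{p_t}. Weights are the meta
#' log-odds for the effect allele.
#'
#' @param meta A \code{meta_result}.
#' @param panel A \code{reference_panel}.
#' @param p_t Inclusion threshold.
#' @param r2 Clumping r-squared (default 0.1).
#' @param window_kb Clumping window (default 250 kb): only variants within
#'   this distance of an index can be absorbed.
#' @return data.frame: SNP, A1, A2, BETA, P.
#' @export
clump_and_threshold <- function(meta, panel, p_t, r2 = 0.1,
                                window_kb = 250) {
  keep <- meta$SNP %in% colnames(panel$genotypes) & is.finite(meta$P)
  df <- meta[keep, , drop = FALSE]
  df <- df[order(df$P, df$CHR, df$BP), , drop = FALSE]
  r2m <- panel_r2(panel, df$SNP)
  taken <- rep(FALSE, nrow(df))
  index <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (taken[i]) next
    index[i] <- TRUE
    near <- !taken & abs(df$BP - df$BP[i]) <= window_kb * 1000 &
      df$CHR == df$CHR[i] & r2m[i, ] > r2
    taken[near] <- TRUE
    taken[i] <- TRUE
  }
  out <- df[index & df$P <= p_t, c("SNP", "A1", "A2", "BETA", "P")]
  if (!nrow(out))
    stop_param("empty score: no clump index variants pass p <= %g", p_t)
  rownames(out) <- NULL
  out
}

#' Score individuals with a weight table
#'
#' Raw score = sum over weight-table variants of weight x effect-allele
#' dosage; dosages whose stated effect allele mismatches the table's are
#' flipped (2 - dosage), missing dosages are mean-imputed (or dropped with
#' \code{missing = "drop"}). Scores are standardised over the cohort
#' (mean 0, SD 1); an all-zero weight table yields all-zero scores with a
#' warning rather than a 0/0 standardisation.
#'
#' @param genotypes Dosage matrix (individuals x variants, columns named
#'   by variant id) or a \code{sim_cohort}.
#' @param weights Weight table from \code{\link{clump_and_threshold}}.
#' @param restrict_to Optional character vector of variant ids (e.g. the
#'   SNPs of one gene set): scoring is restricted to it.
#' @param dosage_a1 Character vector naming the allele the dosage counts,
#'   per weight-table variant (default: the table's A1, i.e. no flips).
#' @param missing \code{"mean"} (impute) or \code{"drop"}.
#' @return Numeric vector of standardised scores, with attribute
#'   \code{n_snps} (variants actually scored).
#' @export
score_individuals <- function(genotypes, weights, restrict_to = NULL,
                              dosage_a1 = NULL, missing = c("mean",
                                                            "drop")) {
  missing <- match.arg(missing)
  g <- if (inherits(genotypes, "sim_cohort") ||
           inherits(genotypes, "reference_panel")) genotypes$genotypes
  else genotypes
  w <- weights
  if (!is.null(restrict_to)) w <- w[w$SNP %in% restrict_to, , drop = FALSE]
  w <- w[w$SNP %in% colnames(g), , drop = FALSE]
  if (nrow(w) < 1L) stop_param("no scorable variants after restriction")
  d <- g[, w$SNP, drop = FALSE]
  storage.mode(d) <- "double"
  if (!is.null(dosage_a1)) {
    flip <- dosage_a1 != w$A1
    d[, flip] <- 2 - d[, flip]
  }
  if (anyNA(d)) {
    if (missing == "drop") {
      ok <- !apply(d, 2, anyNA)
      d <- d[, ok, drop = FALSE]
      w <- w[ok, , drop = FALSE]
      if (!nrow(w)) stop_param("no scorable variants after dropping missing")
    } else {
      for (j in seq_len(ncol(d))) {
        nas <- is.na(d[, j])
        if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
      }
    }
  }
  raw <- as.numeric(d %*% w$BETA)
  s <- stats::sd(raw)
  out <- if (s == 0) {
    warning("zero-variance score; returning unstandardised zeros")
    raw * 0
  } else (raw - mean(raw)) / s
  attr(out, "n_snps") <- nrow(w)
  out
}

#' Association of a pathway score with a binary phenotype
#'
#' Logistic regression of phenotype on the (standardised) PES plus
#' covariates; with \code{adjust_prs} the genome-wide PRS at the matching
#' threshold enters both the null and the full model, so the reported
#' deviance test isolates the pathway signal above the genome-wide score.
#' The chi-square(1) test of residual deviance compares the model with and
#' without the PES term.
#'
#' @param phenotype 0/1 vector.
#' @param pes Standardised pathway score.
#' @param prs Standardised genome-wide PRS (required when
#'   \code{adjust_prs}).
#' @param covariates Optional data.frame/matrix of covariates.
#' @param adjust_prs Include the PRS covariate (default TRUE).
#' @return List of class \code{pes_assoc}: \code{or_per_sd}, \code{ci}
#'   (95\%), \code{p_wald}, \code{p_deviance}, \code{beta}, \code{se},
#'   \code{n}.
#' @export
pes_association <- function(phenotype, pes, prs = NULL, covariates = NULL,
                            adjust_prs = TRUE) {
  if (!all(phenotype %in% c(0, 1)))
    stop_param("phenotype must be binary 0/1")
  if (adjust_prs && is.null(prs))
    stop_param("'prs' required when adjust_prs = TRUE")
  df <- data.frame(y = phenotype, pes = pes)
  base_terms <- character(0)
  if (adjust_prs) { df$prs <- prs; base_terms <- "prs" }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    base_terms <- c(base_terms, colnames(covariates))
  }
  rhs0 <- if (length(base_terms)) paste(base_terms, collapse = " + ")
  else "1"
  f0 <- stats::as.formula(paste("y ~", rhs0))
  f1 <- stats::as.formula(paste("y ~ pes +", rhs0))
  m0 <- stats::glm(f0, family = stats::binomial(), data = df)
  m1 <- stats::glm(f1, family = stats::binomial(), data = df)
  cf <- summary(m1)$coefficients
  if (!"pes" %in% rownames(cf))
    stop_param("PES term dropped from the model (collinear input)")
  beta <- cf["pes", 1]; se <- cf["pes", 2]
  if (abs(beta) > 15)
    stop_param(paste0("apparent separation in the logistic model; consider",
                      " penalised regression (not applied silently)"))
  dev_diff <- max(m0$deviance - m1$deviance, 0)
  structure(list(or_per_sd = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_wald = z_to_p(beta / se),
                 p_deviance = stats::pchisq(dev_diff, df = 1,
                                            lower.tail = FALSE),
                 beta = beta, se = se, n = length(phenotype),
                 adjusted_for_prs = adjust_prs),
            class = "pes_assoc")
}

#' @export
print.pes_assoc <- function(x, ...) {
  cat(sprintf("PES association%s: OR per SD = %.3f [%.3f, %.3f]\n",
              if (x$adjusted_for_prs) " (PRS-adjusted)" else "",
              x$or_per_sd, x$ci[1], x$ci[2]))
  cat(sprintf("  Wald p = %.3g; residual-deviance chi2(1) p = %.3g; n = %d\n",
              x$p_wald, x$p_deviance, x$n))
  invisible(x)
}

#' Correlation between a pathway score and the genome-wide PRS
#'
#' @param pes,prs Score vectors at the same inclusion threshold.
#' @return List: r (Pearson), p (two-sided).
#' @export
pes_prs_correlation <- function(pes, prs) {
  if (stats::sd(pes) == 0 || stats::sd(prs) == 0)
    stop_param("zero-variance score; correlation undefined")
  ct <- stats::cor.test(pes, prs)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' ATC-class overrepresentation among candidate set genes
#'
#' For each ATC code with at least one target gene, Fisher's exact test of
#' the 2x2 table (gene in candidate set x gene targeted by drugs of that
#' code) against the background gene universe, with Bonferroni adjustment
#' across the codes tested.
#'
#' @param set_genes Character vector: genes of the candidate set.
#' @param universe Character vector: all genes considered.
#' @param atc data.frame DRUG, ATC_CODE, GENE.
#' @param alpha Level for the Bonferroni decision (default 0.05).
#' @return data.frame: ATC_CODE, N_SET_TARGETS, N_BG_TARGETS, OR, P,
#'   P_BONF, REJECT. Codes with zero targets in the universe are skipped.
#' @export
atc_overrepresentation <- function(set_genes, universe, atc,
                                   alpha = 0.05) {
  set_genes <- intersect(set_genes, universe)
  codes <- unique(atc$ATC_CODE)
  rows <- list()
  for (code in codes) {
    targets <- intersect(unique(atc$GENE[atc$ATC_CODE == code]), universe)
    if (!length(targets)) next
    a <- length(intersect(set_genes, targets))
    b <- length(setdiff(set_genes, targets))
    c_ <- length(setdiff(targets, set_genes))
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                             alternative = "greater")
    rows[[length(rows) + 1L]] <- data.frame(
      ATC_CODE = code, N_SET_TARGETS = a, N_BG_TARGETS = c_,
      OR = unname(ft$estimate), P = ft$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ATC_CODE = character(), N_SET_TARGETS = integer(),
                      N_BG_TARGETS = integer(), OR = numeric(),
                      P = numeric(), P_BONF = numeric(),
                      REJECT = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$P_BONF <- pmin(out$P * nrow(out), 1)
  out$REJECT <- out$P_BONF < alpha
  rownames(out) <- NULL
  out
}
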