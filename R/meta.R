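#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Per-variant IVW meta-analysis of a harmonised cohort pair (or any matrix
#' of aligned betas/ses), with Cochran's Q heterogeneity test. The pooled
#' estimate is \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i} with
#' \eqn{w_i = 1/se_i^2}, \eqn{se = (\sum w_i)^{-1/2}},
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta)^2} on k-1 df.
#'
#' @param x A \code{harmonised_pair} (its \code{common} stratum is used
#'   unless \code{stratum = "rare"}), or a data.frame with columns
#'   \code{SNP, CHR, BP, BETA_a, SE_a, BETA_b, SE_b} (more cohorts via
#'   further suffixes are not supported; use the matrix interface).
#' @param stratum \code{"common"} or \code{"rare"} when \code{x} is a
#'   \code{harmonised_pair}.
#' @return data.frame of class \code{meta_result}: SNP, CHR, BP, A1, A2,
#'   FRQ (cohort-A eaf), BETA, SE, Z, P, Q, Q_DF, P_HET, N_EFF. Variants
#'   with any non-positive se are skipped (attribute \code{n_skipped}).
#' @export
ivw_meta <- function(x, stratum = c("common", "rare")) {
  stratum <- match.arg(stratum)
  df <- if (inherits(x, "harmonised_pair")) x[[stratum]] else x
  need <- c("SNP", "BETA_a", "SE_a", "BETA_b", "SE_b")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop_param("ivw_meta input missing column(s): %s",
               paste(miss, collapse = ", "))
  ok <- is.finite(df$SE_a) & df$SE_a > 0 & is.finite(df$SE_b) & df$SE_b > 0
  skipped <- sum(!ok)
  df <- df[ok, , drop = FALSE]

  wa <- 1 / df$SE_a^2; wb <- 1 / df$SE_b^2
  beta <- (wa * df$BETA_a + wb * df$BETA_b) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  z <- beta / se
  Q <- wa * (df$BETA_a - beta)^2 + wb * (df$BETA_b - beta)^2
  p_het <- stats::pchisq(Q, df = 1, lower.tail = FALSE)

  n_eff <- if (all(c("N_CASES_a", "N_CONTROLS_a", "N_CASES_b",
                     "N_CONTROLS_b") %in% colnames(df)))
    effective_n(df$N_CASES_a, df$N_CONTROLS_a, rounded = FALSE) +
      effective_n(df$N_CASES_b, df$N_CONTROLS_b, rounded = FALSE)
  else NA_real_

  out <- data.frame(SNP = df$SNP,
                    CHR = if ("CHR" %in% colnames(df)) df$CHR else NA,
                    BP = if ("BP" %in% colnames(df)) df$BP else NA,
                    A1 = if ("A1" %in% colnames(df)) df$A1 else NA,
                    A2 = if ("A2" %in% colnames(df)) df$A2 else NA,
                    FRQ = if ("FRQ_a" %in% colnames(df)) df$FRQ_a else NA,
                    BETA = beta, SE = se, Z = z, P = z_to_p(z),
                    Q = Q, Q_DF = 1L, P_HET = p_het, N_EFF = n_eff,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Effective sample size of a case-control GWAS
#'
#' \eqn{N_{eff} = 4 / (1/n_{cases} + 1/n_{controls})}: the size of a
#' balanced study with the same power. Reported rounded to the nearest
#' integer by default; the unrounded value is used internally.
#'
#' @param n_cases,n_controls Positive counts (vectorised).
#' @param rounded Round to nearest integer (default TRUE).
#' @return Numeric vector of effective sample sizes.
#' @examples
#' effective_n(74323, 316721)   # 240788
#' @export
effective_n <- function(n_cases, n_controls, rounded = TRUE) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop_param("case and control counts must be positive")
  n <- 4 / (1 / n_cases + 1 / n_controls)
  if (rounded) round(n) else n
}

#' Correct association p-values for the LD score regression intercept
#'
#' Conservatively deflates every chi-square statistic by the LDSC
#' intercept: \eqn{\chi^2_{corr} = z^2 / intercept}, p from the upper
#' chi-square(1) tail. Monotone in the input p, so variant ranking is
#' unchanged. Intercepts below 1 are clamped to 1 with a warning.
#'
#' @param z Vector of z-scores (or provide \code{p} instead).
#' @param intercept LDSC intercept (>= 1 in practice).
#' @param p Optional p-values used when \code{z} is missing.
#' @return Corrected two-sided p-values.
#' @export
intercept_correct <- function(z = NULL, intercept, p = NULL) {
  if (length(intercept) != 1L || !is.finite(intercept))
    stop_param("'intercept' must be a single finite value")
  if (intercept < 1) {
    warning("LDSC intercept below 1 clamped to 1")
    intercept <- 1
  }
  if (is.null(z)) {
    if (is.null(p)) stop_param("provide 'z' or 'p'")
    z <- stats::qnorm(p / 2, lower.tail = FALSE)
  }
  stats::pchisq(z^2 / intercept, df = 1, lower.tail = FALSE)
}

#' Define genomic risk loci from meta-analysis results
#'
#' FUMA-style locus definition: significant variants are greedily clumped
#' by ascending p at \code{r2_independent} to find independent significant
#' variants; those are clumped again at \code{r2_lead} to find lead
#' variants; the LD blocks of leads lying within \code{merge_kb} of each
#' other are merged into a single locus. r-squared is the squared Pearson
#' correlation of panel dosages. Ties in p break by (chrom, pos).
#'
#' @param meta A \code{meta_result}.
#' @param panel A \code{reference_panel} covering the significant variants;
#'   significant variants absent from the panel are excluded with a
#'   message.
#' @param p_threshold Significance threshold (default genome-wide 5e-8;
#'   1e-5 is the conventional suggestive threshold).
#' @param r2_independent Clumping r2 for independent significant variants
#'   (default 0.6).
#' @param r2_lead Clumping r2 for lead variants (default 0.1).
#' @param merge_kb Merge LD blocks within this many kb (default 250).
#' @return data.frame of class \code{locus_table}: LOCUS, CHR, START, END,
#'   LEAD_SNP, LEAD_P, N_IND_SIG, N_SNPS, SNPS (semicolon-joined members).
#' @export
define_loci <- function(meta, panel, p_threshold = 5e-8,
                        r2_independent = 0.6, r2_lead = 0.1,
                        merge_kb = 250) {
  stopifnot(inherits(panel, "reference_panel"))
  sig <- meta[is.finite(meta$P) & meta$P < p_threshold, , drop = FALSE]
  empty <- data.frame(LOCUS = integer(), CHR = integer(), START = integer(),
                      END = integer(), LEAD_SNP = character(),
                      LEAD_P = numeric(), N_IND_SIG = integer(),
                      N_SNPS = integer(), SNPS = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(structure(empty, class = c("locus_table",
                                                    "data.frame")))
  absent <- !(sig$SNP %in% colnames(panel$genotypes))
  if (any(absent)) {
    message(sum(absent), " significant variant(s) absent from panel, excluded")
    sig <- sig[!absent, , drop = FALSE]
    if (!nrow(sig)) return(structure(empty, class = c("locus_table",
                                                      "data.frame")))
  }
  sig <- sig[order(sig$P, sig$CHR, sig$BP), , drop = FALSE]
  r2 <- panel_r2(panel, sig$SNP)

  clump <- function(ids, threshold) {
    # returns index assignment: for each id, the id of its clump index
    assign <- stats::setNames(rep(NA_character_, length(ids)), ids)
    for (id in ids) {             # ids already in ascending-p order
      if (!is.na(assign[id])) next
      assign[id] <- id
      members <- ids[is.na(assign) & r2[id, ids] > threshold]
      assign[members] <- id
    }
    assign
  }
  ind_assign <- clump(sig$SNP, r2_independent)   # variant -> independent sig
  ind_ids <- unique(ind_assign)                  # ascending p among indices
  lead_assign <- clump(ind_ids, r2_lead)         # independent sig -> lead
  lead_ids <- unique(lead_assign)

  # one preliminary block per lead; span = positions of all member variants
  blocks <- lapply(lead_ids, function(lead) {
    inds <- ind_ids[lead_assign[ind_ids] == lead]
    members <- sig$SNP[ind_assign[sig$SNP] %in% inds]
    pos <- sig$BP[match(members, sig$SNP)]
    list(lead = lead, inds = inds, members = members,
         chrom = sig$CHR[match(lead, sig$SNP)],
         start = min(pos), end = max(pos))
  })
  # merge blocks within merge_kb on the same chromosome
  ord <- order(vapply(blocks, `[[`, numeric(1), "chrom"),
               vapply(blocks, `[[`, numeric(1), "start"))
  blocks <- blocks[ord]
  merged <- list()
  for (b in blocks) {
    if (length(merged)) {
      last <- merged[[length(merged)]]
      if (b$chrom == last$chrom &&
          b$start - last$end <= merge_kb * 1000) {
        last$end <- max(last$end, b$end)
        last$start <- min(last$start, b$start)
        last$members <- c(last$members, b$members)
        last$inds <- c(last$inds, b$inds)
        lp <- sig$P[match(c(last$lead, b$lead), sig$SNP)]
        last$lead <- c(last$lead, b$lead)[which.min(lp)]
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- b
  }
  out <- do.call(rbind, lapply(seq_along(merged), function(i) {
    b <- merged[[i]]
    data.frame(LOCUS = i, CHR = b$chrom, START = b$start, END = b$end,
               LEAD_SNP = b$lead,
               LEAD_P = sig$P[match(b$lead, sig$SNP)],
               N_IND_SIG = length(b$inds), N_SNPS = length(b$members),
               SNPS = paste(sort(b$members), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("locus_table", "data.frame"))
}
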