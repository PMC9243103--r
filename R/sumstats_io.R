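#' Read and validate GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file (gzip-transparent) into the
#' canonical per-variant representation used by every downstream module.
#' Rows violating basic invariants (non-positive SE, non-numeric beta,
#' frequency outside (0,1), p outside (0,1]) are rejected and counted, not
#' silently kept. Alleles are upper-cased and restricted to A/C/G/T strings.
#' When P is absent it is recomputed from beta/se; when both are present and
#' disagree by more than 10\% in -log10 units the row is flagged in the
#' \code{p_discrepant} column (kept, not corrected).
#'
#' @param path File path (".gz" accepted).
#' @param column_map Named character vector mapping canonical names
#'   (\code{SNP, CHR, BP, A1, A2, FRQ, BETA, SE, P, N_CASES, N_CONTROLS,
#'   INFO}) to the file's column names; identity by default.
#' @return data.frame of validated records in file order, with attributes
#'   \code{n_rejected} and \code{rejection_reasons}.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  canonical <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P",
                 "N_CASES", "N_CONTROLS", "INFO")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% colnames(df))
        stop_param("mapped column '%s' (for %s) not present in %s",
                   column_map[[nm]], nm, path)
      colnames(df)[colnames(df) == column_map[[nm]]] <- nm
    }
  }
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE")
  miss <- setdiff(mandatory, colnames(df))
  if (length(miss))
    stop_param("summary statistics missing mandatory column(s): %s",
               paste(miss, collapse = ", "))
  for (opt in setdiff(canonical, colnames(df))) df[[opt]] <- NA
  df <- df[canonical]

  df$A1 <- toupper(as.character(df$A1))
  df$A2 <- toupper(as.character(df$A2))
  for (numcol in c("BP", "FRQ", "BETA", "SE", "P", "INFO"))
    df[[numcol]] <- suppressWarnings(as.numeric(df[[numcol]]))

  reasons <- character(0)
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    new <- cond & !bad
    if (any(new)) reasons <<- c(reasons, rep(why, sum(new)))
    bad <<- bad | cond
  }
  flag(!is.finite(df$BETA), "non-numeric beta")
  flag(!is.finite(df$SE) | df$SE <= 0, "se not positive")
  flag(!is.finite(df$FRQ) | df$FRQ <= 0 | df$FRQ >= 1, "frequency outside (0,1)")
  flag(!is.finite(df$BP) | df$BP < 1, "position < 1")
  flag(!grepl("^[ACGT]+$", df$A1) | !grepl("^[ACGT]+$", df$A2) |
         df$A1 == df$A2, "invalid allele pair")
  flag(is.finite(df$P) & (df$P <= 0 | df$P > 1), "p outside (0,1]")

  out <- df[!bad, , drop = FALSE]
  # p: recompute when absent, flag when discrepant
  p_from_z <- z_to_p(out$BETA / out$SE)
  absent <- !is.finite(out$P)
  out$P[absent] <- p_from_z[absent]
  out$p_discrepant <- !absent &
    abs(log10(out$P) - log10(p_from_z)) >
      0.1 * pmax(abs(log10(p_from_z)), 1e-10)
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejection_reasons") <- table(reasons)
  out
}

#' Harmonise two cohorts' summary statistics
#'
#' Restricts to variants present in both cohorts, aligns cohort B's effect
#' allele to cohort A's (flipping beta sign and replacing eaf by 1-eaf when
#' B reports the alleles swapped; attempting strand complement before giving
#' up), drops strand-ambiguous palindromic variants (A/T, C/G) when
#' \code{drop_ambiguous}, applies the imputation-quality filter
#' (INFO >= \code{info_min} in both cohorts, default 0.6), and partitions
#' the result into a common stratum (effect-allele frequency in
#' [maf_min, 1 - maf_min] in both cohorts, default 1\%) and a rare stratum.
#'
#' @param cohort_a,cohort_b data.frames from \code{\link{read_sumstats}}.
#' @param drop_ambiguous Drop A/T and C/G variants (default TRUE).
#' @param info_min Minimum imputation INFO in both cohorts; variants with
#'   missing INFO are treated as genotyped (kept).
#' @param maf_min Frequency bound of the common stratum.
#' @return List of class \code{harmonised_pair}: \code{common} and
#'   \code{rare} data.frames (columns \code{SNP CHR BP A1 A2} plus
#'   \code{_a}/\code{_b}-suffixed FRQ BETA SE P N_CASES N_CONTROLS INFO)
#'   and \code{dropped} (data.frame SNP, reason).
#' @export
harmonise_pair <- function(cohort_a, cohort_b, drop_ambiguous = TRUE,
                           info_min = 0.6, maf_min = 0.01) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  complement <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(rev(comp[ch]), collapse = ""), character(1))

  shared <- intersect(cohort_a$SNP, cohort_b$SNP)
  a <- cohort_a[match(shared, cohort_a$SNP), , drop = FALSE]
  b <- cohort_b[match(shared, cohort_b$SNP), , drop = FALSE]
  dropped <- list()
  drop <- function(mask, why) {
    if (any(mask)) dropped[[length(dropped) + 1L]] <<-
        data.frame(SNP = a$SNP[mask], reason = why,
                   stringsAsFactors = FALSE)
    a <<- a[!mask, , drop = FALSE]
    b <<- b[!mask, , drop = FALSE]
  }

  is_palindromic <- a$A1 == complement(a$A2)
  if (drop_ambiguous) drop(is_palindromic, "strand-ambiguous")

  same <- b$A1 == a$A1 & b$A2 == a$A2
  swapped <- b$A1 == a$A2 & b$A2 == a$A1
  strand <- b$A1 == complement(a$A1) & b$A2 == complement(a$A2)
  strand_swapped <- b$A1 == complement(a$A2) & b$A2 == complement(a$A1)
  irreconcilable <- !(same | swapped | strand | strand_swapped)
  drop(irreconcilable, "irreconcilable alleles")
  same <- same[!irreconcilable]; swapped <- swapped[!irreconcilable]
  strand <- strand[!irreconcilable]
  strand_swapped <- strand_swapped[!irreconcilable]

  flip <- (swapped | strand_swapped) & !same & !strand
  b$BETA[flip] <- -b$BETA[flip]
  b$FRQ[flip] <- 1 - b$FRQ[flip]

  low_info <- (!is.na(a$INFO) & a$INFO < info_min) |
    (!is.na(b$INFO) & b$INFO < info_min)
  drop(low_info, sprintf("INFO below %.2g", info_min))

  merged <- data.frame(SNP = a$SNP, CHR = a$CHR, BP = a$BP,
                       A1 = a$A1, A2 = a$A2,
                       FRQ_a = a$FRQ, BETA_a = a$BETA, SE_a = a$SE,
                       P_a = a$P, N_CASES_a = a$N_CASES,
                       N_CONTROLS_a = a$N_CONTROLS, INFO_a = a$INFO,
                       FRQ_b = b$FRQ, BETA_b = b$BETA, SE_b = b$SE,
                       P_b = b$P, N_CASES_b = b$N_CASES,
                       N_CONTROLS_b = b$N_CONTROLS, INFO_b = b$INFO,
                       stringsAsFactors = FALSE)
  common <- merged$FRQ_a >= maf_min & merged$FRQ_a <= 1 - maf_min &
    merged$FRQ_b >= maf_min & merged$FRQ_b <= 1 - maf_min
  structure(list(common = merged[common, , drop = FALSE],
                 rare = merged[!common, , drop = FALSE],
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                   else data.frame(SNP = character(), reason = character(),
                                   stringsAsFactors = FALSE)),
            class = "harmonised_pair")
}

#' @export
print.harmonised_pair <- function(x, ...) {
  cat(sprintf("Harmonised cohort pair: %d common + %d rare variants (%d dropped)\n",
              nrow(x$common), nrow(x$rare), nrow(x$dropped)))
  invisible(x)
}
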