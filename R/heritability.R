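#' LD scores from a reference panel
#'
#' The LD score of variant j is \eqn{\ell_j = \sum_k r^2_{jk}} over all
#' variants within \code{window_kb} of j (including itself), with the
#' small-sample bias correction
#' \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n - 2)} applied to the off-diagonal
#' terms (the self term contributes exactly 1).
#'
#' @param panel A \code{reference_panel}, variants sorted by position.
#' @param window_kb Window half-width in kb (default 1000).
#' @return Numeric vector of LD scores, one per panel variant.
#' @export
ld_scores <- function(panel, window_kb = 1000) {
  stopifnot(inherits(panel, "reference_panel"))
  if (window_kb <= 0) stop_param("'window_kb' must be positive")
  v <- panel$variants
  if (is.unsorted(v$pos)) stop_param("panel must be sorted by position")
  g <- panel$genotypes
  n <- nrow(g)
  m <- ncol(g)
  win <- window_kb * 1000
  ell <- numeric(m)
  # process in position chunks; with block LD only nearby columns matter
  for (b in unique(v$block)) {
    idx <- which(v$block == b)
    near <- which(v$pos >= v$pos[idx[1]] - win &
                    v$pos <= v$pos[idx[length(idx)]] + win)
    r2 <- suppressWarnings(stats::cor(g[, idx, drop = FALSE],
                                      g[, near, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    inwin <- abs(outer(v$pos[idx], v$pos[near], "-")) <= win
    self <- outer(idx, near, "==")
    adj <- r2 - (1 - r2) / (n - 2)
    adj[self] <- 1
    adj[!inwin] <- 0
    ell[idx] <- rowSums(adj)
  }
  ell
}

#' SNP heritability by LD score regression
#'
#' Fits \eqn{E[\chi^2_j] = 1 + N a + (N h^2 / M) \ell_j} by two-step
#' weighted least squares: initial weights \eqn{1/\max(\ell_j, 1)}, one
#' reweighting by the fitted heteroscedastic variance
#' \eqn{2 \, \hat E[\chi^2_j]^2 / \max(\ell_j, 1)}. Standard errors of the
#' slope-implied heritability and the intercept come from a delete-one
#' block jackknife over \code{n_blocks} contiguous blocks of variants.
#'
#' @param z Vector of association z-scores (chi-square = z^2), or pass a
#'   \code{meta_result} whose \code{Z} column is used.
#' @param ell LD scores aligned to \code{z}.
#' @param n GWAS sample size (effective N for case-control on the
#'   observed scale of a balanced design).
#' @param M Number of variants the heritability is spread over (default
#'   \code{length(z)}, the regression variants).
#' @param n_blocks Jackknife blocks (default 200; reduced with a warning
#'   when there are fewer variants than blocks).
#' @return Object of class \code{ldsc_fit}: list with \code{h2_observed},
#'   \code{h2_se}, \code{intercept}, \code{intercept_se}, \code{mean_chi2},
#'   \code{ratio}, \code{M}, \code{n_variants}.
#' @export
ldsc_h2 <- function(z, ell, n, M = NULL, n_blocks = 200L) {
  if (inherits(z, "meta_result")) z <- z$Z
  if (length(z) != length(ell))
    stop_param("'z' and 'ell' must be aligned")
  ok <- is.finite(z) & is.finite(ell)
  z <- z[ok]; ell <- ell[ok]
  if (length(z) < 200L)
    stop_param("LD score regression needs >= 200 variants (got %d)",
               length(z))
  if (is.null(M)) M <- length(z)
  if (length(z) < n_blocks) {
    warning("fewer variants than jackknife blocks; reducing block count")
    n_blocks <- max(2L, length(z) %/% 10L)
  }
  chi2 <- z^2
  fit_once <- function(keep) {
    x <- ell[keep]; y <- chi2[keep]
    w <- 1 / pmax(x, 1)
    f1 <- stats::lm.wfit(cbind(1, x), y, w)
    pred <- pmax(cbind(1, x) %*% f1$coefficients, 0.1)
    w2 <- 1 / (2 * pred^2 / pmax(x, 1))
    f2 <- stats::lm.wfit(cbind(1, x), y, as.numeric(w2))
    cf <- f2$coefficients
    c(intercept = cf[1], h2 = cf[2] * M / n)
  }
  all_idx <- seq_along(z)
  full <- fit_once(all_idx)
  # delete-one-block jackknife
  bounds <- floor(seq(0, length(z), length.out = n_blocks + 1L))
  pseudo <- matrix(NA_real_, n_blocks, 2L)
  for (b in seq_len(n_blocks)) {
    out_idx <- (bounds[b] + 1L):bounds[b + 1L]
    est <- fit_once(all_idx[-out_idx])
    pseudo[b, ] <- n_blocks * full - (n_blocks - 1L) * est
  }
  ses <- sqrt(apply(pseudo, 2, stats::var) / n_blocks)
  mean_chi2 <- mean(chi2)
  ratio <- if (mean_chi2 > 1) (full[1] - 1) / (mean_chi2 - 1) else NA_real_
  structure(list(h2_observed = unname(full[2]), h2_se = ses[2],
                 intercept = unname(full[1]), intercept_se = ses[1],
                 mean_chi2 = mean_chi2, ratio = ratio, M = M,
                 n_variants = length(z), n = n, n_blocks = n_blocks),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD score regression\n")
  cat(sprintf("  h2 (observed scale): %.4f (SE %.4f)\n", x$h2_observed,
              x$h2_se))
  cat(sprintf("  intercept: %.4f (SE %.4f); mean chi2 = %.4f", x$intercept,
              x$intercept_se, x$mean_chi2))
  if (is.finite(x$ratio)) cat(sprintf("; ratio = %.3f", x$ratio))
  cat(sprintf("\n  %d variants, M = %d, N = %.0f, %d jackknife blocks\n",
              x$n_variants, x$M, x$n, x$n_blocks))
  invisible(x)
}

#' Observed-to-liability scale conversion of SNP heritability
#'
#' \eqn{h^2_{lia} = h^2_{obs} \cdot K^2 (1-K)^2 / (P (1-P) z^2)} where K is
#' the population prevalence, P the sample case proportion, and z the
#' standard-normal density at the liability threshold
#' \eqn{\Phi^{-1}(1 - K)}. \code{inverse = TRUE} maps a liability-scale
#' estimate back to the observed scale.
#'
#' @param h2 Heritability estimate to convert.
#' @param P_sample Sample case proportion in (0,1) (0.5 for an
#'   effective-sample-size analysis).
#' @param K_population Population prevalence in (0,1).
#' @param inverse Apply the inverse transform.
#' @return Converted heritability.
#' @examples
#' liability_transform(0.02, P_sample = 0.5, K_population = 0.13)
#' @export
liability_transform <- function(h2, P_sample, K_population,
                                inverse = FALSE) {
  check_prob(P_sample, "P_sample")
  check_prob(K_population, "K_population")
  zK <- stats::dnorm(stats::qnorm(1 - K_population))
  mult <- K_population^2 * (1 - K_population)^2 /
    (P_sample * (1 - P_sample) * zK^2)
  if (inverse) h2 / mult else h2 * mult
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the z-score product of two traits on LD scores: the slope
#' equals \eqn{\rho_g \sqrt{N_1 N_2} / M}, so the genetic covariance is
#' \code{slope * M / sqrt(n1*n2)} and
#' \eqn{r_g = cov_g / \sqrt{h^2_1 h^2_2}} with the heritabilities fitted on
#' the same variants. The SE comes from a delete-one-block jackknife of the
#' whole ratio. Estimates are clipped to [-1.25, 1.25] with a warning when
#' outside [-1, 1].
#'
#' @param z1,z2 Aligned z-score vectors of the two traits.
#' @param ell LD scores aligned to the variants.
#' @param n1,n2 Sample sizes of the two traits.
#' @param M Heritability variant count (default \code{length(z1)}).
#' @param n_blocks Jackknife blocks (default 200).
#' @return Object of class \code{ldsc_rg}: list with \code{rg},
#'   \code{rg_se}, \code{gencov}, \code{h2_1}, \code{h2_2} (each an
#'   \code{ldsc_fit}).
#' @export
ldsc_rg <- function(z1, z2, ell, n1, n2, M = NULL, n_blocks = 200L) {
  if (length(z1) != length(z2) || length(z1) != length(ell))
    stop_param("'z1', 'z2' and 'ell' must be aligned")
  if (length(z1) < 200L)
    stop_param("genetic correlation needs >= 200 shared variants")
  if (is.null(M)) M <- length(z1)
  if (length(z1) < n_blocks) n_blocks <- max(2L, length(z1) %/% 10L)

  h2_1 <- ldsc_h2(z1, ell, n1, M = M, n_blocks = n_blocks)
  h2_2 <- ldsc_h2(z2, ell, n2, M = M, n_blocks = n_blocks)
  if (h2_1$h2_observed <= 0 || h2_2$h2_observed <= 0)
    stop_param("rg undefined: non-positive heritability estimate (%.4g, %.4g)",
               h2_1$h2_observed, h2_2$h2_observed)

  rg_once <- function(keep) {
    x <- ell[keep]
    w <- 1 / pmax(x, 1)
    co <- stats::lm.wfit(cbind(1, x), (z1 * z2)[keep], w)$coefficients[2] *
      M / sqrt(n1 * n2)
    wls_h2 <- function(zz, nn) {
      cf <- stats::lm.wfit(cbind(1, x), zz[keep]^2, w)$coefficients
      cf[2] * M / nn
    }
    co / sqrt(max(wls_h2(z1, n1), 1e-12) * max(wls_h2(z2, n2), 1e-12))
  }
  all_idx <- seq_along(z1)
  full <- rg_once(all_idx)
  bounds <- floor(seq(0, length(z1), length.out = n_blocks + 1L))
  pseudo <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    est <- rg_once(all_idx[-((bounds[b] + 1L):bounds[b + 1L])])
    pseudo[b] <- n_blocks * full - (n_blocks - 1L) * est
  }
  rg_se <- sqrt(stats::var(pseudo) / n_blocks)
  rg <- full
  if (abs(rg) > 1) warning(sprintf("rg estimate %.3f outside [-1, 1]", rg))
  rg <- max(min(rg, 1.25), -1.25)
  gencov <- rg * sqrt(h2_1$h2_observed * h2_2$h2_observed)
  structure(list(rg = rg, rg_se = rg_se, gencov = gencov,
                 h2_1 = h2_1, h2_2 = h2_2, n_blocks = n_blocks),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("Genetic correlation: rg = %.3f (SE %.3f)\n", x$rg, x$rg_se))
  cat(sprintf("  h2 trait 1 = %.4f, h2 trait 2 = %.4f, gencov = %.4g\n",
              x$h2_1$h2_observed, x$h2_2$h2_observed, x$gencov))
  invisible(x)
}
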