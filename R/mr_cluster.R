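#' Mixture-model clustering of instrument-level causal estimates
#'
#' Fits, by EM, a mixture over the per-instrument Wald ratio estimates
#' \eqn{r_i} (with known sampling variances \eqn{se_i^2}) consisting of:
#' a null component fixed at mean 0, K substantive normal components with
#' free means, and a uniform "junk" component over the observed ratio
#' range for instruments not parsimoniously assigned to any cluster. K is
#' chosen by BIC over 1..\code{K_max}. Instruments are assigned to their
#' maximum-posterior component; those whose maximum inclusion probability
#' falls below \code{inclusion_threshold} are reported unassigned.
#'
#' @param iv Instrument data.frame (beta_x, se_x, beta_y, se_y).
#' @param K_max Maximum number of substantive clusters (default 5).
#' @param inclusion_threshold Minimum posterior inclusion probability for
#'   a confident assignment (default 0.8).
#' @param seed Seed for EM initialisation.
#' @param max_iter EM iteration cap; non-convergence returns the best fit
#'   so far with \code{converged = FALSE}.
#' @return Object of class \code{mr_clusters}: list with
#'   \code{assignments} (data.frame: id, ratio, se, cluster label
#'   ("null", "junk", "1", "2", ... or "unassigned"), inclusion_prob),
#'   \code{means} (substantive cluster means), \code{K}, \code{bic},
#'   \code{converged}.
#' @export
cluster_instruments <- function(iv, K_max = 5L, inclusion_threshold = 0.8,
                                seed = 1L, max_iter = 1000L) {
  check_instruments(iv, 4L, "instrument clustering")
  rr <- iv_ratios(iv)
  r <- rr$r
  se <- rr$se
  n <- length(r)
  rng <- range(r)
  junk_dens <- 1 / max(diff(rng), 1e-6)
  gen <- local_rng(check_count(seed, "seed", 0L), stream = 11L)

  fit_K <- function(K) {
    # components: 1 = null (mean 0), 2..K+1 substantive, K+2 junk;
    # K = 0 is the null+junk-only model
    mu <- if (K > 0)
      as.numeric(stats::quantile(r, probs = seq_len(K) / (K + 1))) +
        1e-3 * gen$rnorm(K)
    else numeric(0)
    n_comp <- K + 2L
    pi_k <- rep(1 / n_comp, n_comp)
    loglik_old <- -Inf
    converged <- FALSE
    resp <- NULL
    for (iter in seq_len(max_iter)) {
      dens <- cbind(stats::dnorm(r, 0, se),
                    if (K > 0) vapply(seq_len(K), function(k)
                      stats::dnorm(r, mu[k], se), numeric(n)),
                    rep(junk_dens, n))
      num <- sweep(dens, 2, pi_k, `*`)
      rs <- rowSums(num)
      rs[rs == 0] <- .Machine$double.xmin
      resp <- num / rs
      loglik <- sum(base::log(rs))
      pi_k <- colMeans(resp)
      for (k in seq_len(K)) {
        w <- resp[, k + 1L] / se^2
        mu[k] <- if (sum(w) > 0) sum(w * r) / sum(w) else mu[k]
      }
      if (abs(loglik - loglik_old) < 1e-8) { converged <- TRUE; break }
      loglik_old <- loglik
    }
    n_par <- (n_comp - 1L) + K          # mixing proportions + free means
    list(K = K, mu = mu, pi = pi_k, resp = resp, loglik = loglik,
         bic = -2 * loglik + n_par * base::log(n), converged = converged)
  }

  fits <- lapply(0:K_max, fit_K)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  if (!best$converged)
    warning("EM did not fully converge; returning best fit so far")

  comp_labels <- c("null", as.character(seq_len(best$K)), "junk")
  max_post <- apply(best$resp, 1, max)
  comp <- comp_labels[apply(best$resp, 1, which.max)]
  label <- ifelse(max_post >= inclusion_threshold, comp, "unassigned")
  ids <- if ("id" %in% colnames(iv)) iv$id else sprintf("iv%03d", seq_len(n))
  structure(list(
    assignments = data.frame(id = ids, ratio = r, se = se,
                             cluster = label, map_cluster = comp,
                             inclusion_prob = max_post,
                             stringsAsFactors = FALSE),
    means = best$mu, proportions = best$pi, K = best$K, bic = best$bic,
    converged = best$converged,
    inclusion_threshold = inclusion_threshold),
    class = "mr_clusters")
}

#' @export
print.mr_clusters <- function(x, ...) {
  cat(sprintf("Instrument clustering: K = %d substantive cluster(s), BIC = %.1f\n",
              x$K, x$bic))
  cat("  means:", paste(sprintf("%.3f", x$means), collapse = ", "), "\n")
  tab <- table(x$assignments$cluster)
  cat("  assignments:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "),
      sprintf("(inclusion threshold %.0f%%)\n",
              100 * x$inclusion_threshold))
  invisible(x)
}
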