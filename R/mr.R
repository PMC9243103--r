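# Two-sample Mendelian randomisation estimator suite. All estimators take
# an instrument data.frame (columns beta_x, se_x, beta_y, se_y) and return
# an mr_estimate.

mr_estimate <- function(method, theta, se, extra = list()) {
  structure(c(list(method = method, theta = theta, se = se,
                   p = z_to_p(theta / se)), extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  ci <- x$theta + c(-1, 1) * stats::qnorm(0.975) * x$se
  cat(sprintf("%s: theta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$theta, x$se, exp(x$theta), exp(ci[1]), exp(ci[2]),
              x$p))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n", x$intercept,
                x$intercept_se, x$intercept_p))
  if (!is.null(x$Q))
    cat(sprintf("  Q = %.2f on %d df, p = %.3g\n", x$Q, x$df, x$p_het))
  invisible(x)
}

check_instruments <- function(iv, k_min = 2L, caller = "this estimator") {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, colnames(iv))
  if (length(miss))
    stop_param("instrument set missing column(s): %s",
               paste(miss, collapse = ", "))
  if (any(iv$se_x <= 0) || any(iv$se_y <= 0))
    stop_param("all instrument SEs must be positive")
  if (nrow(iv) < k_min)
    stop_param("%s needs >= %d instruments (got %d)%s", caller, k_min,
               nrow(iv),
               if (k_min == 2L) "; use wald_ratio for a single instrument"
               else "")
  invisible(iv)
}

#' Wald ratio estimator (single instrument)
#'
#' \eqn{\theta = \beta_y / \beta_x} with first-order delta-method SE
#' \eqn{se_y / |\beta_x|}; \code{second_order = TRUE} adds the exposure
#' uncertainty term
#' \eqn{\sqrt{se_y^2/\beta_x^2 + \beta_y^2 se_x^2 / \beta_x^4}}.
#'
#' @param beta_x,se_x Exposure effect and SE.
#' @param beta_y,se_y Outcome effect and SE.
#' @param second_order Use the second-order delta SE.
#' @return An \code{mr_estimate}.
#' @examples wald_ratio(0.1, 0.01, 0.2, 0.05)   # theta 2, se 0.5
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (abs(beta_x) < 1e-12)
    stop_param("weak instrument: |beta_x| below tolerance 1e-12")
  theta <- beta_y / beta_x
  se <- if (second_order)
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  else se_y / abs(beta_x)
  mr_estimate("Wald ratio", theta, se)
}

#' Inverse-variance-weighted MR estimator
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights \eqn{1/se_y^2}. Fixed effects (\code{"fixed"}) take the SE
#' from the weighted design; multiplicative random effects
#' (\code{"multiplicative_random"}) inflate it by
#' \eqn{\max(1, \sqrt{Q/(k-1)})}, modelling between-instrument
#' heterogeneity.
#'
#' @param iv Instrument data.frame (beta_x, se_x, beta_y, se_y).
#' @param effects \code{"fixed"} or \code{"multiplicative_random"}.
#' @return An \code{mr_estimate} with Q, df and p_het attached.
#' @export
mr_ivw <- function(iv, effects = c("fixed", "multiplicative_random")) {
  effects <- match.arg(effects)
  check_instruments(iv, 2L, "IVW")
  w <- 1 / iv$se_y^2
  theta <- sum(w * iv$beta_x * iv$beta_y) / sum(w * iv$beta_x^2)
  se <- 1 / sqrt(sum(w * iv$beta_x^2))
  k <- nrow(iv)
  Q <- sum(w * (iv$beta_y - theta * iv$beta_x)^2)
  if (effects == "multiplicative_random")
    se <- se * max(1, sqrt(Q / (k - 1)))
  mr_estimate(if (effects == "fixed") "IVW-FE" else "IVW-MRE", theta, se,
              list(Q = Q, df = k - 1L,
                   p_het = stats::pchisq(Q, k - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, after orienting every instrument to positive exposure
#' effect. The slope is the causal estimate; the intercept estimates
#' average directional pleiotropy, with its own test.
#'
#' @param iv Instrument data.frame.
#' @return An \code{mr_estimate} with intercept, intercept_se,
#'   intercept_p.
#' @export
mr_egger <- function(iv) {
  check_instruments(iv, 3L, "MR-Egger")
  flip <- sign(iv$beta_x)
  flip[flip == 0] <- 1
  bx <- iv$beta_x * flip
  by <- iv$beta_y * flip
  w <- 1 / iv$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  mr_estimate("MR-Egger", sm[2, 1], sm[2, 2], list(
    intercept = sm[1, 1], intercept_se = sm[1, 2],
    intercept_p = 2 * stats::pt(abs(sm[1, 3]), df, lower.tail = FALSE)))
}

# per-instrument ratio estimates and their first-order SEs
iv_ratios <- function(iv) {
  list(r = iv$beta_y / iv$beta_x, se = iv$se_y / abs(iv$beta_x))
}

#' Weighted median MR estimator
#'
#' Median of the per-instrument ratio estimates at cumulative
#' inverse-variance weight 0.5, with linear interpolation; consistent when
#' at least half the weight comes from valid instruments. SE by parametric
#' bootstrap (resampling beta_x, beta_y from their stated SEs).
#'
#' @param iv Instrument data.frame.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (mandatory for reproducibility).
#' @return An \code{mr_estimate}.
#' @export
mr_weighted_median <- function(iv, n_boot = 1000L, seed = 1L) {
  check_instruments(iv, 3L, "weighted median")
  est <- function(r, w) {
    ord <- order(r)
    r <- r[ord]; w <- w[ord] / sum(w)
    cw <- cumsum(w) - w / 2
    below <- max(which(cw < 0.5))
    r[below] + (r[below + 1] - r[below]) *
      (0.5 - cw[below]) / (cw[below + 1] - cw[below])
  }
  rr <- iv_ratios(iv)
  w <- 1 / rr$se^2
  theta <- est(rr$r, w)
  gen <- local_rng(check_count(seed, "seed", 0L), stream = 9L)
  k <- nrow(iv)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- iv$beta_x + iv$se_x * gen$rnorm(k)
    by <- iv$beta_y + iv$se_y * gen$rnorm(k)
    r <- by / bx
    est(r, w)
  }, numeric(1))
  mr_estimate("Weighted median", theta, stats::sd(boots),
              list(n_boot = n_boot))
}

#' Weighted mode MR estimator
#'
#' Mode of the inverse-variance-weighted normal-kernel density of the
#' per-instrument ratio estimates; consistent when the largest group of
#' instruments sharing a causal estimate is valid (plurality rule).
#' Bandwidth is \code{bandwidth_factor} times a weighted
#' median-absolute-deviation scale. SE by parametric bootstrap. When every
#' ratio is identical that common value is returned with SE 0.
#'
#' @param iv Instrument data.frame.
#' @param bandwidth_factor Multiplier on the MAD-based bandwidth.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return An \code{mr_estimate}.
#' @export
mr_weighted_mode <- function(iv, bandwidth_factor = 1, n_boot = 1000L,
                             seed = 1L) {
  check_instruments(iv, 3L, "weighted mode")
  mode_est <- function(r, w) {
    s <- stats::mad(r)
    if (s == 0) s <- stats::sd(r)
    if (s == 0 || !is.finite(s)) return(r[1])
    h <- bandwidth_factor * 0.9 * s * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
    dens <- vapply(grid, function(g)
      sum(w * stats::dnorm((g - r) / h)), numeric(1))
    grid[which.max(dens)]
  }
  rr <- iv_ratios(iv)
  w <- 1 / rr$se^2
  if (diff(range(rr$r)) < 1e-12)
    return(mr_estimate("Weighted mode", rr$r[1], 0))
  theta <- mode_est(rr$r, w)
  gen <- local_rng(check_count(seed, "seed", 0L), stream = 10L)
  k <- nrow(iv)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- iv$beta_x + iv$se_x * gen$rnorm(k)
    by <- iv$beta_y + iv$se_y * gen$rnorm(k)
    mode_est(by / bx, w)
  }, numeric(1))
  mr_estimate("Weighted mode", theta, stats::sd(boots),
              list(n_boot = n_boot))
}

#' Cochran's Q heterogeneity test between instrument estimates
#'
#' \eqn{Q = \sum_i w_i (\beta_{yi} - \theta \beta_{xi})^2} with
#' \eqn{w_i = 1/se_{yi}^2}, on k-1 df.
#'
#' @param iv Instrument data.frame.
#' @param theta Causal estimate to test around (typically IVW).
#' @return List: Q, df, p.
#' @export
mr_heterogeneity <- function(iv, theta) {
  check_instruments(iv, 2L, "heterogeneity")
  w <- 1 / iv$se_y^2
  Q <- sum(w * (iv$beta_y - theta * iv$beta_x)^2)
  k <- nrow(iv)
  list(Q = Q, df = k - 1L,
       p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Run the full MR estimator suite
#'
#' Wald ratio for a single instrument; otherwise IVW-FE, IVW-MRE, weighted
#' median, weighted mode and MR-Egger, plus Cochran's Q at the IVW-FE
#' estimate.
#'
#' @param iv Instrument data.frame.
#' @param n_boot,seed Bootstrap controls for the median/mode estimators.
#' @return Named list of \code{mr_estimate}s (class \code{mr_suite}).
#' @export
mr_all <- function(iv, n_boot = 1000L, seed = 1L) {
  if (nrow(iv) == 1L)
    return(structure(list(wald = wald_ratio(iv$beta_x, iv$se_x, iv$beta_y,
                                            iv$se_y)),
                     class = "mr_suite"))
  out <- list(ivw_fe = mr_ivw(iv, "fixed"),
              ivw_mre = mr_ivw(iv, "multiplicative_random"))
  if (nrow(iv) >= 3L) {
    out$weighted_median <- mr_weighted_median(iv, n_boot, seed)
    out$weighted_mode <- mr_weighted_mode(iv, n_boot = n_boot, seed = seed)
    out$egger <- mr_egger(iv)
  }
  out$heterogeneity <- mr_heterogeneity(iv, out$ivw_fe$theta)
  structure(out, class = "mr_suite")
}

#' @export
print.mr_suite <- function(x, ...) {
  for (nm in names(x)) {
    if (inherits(x[[nm]], "mr_estimate")) print(x[[nm]])
    else cat(sprintf("Cochran's Q = %.2f on %d df, p = %.3g\n",
                     x[[nm]]$Q, x[[nm]]$df, x[[nm]]$p))
  }
  invisible(x)
}
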