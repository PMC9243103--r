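#' Simulate a two-sample MR instrument set
#'
#' Generates harmonised exposure/outcome effect pairs with known causal
#' structure. Instruments are partitioned into clusters, each with its own
#' causal effect theta (a theta of 0 yields a null cluster); outcome effects
#' are \eqn{\beta_y = \theta_c \beta_x + a + u + \epsilon} where \code{a} is
#' a directional-pleiotropy intercept, \code{u} optional balanced pleiotropy
#' noise, and \eqn{\epsilon} sampling noise at the stated outcome SE.
#' Cluster labels are retained as ground truth for clustering-recovery
#' tests.
#'
#' @param k Number of instruments (>= 1).
#' @param theta Numeric vector of per-cluster causal effects; instruments
#'   are split across clusters as evenly as possible (or per
#'   \code{cluster_sizes}).
#' @param cluster_sizes Optional integer vector (same length as
#'   \code{theta}) of instruments per cluster; must sum to \code{k}.
#' @param pleiotropy_intercept Directional pleiotropy added to every
#'   outcome effect (MR-Egger intercept ground truth).
#' @param pleiotropy_sd SD of balanced (zero-mean) pleiotropy.
#' @param se_x,se_y Sampling SEs of exposure and outcome effects.
#' @param beta_x_range Absolute exposure effects drawn uniformly from this
#'   range (sign random), keeping instruments away from zero.
#' @param seed Integer seed.
#' @return Object of class \code{instrument_set}: data.frame with id,
#'   beta_x, se_x, beta_y, se_y, and ground-truth columns cluster and
#'   theta_true.
#' @export
simulate_instruments <- function(k, theta = 0.2, cluster_sizes = NULL,
                                 pleiotropy_intercept = 0,
                                 pleiotropy_sd = 0,
                                 se_x = 0.01, se_y = 0.02,
                                 beta_x_range = c(0.05, 0.25),
                                 seed = 1L) {
  k <- check_count(k, "k")
  if (length(theta) < 1L) stop_param("empty cluster specification")
  n_cl <- length(theta)
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(k %/% n_cl, n_cl)
    if (k %% n_cl) cluster_sizes[seq_len(k %% n_cl)] <-
        cluster_sizes[seq_len(k %% n_cl)] + 1L
  }
  if (length(cluster_sizes) != n_cl || sum(cluster_sizes) != k)
    stop_param("'cluster_sizes' must match 'theta' and sum to k")

  gen <- local_rng(check_count(seed, "seed", 0L), stream = 7L)
  cl <- rep(seq_len(n_cl), cluster_sizes)
  bx_true <- gen$runif(k, beta_x_range[1], beta_x_range[2]) *
    sign(gen$runif(k, -1, 1))
  bx <- bx_true + se_x * gen$rnorm(k)
  # directional pleiotropy is defined in the positive-exposure orientation
  # (the frame Egger regression works in), so it follows the sign flip
  plei <- pleiotropy_intercept * sign(bx_true) +
    if (pleiotropy_sd > 0) gen$rnorm(k, sd = pleiotropy_sd) else 0
  by <- theta[cl] * bx_true + plei + se_y * gen$rnorm(k)

  structure(data.frame(id = sprintf("iv%03d", seq_len(k)),
                       beta_x = bx, se_x = se_x,
                       beta_y = by, se_y = se_y,
                       cluster = cl, theta_true = theta[cl],
                       stringsAsFactors = FALSE),
            class = c("instrument_set", "data.frame"))
}
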