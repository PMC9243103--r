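exact_iv <- function(theta, k = 10, bx = NULL) {
  if (is.null(bx)) bx <- seq(0.05, 0.3, length.out = k)
  data.frame(beta_x = bx, se_x = 0.01, beta_y = theta * bx, se_y = 0.02,
             stringsAsFactors = FALSE)
}

test_that("Wald ratio matches hand evaluation and invariances", {
  w <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(w$theta, 2)
  expect_equal(w$se, 0.5)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.05)$theta, 0)
  # simultaneous sign flip leaves the ratio unchanged
  w2 <- wald_ratio(-0.1, 0.01, -0.2, 0.05)
  expect_equal(w2$theta, w$theta)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "weak instrument")
  # second-order se adds the exposure term
  w3 <- wald_ratio(0.1, 0.01, 0.2, 0.05, second_order = TRUE)
  expect_gt(w3$se, w$se)
})

test_that("IVW matches closed forms and handles heterogeneity", {
  iv <- exact_iv(0.3)
  fe <- mr_ivw(iv, "fixed")
  mre <- mr_ivw(iv, "multiplicative_random")
  expect_equal(fe$theta, 0.3, tolerance = 1e-12)
  expect_equal(fe$Q, 0, tolerance = 1e-12)
  expect_equal(fe$se, mre$se)

  # two instruments with ratio estimates 0.1 and 0.3, equal weights
  iv2 <- data.frame(beta_x = c(1, 1), se_x = 0.01,
                    beta_y = c(0.1, 0.3), se_y = c(0.1, 0.1))
  est2 <- mr_ivw(iv2)
  expect_equal(est2$theta, 0.2, tolerance = 1e-12)
  Q_hand <- sum((c(0.1, 0.3) - 0.2)^2 / 0.1^2)
  expect_equal(est2$Q, Q_hand, tolerance = 1e-12)
  het <- mr_heterogeneity(iv2, est2$theta)
  expect_equal(het$Q, Q_hand)
  expect_equal(het$df, 1)

  expect_error(mr_ivw(iv2[1, ]), "wald_ratio")
})

test_that("MRE widens intervals under overdispersion with good coverage", {
  set.seed(41)
  n_rep <- 300
  cover <- wider <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    k <- 50
    bx <- runif(k, 0.05, 0.3)
    by <- 0.2 * bx + rnorm(k, 0, 0.03) + rnorm(k, 0, 0.02)
    iv <- data.frame(beta_x = bx, se_x = 0.005, beta_y = by, se_y = 0.02)
    mre <- mr_ivw(iv, "multiplicative_random")
    fe <- mr_ivw(iv, "fixed")
    wider[r] <- mre$se > fe$se
    cover[r] <- abs(mre$theta - 0.2) < qnorm(0.975) * mre$se
  }
  expect_true(all(wider))
  expect_gte(mean(cover), 0.90)
})

test_that("Egger regression separates slope from directional pleiotropy", {
  iv <- exact_iv(0.25, k = 12)
  e0 <- mr_egger(iv)
  expect_equal(e0$theta, 0.25, tolerance = 1e-10)
  expect_equal(e0$intercept, 0, tolerance = 1e-10)

  # constant pleiotropy shifts the intercept, not the slope
  iva <- iv; iva$beta_y <- iva$beta_y + 0.04
  ea <- mr_egger(iva)
  expect_equal(ea$intercept, 0.04, tolerance = 1e-10)
  expect_equal(ea$theta, 0.25, tolerance = 1e-10)

  # balanced pleiotropy: intercept within 2 se
  set.seed(7)
  ivb <- simulate_instruments(80, theta = 0.2, pleiotropy_sd = 0.02,
                              se_y = 0.01, seed = 8)
  eb <- mr_egger(ivb)
  expect_lt(abs(eb$intercept), 3 * eb$intercept_se)
  expect_error(mr_egger(iv[1:2, ]), ">= 3")
})

test_that("weighted median is robust and exact on degenerate input", {
  expect_equal(mr_weighted_median(exact_iv(0.4), n_boot = 50,
                                  seed = 1)$theta, 0.4, tolerance = 1e-10)
  iv <- data.frame(beta_x = c(1, 1, 1), se_x = 0.01,
                   beta_y = c(1, 2, 100), se_y = c(0.5, 0.5, 0.5))
  expect_equal(mr_weighted_median(iv, n_boot = 50, seed = 1)$theta, 2,
               tolerance = 1e-9)

  # breakdown: valid majority at 0.2, half-ish invalid shifted
  set.seed(3)
  k <- 40
  bx <- runif(k, 0.1, 0.3)
  by <- 0.2 * bx + rnorm(k, 0, 0.002)
  by[1:18] <- by[1:18] + 0.05   # invalid minority
  ivm <- data.frame(beta_x = bx, se_x = 0.002, beta_y = by, se_y = 0.01)
  wm <- mr_weighted_median(ivm, n_boot = 100, seed = 2)
  expect_lt(abs(wm$theta - 0.2), 0.05)
})

test_that("weighted mode follows the plurality and smoothing limits", {
  expect_equal(mr_weighted_mode(exact_iv(0.15), n_boot = 20,
                                seed = 1)$se, 0)
  # bimodal: 30 instruments at 0.2, 10 at 0.8 -> mode near 0.2
  set.seed(9)
  bx <- runif(40, 0.1, 0.3)
  theta_i <- c(rep(0.2, 30), rep(0.8, 10))
  ivb <- data.frame(beta_x = bx, se_x = 0.002,
                    beta_y = theta_i * bx + rnorm(40, 0, 0.001),
                    se_y = 0.01)
  expect_lt(abs(mr_weighted_mode(ivb, n_boot = 20, seed = 3)$theta - 0.2),
            0.05)
  # infinite-bandwidth limit approaches the weighted mean of ratios
  wide <- mr_weighted_mode(ivb, bandwidth_factor = 500, n_boot = 20,
                           seed = 4)
  r <- ivb$beta_y / ivb$beta_x
  w <- (abs(ivb$beta_x) / ivb$se_y)^2
  expect_lt(abs(wide$theta - sum(w * r) / sum(w)), 0.1)
})

test_that("all estimators are sign-flip equivariant and agree without pleiotropy", {
  iv <- simulate_instruments(40, theta = 0.2, se_y = 0.008, seed = 21)
  flip <- iv
  flip$beta_x <- -flip$beta_x
  flip$beta_y <- -flip$beta_y
  for (f in list(function(d) mr_ivw(d)$theta,
                 function(d) mr_egger(d)$theta,
                 function(d) mr_weighted_median(d, n_boot = 30,
                                                seed = 5)$theta,
                 function(d) mr_weighted_mode(d, n_boot = 30,
                                              seed = 5)$theta))
    expect_equal(f(iv), f(flip), tolerance = 1e-8)

  suite <- mr_all(iv, n_boot = 100, seed = 6)
  ests <- vapply(c("ivw_fe", "ivw_mre", "weighted_median",
                   "weighted_mode", "egger"),
                 function(nm) suite[[nm]]$theta, numeric(1))
  ses <- vapply(c("ivw_fe", "ivw_mre", "weighted_median",
                  "weighted_mode", "egger"),
                function(nm) suite[[nm]]$se, numeric(1))
  expect_true(all(abs(ests - 0.2) < 2 * pmax(ses, 0.01)))
})

test_that("instrument clustering recovers planted structure", {
  # all-null instruments collapse into the null cluster
  iv0 <- simulate_instruments(30, theta = 0, se_y = 0.004, seed = 31)
  cl0 <- cluster_instruments(iv0, seed = 1)
  expect_gt(mean(cl0$assignments$cluster == "null"), 0.8)

  # two planted clusters at 0.2 and -0.1
  iv2 <- simulate_instruments(60, theta = c(0.2, -0.1), se_x = 0.002,
                              se_y = 0.002, seed = 32)
  cl2 <- cluster_instruments(iv2, seed = 2)
  expect_equal(cl2$K, 2)
  expect_equal(sort(round(cl2$means, 2)), c(-0.1, 0.2), tolerance = 0.02,
               ignore_attr = TRUE)
  conf <- cl2$assignments[cl2$assignments$cluster %in% c("1", "2"), ]
  expect_gt(nrow(conf) / nrow(iv2), 0.9)

  # a wild outlier lands in the junk cluster
  iv3 <- rbind(iv2[, c("beta_x", "se_x", "beta_y", "se_y")],
               data.frame(beta_x = 0.2, se_x = 0.002, beta_y = 0.5,
                          se_y = 0.002))
  cl3 <- cluster_instruments(iv3, seed = 3)
  expect_equal(cl3$assignments$map_cluster[61], "junk")
  expect_error(cluster_instruments(iv2[1:3, ]), ">= 4")
})
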