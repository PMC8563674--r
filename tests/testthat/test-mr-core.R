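test_that("Wald ratios follow the first-order delta method", {
  h <- make_harmonised(beta_x = 0.5, se_x = 0.01, beta_y = 0.1, se_y = 0.02)
  r <- wald_ratios(h)
  expect_equal(r$theta, 0.2)
  expect_equal(r$se_theta, 0.04)

  h$beta_y <- -0.1
  expect_equal(wald_ratios(h)$theta, -0.2)

  # the absolute value in the SE: simulate outcome noise at beta_x = -0.5
  h2 <- make_harmonised(beta_x = -0.5, se_x = 0.01, beta_y = 0.1, se_y = 0.02)
  r2 <- wald_ratios(h2)
  expect_equal(r2$theta, -0.2)
  expect_equal(r2$se_theta, 0.04)
  set.seed(99)
  sim_theta <- rnorm(200000, 0.1, 0.02) / -0.5
  expect_equal(sd(sim_theta), r2$se_theta, tolerance = 0.01)

  h$beta_x <- 0
  expect_error(wald_ratios(h), class = "maternalmr_undefined_ratio")
})

test_that("fixed-effect IVW equals WLS through the origin", {
  r <- tibble::tibble(snp = c("a", "b"), theta = c(1, 3), se_theta = c(1, 1),
                      weight = 1)
  est <- ivw_pool(r)
  expect_equal(est$beta, 2)
  expect_equal(est$se, 1 / sqrt(2))

  # identical ratios: no heterogeneity, no random-effects inflation
  rid <- tibble::tibble(snp = letters[1:4], theta = 0.7,
                        se_theta = c(0.1, 0.2, 0.3, 0.4), weight = 0)
  expect_equal(ivw_pool(rid)$beta, 0.7)
  expect_equal(ivw_pool(rid, "multiplicative_random")$se, ivw_pool(rid)$se)

  # WLS-through-origin oracle on random instances
  for (seed in 1:5) {
    h <- random_harmonised(10, seed)
    est <- ivw_pool(wald_ratios(h))
    fit <- lm(beta_y ~ 0 + beta_x, data = h, weights = 1 / h$se_y^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  }
})

test_that("Cochran's Q and I-squared match published desk values", {
  r <- tibble::tibble(snp = letters[1:3], theta = 0.5,
                      se_theta = c(0.1, 0.2, 0.3), weight = 0)
  het <- cochran_q(r)
  expect_equal(het$Q, 0)
  expect_equal(het$i2_percent, 0)

  expect_equal(round(i_squared(33.46, 13), 1), 61.1)
  expect_equal(round(i_squared(178.42, 75), 1), 58.0)
  expect_equal(i_squared(5, 13), 0)

  expect_error(cochran_q(r[1, ]), class = "maternalmr_insufficient_data")
})

test_that("MR-Egger recovers noiseless lines and reduces to IVW at zero intercept", {
  # exact line: slope and intercept to machine precision
  h <- make_harmonised(beta_x = c(0.02, 0.05, 0.08, 0.12), se_x = 0.01,
                       beta_y = 0.003 + 1.4 * c(0.02, 0.05, 0.08, 0.12),
                       se_y = c(0.01, 0.012, 0.02, 0.015))
  eg <- mr_egger(h)
  expect_equal(eg$beta[eg$method == "egger_slope"], 1.4, tolerance = 1e-10)
  expect_equal(eg$beta[eg$method == "egger_intercept"], 0.003, tolerance = 1e-10)

  # data through the origin: slope equals the IVW estimate
  h0 <- make_harmonised(beta_x = c(0.02, 0.05, 0.08, 0.12), se_x = 0.01,
                        beta_y = -0.8 * c(0.02, 0.05, 0.08, 0.12),
                        se_y = c(0.01, 0.012, 0.02, 0.015))
  eg0 <- mr_egger(h0)
  ivw0 <- ivw_pool(wald_ratios(h0))
  expect_equal(eg0$beta[eg0$method == "egger_slope"], ivw0$beta, tolerance = 1e-10)

  expect_error(mr_egger(h[1:2, ]), class = "maternalmr_insufficient_data")
  hneg <- make_harmonised(beta_x = c(-0.1, 0.2, 0.3), se_x = 0.01,
                          beta_y = c(0, 0, 0), se_y = 0.01)
  expect_error(mr_egger(hneg), class = "maternalmr_orientation_error")
  hflat <- make_harmonised(beta_x = rep(0.1, 4), se_x = 0.01,
                           beta_y = rnorm(4), se_y = 0.01)
  expect_error(mr_egger(hflat), class = "maternalmr_rank_deficiency")
})

test_that("Egger intercept detects simulated directional pleiotropy", {
  # summary-level simulation with known pleiotropy: intercept should be
  # positive and its 95% CI should cover the true average pleiotropy in
  # roughly 95% of replicates
  set.seed(202)
  n_rep <- 300
  truth_int <- 0.01
  cover <- logical(n_rep)
  positive <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    bx <- runif(20, 0.03, 0.15)
    se_y <- runif(20, 0.008, 0.012)
    by <- truth_int + 0.3 * bx + rnorm(20, 0, se_y)
    h <- make_harmonised(bx, 0.01, by, se_y)
    eg <- mr_egger(h)
    int <- eg[eg$method == "egger_intercept", ]
    cover[i] <- int$ci_low <= truth_int && truth_int <= int$ci_high
    positive[i] <- int$beta > 0
  }
  expect_gt(mean(positive), 0.8)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("weighted median interpolates the cumulative weight distribution", {
  h3 <- make_harmonised(beta_x = 1, se_x = 0.01, beta_y = c(1, 2, 9),
                        se_y = 1)
  h3$beta_x <- rep(1, 3)
  wm <- weighted_median(h3, n_boot = 200, seed = 5)
  expect_equal(wm$beta, 2)

  # weight concentrated on one SNP gives that SNP's ratio
  hconc <- make_harmonised(beta_x = rep(1, 3), se_x = 0.01,
                           beta_y = c(1, 2, 9), se_y = c(1e-4, 1, 1))
  expect_equal(weighted_median(hconc, n_boot = 200, seed = 5)$beta, 1,
               tolerance = 1e-6)

  # unequal weights against the independent interpolation oracle
  for (seed in 1:5) {
    h <- random_harmonised(5, seed + 40)
    r <- wald_ratios(h)
    got <- weighted_median(h, n_boot = 100, seed = 1)$beta
    expect_equal(got, oracle_weighted_median(r$theta, r$weight),
                 tolerance = 1e-9)
  }

  expect_warning(weighted_median(h3, n_boot = 50, seed = 1), "n_boot")
  expect_error(weighted_median(h3[1:2, ], n_boot = 200, seed = 1),
               class = "maternalmr_insufficient_data")
})

test_that("weighted median bootstrap is seed-deterministic", {
  h <- random_harmonised(8, 77)
  a <- weighted_median(h, n_boot = 300, seed = 42)
  b <- weighted_median(h, n_boot = 300, seed = 42)
  expect_identical(a, b)
})

test_that("leave-one-out recomputes the pool per exclusion", {
  h <- random_harmonised(8, 3)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 8)
  expect_equal(loo$excluded_snp, h$snp)
  expect_equal(loo$n_snps, rep(7L, 8))
  # direct recomputation oracle for one exclusion
  manual <- ivw_pool(wald_ratios(h[-3, ]))
  expect_equal(loo$beta[3], manual$beta, tolerance = 1e-12)
  expect_equal(loo$se[3], manual$se, tolerance = 1e-12)

  # a SNP with vanishing weight leaves the estimate essentially unchanged
  h$se_y[1] <- 50
  loo2 <- leave_one_out(h)
  full <- ivw_pool(wald_ratios(h))
  expect_equal(loo2$beta[1], full$beta, tolerance = 1e-4)
})

test_that("radial MR q contributions sum to Cochran's Q and flag spike-ins", {
  h <- random_harmonised(12, 8)
  rad <- radial_mr(h)
  het <- cochran_q(wald_ratios(h))
  expect_equal(rad$global_q, het$Q, tolerance = 1e-10)
  expect_equal(sum(rad$rows$q_contribution), het$Q, tolerance = 1e-10)
  # radial IVW slope is the IVW estimate
  expect_equal(rad$estimate$beta, ivw_pool(wald_ratios(h))$beta,
               tolerance = 1e-12)

  # spike a gross outcome effect into one SNP
  hs <- make_harmonised(beta_x = rep(c(0.05, 0.08, 0.11), 4), se_x = 0.01,
                        beta_y = 0.5 * rep(c(0.05, 0.08, 0.11), 4),
                        se_y = 0.008)
  set.seed(14)
  hs$beta_y <- hs$beta_y + rnorm(12, 0, 0.004)
  hs$beta_y[5] <- hs$beta_y[5] + 0.2
  rad_s <- radial_mr(hs, alpha = 0.05)
  expect_true(rad_s$rows$is_outlier[5])
  expect_equal(unname(which.max(rad_s$rows$q_contribution)), 5L)

  # egger variant runs and reports an intercept-adjusted slope
  rad_e <- radial_mr(h, model = "egger")
  expect_equal(rad_e$estimate$method, "radial_egger")
  expect_error(radial_mr(h[1:2, ]), class = "maternalmr_insufficient_data")
})

test_that("multivariable MR reduces to IVW for one exposure and flags collinearity", {
  h <- random_harmonised(12, 21)
  d <- tibble::tibble(snp = h$snp, x1 = h$beta_x, beta_y = h$beta_y,
                      se_y = h$se_y)
  uni <- mvmr(d, exposures = "x1")
  ivw <- ivw_pool(wald_ratios(h), model = "multiplicative_random")
  expect_equal(uni$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(uni$se, ivw$se, tolerance = 1e-12)

  d$x2 <- 2 * d$x1
  expect_error(mvmr(d, exposures = c("x1", "x2")),
               class = "maternalmr_collinearity_error")
  d$zero <- 0
  expect_error(mvmr(d, exposures = c("x1", "zero")),
               class = "maternalmr_collinearity_error")
  expect_error(mvmr(d, exposures = c("x1", "zero")), "zero")
  expect_error(mvmr(d[1:2, ], exposures = c("x1", "x2")),
               class = "maternalmr_insufficient_data")
})

test_that("multivariable MR isolates direct effects under full mediation", {
  # outcome depends on the exposures only through the mediator column:
  # the direct-exposure coefficient should be ~0 and covered by its CI in
  # about 95% of replicates
  set.seed(303)
  n_rep <- 200
  cover_zero <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    bx <- runif(25, 0.03, 0.15)
    bm <- 0.8 * bx + rnorm(25, 0, 0.01)       # SNP-mediator betas
    se_y <- runif(25, 0.008, 0.012)
    by <- 0.5 * bm + rnorm(25, 0, se_y)        # outcome via mediator only
    d <- tibble::tibble(exposure = bx, mediator = bm, beta_y = by, se_y = se_y)
    fit <- mvmr(d, exposures = c("exposure", "mediator"))
    direct <- fit[fit$exposure == "exposure", ]
    cover_zero[i] <- direct$ci_low <= 0 && 0 <= direct$ci_high
  }
  expect_gt(mean(cover_zero), 0.90)
})

test_that("causal estimates are coherent under exposure unit changes", {
  h <- random_harmonised(10, 55)
  c_scale <- 2.5
  hs <- dplyr::mutate(h, beta_x = beta_x * c_scale, se_x = se_x * c_scale)
  expect_equal(ivw_pool(wald_ratios(hs))$beta,
               ivw_pool(wald_ratios(h))$beta / c_scale, tolerance = 1e-12)
  eg <- mr_egger(h); egs <- mr_egger(hs)
  expect_equal(egs$beta[egs$method == "egger_slope"],
               eg$beta[eg$method == "egger_slope"] / c_scale, tolerance = 1e-12)
  wm <- weighted_median(h, n_boot = 100, seed = 9)
  wms <- weighted_median(hs, n_boot = 100, seed = 9)
  expect_equal(wms$beta, wm$beta / c_scale, tolerance = 1e-12)
})

test_that("the estimator suite returns a tidy, broom-compatible object", {
  h <- random_harmonised(10, 67)
  res <- mr_all(h, n_boot = 100, seed = 2)
  expect_s3_class(res, "mr_result")
  expect_setequal(res$estimates$method,
                  c("wald_ivw_fixed", "ivw_mre", "egger_slope",
                    "egger_intercept", "weighted_median"))
  td <- tidy(res)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_snps, 10)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_radial(h), "ggplot")
})
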