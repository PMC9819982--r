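make_sim <- function(...) simulate_panel(dgp_spec(...))

test_that("regime indicator implements the strict spatial-lag comparison", {
  w <- four_cycle_weights()
  # constant column: lag equals value, strict inequality -> all zero
  Y <- matrix(5, 4, 2)
  expect_true(all(build_regime_indicator(Y, w)$d == 0))
  # alternating +-1 on the 4-cycle: lag = -Y, so d = 1 exactly where Y > 0
  Y2 <- matrix(c(1, -1, 1, -1), 4, 2)
  d2 <- build_regime_indicator(Y2, w)$d
  expect_equal(unname(d2[, 1]), c(1, 0, 1, 0))
  # per-cell brute-force check on random data
  set.seed(21)
  Y3 <- matrix(rnorm(8), 4, 2)
  d3 <- build_regime_indicator(Y3, w)$d
  for (i in 1:4) for (t in 1:2) {
    expect_identical(d3[i, t], as.numeric(Y3[i, t] > sum(w$w[i, ] * Y3[, t])))
  }
  expect_error(build_regime_indicator(Y3, four_cycle_weights(FALSE)),
               "row-standardized")
  expect_error(build_regime_indicator(matrix(0, 3, 2), w), "shape")
})

test_that("two-regime log-likelihood equals naive per-period evaluation", {
  sim <- make_sim(n = 8, T_ = 4, seed = 5)
  w <- sim$w
  d <- sim$regime$d
  delta_names <- c(paste0("beta_", names(sim$panel$covariates)),
                   paste0("theta_", names(sim$panel$covariates)))
  set.seed(33)
  for (k in 1:25) {
    r <- runif(2, -0.6, 0.6)
    delta <- setNames(rnorm(12), delta_names)
    s2 <- runif(1, 0.2, 2)
    ll_pkg <- two_regime_loglik(sim$panel, w, r[1], r[2],
                                delta = delta, sigma2 = s2,
                                regime = sim$regime)
    ll_naive <- naive_two_regime_loglik(sim$panel, w$w, d, r[1], r[2],
                                        delta, s2)
    expect_equal(ll_pkg, ll_naive, tolerance = 1e-8)
  }
})

test_that("with an all-ones regime the profile reduces to single-regime SDM", {
  sim <- make_sim(n = 8, T_ = 5, seed = 9)
  ones <- structure(list(d = matrix(1, 8, 5), source = "simulated",
                         regime1_counts = rep(8, 5)),
                    class = "regime_panel")
  rho_grid <- seq(-0.7, 0.7, by = 0.14)
  for (r in rho_grid) {
    two <- two_regime_loglik(sim$panel, sim$w, r, 0.123, regime = ones)
    naive_single <- naive_profile_loglik(sim$panel, sim$w$w,
                                         matrix(1, 8, 5), r, 0)
    expect_equal(two, naive_single, tolerance = 1e-6)
  }
  # and the fitted object reports rho2 as unidentified
  fit <- fit_two_regime_sdm(sim$panel, sim$w, regime = ones)
  expect_true(is.na(fit$rho2))
  expect_false(fit$identified[["rho2"]])
  sdm <- fit_comparison(sim$panel, sim$w, "sdm")
  expect_equal(fit$loglik, sdm$loglik, tolerance = 1e-6)
})

test_that("level shifts of Y move only the fixed effects in nested models", {
  # With a row-standardized W a constant added to Y passes through WY and
  # is absorbed by the within transformation for the single-regime models.
  # (The two-regime lag split d*WY is not shift-invariant because d varies;
  # only the indicator itself is.)
  sim <- make_sim(n = 10, T_ = 5, seed = 13)
  p2 <- sim$panel
  p2$outcome <- p2$outcome + 100
  d1 <- build_regime_indicator(sim$panel$outcome, sim$w)$d
  d2 <- build_regime_indicator(p2$outcome, sim$w)$d
  expect_identical(d1, d2)
  for (m in c("ols", "sar", "sdm")) {
    f1 <- fit_comparison(sim$panel, sim$w, m)
    f2 <- fit_comparison(p2, sim$w, m)
    expect_equal(f1$coef_table$estimate, f2$coef_table$estimate,
                 tolerance = 1e-8)
    if (!is.null(f1$rho)) expect_equal(f1$rho, f2$rho, tolerance = 1e-8)
  }
})

test_that("OLS comparison fit matches the closed-form least-squares oracle", {
  sim <- make_sim(n = 8, T_ = 6, seed = 17)
  fit <- fit_comparison(sim$panel, sim$w, "ols")
  # closed form on naively demeaned data (no spatial lags in OLS)
  y <- as.vector(naive_demean(sim$panel$outcome))
  X <- do.call(cbind, lapply(sim$panel$covariates,
                             function(m) as.vector(naive_demean(m))))
  b <- solve(t(X) %*% X, t(X) %*% y)
  est <- setNames(fit$coef_table$estimate, fit$coef_table$term)
  expect_equal(unname(est[paste0("beta_", colnames(X))]), as.vector(b),
               tolerance = 1e-10)
})

test_that("single-regime spatial fits recover their generating models", {
  # SAR data (theta = 0): SDM's theta should be insignificant jointly often,
  # and SAR rho estimate close to truth
  spec <- dgp_spec(n = 20, T_ = 8, rho1 = 0.4, rho2 = 0.4,
                   theta = setNames(rep(0, 6), names(dgp_spec()$theta)),
                   seed = 2)
  sim <- simulate_panel(spec)
  sar <- fit_comparison(sim$panel, sim$w, "sar")
  expect_lt(abs(sar$rho[["rho"]] - 0.4), 0.15)
  sdm <- fit_comparison(sim$panel, sim$w, "sdm")
  expect_gte(sdm$loglik, sar$loglik - 1e-6)
  sem <- fit_comparison(sim$panel, sim$w, "sem")
  expect_true(is.finite(sem$loglik))
  expect_equal(sem$T, 8)
})

test_that("strategy classification follows the point-comparison rule", {
  expect_equal(classify_strategy(0.163, 0.151)$label, "race_to_bottom")
  expect_equal(classify_strategy(0.160, 0.170)$label, "race_to_top")
  v <- classify_strategy(0.075, 0.117)
  expect_equal(v$label, "race_to_top")
  expect_equal(v$rho_ratio, 0.075 / 0.117, tolerance = 1e-12)
  expect_equal(classify_strategy(0.1, 0.1)$label, "indeterminate")
  expect_equal(classify_strategy(0.2, 0)$label, "race_to_bottom")
  expect_true(is.na(classify_strategy(0.2, 0)$rho_ratio))
})

test_that("staged fits partition years and agree with the full fit", {
  sim <- make_sim(n = 10, T_ = 6, seed = 23)
  p <- sim$panel
  expect_error(staged_fit(p, sim$w, list(c(2005, 2007))), "partition")
  expect_error(staged_fit(p, sim$w,
                          list(c(2005, 2009), 2010)), "at least 2 years")
  st <- staged_fit(p, sim$w, list(c(2005, 2007), c(2008, 2010)))
  expect_equal(nrow(st$summary), 2)
  expect_equal(st$summary$stage, c("2005-2007", "2008-2010"))
  # single full-range split equals the plain fit
  st1 <- staged_fit(p, sim$w, list(c(2005, 2010)))
  full <- fit_two_regime_sdm(p, sim$w)
  expect_equal(st1$fits[[1]]$rho1, full$rho1, tolerance = 1e-8)
  expect_equal(st1$fits[[1]]$loglik, full$loglik, tolerance = 1e-8)
})
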