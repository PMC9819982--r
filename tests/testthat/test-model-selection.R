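test_that("LM statistics match a literal-formula oracle", {
  sim <- simulate_panel(dgp_spec(n = 10, T_ = 5, seed = 3))
  p <- sim$panel; w <- sim$w
  res <- lm_tests(p, w)

  # literal re-derivation with explicit dense matrices
  W <- w$w; n <- 10; T_ <- 5; N <- n * T_
  y <- as.vector(naive_demean(p$outcome))
  X <- do.call(cbind, lapply(p$covariates,
                             function(m) as.vector(naive_demean(m))))
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  e <- as.vector((diag(N) - P) %*% y)
  bigW <- kronecker(diag(T_), W)
  Pn <- diag(n) - matrix(1 / n, n, n)
  PT <- diag(T_) - matrix(1 / T_, T_, T_)
  Q <- kronecker(PT, Pn)
  H <- Q - P
  nu <- sum(diag(H))
  s2 <- sum(e^2) / nu
  B <- H %*% bigW %*% H
  trB <- sum(diag(B))
  Tq <- sum(diag(B %*% t(B))) + sum(diag(B %*% B)) - 2 * trB^2 / nu
  s_lam <- as.numeric(t(e) %*% bigW %*% e) / s2 - trB
  s_rho <- as.numeric(t(e) %*% bigW %*% y) / s2 - trB
  wxb <- bigW %*% (Q %*% y - e)
  Gq <- as.numeric(t(wxb) %*% H %*% wxb) / s2

  expect_equal(res$lm_lag$statistic, s_rho^2 / (Gq + Tq), tolerance = 1e-10)
  expect_equal(res$lm_error$statistic, s_lam^2 / Tq, tolerance = 1e-10)
  expect_equal(res$robust_lm_lag$statistic,
               (s_rho - s_lam)^2 / Gq, tolerance = 1e-10)
  shrink <- Tq / (Gq + Tq)
  expect_equal(res$robust_lm_error$statistic,
               (s_lam - shrink * s_rho)^2 / (Tq * (1 - shrink)),
               tolerance = 1e-10)
  for (r in res) {
    expect_gte(r$statistic, 0)
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("LM tests have power against strong spatial-lag dependence", {
  zero6 <- setNames(rep(0, 6), c("HC", "PG", "PD", "ES", "URB", "IND"))
  hits <- 0; sig <- 0
  for (r in 1:20) {
    # pure SAR data: common rho, no spatially lagged covariates
    sim <- simulate_panel(dgp_spec(n = 20, T_ = 6, rho1 = 0.5, rho2 = 0.5,
                                   theta = zero6, seed = 100 + r))
    res <- lm_tests(sim$panel, sim$w)
    if (res$lm_lag$statistic > res$lm_error$statistic) hits <- hits + 1
    if (res$lm_lag$p < 0.05) sig <- sig + 1
  }
  expect_gte(hits, 14)  # LM-lag should usually dominate under SAR-type data
  expect_gte(sig, 16)   # and reject the non-spatial null almost always
})

test_that("chi-square p-values decrease in the statistic at fixed df", {
  p1 <- pchisq(2, 1, lower.tail = FALSE)
  stats_seq <- c(0.5, 1, 2, 5, 10)
  pv <- pchisq(stats_seq, df = 1, lower.tail = FALSE)
  expect_true(all(diff(pv) < 0))
  expect_equal(pchisq(2, 1, lower.tail = FALSE), p1)
})

test_that("LR test handles identical and nested fits", {
  sim <- simulate_panel(dgp_spec(n = 10, T_ = 5, seed = 41))
  sdm <- fit_comparison(sim$panel, sim$w, "sdm")
  sar <- fit_comparison(sim$panel, sim$w, "sar")
  same <- lr_test(sdm, sdm)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lr <- lr_test(sdm, sar)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 6L)
  expect_error(lr_test(sar, sdm), "not nested")
})

test_that("single-constraint Wald equals the squared z statistic", {
  sim <- simulate_panel(dgp_spec(n = 12, T_ = 6, seed = 19))
  fit <- fit_two_regime_sdm(sim$panel, sim$w)
  ct <- fit$coef_table
  term <- "beta_PG"
  R <- setNames(1, term)
  wt <- wald_test(fit, R)
  zsq <- (ct$estimate[ct$term == term] / ct$se[ct$term == term])^2
  expect_equal(wt$statistic, zsq, tolerance = 1e-8)
  # constraint exactly satisfied at the estimate -> statistic 0
  wt0 <- wald_test(fit, R, r = ct$estimate[ct$term == term])
  expect_equal(wt0$statistic, 0, tolerance = 1e-10)
})

test_that("Wald and LR agree asymptotically for the SDM reduction", {
  set.seed(61)
  ratios <- replicate(5, {
    sim <- simulate_panel(dgp_spec(n = 20, T_ = 10,
                                   seed = sample.int(1e6, 1)))
    sdm <- fit_comparison(sim$panel, sim$w, "sdm")
    sar <- fit_comparison(sim$panel, sim$w, "sar")
    theta_names <- grep("^theta_", sdm$coef_table$term, value = TRUE)
    Rm <- diag(6); colnames(Rm) <- theta_names
    wald_test(sdm, Rm)$statistic / max(lr_test(sdm, sar)$statistic, 1e-9)
  })
  # same chi-square(6) limit: ratios should hover near 1
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("Hausman test runs, errors on T=1, and detects correlated effects", {
  sim <- simulate_panel(dgp_spec(n = 20, T_ = 8, seed = 77))
  h <- hausman_test(sim$panel)
  expect_equal(h$df, 6L)
  expect_true(h$p >= 0 && h$p <= 1)

  p1 <- sim$panel
  p1$years <- p1$years[1]
  p1$outcome <- p1$outcome[, 1, drop = FALSE]
  p1$covariates <- lapply(p1$covariates, function(m) m[, 1, drop = FALSE])
  expect_error(hausman_test(p1), "T = 1")

  # effects strongly correlated with a covariate: FE and RE should diverge
  rej <- 0
  for (r in 1:20) {
    sim2 <- simulate_panel(dgp_spec(n = 25, T_ = 6, sigma_mu = 0,
                                    seed = 300 + r))
    p2 <- sim2$panel
    mu_corr <- 3 * scale(rowMeans(p2$covariates$PG))[, 1]
    p2$outcome <- p2$outcome + mu_corr
    if (hausman_test(p2)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej, 15)
})

test_that("the full battery returns every section", {
  sim <- simulate_panel(dgp_spec(n = 12, T_ = 6, seed = 55))
  bat <- model_selection_battery(sim$panel, sim$w)
  expect_named(bat, c("fits", "lm", "lr_sdm_sar", "wald_sdm_sar", "hausman"))
  expect_named(bat$fits, c("ols", "sar", "sem", "sdm"))
  lls <- vapply(bat$fits[c("sar", "sdm")], function(f) f$loglik, numeric(1))
  expect_gte(lls["sdm"], lls["sar"] - 1e-6)
})
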