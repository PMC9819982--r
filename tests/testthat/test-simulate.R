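test_that("simulation is deterministic in the seed", {
  s1 <- simulate_panel(dgp_spec(n = 8, T_ = 4, seed = 7))
  s2 <- simulate_panel(dgp_spec(n = 8, T_ = 4, seed = 7))
  expect_identical(s1$panel$outcome, s2$panel$outcome)
  expect_identical(s1$regime$d, s2$regime$d)
  s3 <- simulate_panel(dgp_spec(n = 8, T_ = 4, seed = 8))
  expect_false(identical(s1$panel$outcome, s3$panel$outcome))
})

test_that("covariates are positive, fractions bounded, persistence as set", {
  spec0 <- dgp_spec(n = 12, T_ = 10, ar1 = 0, seed = 2)
  spec9 <- dgp_spec(n = 12, T_ = 10, ar1 = 0.9, seed = 2)
  ac1 <- function(m) {
    cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  }
  a0 <- a9 <- numeric(30)
  for (r in 1:30) {
    c0 <- generate_covariates(spec0, seed = 1000 + r)
    c9 <- generate_covariates(spec9, seed = 1000 + r)
    a0[r] <- ac1(log(c0$PG))
    a9[r] <- ac1(log(c9$PG))
    if (r == 1) {
      expect_true(all(unlist(c0[c("HC", "PG", "PD", "ES")]) > 0))
      expect_true(all(unlist(c0[c("URB", "IND")]) >= 0 &
                        unlist(c0[c("URB", "IND")]) <= 1))
    }
  }
  expect_lt(abs(mean(a0)), 0.1)
  expect_true(mean(a9) > 0.75 && mean(a9) < 0.95)
})

test_that("simulated panels satisfy the regime self-consistency exactly", {
  for (seed in c(3, 14, 27)) {
    sim <- simulate_panel(dgp_spec(n = 10, T_ = 6, seed = seed))
    d_check <- build_regime_indicator(sim$panel$outcome, sim$w)
    expect_identical(unname(d_check$d), unname(sim$regime$d))
  }
})

test_that("plugging truth into the model equation recovers the drawn noise", {
  spec <- dgp_spec(n = 9, T_ = 5, seed = 11)
  sim <- simulate_panel(spec)
  W <- sim$w$w
  Y <- sim$panel$outcome
  d <- sim$regime$d
  WY <- W %*% Y
  xb <- matrix(0, 9, 5)
  for (nm in names(sim$panel$covariates)) {
    Xk <- sim$panel$covariates[[nm]]
    xb <- xb + spec$beta[[nm]] * Xk + spec$theta[[nm]] * (W %*% Xk)
  }
  eps_implied <- Y - spec$rho1 * d * WY - spec$rho2 * (1 - d) * WY -
    xb - sim$mu - rep(sim$lambda, each = 9)
  expect_equal(unname(eps_implied), unname(sim$eps), tolerance = 1e-10)
})

test_that("equal regime coefficients reduce to the closed-form solution", {
  spec <- dgp_spec(n = 8, T_ = 4, rho1 = 0.3, rho2 = 0.3, seed = 19)
  sim <- simulate_panel(spec)
  W <- sim$w$w
  xb <- matrix(0, 8, 4)
  for (nm in names(sim$panel$covariates)) {
    Xk <- sim$panel$covariates[[nm]]
    xb <- xb + spec$beta[[nm]] * Xk + spec$theta[[nm]] * (W %*% Xk)
  }
  rhs <- xb + sim$mu + rep(sim$lambda, each = 8) + sim$eps
  Y_closed <- solve(diag(8) - 0.3 * W) %*% rhs
  expect_equal(unname(sim$panel$outcome), unname(Y_closed), tolerance = 1e-10)
})

test_that("a fully null process yields a zero outcome in regime 0", {
  zero6 <- setNames(rep(0, 6), c("HC", "PG", "PD", "ES", "URB", "IND"))
  spec <- dgp_spec(n = 6, T_ = 3, beta = zero6, theta = zero6,
                   sigma_eps = 0, sigma_mu = 0, sigma_lambda = 0, seed = 1)
  sim <- simulate_panel(spec)
  expect_true(all(sim$panel$outcome == 0))
  expect_true(all(sim$regime$d == 0))
})

test_that("regime shares stay in a balanced band across replicates", {
  shares <- vapply(1:30, function(r) {
    mean(simulate_panel(dgp_spec(n = 12, T_ = 6, seed = 400 + r))$regime$d)
  }, numeric(1))
  expect_true(mean(shares) > 0.3 && mean(shares) < 0.7)
})

test_that("recovery experiments are reproducible and well-formed", {
  spec <- dgp_spec(n = 8, T_ = 5, seed = 1)
  r1 <- recovery_experiment(spec, n_replicates = 10, seed = 5)
  r2 <- recovery_experiment(spec, n_replicates = 10, seed = 5)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$summary, r2$summary)
  s <- r1$summary
  expect_equal(s$n_replicates, 10)
  expect_true(all(c("bias_rho1", "bias_rho2", "coverage_rho1",
                    "coverage_rho2", "verdict_accuracy") %in% names(s)))
  expect_true(s$coverage_rho1 >= 0 && s$coverage_rho1 <= 1)
})
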