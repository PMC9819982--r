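# Shared fixtures and independent oracle implementations.
# Oracles are deliberately naive (double loops, explicit determinants) and
# never call the package code paths they are used to check.

# 4-cycle contiguity weights A-B-C-D-A
four_cycle_weights <- function(standardize = TRUE) {
  adj <- data.frame(region_a = c("A", "B", "C", "D"),
                    region_b = c("B", "C", "D", "A"))
  w <- build_contiguity(adj, c("A", "B", "C", "D"))
  if (standardize) row_standardize(w) else w
}

# Minimal valid balanced panel with arbitrary but legal values.
toy_panel <- function(n = 4, T_ = 3, seed = 42) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n)]
  mk <- function(lo, hi) matrix(stats::runif(n * T_, lo, hi), n, T_)
  panel_data(outcome = matrix(stats::rnorm(n * T_), n, T_),
             covariates = list(HC = mk(20, 80), PG = mk(1, 10),
                               PD = mk(100, 900), ES = mk(0.5, 2),
                               URB = mk(0.3, 0.9), IND = mk(0.2, 0.6)),
             region_ids = ids, years = seq(2005, length.out = T_))
}

# Naive global Moran's I: literal double loop over the defining formula.
naive_global_moran <- function(x, wmat) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- sum((x - xbar)^2) / n
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + wmat[i, j] * (x[i] - xbar) * (x[j] - xbar)
    s0 <- s0 + wmat[i, j]
  }
  num / (s2 * s0)
}

# Naive local Moran's I_i.
naive_local_moran <- function(x, wmat) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- sum((x - xbar)^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + wmat[i, j] * (x[j] - xbar)
    out[i] <- (x[i] - xbar) * acc / s2
  }
  out
}

# Explicit two-way demeaning by loops (independent of within_transform).
naive_demean <- function(m) {
  n <- nrow(m); T_ <- ncol(m)
  out <- m
  rm_ <- rowSums(m) / T_
  cm_ <- colSums(m) / n
  gm <- sum(m) / (n * T_)
  for (i in seq_len(n)) for (t in seq_len(T_)) {
    out[i, t] <- m[i, t] - rm_[i] - cm_[t] + gm
  }
  out
}

# Naive two-regime SDM log-likelihood: explicit per-period determinant and
# residuals on naively demeaned data.
naive_two_regime_loglik <- function(panel, wmat, d, rho1, rho2,
                                    delta, sigma2) {
  n <- nrow(panel$outcome); T_ <- ncol(panel$outcome)
  Yt <- naive_demean(panel$outcome)
  WY <- wmat %*% panel$outcome
  L1 <- naive_demean(d * WY)
  L2 <- naive_demean((1 - d) * WY)
  Zc <- list()
  for (nm in names(panel$covariates)) {
    Zc[[paste0("beta_", nm)]] <- naive_demean(panel$covariates[[nm]])
  }
  for (nm in names(panel$covariates)) {
    Zc[[paste0("theta_", nm)]] <- naive_demean(wmat %*% panel$covariates[[nm]])
  }
  ld <- 0
  rss <- 0
  for (t in seq_len(T_)) {
    A <- diag(n) - (rho1 * d[, t] + rho2 * (1 - d[, t])) * wmat
    ld <- ld + log(det(A))
    e_t <- Yt[, t] - rho1 * L1[, t] - rho2 * L2[, t]
    for (nm in names(Zc)) e_t <- e_t - delta[[nm]] * Zc[[nm]][, t]
    rss <- rss + sum(e_t^2)
  }
  N <- n * T_
  -(N / 2) * log(2 * pi * sigma2) + ld - rss / (2 * sigma2)
}

# Concentrated version of the naive likelihood: profile out delta and
# sigma2 by least squares on the naively demeaned stacked data.
naive_profile_loglik <- function(panel, wmat, d, rho1, rho2) {
  n <- nrow(panel$outcome); T_ <- ncol(panel$outcome)
  Yt <- as.vector(naive_demean(panel$outcome))
  WY <- wmat %*% panel$outcome
  L1 <- as.vector(naive_demean(d * WY))
  L2 <- as.vector(naive_demean((1 - d) * WY))
  Zc <- cbind(
    do.call(cbind, lapply(panel$covariates,
                          function(m) as.vector(naive_demean(m)))),
    do.call(cbind, lapply(panel$covariates,
                          function(m) as.vector(naive_demean(wmat %*% m)))))
  ld <- 0
  for (t in seq_len(T_)) {
    A <- diag(n) - (rho1 * d[, t] + rho2 * (1 - d[, t])) * wmat
    ld <- ld + log(det(A))
  }
  ystar <- Yt - rho1 * L1 - rho2 * L2
  e <- stats::lm.fit(Zc, ystar)$residuals
  N <- n * T_
  s2 <- sum(e^2) / N
  -(N / 2) * log(2 * pi * s2) + ld - N / 2
}
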