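new_test_result <- function(name, statistic, df, p, note = "") {
  structure(list(name = name, statistic = statistic, df = df, p = p,
                 note = note),
            class = "spec_test_result")
}

#' @export
print.spec_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f (df %d), p = %.4g %s\n",
              x$name, x$statistic, x$df, x$p,
              if (nzchar(x$note)) paste0("[", x$note, "]") else ""))
  invisible(x)
}

# Projection matrix of the within transformation on the stacked
# (region-fastest, period-major) data vector.
within_projector <- function(n, T_, effects) {
  Pn <- diag(n) - matrix(1 / n, n, n)
  PT <- diag(T_) - matrix(1 / T_, T_, T_)
  switch(effects,
         two_way = kronecker(PT, Pn),
         unit = kronecker(PT, diag(n)),
         time = kronecker(diag(T_), Pn),
         none = diag(n * T_),
         stop("unknown effects: ", effects))
}

#' Lagrange-multiplier tests for spatial dependence
#'
#' LM-lag and LM-error score tests and their robust variants (each robust
#' to the other alternative), computed from the residuals of a pooled OLS
#' fit on within-transformed data with a block-diagonal `I_T (x) W`
#' weight structure. Because the within transformation correlates the
#' residuals -- after time-effect demeaning `E[e'(I_T (x) W)e]` is
#' `-(T-1) sigma^2`, not 0 -- the scores `e'We` and `e'Wy` are centred
#' and scaled by their exact null moments under demeaning (quadratic-form
#' moments of `B = H (I_T (x) W) H`, with `H` the residual projector of
#' the demeaned regression), rather than by the cross-section plug-in
#' `tr(W'W + W^2)` that assumes untransformed iid errors and over-rejects
#' on demeaned panels. Each statistic is chi-square with 1 df; together
#' the four tests guide the choice between lag, error and Durbin
#' specifications before any spatial model is fitted.
#'
#' @param p a `panel_data`.
#' @param w a `spatial_weights` (row-standardized automatically).
#' @param effects within transformation, as in [fit_two_regime_sdm()].
#' @return named list of four `spec_test_result`s:
#'   `lm_lag`, `lm_error`, `robust_lm_lag`, `robust_lm_error`.
#' @export
lm_tests <- function(p, w, effects = "two_way") {
  if (!w$standardized) w <- row_standardize(w)
  pd <- prep_design(p, w, effects, include_wx = FALSE)
  W <- pd$W; n <- pd$n; T_ <- pd$T
  Z <- pd$Z; qz <- pd$qz; yv <- pd$yv
  e <- qr.resid(qz, yv)

  Wbig <- kronecker(diag(T_), W)
  Q <- within_projector(n, T_, effects)
  Pz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  H <- Q - Pz               # idempotent residual-maker on the demeaned space
  nu <- sum(diag(H))
  sigma2 <- sum(e^2) / nu
  B <- H %*% Wbig %*% H
  trB <- sum(diag(B))
  # variance of e'We/sigma2, accounting for the shared sigma2 estimate
  Tq <- sum(B * B) + sum(B * t(B)) - 2 * trB^2 / nu

  s_lam <- sum(e * (Wbig %*% e)) / sigma2 - trB
  fitted <- as.vector(Q %*% yv) - e     # P_Z y on the demeaned space
  Wxb <- Wbig %*% fitted
  Gq <- sum(Wxb * (H %*% Wxb)) / sigma2
  s_rho <- sum(e * (Wbig %*% yv)) / sigma2 - trB

  lm_lag <- s_rho^2 / (Gq + Tq)
  lm_err <- s_lam^2 / Tq
  rlm_lag <- (s_rho - s_lam)^2 / Gq
  shrink <- Tq / (Gq + Tq)
  rlm_err <- (s_lam - shrink * s_rho)^2 / (Tq * (1 - shrink))
  pval <- function(s) stats::pchisq(s, df = 1, lower.tail = FALSE)
  list(
    lm_lag = new_test_result("LM spatial lag", lm_lag, 1L, pval(lm_lag)),
    lm_error = new_test_result("LM spatial error", lm_err, 1L, pval(lm_err)),
    robust_lm_lag = new_test_result("Robust LM lag", rlm_lag, 1L,
                                    pval(rlm_lag)),
    robust_lm_error = new_test_result("Robust LM error", rlm_err, 1L,
                                      pval(rlm_err)))
}

#' Likelihood-ratio test of nested fits
#'
#' `2 * (loglik_full - loglik_restricted)` compared to chi-square with df
#' equal to the difference in parameter counts. A statistic below `-1e-6`
#' signals a convergence failure in one of the fits and is an error.
#'
#' @param full,restricted fitted models carrying `loglik` and `n_params`
#'   (any `sdm_fit` or `two_regime_sdm_fit`).
#' @return a `spec_test_result`.
#' @export
lr_test <- function(full, restricted) {
  df <- full$n_params - restricted$n_params
  if (df < 0) stop("models are not nested: restricted has more parameters")
  stat <- 2 * (full$loglik - restricted$loglik)
  if (stat < -1e-6) {
    stop("negative LR statistic (", format(stat),
         "): likely convergence failure")
  }
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (df == 0 && stat > 1e-6) p <- NA_real_
  new_test_result(
    sprintf("LR %s vs %s", full$model, restricted$model), stat,
    as.integer(max(df, 0)), p)
}

#' Wald test of linear restrictions
#'
#' Tests `R b = r` with statistic `(Rb - r)' (R V R')^{-1} (Rb - r)`,
#' chi-square with `rank(R)` degrees of freedom, using the fit's
#' estimates and covariance matrix.
#'
#' @param fit a fitted model with `vcov` and a `coef_table`.
#' @param R restriction matrix with columns named after parameters (or a
#'   single named numeric vector for one restriction).
#' @param r right-hand-side vector (default zeros).
#' @return a `spec_test_result`.
#' @export
wald_test <- function(fit, R, r = NULL) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1, dimnames = list(NULL, names(R)))
  if (is.null(colnames(R))) stop("R must have parameter names as colnames")
  est <- stats::setNames(fit$coef_table$estimate, fit$coef_table$term)
  V <- fit$vcov
  miss <- setdiff(colnames(R), rownames(V))
  if (length(miss)) stop("parameters not in covariance matrix: ",
                         paste(miss, collapse = ", "))
  b <- est[colnames(R)]
  Vb <- V[colnames(R), colnames(R), drop = FALSE]
  if (is.null(r)) r <- rep(0, nrow(R))
  dev <- as.vector(R %*% b) - r
  RVR <- R %*% Vb %*% t(R)
  qrr <- qr(RVR)
  if (qrr$rank < nrow(R)) stop("rank-deficient R V R' in Wald test")
  stat <- as.numeric(crossprod(dev, solve(RVR, dev)))
  df <- nrow(R)
  new_test_result("Wald", stat, as.integer(df),
                  stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Hausman test of fixed versus random effects
#'
#' The classical Hausman contrast between the within (fixed-effects)
#' estimator and the Swamy-Arora random-effects GLS estimator of the
#' non-spatial panel regression of RS on the covariates -- the standard
#' screening step before committing to fixed effects. Year dummies are
#' included in both estimators so common time shocks are not left in the
#' error, and only the covariate slopes enter the contrast. Because the
#' contrast is identified from between-unit variation, the p-value uses
#' the finite-sample `F(k, n - k - 1)` reference rather than the
#' chi-square limit, which over-rejects at small n. A
#' non-positive-definite difference matrix triggers a Moore-Penrose
#' fallback flagged in the result's note.
#'
#' @param p a `panel_data` with at least 2 periods.
#' @param x_names covariates to include (default all six).
#' @return a `spec_test_result` with df = number of regressors.
#' @export
hausman_test <- function(p, x_names = PANEL_COVARIATES) {
  n <- length(p$region_ids); T_ <- length(p$years); N <- n * T_
  if (T_ < 2) stop("within estimator undefined for T = 1")
  k <- length(x_names)
  y <- p$outcome
  Xl <- p$covariates[x_names]

  # within (FE) estimator: two-way demeaning = unit demeaning + year dummies
  yw <- as.vector(within_transform(y, "two_way"))
  Xw <- do.call(cbind, lapply(Xl, function(m)
    as.vector(within_transform(m, "two_way"))))
  colnames(Xw) <- x_names
  fw <- stats::lm.fit(Xw, yw)
  b_fe <- fw$coefficients
  s2_e <- sum(fw$residuals^2) / (N - n - (T_ - 1) - k)
  V_fe <- chol2inv(chol(crossprod(Xw))) * s2_e

  # between regression for the Swamy-Arora variance components
  yb <- rowMeans(y)
  Xb <- cbind(1, do.call(cbind, lapply(Xl, rowMeans)))
  fb <- stats::lm.fit(Xb, yb)
  s2_b <- sum(fb$residuals^2) / (n - k - 1)
  s2_u <- max(s2_b - s2_e / T_, 0)
  theta <- 1 - sqrt(s2_e / (T_ * s2_u + s2_e))

  # RE GLS by quasi-demeaning, with year dummies among the regressors
  dummies <- kronecker(diag(T_)[, -1, drop = FALSE], rep(1, n))
  colnames(dummies) <- paste0("yr", p$years[-1])
  qd <- function(m) as.vector(m - theta * rowMeans(m))
  yq <- qd(y)
  Xq <- cbind(`(Intercept)` = 1 - theta,
              do.call(cbind, lapply(Xl, qd)),
              apply(dummies, 2, function(v) qd(matrix(v, n, T_))))
  colnames(Xq) <- c("(Intercept)", x_names, colnames(dummies))
  fq <- stats::lm.fit(Xq, yq)
  b_re <- fq$coefficients[x_names]
  V_re_full <- chol2inv(chol(crossprod(Xq))) * s2_e
  dimnames(V_re_full) <- list(colnames(Xq), colnames(Xq))
  V_re <- V_re_full[x_names, x_names]

  dif <- b_fe - b_re
  Vd <- V_fe - V_re
  note <- ""
  stat <- tryCatch(
    as.numeric(crossprod(dif, solve(Vd, dif))),
    error = function(e) NA_real_)
  ev <- eigen(Vd, symmetric = TRUE, only.values = TRUE)$values
  if (!is.finite(stat) || stat < 0 || min(ev) < -1e-8 * max(abs(ev))) {
    stat <- as.numeric(crossprod(dif, MASS::ginv(Vd) %*% dif))
    stat <- max(stat, 0)
    note <- "non-positive-definite difference matrix; Moore-Penrose inverse used"
  }
  # finite-sample F reference: the FE/RE contrast is identified from
  # between-unit variation, so n - k - 1 residual df, not the chi-square
  # limit, governs its null at small n
  if (n > k + 1) {
    p <- stats::pf(stat / k, k, n - k - 1, lower.tail = FALSE)
  } else {
    p <- stats::pchisq(stat, df = k, lower.tail = FALSE)
  }
  new_test_result("Hausman FE vs RE", stat, as.integer(k), p, note)
}

#' Run the full model-selection battery
#'
#' OLS/SAR/SEM/SDM comparison fits, the four LM diagnostics, LR and Wald
#' tests of reducing the SDM to SAR (theta = 0), and the Hausman FE/RE
#' screen -- the complete pre-estimation battery, in one call.
#'
#' @inheritParams lm_tests
#' @return list with `fits` (named list of comparison fits), `lm` (the LM
#'   battery), `lr_sdm_sar`, `wald_sdm_sar` and `hausman`.
#' @export
model_selection_battery <- function(p, w, effects = "two_way") {
  if (!w$standardized) w <- row_standardize(w)
  fits <- lapply(stats::setNames(c("ols", "sar", "sem", "sdm"),
                                 c("ols", "sar", "sem", "sdm")),
                 function(m) fit_comparison(p, w, model = m, effects = effects))
  theta_names <- grep("^theta_", fits$sdm$coef_table$term, value = TRUE)
  Rm <- diag(length(theta_names))
  colnames(Rm) <- theta_names
  list(fits = fits,
       lm = lm_tests(p, w, effects = effects),
       lr_sdm_sar = lr_test(fits$sdm, fits$sar),
       wald_sdm_sar = wald_test(fits$sdm, Rm),
       hausman = hausman_test(p))
}
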