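#' Regime indicator from outcome versus spatial lag
#'
#' For each region-year cell, the regime indicator is 1 iff the outcome
#' strictly exceeds its spatial lag (the neighbour average under a
#' row-standardized W): regions regulating harder than their competitors
#' are in regime 1, the rest in regime 0. Ties (outcome exactly equal to
#' the lag) fall in regime 0 by the strict inequality.
#'
#' @param Y numeric `[n x T]` outcome matrix.
#' @param w a row-standardized `spatial_weights`.
#' @param source provenance tag, `"observed"` or `"simulated"`.
#' @return a `regime_panel`: 0/1 matrix `d`, the source tag, and per-period
#'   counts of regime-1 units.
#' @export
build_regime_indicator <- function(Y, w, source = "observed") {
  stopifnot(inherits(w, "spatial_weights"))
  if (!w$standardized) stop("regime indicator requires a row-standardized W")
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(w$w)) stop("shape mismatch: Y rows != weight matrix size")
  lag <- w$w %*% Y
  d <- (Y > lag) * 1
  dimnames(d) <- dimnames(Y)
  structure(list(d = d, source = source, regime1_counts = colSums(d)),
            class = "regime_panel")
}

#' @export
print.regime_panel <- function(x, ...) {
  cat(sprintf("regime_panel (%s): %d x %d, regime-1 share %.2f\n",
              x$source, nrow(x$d), ncol(x$d), mean(x$d)))
  invisible(x)
}

# Two-way / one-way within transformation of an n x T matrix.
within_transform <- function(m, effects = "two_way") {
  switch(effects,
         two_way = m - rowMeans(m) -
           rep(colMeans(m), each = nrow(m)) + mean(m),
         unit = m - rowMeans(m),
         time = m - rep(colMeans(m), each = nrow(m)),
         none = m,
         stop("unknown effects: ", effects))
}

# Shared design-matrix prep for all spatial ML fits. Stacks the within-
# transformed covariates (and optionally their spatial lags) column-major:
# all regions for year 1, then year 2, ...
prep_design <- function(p, w, effects, include_wx = TRUE) {
  W <- w$w
  Xs <- p$covariates
  cols <- list()
  for (nm in names(Xs)) {
    cols[[paste0("beta_", nm)]] <- as.vector(within_transform(Xs[[nm]], effects))
  }
  if (include_wx) {
    for (nm in names(Xs)) {
      cols[[paste0("theta_", nm)]] <-
        as.vector(within_transform(W %*% Xs[[nm]], effects))
    }
  }
  Z <- do.call(cbind, cols)
  if (effects == "none") Z <- cbind(`(Intercept)` = 1, Z)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    drop_idx <- qz$pivot[seq(qz$rank + 1, ncol(Z))]
    stop("collinear regressors: ", paste(colnames(Z)[drop_idx], collapse = ", "))
  }
  list(Z = Z, qz = qz,
       yv = as.vector(within_transform(p$outcome, effects)),
       n = nrow(W), T = ncol(p$outcome), W = W)
}

# Sum over periods of log|I - rho1 D_t W - rho2 (1 - D_t) W|. `d` is the
# n x T regime matrix; for single-regime models pass d = 1 and rho2 = 0.
logdet_regime <- function(rho1, rho2, W, d, T_) {
  n <- nrow(W)
  if (identical(d, 1)) d <- matrix(1, n, T_)
  tot <- 0
  for (t in seq_len(T_)) {
    coef <- rho1 * d[, t] + rho2 * (1 - d[, t])
    A <- diag(n) - coef * W
    ld <- determinant(A, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    tot <- tot + as.numeric(ld$modulus)
  }
  tot
}

#' Fit the two-regime spatial Durbin panel model by maximum likelihood
#'
#' Estimates
#' \deqn{Y_{it} = \rho_1 d_{it} (WY_t)_i + \rho_2 (1-d_{it}) (WY_t)_i +
#'   X_{it}\beta + (WX_t)_i\theta + \mu_i + \lambda_t + \varepsilon_{it}}
#' where the regime indicator `d` ([build_regime_indicator()]) is held
#' fixed at its observed value. Fixed effects are removed by the within
#' transformation; for each \eqn{(\rho_1, \rho_2)} the slope parameters and
#' error variance are concentrated out by least squares, and the
#' concentrated log-likelihood
#' \deqn{\ell_c(\rho_1,\rho_2) = -\frac{nT}{2}\log\hat\sigma^2 +
#'   \sum_t \log|I - \rho_1 D_t W - \rho_2 (1-D_t) W|}
#' is maximized by a 21 x 21 coarse grid followed by bounded quasi-Newton
#' polish (no random starts). Standard errors come from the numerical
#' Hessian of the full likelihood. If one regime is empty in every period
#' its coefficient is unidentified and reported as `NA`.
#'
#' @param p a `panel_data`.
#' @param w a `spatial_weights` (row-standardized automatically if not).
#' @param effects fixed effects: `"two_way"` (default), `"unit"`,
#'   `"time"` or `"none"`.
#' @param regime optional precomputed `regime_panel`; by default built
#'   from `p$outcome` and `w`.
#' @return object of class `two_regime_sdm_fit` with the coefficient table
#'   (estimate, se, z, p), `rho1`, `rho2`, `sigma2`, `loglik`, `adj_r2`,
#'   the covariance matrix, the regime panel and a strategy verdict.
#' @export
fit_two_regime_sdm <- function(p, w, effects = "two_way", regime = NULL) {
  if (!w$standardized) w <- row_standardize(w)
  if (is.null(regime)) regime <- build_regime_indicator(p$outcome, w)
  d <- regime$d
  pd <- prep_design(p, w, effects, include_wx = TRUE)
  W <- pd$W; n <- pd$n; T_ <- pd$T; N <- n * T_
  WY <- W %*% p$outcome
  L1 <- as.vector(within_transform(d * WY, effects))
  L2 <- as.vector(within_transform((1 - d) * WY, effects))
  ident <- c(rho1 = stats::sd(L1) > 1e-12, rho2 = stats::sd(L2) > 1e-12)
  if (!any(ident)) stop("no spatial variation: both regime lags degenerate")

  e0 <- qr.resid(pd$qz, pd$yv)
  e1 <- qr.resid(pd$qz, L1)
  e2 <- qr.resid(pd$qz, L2)

  conc_ll <- function(r1, r2) {
    ld <- logdet_regime(r1, r2, W, d, T_)
    if (!is.finite(ld)) return(-Inf)
    e <- e0 - r1 * e1 - r2 * e2
    -(N / 2) * log(sum(e^2) / N) + ld
  }

  grid <- seq(-0.9, 0.9, length.out = 21)
  if (all(ident)) {
    gv <- outer(grid, grid, Vectorize(conc_ll))
    best <- which(gv == max(gv), arr.ind = TRUE)[1, ]
    start <- c(grid[best[1]], grid[best[2]])
    opt <- stats::optim(start, function(r) -conc_ll(r[1], r[2]),
                        method = "L-BFGS-B",
                        lower = c(-0.99, -0.99), upper = c(0.99, 0.99),
                        control = list(factr = 1e4))
    rho <- c(rho1 = opt$par[1], rho2 = opt$par[2])
  } else {
    which_id <- names(ident)[ident]
    f1 <- if (ident[["rho1"]]) function(r) conc_ll(r, 0) else function(r) conc_ll(0, r)
    start <- grid[which.max(vapply(grid, f1, numeric(1)))]
    opt <- stats::optim(start, function(r) -f1(r), method = "L-BFGS-B",
                        lower = -0.99, upper = 0.99,
                        control = list(factr = 1e4))
    rho <- c(rho1 = NA_real_, rho2 = NA_real_)
    rho[which_id] <- opt$par
  }
  converged <- opt$convergence == 0
  r1 <- if (is.na(rho[1])) 0 else rho[1]
  r2 <- if (is.na(rho[2])) 0 else rho[2]

  ystar <- pd$yv - r1 * L1 - r2 * L2
  delta <- qr.coef(pd$qz, ystar)
  e <- e0 - r1 * e1 - r2 * e2
  sigma2 <- sum(e^2) / N
  ld <- logdet_regime(r1, r2, W, d, T_)
  loglik <- -(N / 2) * log(2 * pi * sigma2) + ld - N / 2

  # admissibility at the optimum: spectral radius of the regime-mixed lag
  sr <- max(vapply(seq_len(T_), function(t) {
    coef <- r1 * d[, t] + r2 * (1 - d[, t])
    max(abs(eigen(coef * W, only.values = TRUE)$values))
  }, numeric(1)))
  if (sr >= 1) stop("inadmissible optimum: spectral radius ", format(sr))

  # full-likelihood numerical Hessian for standard errors
  rho_id <- names(ident)[ident]
  par <- c(rho[rho_id], delta, sigma2)
  names(par) <- c(rho_id, colnames(pd$Z), "sigma2")
  full_ll <- function(pv) {
    rr1 <- if ("rho1" %in% rho_id) pv[match("rho1", names(par))] else 0
    rr2 <- if ("rho2" %in% rho_id) pv[match("rho2", names(par))] else 0
    dl <- pv[seq(length(rho_id) + 1, length(pv) - 1)]
    s2 <- pv[length(pv)]
    if (s2 <= 0) return(-Inf)
    ldp <- logdet_regime(rr1, rr2, W, d, T_)
    if (!is.finite(ldp)) return(-Inf)
    ee <- pd$yv - rr1 * L1 - rr2 * L2 - pd$Z %*% dl
    -(N / 2) * log(2 * pi * s2) + ldp - sum(ee^2) / (2 * s2)
  }
  H <- stats::optimHess(par, full_ll)
  V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
  dimnames(V) <- list(names(par), names(par))
  se <- sqrt(pmax(diag(V), 0))

  est <- c(rho, delta, sigma2 = sigma2)
  se_full <- stats::setNames(rep(NA_real_, length(est)), names(est))
  se_full[names(par)] <- se
  zv <- est / se_full
  coef_table <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se_full),
    z = unname(zv), p = unname(2 * stats::pnorm(-abs(zv))),
    stringsAsFactors = FALSE)

  sst <- sum((pd$yv - mean(pd$yv))^2)
  k <- length(rho_id) + ncol(pd$Z)
  adj_r2 <- 1 - (sum(e^2) / (N - k)) / (sst / (N - 1))

  fit <- structure(list(
    model = "two_regime_sdm",
    rho1 = unname(rho[1]), rho2 = unname(rho[2]),
    beta = delta[grep("^beta_", names(delta))],
    theta = delta[grep("^theta_", names(delta))],
    sigma2 = sigma2, loglik = loglik, adj_r2 = adj_r2,
    coef_table = coef_table, vcov = V,
    n = n, T = T_, effects = effects,
    n_params = k + 1, converged = converged,
    identified = ident, regime_panel = regime),
    class = c("two_regime_sdm_fit", "sdm_fit"))
  fit$verdict <- classify_strategy(fit)
  fit
}

#' @export
print.two_regime_sdm_fit <- function(x, ...) {
  cat(sprintf("Two-regime SDM (%s effects): n=%d, T=%d\n",
              x$effects, x$n, x$T))
  cat(sprintf("  rho1 = %.4f, rho2 = %.4f  ->  %s\n",
              x$rho1, x$rho2, x$verdict$label))
  cat(sprintf("  loglik = %.3f, adj R2 = %.3f, sigma2 = %.4f\n",
              x$loglik, x$adj_r2, x$sigma2))
  invisible(x)
}

#' Evaluate the two-regime SDM log-likelihood
#'
#' Computes the full log-likelihood of the two-regime model at given
#' spatial coefficients, either at supplied slope/variance values or --
#' when `delta`/`sigma2` are `NULL` -- at their concentrated (profiled)
#' maximizers for that `(rho1, rho2)`. Useful for likelihood diagnostics,
#' profile plots and reduction checks against single-regime fits.
#'
#' @inheritParams fit_two_regime_sdm
#' @param rho1,rho2 spatial-reaction coefficients (admissible).
#' @param delta optional named vector over the design columns
#'   (`beta_HC ... theta_IND`).
#' @param sigma2 optional error variance.
#' @return scalar log-likelihood.
#' @export
two_regime_loglik <- function(p, w, rho1, rho2, delta = NULL, sigma2 = NULL,
                              effects = "two_way", regime = NULL) {
  if (!w$standardized) w <- row_standardize(w)
  if (is.null(regime)) regime <- build_regime_indicator(p$outcome, w)
  d <- regime$d
  pd <- prep_design(p, w, effects, include_wx = TRUE)
  N <- pd$n * pd$T
  WY <- pd$W %*% p$outcome
  L1 <- as.vector(within_transform(d * WY, effects))
  L2 <- as.vector(within_transform((1 - d) * WY, effects))
  ld <- logdet_regime(rho1, rho2, pd$W, d, pd$T)
  if (!is.finite(ld)) stop("inadmissible (rho1, rho2): singular Jacobian")
  ystar <- pd$yv - rho1 * L1 - rho2 * L2
  if (is.null(delta)) {
    e <- qr.resid(pd$qz, ystar)
  } else {
    e <- ystar - pd$Z %*% delta[colnames(pd$Z)]
  }
  if (is.null(sigma2)) sigma2 <- sum(e^2) / N
  -(N / 2) * log(2 * pi * sigma2) + ld - sum(e^2) / (2 * sigma2)
}

#' Fit a single-regime comparison model
#'
#' The pre-selection battery compares non-spatial OLS, the spatial
#' autoregressive model (SAR, lag of Y only), the spatial error model
#' (SEM) and the spatial Durbin model (SDM, lags of Y and X), all with the
#' same fixed effects removed by the within transformation and spatial
#' parameters estimated by concentrated maximum likelihood.
#'
#' @param p a `panel_data`.
#' @param w a `spatial_weights` (row-standardized automatically).
#' @param model one of `"ols"`, `"sar"`, `"sem"`, `"sdm"`.
#' @param effects as in [fit_two_regime_sdm()].
#' @return an `sdm_fit` record with coefficient table, `loglik`,
#'   `adj_r2`, `sigma2` and (for spatial models) `rho` or `lambda`.
#' @export
fit_comparison <- function(p, w, model = c("ols", "sar", "sem", "sdm"),
                           effects = "two_way") {
  model <- match.arg(model)
  if (!w$standardized) w <- row_standardize(w)
  include_wx <- model == "sdm"
  pd <- prep_design(p, w, effects, include_wx = include_wx)
  n <- pd$n; T_ <- pd$T; N <- n * T_
  if (model == "ols") {
    fit <- stats::lm.fit(pd$Z, pd$yv)
    e <- fit$residuals
    sigma2 <- sum(e^2) / N
    loglik <- -(N / 2) * (log(2 * pi * sigma2) + 1)
    delta <- fit$coefficients
    XtXinv <- chol2inv(chol(crossprod(pd$Z)))
    se <- sqrt(diag(XtXinv) * sum(e^2) / (N - ncol(pd$Z)))
    rho <- NULL
    V <- XtXinv * sum(e^2) / (N - ncol(pd$Z))
    dimnames(V) <- list(colnames(pd$Z), colnames(pd$Z))
    k <- ncol(pd$Z)
  } else if (model %in% c("sar", "sdm")) {
    WY <- pd$W %*% p$outcome
    Lv <- as.vector(within_transform(WY, effects))
    e0 <- qr.resid(pd$qz, pd$yv)
    e1 <- qr.resid(pd$qz, Lv)
    conc <- function(r) {
      ld <- logdet_regime(r, 0, pd$W, 1, T_)
      if (!is.finite(ld)) return(-Inf)
      e <- e0 - r * e1
      -(N / 2) * log(sum(e^2) / N) + ld
    }
    grid <- seq(-0.9, 0.9, length.out = 21)
    start <- grid[which.max(vapply(grid, conc, numeric(1)))]
    opt <- stats::optim(start, function(r) -conc(r), method = "L-BFGS-B",
                        lower = -0.99, upper = 0.99,
                        control = list(factr = 1e4))
    rho <- c(rho = opt$par)
    delta <- qr.coef(pd$qz, pd$yv - opt$par * Lv)
    e <- e0 - opt$par * e1
    sigma2 <- sum(e^2) / N
    loglik <- -(N / 2) * log(2 * pi * sigma2) +
      logdet_regime(opt$par, 0, pd$W, 1, T_) - N / 2
    par <- c(rho, delta, sigma2 = sigma2)
    full_ll <- function(pv) {
      r <- pv[1]; dl <- pv[seq(2, length(pv) - 1)]; s2 <- pv[length(pv)]
      if (s2 <= 0) return(-Inf)
      ld <- logdet_regime(r, 0, pd$W, 1, T_)
      if (!is.finite(ld)) return(-Inf)
      ee <- pd$yv - r * Lv - pd$Z %*% dl
      -(N / 2) * log(2 * pi * s2) + ld - sum(ee^2) / (2 * s2)
    }
    H <- stats::optimHess(par, full_ll)
    V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
    dimnames(V) <- list(names(par), names(par))
    se <- sqrt(pmax(diag(V), 0))[seq(2, 1 + ncol(pd$Z))]
    k <- 1 + ncol(pd$Z)
  } else { # sem
    ytm <- within_transform(p$outcome, effects)
    Xtm <- lapply(names(p$covariates), function(nm)
      within_transform(p$covariates[[nm]], effects))
    names(Xtm) <- paste0("beta_", names(p$covariates))
    conc <- function(lam) {
      B <- diag(n) - lam * pd$W
      ys <- as.vector(B %*% ytm)
      Zs <- do.call(cbind, lapply(Xtm, function(m) as.vector(B %*% m)))
      ld <- T_ * as.numeric(determinant(B, logarithm = TRUE)$modulus)
      if (determinant(B)$sign <= 0) return(list(ll = -Inf))
      f <- stats::lm.fit(Zs, ys)
      s2 <- sum(f$residuals^2) / N
      list(ll = -(N / 2) * log(s2) + ld, delta = f$coefficients,
           sigma2 = s2, Zs = Zs, e = f$residuals, ld = ld)
    }
    grid <- seq(-0.9, 0.9, length.out = 21)
    start <- grid[which.max(vapply(grid, function(l) conc(l)$ll, numeric(1)))]
    opt <- stats::optim(start, function(l) -conc(l)$ll, method = "L-BFGS-B",
                        lower = -0.99, upper = 0.99,
                        control = list(factr = 1e4))
    cc <- conc(opt$par)
    rho <- c(lambda = opt$par)
    delta <- stats::setNames(cc$delta, names(Xtm))
    sigma2 <- cc$sigma2
    e <- cc$e
    loglik <- -(N / 2) * log(2 * pi * sigma2) + cc$ld - N / 2
    par <- c(rho, delta, sigma2 = sigma2)
    Xmat <- do.call(cbind, lapply(Xtm, as.vector))
    full_ll <- function(pv) {
      lam <- pv[1]; dl <- pv[seq(2, length(pv) - 1)]; s2 <- pv[length(pv)]
      if (s2 <= 0) return(-Inf)
      B <- diag(n) - lam * pd$W
      dt <- determinant(B, logarithm = TRUE)
      if (dt$sign <= 0) return(-Inf)
      u <- as.vector(ytm) - Xmat %*% dl
      um <- matrix(u, n, T_)
      ee <- as.vector(B %*% um)
      -(N / 2) * log(2 * pi * s2) + T_ * as.numeric(dt$modulus) -
        sum(ee^2) / (2 * s2)
    }
    H <- stats::optimHess(par, full_ll)
    V <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
    dimnames(V) <- list(names(par), names(par))
    se <- sqrt(pmax(diag(V), 0))[seq(2, 1 + length(delta))]
    k <- 1 + length(delta)
  }

  zv <- delta / se
  coef_table <- data.frame(
    term = names(delta), estimate = unname(delta), se = unname(se),
    z = unname(zv), p = unname(2 * stats::pnorm(-abs(zv))),
    stringsAsFactors = FALSE)
  sst <- sum((pd$yv - mean(pd$yv))^2)
  adj_r2 <- 1 - (sum(e^2) / (N - k)) / (sst / (N - 1))
  structure(list(model = model, rho = rho, coef_table = coef_table,
                 sigma2 = sigma2, loglik = loglik, adj_r2 = adj_r2,
                 vcov = V, n = n, T = T_, effects = effects,
                 n_params = k + 1),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s effects): loglik = %.3f, adj R2 = %.3f",
              toupper(x$model), x$effects, x$loglik, x$adj_r2))
  if (!is.null(x$rho)) cat(sprintf(", %s = %.4f", names(x$rho)[1], x$rho[1]))
  cat("\n")
  invisible(x)
}

#' Classify the competition strategy from regime coefficients
#'
#' The point-comparison rule: `rho1 > rho2` means regions respond more
#' strongly when they already out-regulate their neighbours --
#' race-to-the-bottom imitation of relaxation; `rho1 < rho2` means
#' race-to-the-top. An exact tie or a non-finite coefficient is
#' `indeterminate`. A Wald test of `rho1 = rho2` is attached as a caveat
#' statistic when a covariance matrix is available; it does not change the
#' label.
#'
#' @param fit a `two_regime_sdm_fit`, or the numeric value of `rho1`.
#' @param rho2 when `fit` is numeric, the value of `rho2`.
#' @return a `strategy_verdict`: `label`, `rho_ratio` (`rho1/rho2`), and
#'   `wald_equal_p` (NA without a covariance matrix).
#' @export
classify_strategy <- function(fit, rho2 = NULL) {
  wald_p <- NA_real_
  if (is.numeric(fit)) {
    rho1 <- fit[1]
    if (is.null(rho2)) stop("supply rho2 when passing rho1 as a number")
  } else {
    rho1 <- fit$rho1; rho2 <- fit$rho2
    V <- fit$vcov
    if (!is.null(V) && all(c("rho1", "rho2") %in% rownames(V))) {
      dv <- rho1 - rho2
      vd <- V["rho1", "rho1"] + V["rho2", "rho2"] - 2 * V["rho1", "rho2"]
      if (is.finite(vd) && vd > 0) {
        wald_p <- stats::pchisq(dv^2 / vd, df = 1, lower.tail = FALSE)
      }
    }
  }
  label <- if (!is.finite(rho1) || !is.finite(rho2) || rho1 == rho2) {
    "indeterminate"
  } else if (rho1 > rho2) "race_to_bottom" else "race_to_top"
  ratio <- if (is.finite(rho2) && rho2 != 0) rho1 / rho2 else NA_real_
  structure(list(label = label, rho_ratio = ratio, wald_equal_p = wald_p,
                 rho1 = rho1, rho2 = rho2),
            class = "strategy_verdict")
}

#' @export
print.strategy_verdict <- function(x, ...) {
  cat(sprintf("strategy: %s (rho1 = %.3f, rho2 = %.3f, ratio = %.3f)\n",
              x$label, x$rho1, x$rho2, x$rho_ratio))
  invisible(x)
}

#' Stage-by-stage two-regime fits over period splits
#'
#' Splits the panel into consecutive policy stages, fits the two-regime
#' SDM independently on each, and tabulates the per-stage regime
#' coefficients and strategy verdicts.
#'
#' @param p a `panel_data`.
#' @param w a `spatial_weights`.
#' @param splits list of year ranges; each element is either a full year
#'   vector or `c(first, last)`. The splits must partition the panel's
#'   years and each stage needs at least 2 years.
#' @param effects as in [fit_two_regime_sdm()].
#' @return a `staged_fit` object: `fits` (list of per-stage fits) and
#'   `summary` (data frame with stage, rho1, rho2, z values, ratio,
#'   verdict, loglik, adj_r2).
#' @export
staged_fit <- function(p, w, splits, effects = "two_way") {
  splits <- lapply(splits, function(s) {
    s <- as.integer(s)
    if (length(s) == 2 && s[2] > s[1] + 1) seq(s[1], s[2]) else sort(s)
  })
  all_years <- sort(unlist(splits))
  if (anyDuplicated(all_years) || !identical(all_years, sort(p$years))) {
    stop("splits must partition the panel's years exactly")
  }
  short <- vapply(splits, length, integer(1)) < 2
  if (any(short)) stop("each stage needs at least 2 years")

  fits <- lapply(splits, function(yrs) {
    fit_two_regime_sdm(subset_years(p, yrs), w, effects = effects)
  })
  labels <- vapply(splits, function(yrs)
    paste0(min(yrs), "-", max(yrs)), character(1))
  names(fits) <- labels
  zrow <- function(f, term) {
    r <- f$coef_table[f$coef_table$term == term, ]
    if (nrow(r)) r$z else NA_real_
  }
  summary_df <- data.frame(
    stage = labels,
    rho1 = vapply(fits, function(f) f$rho1, numeric(1)),
    rho2 = vapply(fits, function(f) f$rho2, numeric(1)),
    z_rho1 = vapply(fits, zrow, numeric(1), term = "rho1"),
    z_rho2 = vapply(fits, zrow, numeric(1), term = "rho2"),
    rho_ratio = vapply(fits, function(f) f$verdict$rho_ratio, numeric(1)),
    verdict = vapply(fits, function(f) f$verdict$label, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  structure(list(fits = fits, summary = summary_df),
            class = "staged_fit")
}

#' @export
print.staged_fit <- function(x, ...) {
  cat("Staged two-regime SDM fits:\n")
  print(x$summary[, c("stage", "rho1", "rho2", "rho_ratio", "verdict")],
        row.names = FALSE)
  invisible(x)
}
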