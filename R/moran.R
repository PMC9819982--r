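#' Global Moran's I with normal and permutation inference
#'
#' Computes the classical global spatial-autocorrelation statistic
#' \deqn{I = \frac{\sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'                {S^2 \sum_i \sum_j w_{ij}}, \qquad
#'       S^2 = \frac{1}{n}\sum_i (x_i - \bar x)^2,}
#' its expectation under the null `E[I] = -1/(n-1)`, a z score and
#' two-sided p-value from the randomization (permutation) moments, and --
#' when `n_perm > 0` -- a two-sided pseudo p-value from `n_perm` random
#' permutations of `x` with the +1 correction
#' `p = (1 + #{|I_perm| >= |I_obs|}) / (n_perm + 1)`.
#'
#' @param x numeric vector of length n >= 3, not constant.
#' @param w a `spatial_weights` (any standardization; used as passed).
#' @param n_perm number of permutations (0 disables; use >= 99 for
#'   meaningful resolution).
#' @param seed optional integer seed for the permutations.
#' @return object of class `moran_result` with fields `I`, `expected_I`,
#'   `z`, `p_normal`, `p_perm`, `n_perm`, `n`.
#' @export
global_moran <- function(x, w, n_perm = 0, seed = NULL) {
  wm <- if (inherits(w, "spatial_weights")) w$w else as.matrix(w)
  n <- length(x)
  if (n < 3) stop("need at least 3 regions")
  if (nrow(wm) != n) stop("length(x) does not match weight matrix")
  z <- x - mean(x)
  s2 <- sum(z^2) / n
  if (s2 == 0) stop("x is constant: Moran's I is undefined (zero variance)")
  s0 <- sum(wm)
  I_obs <- sum(wm * outer(z, z)) / (s2 * s0)
  eI <- -1 / (n - 1)

  # randomization moments (Cliff & Ord)
  s1 <- 0.5 * sum((wm + t(wm))^2)
  s2w <- sum((rowSums(wm) + colSums(wm))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2w + 3 * s0^2) -
             b2 * ((n^2 - n) * s1 - 2 * n * s2w + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - eI^2
  zstat <- (I_obs - eI) / sqrt(varI)
  p_normal <- 2 * stats::pnorm(-abs(zstat))

  p_perm <- NULL
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    denom <- s2 * s0
    for (k in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      Ip <- sum(wm * outer(zp, zp)) / denom
      if (abs(Ip) >= abs(I_obs)) cnt <- cnt + 1L
    }
    p_perm <- (1 + cnt) / (n_perm + 1)
  }
  structure(list(I = I_obs, expected_I = eI, z = zstat,
                 p_normal = p_normal, p_perm = p_perm,
                 n_perm = as.integer(n_perm), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), z = %.3f, p_normal = %.4g",
              x$I, x$expected_I, x$z, x$p_normal))
  if (!is.null(x$p_perm)) {
    cat(sprintf(", p_perm = %.4g (%d perms)", x$p_perm, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Local Moran's I (Anselin LISA)
#'
#' Per-region decomposition `I_i = (x_i - xbar) / S^2 * sum_j w_ij (x_j - xbar)`
#' with the population variance `S^2 = sum_i (x_i - xbar)^2 / n`. With a
#' row-standardized W the mean of the local values equals the global
#' statistic.
#'
#' @inheritParams global_moran
#' @return numeric vector of length n (named if `w` carries region names).
#' @export
local_moran <- function(x, w) {
  wm <- if (inherits(w, "spatial_weights")) w$w else as.matrix(w)
  n <- length(x)
  if (n < 3) stop("need at least 3 regions")
  z <- x - mean(x)
  s2 <- sum(z^2) / n
  if (s2 == 0) stop("x is constant: local Moran's I is undefined")
  li <- as.numeric(z * (wm %*% z) / s2)
  names(li) <- rownames(wm)
  li
}

#' Moran scatter quadrant labels
#'
#' Assigns each region to a quadrant of the Moran scatter plot of
#' mean-deviations versus spatial lag of mean-deviations: HH (high value,
#' high-lag neighbourhood), LL, HL, LH. Exact zeros are assigned to the
#' "high" side deterministically.
#'
#' @inheritParams global_moran
#' @return character vector of labels in `{"HH","HL","LH","LL"}`.
#' @export
moran_quadrants <- function(x, w) {
  wm <- if (inherits(w, "spatial_weights")) w$w else as.matrix(w)
  z <- x - mean(x)
  lag <- as.numeric(wm %*% z)
  hi_x <- z >= 0
  hi_l <- lag >= 0
  lab <- ifelse(hi_x & hi_l, "HH",
                ifelse(hi_x & !hi_l, "HL",
                       ifelse(!hi_x & hi_l, "LH", "LL")))
  names(lab) <- rownames(wm)
  lab
}

#' Moran's I table across panel years
#'
#' Runs [global_moran()] on one panel variable for every year, the way a
#' year-by-year autocorrelation table is reported before fitting spatial
#' models.
#'
#' @param p a `panel_data`.
#' @param w a `spatial_weights`.
#' @param variable which series to test: `"RS"` or a covariate name
#'   (default `"HC"`, haze concentration).
#' @param n_perm,seed passed to [global_moran()].
#' @return data frame with columns `year, I, z, p_normal, p_perm`.
#' @export
moran_by_year <- function(p, w, variable = "HC", n_perm = 0, seed = NULL) {
  m <- if (variable == PANEL_OUTCOME) p$outcome else p$covariates[[variable]]
  if (is.null(m)) stop("unknown variable: ", variable)
  rows <- lapply(seq_along(p$years), function(t) {
    r <- global_moran(m[, t], w, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + t)
    data.frame(year = p$years[t], I = r$I, z = r$z,
               p_normal = r$p_normal,
               p_perm = if (is.null(r$p_perm)) NA_real_ else r$p_perm)
  })
  do.call(rbind, rows)
}
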