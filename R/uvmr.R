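makeEstimate <- function(method, exposure, theta, se, nSNP,
                         crit = qnorm(0.975), pval = NULL, df = NULL,
                         q = NA_real_, qPval = NA_real_,
                         eggerIntercept = NA_real_,
                         eggerInterceptPval = NA_real_,
                         binary = TRUE) {
  theta <- unname(theta); se <- unname(se)
  q <- unname(q); qPval <- unname(qPval)
  eggerIntercept <- unname(eggerIntercept)
  eggerInterceptPval <- unname(eggerInterceptPval)
  if (is.null(pval)) {
    z <- theta / se
    pval <- if (is.null(df)) 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df)
  }
  new("MREstimate", method = method, exposure = exposure,
      theta = theta, se = se,
      ciLow = theta - crit * se, ciHigh = theta + crit * se,
      pval = unname(pval), nSNP = as.integer(nSNP),
      q = q, qPval = qPval,
      eggerIntercept = eggerIntercept,
      eggerInterceptPval = eggerInterceptPval,
      outcomeBinary = binary)
}

firstExposure <- function(h) {
  if (length(h@exposureNames) != 1L)
    stop("this estimator takes a single-exposure HarmonizedSet; use the mvmr* functions")
  list(bx = h@betaExp[, 1L], sx = h@seExp[, 1L],
       by = h@betaOut, sy = h@seOut,
       name = h@exposureNames[1L],
       binary = identical(h@outcomeType, "binary"))
}

#' Wald ratio estimate for a single variant
#'
#' theta = beta_y / beta_x with first-order SE |se_y / beta_x| (the
#' uncertainty in beta_x is ignored, the usual leading-order treatment).
#'
#' @param beta_x,se_x variant-exposure effect and SE.
#' @param beta_y,se_y variant-outcome effect and SE.
#' @param exposure,binary labels carried into the result.
#' @return An [MREstimate-class] with method `"wald"`.
#' @export
waldRatio <- function(beta_x, se_x, beta_y, se_y, exposure = "exposure",
                      binary = TRUE) {
  if (beta_x == 0) stop("undefined Wald ratio: beta_x = 0")
  makeEstimate("wald", exposure, theta = beta_y / beta_x,
               se = abs(se_y / beta_x), nSNP = 1L, binary = binary)
}

#' Cochran's Q heterogeneity statistic at a given causal effect
#'
#' Q = sum over variants of (beta_out - theta * beta_exp)^2 / se_out^2,
#' compared to chi-square with J - 1 degrees of freedom.
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 2 variants.
#' @param theta causal effect at which residuals are taken (typically the
#'   IVW estimate).
#' @return Named numeric `c(q, q_pval)`.
#' @export
cochranQ <- function(h, theta) {
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 2L) stop("Cochran's Q requires >= 2 variants")
  q <- sum((d$by - theta * d$bx)^2 / d$sy^2)
  c(q = q, q_pval = pchisq(q, df = J - 1L, lower.tail = FALSE))
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted least squares of variant-outcome on variant-exposure effects
#' through the origin with weights 1/se_out^2:
#' theta = sum(w bx by) / sum(w bx^2).  Under the multiplicative
#' random-effects model (the default, and the conventional main analysis)
#' the fixed-effect SE is inflated by max(1, sqrt(Q / (J - 1))); the floor
#' at 1 means homogeneous data fall back to the fixed-effect SE.  Normal
#' inference; Cochran's Q attached.
#'
#' @param h single-exposure [HarmonizedSet-class].
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An [MREstimate-class] with method `"ivw"` (or `"wald"` when only
#'   one variant is available, with a warning).
#' @export
mrIVW <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 1L) stop("no variants")
  if (all(d$bx == 0)) stop("degenerate: all exposure betas are zero")
  if (J == 1L) {
    warning("single variant: IVW degrades to the Wald ratio")
    return(waldRatio(d$bx, d$sx, d$by, d$sy, exposure = d$name,
                     binary = d$binary))
  }
  w <- 1 / d$sy^2
  theta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- 1 / sqrt(sum(w * d$bx^2))
  qq <- cochranQ(h, theta)
  se <- if (effects_model == "fixed") se_fixed
        else se_fixed * max(1, sqrt(qq[["q"]] / (J - 1L)))
  makeEstimate("ivw", d$name, theta, se, J,
               q = qq[["q"]], qPval = qq[["q_pval"]], binary = d$binary)
}

#' MR-Egger regression
#'
#' Variants are first oriented so every exposure beta is non-negative
#' (jointly negating exposure and outcome effects where needed), then
#' outcome effects are regressed on exposure effects WITH an intercept,
#' weighted by 1/se_out^2.  The slope is the causal estimate; the
#' intercept alpha indexes directional pleiotropy (its test is the Egger
#' intercept test).  Both SEs are inflated by max(1, dispersion) with
#' dispersion^2 = residual Q / (J - 2); inference and the 95% CI use the t
#' distribution with J - 2 df.
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 3 variants.
#' @return An [MREstimate-class] with method `"egger"`, carrying the
#'   intercept and its p-value.
#' @export
mrEgger <- function(h) {
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 3L) stop("MR-Egger requires >= 3 variants")
  flip <- d$bx < 0
  bx <- ifelse(flip, -d$bx, d$bx)
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  X <- cbind(intercept = 1, slope = bx)
  A <- crossprod(X, w * X)
  coef <- drop(solve(A, crossprod(X, w * by)))
  resid <- by - drop(X %*% coef)
  qres <- sum(w * resid^2)
  disp <- max(1, sqrt(qres / (J - 2L)))
  covm <- solve(A) * disp^2
  se <- sqrt(diag(covm))
  df <- J - 2L
  makeEstimate("egger", d$name,
               theta = coef[["slope"]], se = se[["slope"]], nSNP = J,
               crit = qt(0.975, df), df = df,
               q = qres, qPval = pchisq(qres, df, lower.tail = FALSE),
               eggerIntercept = coef[["intercept"]],
               eggerInterceptPval =
                 2 * pt(-abs(coef[["intercept"]] / se[["intercept"]]), df),
               binary = d$binary)
}

# Point estimate of the weighted median of ratios: sort ratios, take the
# 0.5 crossing of the cumulative-midpoint weights by linear interpolation.
weightedMedianPoint <- function(ratios, weights) {
  ord <- order(ratios)
  th <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(th[1L])
  J <- length(th)
  if (0.5 >= s[J]) return(th[J])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

ratioWeights <- function(d) {
  w <- (d$bx / d$sy)^2
  w / sum(w)
}

#' Weighted-median MR estimate
#'
#' Consistent when instruments carrying at least half the weight are valid.
#' Per-variant ratios are ordered and the inverse-variance weights
#' w_j = (beta_exp_j / se_out_j)^2 (normalized) define cumulative midpoints
#' s_j = cumsum(w)_j - w_j/2; the estimate interpolates the ratios over s
#' at 0.5.  The SE is the standard deviation of the estimator over
#' `n_boot` parametric bootstrap replicates (exposure and outcome effects
#' resampled from their estimation normals), so a seed is mandatory.
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MREstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(h, n_boot = 1000L, seed) {
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 3L) stop("weighted median requires >= 3 variants")
  theta <- weightedMedianPoint(d$by / d$bx, ratioWeights(d))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(J, d$bx, d$sx)
    by <- rnorm(J, d$by, d$sy)
    db <- list(bx = bx, by = by, sy = d$sy)
    weightedMedianPoint(by / bx, ratioWeights(db))
  }, numeric(1))
  makeEstimate("weighted_median", d$name, theta, sd(boots), J,
               binary = d$binary)
}

# Kernel-density mode of the ratio distribution.  Bandwidth
# b = phi * 0.9 * min(sd, mad) * J^(-1/5) (mad with the sd-consistent
# 1.4826 scaling); density on a 1000-point grid over
# [min - 3b, max + 3b]; returns the grid argmax.
modePoint <- function(ratios, weights = NULL, phi = 1, grid_n = 1000L) {
  J <- length(ratios)
  if (is.null(weights)) weights <- rep(1 / J, J)
  weights <- weights / sum(weights)
  b <- phi * 0.9 * min(sd(ratios), mad(ratios)) * J^(-1 / 5)
  if (!is.finite(b) || b <= 0) {
    # all ratios identical (or collapse to a point): mode is that value
    return(ratios[which.max(weights)])
  }
  grid <- seq(min(ratios) - 3 * b, max(ratios) + 3 * b, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(weights * dnorm(g, ratios, b)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based MR estimate (simple and weighted)
#'
#' Consistent when the largest cluster of instruments has zero horizontal
#' pleiotropy (the plurality-valid assumption).  A normal-kernel density of
#' the per-variant ratios is maximized over a 1000-point grid; the simple
#' mode weighs ratios equally, the weighted mode uses the same
#' inverse-variance weights as the weighted median.  Bandwidth
#' b = phi * 0.9 * min(sd, mad) * J^(-1/5).  SE by the same parametric
#' bootstrap as [mrWeightedMedian()].
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 3 variants.
#' @param weighted use inverse-variance weights (`TRUE`) or equal weights.
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param n_boot,seed bootstrap settings.
#' @return An [MREstimate-class] with method `"simple_mode"` or
#'   `"weighted_mode"`.
#' @export
mrMode <- function(h, weighted = FALSE, phi = 1, n_boot = 1000L, seed) {
  stopifnot(phi > 0)
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 3L) stop("mode estimator requires >= 3 variants")
  wts <- function(db) if (weighted) ratioWeights(db) else NULL
  theta <- modePoint(d$by / d$bx, wts(d), phi)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- rnorm(J, d$bx, d$sx)
    by <- rnorm(J, d$by, d$sy)
    db <- list(bx = bx, by = by, sy = d$sy)
    modePoint(by / bx, wts(db), phi)
  }, numeric(1))
  makeEstimate(if (weighted) "weighted_mode" else "simple_mode",
               d$name, theta, sd(boots), J, binary = d$binary)
}
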