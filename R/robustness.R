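# Leave-one-out IVW thetas from weighted sums; vectorized over variants.
looTheta <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: global pleiotropy, per-variant outlier, and distortion tests
#'
#' Simulation-based outlier framework run before the main MR fit.  The
#' observed statistic is the leave-one-out residual sum of squares
#' RSS = sum_j w_j (beta_out_j - theta_(-j) beta_exp_j)^2 with
#' w_j = 1/se_out_j^2 and theta_(-j) the IVW estimate excluding variant j.
#' Its null distribution is simulated by redrawing
#' beta_out_j ~ N(theta_(-j) beta_exp_j, se_out_j) and
#' beta_exp_j ~ N(beta_exp_j, se_exp_j) `n_sim` times and recomputing RSS
#' (including the leave-one-out fits) on each replicate.  Add-one
#' Monte-Carlo p-values: global p = (1 + #\{RSS* >= RSS\}) / (n_sim + 1);
#' per-variant p-values are computed the same way on each variant's RSS
#' contribution and Bonferroni-adjusted by J.  Variants with adjusted
#' p below `outlier_alpha` are outliers; the corrected estimate is IVW on
#' the rest.  When outliers exist, the distortion test compares the
#' corrected-vs-full change in theta against the distribution obtained by
#' removing equally many random variants.
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 4 variants.
#' @param n_sim simulated replicates (>= 100; default 1000).
#' @param seed RNG seed (mandatory; results are bit-reproducible).
#' @param outlier_alpha threshold on the Bonferroni-adjusted per-variant p.
#' @return A [PressoResult-class].
#' @export
mrPresso <- function(h, n_sim = 1000L, seed, outlier_alpha = 0.05) {
  d <- firstExposure(h)
  J <- length(d$bx)
  if (J < 4L) stop("MR-PRESSO requires >= 4 variants")
  if (n_sim < 100L) stop("n_sim must be >= 100")
  n_sim <- as.integer(n_sim)
  w <- 1 / d$sy^2

  th_loo <- looTheta(d$bx, d$by, w)
  rss_j <- w * (d$by - th_loo * d$bx)^2
  rss <- sum(rss_j)

  set.seed(seed)
  BX <- matrix(rnorm(n_sim * J, mean = rep(d$bx, each = n_sim),
                     sd = rep(d$sx, each = n_sim)), n_sim, J)
  BY <- matrix(rnorm(n_sim * J, mean = rep(th_loo * d$bx, each = n_sim),
                     sd = rep(d$sy, each = n_sim)), n_sim, J)
  W <- matrix(w, n_sim, J, byrow = TRUE)
  SXY <- rowSums(W * BX * BY)
  SXX <- rowSums(W * BX^2)
  TH <- (SXY - W * BX * BY) / (SXX - W * BX^2)
  RSSJ <- W * (BY - TH * BX)^2
  RSS <- rowSums(RSSJ)

  global_p <- (1 + sum(RSS >= rss)) / (n_sim + 1)
  per_p <- (1 + colSums(RSSJ >= matrix(rss_j, n_sim, J, byrow = TRUE))) /
    (n_sim + 1)
  per_p_adj <- pmin(1, per_p * J)
  out_idx <- which(per_p_adj < outlier_alpha)
  outlier_ids <- h@variantIds[out_idx]

  keep_ids <- setdiff(h@variantIds, outlier_ids)
  full <- mrIVW(h)
  corrected <- if (length(keep_ids) >= 2L)
    mrIVW(subsetHarmonized(h, keep_ids)) else full

  distortion_p <- NA_real_
  if (length(out_idx) && length(keep_ids) >= 2L) {
    d_obs <- theta(corrected) - theta(full)
    d_sim <- vapply(seq_len(n_sim), function(b) {
      drop_b <- sample.int(J, length(out_idx))
      keep <- setdiff(seq_len(J), drop_b)
      bx <- d$bx[keep]; by <- d$by[keep]; wk <- w[keep]
      sum(wk * bx * by) / sum(wk * bx^2) - theta(full)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  new("PressoResult",
      globalRSS = rss, globalPval = global_p,
      perSNPPval = per_p, perSNPPvalAdj = per_p_adj,
      outlierIds = outlier_ids, corrected = corrected,
      distortionPval = distortion_p, nSim = n_sim,
      seed = as.integer(seed))
}

#' Radial MR: per-variant Q contributions and iterative outlier removal
#'
#' Radial (modified second-stage) reformulation of IVW with first-order
#' weights W_j = beta_exp_j^2 / se_out_j^2: regressing sqrt(W_j) * ratio_j
#' on sqrt(W_j) without intercept returns exactly the IVW estimate (an
#' algebraic identity), and the per-variant contributions
#' Q_j = W_j (ratio_j - theta)^2 decompose total Q.  Each Q_j is referred
#' to chi-square(1); variants with p below `alpha` are outliers.  With
#' `iterate = TRUE` outliers are removed and the fit repeated until none
#' remain or fewer than 2 variants would be left.
#'
#' @param h single-exposure [HarmonizedSet-class] with >= 2 variants.
#' @param alpha per-variant outlier threshold (default 0.05).
#' @param iterate remove-and-refit until stable (default TRUE).
#' @return A [RadialResult-class]; `perSNPQ`/`perSNPPval` refer to the
#'   final fit on the retained variants.
#' @export
radialIVW <- function(h, alpha = 0.05, iterate = TRUE) {
  d <- firstExposure(h)
  zero <- d$bx == 0
  if (any(zero)) {
    warning("excluding variant(s) with beta_exp = 0: ",
            paste(h@variantIds[zero], collapse = ", "))
  }
  ids <- h@variantIds[!zero]
  bx <- d$bx[!zero]; by <- d$by[!zero]; sy <- d$sy[!zero]
  if (length(bx) < 2L) stop("radial MR requires >= 2 usable variants")

  removed <- character()
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    W <- bx^2 / sy^2
    ratio <- by / bx
    th <- sum(W * ratio) / sum(W)
    qj <- W * (ratio - th)^2
    pj <- pchisq(qj, df = 1, lower.tail = FALSE)
    out <- pj < alpha
    if (!iterate || !any(out) || (length(bx) - sum(out)) < 2L) break
    removed <- c(removed, ids[out])
    keep <- !out
    ids <- ids[keep]; bx <- bx[keep]; by <- by[keep]; sy <- sy[keep]
  }

  new("RadialResult",
      theta = th, qTotal = sum(qj),
      perSNPQ = setNames(qj, ids),
      perSNPPval = setNames(pj, ids),
      outlierIds = removed, keptIds = ids,
      iterations = iterations)
}

#' Union of MR-PRESSO and radial-MR outliers
#'
#' Convenience for the pipeline's pre-filtering step: both diagnostics are
#' run and the union of their flagged variants is removed before the main
#' estimator battery.
#'
#' @param h single-exposure [HarmonizedSet-class].
#' @param n_sim,seed,alpha settings passed through.
#' @return list(`kept` filtered [HarmonizedSet-class], `outliers` ids,
#'   `presso` [PressoResult-class] or NULL when too few variants,
#'   `radial` [RadialResult-class]).
#' @export
filterOutliers <- function(h, n_sim = 1000L, seed, alpha = 0.05) {
  presso <- if (nVariants(h) >= 4L) mrPresso(h, n_sim, seed, alpha) else NULL
  radial <- radialIVW(h, alpha = alpha, iterate = TRUE)
  outliers <- union(if (is.null(presso)) character() else outlierIds(presso),
                    outlierIds(radial))
  keep <- setdiff(variantIds(h), outliers)
  kept <- if (length(keep) >= 2L && length(outliers)) subsetHarmonized(h, keep)
          else h
  list(kept = kept, outliers = outliers, presso = presso, radial = radial)
}
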