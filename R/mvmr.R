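mvmrDesign <- function(h) {
  list(X = h@betaExp, y = h@betaOut, w = 1 / h@seOut^2,
       names = h@exposureNames, J = length(h@betaOut),
       k = length(h@exposureNames),
       binary = identical(h@outcomeType, "binary"))
}

checkRank <- function(X, w, names) {
  qrd <- qr(sqrt(w) * X)
  if (qrd$rank < ncol(X)) {
    dep <- names[qrd$pivot[seq.int(qrd$rank + 1L, ncol(X))]]
    stop("collinear exposure effect matrix; offending exposure(s): ",
         paste(dep, collapse = ", "))
  }
}

#' Multivariable IVW
#'
#' Weighted least squares of the variant-outcome effects on the full
#' exposure effect matrix, no intercept, weights 1/se_out^2.  Each
#' exposure's coefficient is its direct effect adjusted for the others —
#' the beta2 of two-step mediation when the exposures are (exposure,
#' mediator).  Per-exposure SEs are inflated by max(1, dispersion) with
#' dispersion^2 = Q/(J - k); Q (df J - k) is attached to every estimate.
#'
#' @param h [HarmonizedSet-class] with k >= 1 exposures and J >= k + 1
#'   variants.
#' @return Named list of [MREstimate-class] (method `"mvmr_ivw"`), one per
#'   exposure.
#' @export
mvmrIVW <- function(h) {
  d <- mvmrDesign(h)
  if (d$J < d$k + 1L) stop("need at least exposures + 1 variants")
  checkRank(d$X, d$w, d$names)
  A <- crossprod(d$X, d$w * d$X)
  coef <- drop(solve(A, crossprod(d$X, d$w * d$y)))
  resid <- d$y - drop(d$X %*% coef)
  q <- sum(d$w * resid^2)
  df <- d$J - d$k
  disp <- max(1, sqrt(q / df))
  se <- sqrt(diag(solve(A))) * disp
  qp <- pchisq(q, df, lower.tail = FALSE)
  out <- lapply(seq_len(d$k), function(i)
    makeEstimate("mvmr_ivw", d$names[i], coef[i], se[i], d$J,
                 q = q, qPval = qp, binary = d$binary))
  setNames(out, d$names)
}

#' Multivariable MR-Egger
#'
#' As [mvmrIVW()] but with an intercept after orienting every variant so
#' the `orient_to` exposure's betas are non-negative (jointly negating the
#' variant's whole effect row where needed).  t-based inference with
#' J - k - 1 df; the shared intercept and its p-value are carried on every
#' returned estimate (and as the `"intercept"` attribute).
#'
#' @param h [HarmonizedSet-class] with k >= 2 exposures and J >= k + 2
#'   variants.
#' @param orient_to exposure name whose betas define the orientation;
#'   defaults to the first exposure.
#' @return Named list of [MREstimate-class] (method `"mvmr_egger"`).
#' @export
mvmrEgger <- function(h, orient_to = NULL) {
  d <- mvmrDesign(h)
  if (is.null(orient_to)) orient_to <- d$names[1L]
  oi <- match(orient_to, d$names)
  if (is.na(oi)) stop("unknown exposure: ", orient_to)
  if (d$J < d$k + 2L) stop("need at least exposures + 2 variants")
  flip <- d$X[, oi] < 0
  X <- d$X; y <- d$y
  X[flip, ] <- -X[flip, , drop = FALSE]
  y[flip] <- -y[flip]
  Xi <- cbind(`(intercept)` = 1, X)
  checkRank(Xi, d$w, c("(intercept)", d$names))
  A <- crossprod(Xi, d$w * Xi)
  coef <- drop(solve(A, crossprod(Xi, d$w * y)))
  resid <- y - drop(Xi %*% coef)
  q <- sum(d$w * resid^2)
  df <- d$J - d$k - 1L
  disp <- max(1, sqrt(q / df))
  se <- sqrt(diag(solve(A))) * disp
  alpha <- coef[1L]
  alpha_p <- 2 * pt(-abs(alpha / se[1L]), df)
  qp <- pchisq(q, df, lower.tail = FALSE)
  out <- lapply(seq_len(d$k), function(i)
    makeEstimate("mvmr_egger", d$names[i], coef[i + 1L], se[i + 1L], d$J,
                 crit = qt(0.975, df), df = df,
                 q = q, qPval = qp,
                 eggerIntercept = alpha, eggerInterceptPval = alpha_p,
                 binary = d$binary))
  out <- setNames(out, d$names)
  attr(out, "intercept") <- c(intercept = unname(alpha), pval = unname(alpha_p))
  out
}
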