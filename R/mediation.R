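#' Bonferroni-corrected significance threshold
#'
#' alpha / m for a family of m tests; the screening cascade uses the
#' data-driven family sizes (panel size M, then the survivor counts).
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @examples
#' bonferroniThreshold(0.05, 168)  # 2.976e-4
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Two-step MR mediation: indirect effect and mediated proportion
#'
#' Product-of-coefficients mediation on summary estimates: beta1 is the
#' exposure-to-mediator effect (SD per 1 SD exposure), beta2 the
#' mediator-to-outcome effect adjusted for the exposure (log-odds per SD,
#' from MVMR), and `total` the total exposure-to-outcome effect
#' (log-odds).  Then indirect = beta1 * beta2, the mediated proportion is
#' indirect / total, and the delta-method SE of the product is
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2) (first order; the se1^2 * se2^2
#' second-order term is included with `second_order = TRUE`).  No
#' covariance term between beta1 and beta2 is used: in the two-sample
#' design they come from non-overlapping regressions.
#'
#' By default the total effect is treated as FIXED in the proportion SE
#' (se_prop = se_indirect / |total|); `total_fixed = FALSE` switches to the
#' full ratio delta method that also propagates `se_total`, which gives a
#' markedly wider interval.  95% CI is proportion -/+ 1.96 se_prop with a
#' two-sided normal p.
#'
#' @param beta1,se1 exposure-to-mediator estimate and SE.
#' @param beta2,se2 adjusted mediator-to-outcome estimate and SE.
#' @param total,se_total total-effect estimate and SE (`total` nonzero).
#' @param mediator label carried into the result.
#' @param total_fixed treat the total as fixed in se_prop (default TRUE).
#' @param second_order include the se1^2 se2^2 product-variance term.
#' @return A [MediationResult-class]; the proportion is stored as a
#'   fraction (reports print percentages).
#' @examples
#' mediationProportion(0.42, 0.0995, log(0.88), 0.0433,
#'                     log(0.51), 0.328)
#' @export
mediationProportion <- function(beta1, se1, beta2, se2, total, se_total,
                                mediator = "mediator",
                                total_fixed = TRUE, second_order = FALSE) {
  if (total == 0) stop("undefined mediated proportion: total effect is 0")
  stopifnot(se1 > 0, se2 > 0, se_total >= 0)
  indirect <- beta1 * beta2
  v_ind <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) v_ind <- v_ind + se1^2 * se2^2
  se_ind <- sqrt(v_ind)
  prop <- indirect / total
  se_prop <- if (total_fixed) se_ind / abs(total)
             else sqrt(v_ind / total^2 + indirect^2 * se_total^2 / total^4)
  z <- if (se_prop > 0) prop / se_prop else 0
  new("MediationResult",
      mediator = mediator,
      beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
      total = total, seTotal = se_total,
      indirect = indirect, seIndirect = se_ind,
      proportion = prop, seProp = se_prop,
      ciLow = prop - qnorm(0.975) * se_prop,
      ciHigh = prop + qnorm(0.975) * se_prop,
      pval = if (se_prop > 0) 2 * pnorm(-abs(z)) else as.numeric(prop == 0))
}
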