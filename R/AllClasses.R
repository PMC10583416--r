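#' @import methods
#' @importFrom stats approx dnorm integrate mad median pchisq pnorm pt
#'   qnorm qt rbinom rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' SummaryStats: per-variant GWAS summary associations for one trait
#'
#' Holds one trait's GWAS summary statistics as a validated table with one
#' row per variant.  `beta` is on the standardized scale for quantitative
#' traits (SD units per effect-allele copy) and on the log-odds scale for
#' binary traits.
#'
#' @slot traitName character(1) trait label.
#' @slot traitType `"quantitative"` or `"binary"`; fixes the scale of `beta`.
#' @slot records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`;
#'   `variant_id` values are unique, `se > 0`, `pval` in (0, 1], `eaf`
#'   in \[0, 1\] or `NA`.
#'
#' @seealso [readSummaryStats()], [harmonize()]
#' @export
setClass("SummaryStats",
  slots = c(traitName = "character",
            traitType = "character",
            records   = "data.frame"))

setValidity("SummaryStats", function(object) {
  msgs <- character()
  if (length(object@traitName) != 1L || is.na(object@traitName))
    msgs <- c(msgs, "traitName must be a single non-missing string")
  if (!object@traitType %in% c("quantitative", "binary"))
    msgs <- c(msgs, "traitType must be 'quantitative' or 'binary'")
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  miss <- setdiff(req, names(object@records))
  if (length(miss))
    return(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  r <- object@records
  if (anyDuplicated(r$variant_id))
    msgs <- c(msgs, "variant_id values must be unique")
  if (nrow(r)) {
    if (any(!r$effect_allele %in% VALID_BASES) ||
        any(!r$other_allele %in% VALID_BASES))
      msgs <- c(msgs, "alleles must be single bases A/C/G/T")
    if (any(r$effect_allele == r$other_allele))
      msgs <- c(msgs, "effect_allele must differ from other_allele")
    if (any(!is.finite(r$se)) || any(r$se <= 0))
      msgs <- c(msgs, "all se must be finite and > 0")
    if (any(!is.finite(r$pval)) || any(r$pval <= 0 | r$pval > 1))
      msgs <- c(msgs, "all pval must lie in (0, 1]")
    ok_eaf <- is.na(r$eaf) | (r$eaf >= 0 & r$eaf <= 1)
    if (!all(ok_eaf))
      msgs <- c(msgs, "eaf must be NA or in [0, 1]")
    if (any(!is.finite(r$n)) || any(r$n <= 0))
      msgs <- c(msgs, "all n must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' LDMatrix: pairwise LD correlations for a set of variants
#'
#' Symmetric matrix of pairwise LD correlations r (not r-squared), with unit
#' diagonal, keyed by variant id in both dimensions.
#'
#' @slot variantIds ordered character vector of variant ids.
#' @slot r symmetric numeric matrix of correlations in \[-1, 1\].
#'
#' @seealso [readLDMatrix()], [clumpVariants()]
#' @export
setClass("LDMatrix",
  slots = c(variantIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r
  ids <- object@variantIds
  if (nrow(m) != ncol(m)) return("r must be square")
  if (length(ids) != nrow(m)) return("variantIds length must match matrix dimension")
  if (anyDuplicated(ids)) return("variantIds must be unique")
  if (any(!is.finite(m))) return("r entries must be finite")
  if (max(abs(m)) > 1 + 1e-8) return("|r| entries must not exceed 1")
  if (max(abs(m - t(m))) > 1e-8) return("r must be symmetric (tolerance 1e-8)")
  if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal of r must be 1")
  TRUE
})

#' HarmonizedSet: allele-aligned exposure-by-outcome effect matrices
#'
#' The working data structure for all MR estimators: for each retained
#' variant, effects of one or more exposures and of the outcome, all
#' expressed per copy of the same (first exposure's) effect allele.
#'
#' @slot variantIds retained variant ids.
#' @slot exposureNames ordered exposure labels (>= 1).
#' @slot betaExp,seExp variants x exposures matrices of effects and SEs.
#' @slot betaOut,seOut outcome effect and SE vectors.
#' @slot effectAllele,otherAllele the shared aligned alleles per variant.
#' @slot outcomeName,outcomeType outcome label and trait type.
#' @slot dropped data.frame (`variant_id`, `reason`) of excluded variants.
#'
#' @seealso [harmonize()], [mrIVW()], [mvmrIVW()]
#' @export
setClass("HarmonizedSet",
  slots = c(variantIds    = "character",
            exposureNames = "character",
            betaExp       = "matrix",
            seExp         = "matrix",
            betaOut       = "numeric",
            seOut         = "numeric",
            effectAllele  = "character",
            otherAllele   = "character",
            outcomeName   = "character",
            outcomeType   = "character",
            dropped       = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  J <- length(object@variantIds)
  k <- length(object@exposureNames)
  if (k < 1L) return("at least one exposure required")
  if (!identical(dim(object@betaExp), c(J, k)) ||
      !identical(dim(object@seExp), c(J, k)))
    return("betaExp/seExp must be variants x exposures matrices")
  if (length(object@betaOut) != J || length(object@seOut) != J)
    return("betaOut/seOut length must match variantIds")
  if (J) {
    if (any(!is.finite(object@betaExp)) || any(!is.finite(object@betaOut)))
      return("no missing values allowed in retained rows")
    if (any(object@seExp <= 0) || any(object@seOut <= 0))
      return("all se entries must be > 0")
  }
  TRUE
})

#' MREstimate: one MR method's causal estimate
#'
#' A single causal-effect estimate on the outcome scale (log-odds per 1 SD
#' exposure for a binary outcome), with normal- or t-based 95% CI, and
#' optional heterogeneity (Cochran's Q) and MR-Egger intercept fields.
#'
#' @slot method one of `wald`, `ivw`, `egger`, `weighted_median`,
#'   `simple_mode`, `weighted_mode`, `mvmr_ivw`, `mvmr_egger`.
#' @slot exposure exposure label the estimate refers to.
#' @slot theta,se,ciLow,ciHigh,pval estimate, SE, 95% CI bounds, p-value.
#' @slot nSNP number of variants used.
#' @slot q,qPval Cochran's Q and its p-value (`NA` when not computed).
#' @slot eggerIntercept,eggerInterceptPval MR-Egger intercept and p
#'   (`NA` for non-Egger methods).
#' @slot outcomeBinary if `TRUE`, [orScale()] exponentiates to odds ratios.
#'
#' @seealso [mrIVW()], [mrEgger()], [orScale()]
#' @export
setClass("MREstimate",
  slots = c(method  = "character",
            exposure = "character",
            theta   = "numeric",
            se      = "numeric",
            ciLow   = "numeric",
            ciHigh  = "numeric",
            pval    = "numeric",
            nSNP    = "integer",
            q       = "numeric",
            qPval   = "numeric",
            eggerIntercept     = "numeric",
            eggerInterceptPval = "numeric",
            outcomeBinary      = "logical"))

setValidity("MREstimate", function(object) {
  if (!object@method %in% c("wald", "ivw", "egger", "weighted_median",
                            "simple_mode", "weighted_mode",
                            "mvmr_ivw", "mvmr_egger"))
    return("unknown method")
  if (is.finite(object@theta) &&
      (object@ciLow > object@theta + 1e-12 ||
       object@ciHigh < object@theta - 1e-12))
    return("ciLow <= theta <= ciHigh violated")
  if (is.finite(object@q) && object@q < 0) return("q must be >= 0")
  TRUE
})

#' InstrumentSet: selected genetic instruments for one exposure
#'
#' Output of instrument selection: the retained exposure associations,
#' per-variant F statistics (the squared Wald z), weak-instrument flags at
#' the conventional F < 10 cutoff, and a log of counts at each selection
#' step.
#'
#' @slot exposureName exposure label.
#' @slot variants data.frame of retained exposure associations
#'   (SummaryStats record columns).
#' @slot fStats per-variant F = (beta/se)^2.
#' @slot weakFlags per-variant `TRUE` when F < 10.
#' @slot selectionLog data.frame (`step`, `n_before`, `n_after`).
#' @slot reason non-empty when the set is empty for a structural reason
#'   (e.g. a failed colocalization gate).
#'
#' @seealso [selectBiomarkerInstruments()], [selectDrugTargetInstruments()]
#' @export
setClass("InstrumentSet",
  slots = c(exposureName = "character",
            variants     = "data.frame",
            fStats       = "numeric",
            weakFlags    = "logical",
            selectionLog = "data.frame",
            reason       = "character"))

setValidity("InstrumentSet", function(object) {
  J <- nrow(object@variants)
  if (length(object@fStats) != J || length(object@weakFlags) != J)
    return("fStats/weakFlags length must match variants")
  if (J) {
    f <- (object@variants$beta / object@variants$se)^2
    if (max(abs(object@fStats - f)) > 1e-10)
      return("fStats must equal (beta/se)^2")
    if (!identical(object@weakFlags, unname(object@fStats < 10)))
      return("weakFlags must be fStats < 10")
  }
  TRUE
})

#' ColocResult: approximate-Bayes-factor colocalization posteriors
#'
#' Per-variant log approximate Bayes factors for two traits over a shared
#' region, and the posterior probabilities of the five standard hypotheses:
#' H0 no association, H1/H2 association with one trait only, H3 two
#' distinct causal variants, H4 one shared causal variant.
#'
#' @slot variantIds region variant ids.
#' @slot labf1,labf2 per-variant log ABFs for each trait.
#' @slot pp named numeric of length 5 (`PP.H0` .. `PP.H4`), sums to 1.
#' @slot priors named numeric (`p1`, `p2`, `p12`).
#'
#' @seealso [colocalize()], [wakefieldLABF()]
#' @export
setClass("ColocResult",
  slots = c(variantIds = "character",
            labf1 = "numeric",
            labf2 = "numeric",
            pp    = "numeric",
            priors = "numeric"))

setValidity("ColocResult", function(object) {
  if (length(object@pp) != 5L) return("pp must have 5 entries")
  if (any(object@pp < 0)) return("pp entries must be >= 0")
  if (abs(sum(object@pp) - 1) > 1e-12) return("pp must sum to 1 (tol 1e-12)")
  if (any(!is.finite(object@labf1)) || any(!is.finite(object@labf2)))
    return("labf values must be finite")
  TRUE
})

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot globalRSS observed leave-one-out residual sum of squares.
#' @slot globalPval simulation p-value (add-one rule; never 0).
#' @slot perSNPPval raw per-variant simulation p-values.
#' @slot perSNPPvalAdj Bonferroni-adjusted copy.
#' @slot outlierIds variants flagged at the adjusted threshold.
#' @slot corrected IVW [MREstimate] after outlier removal.
#' @slot distortionPval distortion-test p (`NA` when no outliers).
#' @slot nSim,seed simulation settings used.
#'
#' @seealso [mrPresso()]
#' @export
setClass("PressoResult",
  slots = c(globalRSS  = "numeric",
            globalPval = "numeric",
            perSNPPval = "numeric",
            perSNPPvalAdj = "numeric",
            outlierIds = "character",
            corrected  = "MREstimate",
            distortionPval = "numeric",
            nSim = "integer",
            seed = "integer"))

#' RadialResult: radial-MR outlier diagnostics
#'
#' @slot theta radial IVW estimate at the final iteration (identical to
#'   [mrIVW()] on the retained variants, a first-order-weights identity).
#' @slot qTotal total Q at the final fit.
#' @slot perSNPQ per-variant Q contributions.
#' @slot perSNPPval chi-square(1) upper tails of `perSNPQ`.
#' @slot outlierIds variants removed over all iterations.
#' @slot keptIds variants retained at the final fit.
#' @slot iterations number of fit-remove rounds performed.
#'
#' @seealso [radialIVW()]
#' @export
setClass("RadialResult",
  slots = c(theta = "numeric",
            qTotal = "numeric",
            perSNPQ = "numeric",
            perSNPPval = "numeric",
            outlierIds = "character",
            keptIds = "character",
            iterations = "integer"))

#' MediationResult: two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation: `indirect = beta1 * beta2`,
#' `proportion = indirect / total`, with a first-order delta-method SE for
#' the product and (by default) the total effect treated as fixed in the
#' proportion SE.  The proportion is stored as a fraction; reports print it
#' as a percentage.
#'
#' @slot beta1,se1 exposure-to-mediator effect (SD per SD) and SE.
#' @slot beta2,se2 mediator-to-outcome effect adjusted for the exposure
#'   (log-odds per SD) and SE.
#' @slot total,seTotal total exposure-to-outcome effect (log-odds) and SE.
#' @slot indirect,seIndirect product `beta1*beta2` and delta-method SE.
#' @slot proportion,seProp,ciLow,ciHigh,pval mediated proportion (fraction),
#'   SE, 95% CI and two-sided normal p.
#' @slot mediator mediator label.
#'
#' @seealso [mediationProportion()]
#' @export
setClass("MediationResult",
  slots = c(mediator = "character",
            beta1 = "numeric", se1 = "numeric",
            beta2 = "numeric", se2 = "numeric",
            total = "numeric", seTotal = "numeric",
            indirect = "numeric", seIndirect = "numeric",
            proportion = "numeric", seProp = "numeric",
            ciLow = "numeric", ciHigh = "numeric",
            pval = "numeric"))

setValidity("MediationResult", function(object) {
  if (abs(object@indirect - object@beta1 * object@beta2) > 1e-12)
    return("indirect must equal beta1*beta2")
  if (abs(object@proportion - object@indirect / object@total) > 1e-12)
    return("proportion must equal indirect/total")
  TRUE
})
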