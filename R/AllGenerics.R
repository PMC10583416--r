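#' Accessors for medimr classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a medimr S4 object.
#' @return The corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitName", function(object) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(object) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("ldValues", function(object) standardGeneric("ldValues"))
#' @rdname accessors
#' @export
setGeneric("exposureNames", function(object) standardGeneric("exposureNames"))
#' @rdname accessors
#' @export
setGeneric("betaExp", function(object) standardGeneric("betaExp"))
#' @rdname accessors
#' @export
setGeneric("seExp", function(object) standardGeneric("seExp"))
#' @rdname accessors
#' @export
setGeneric("betaOut", function(object) standardGeneric("betaOut"))
#' @rdname accessors
#' @export
setGeneric("seOut", function(object) standardGeneric("seOut"))
#' @rdname accessors
#' @export
setGeneric("droppedVariants", function(object) standardGeneric("droppedVariants"))
#' @rdname accessors
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("orScale", function(object) standardGeneric("orScale"))
#' @rdname accessors
#' @export
setGeneric("cochranQStat", function(object) standardGeneric("cochranQStat"))
#' @rdname accessors
#' @export
setGeneric("eggerIntercept", function(object) standardGeneric("eggerIntercept"))
#' @rdname accessors
#' @export
setGeneric("fStatistics", function(object) standardGeneric("fStatistics"))
#' @rdname accessors
#' @export
setGeneric("weakFlags", function(object) standardGeneric("weakFlags"))
#' @rdname accessors
#' @export
setGeneric("selectionLog", function(object) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setGeneric("posteriorProbs", function(object) standardGeneric("posteriorProbs"))
#' @rdname accessors
#' @export
setGeneric("outlierIds", function(object) standardGeneric("outlierIds"))
#' @rdname accessors
#' @export
setGeneric("mediatedProportion", function(object) standardGeneric("mediatedProportion"))

setMethod("traitName", "SummaryStats", function(object) object@traitName)
setMethod("traitType", "SummaryStats", function(object) object@traitType)
setMethod("records", "SummaryStats", function(object) object@records)
setMethod("variantIds", "SummaryStats", function(object) object@records$variant_id)
setMethod("nVariants", "SummaryStats", function(object) nrow(object@records))

setMethod("variantIds", "LDMatrix", function(object) object@variantIds)
setMethod("nVariants", "LDMatrix", function(object) length(object@variantIds))
setMethod("ldValues", "LDMatrix", function(object) {
  m <- object@r
  dimnames(m) <- list(object@variantIds, object@variantIds)
  m
})

setMethod("variantIds", "HarmonizedSet", function(object) object@variantIds)
setMethod("nVariants", "HarmonizedSet", function(object) length(object@variantIds))
setMethod("exposureNames", "HarmonizedSet", function(object) object@exposureNames)
setMethod("betaExp", "HarmonizedSet", function(object) object@betaExp)
setMethod("seExp", "HarmonizedSet", function(object) object@seExp)
setMethod("betaOut", "HarmonizedSet", function(object) object@betaOut)
setMethod("seOut", "HarmonizedSet", function(object) object@seOut)
setMethod("droppedVariants", "HarmonizedSet", function(object) object@dropped)

setMethod("theta", "MREstimate", function(object) object@theta)
setMethod("stdError", "MREstimate", function(object) object@se)
setMethod("confInt", "MREstimate",
          function(object) c(object@ciLow, object@ciHigh))
setMethod("pValue", "MREstimate", function(object) object@pval)
setMethod("orScale", "MREstimate", function(object) {
  if (!object@outcomeBinary)
    stop("orScale is only defined for binary outcomes")
  c(or = exp(object@theta), or_low = exp(object@ciLow),
    or_high = exp(object@ciHigh))
})
setMethod("cochranQStat", "MREstimate",
          function(object) c(q = object@q, q_pval = object@qPval))
setMethod("eggerIntercept", "MREstimate",
          function(object) c(intercept = object@eggerIntercept,
                             pval = object@eggerInterceptPval))

setMethod("variantIds", "InstrumentSet", function(object) object@variants$variant_id)
setMethod("nVariants", "InstrumentSet", function(object) nrow(object@variants))
setMethod("records", "InstrumentSet", function(object) object@variants)
setMethod("fStatistics", "InstrumentSet", function(object) object@fStats)
setMethod("weakFlags", "InstrumentSet", function(object) object@weakFlags)
setMethod("selectionLog", "InstrumentSet", function(object) object@selectionLog)

setMethod("variantIds", "ColocResult", function(object) object@variantIds)
setMethod("posteriorProbs", "ColocResult", function(object) object@pp)

setMethod("outlierIds", "PressoResult", function(object) object@outlierIds)
setMethod("outlierIds", "RadialResult", function(object) object@outlierIds)
setMethod("theta", "RadialResult", function(object) object@theta)

setMethod("theta", "MediationResult", function(object) object@indirect)
setMethod("mediatedProportion", "MediationResult", function(object) {
  c(proportion = object@proportion, se = object@seProp,
    ci_low = object@ciLow, ci_high = object@ciHigh, pval = object@pval)
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats '", object@traitName, "' (", object@traitType, "): ",
      nrow(object@records), " variants\n", sep = "")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix: ", length(object@variantIds), " variants\n", sep = "")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet: ", length(object@variantIds), " variants, exposures [",
      paste(object@exposureNames, collapse = ", "), "] -> outcome '",
      object@outcomeName, "'; ", nrow(object@dropped), " dropped\n", sep = "")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s] %s: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, nSNP = %d\n",
              object@method, object@exposure, object@theta, object@se,
              object@ciLow, object@ciHigh, object@pval, object@nSNP))
  if (object@outcomeBinary)
    cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", exp(object@theta),
                exp(object@ciLow), exp(object@ciHigh)))
  if (is.finite(object@q))
    cat(sprintf("  Cochran's Q = %.3f (p = %.3g)\n", object@q, object@qPval))
  if (is.finite(object@eggerIntercept))
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptPval))
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet '", object@exposureName, "': ", nrow(object@variants),
      " instruments", sep = "")
  if (nrow(object@variants))
    cat(sprintf(" (min F = %.1f, %d weak)", min(object@fStats),
                sum(object@weakFlags)))
  if (nzchar(object@reason)) cat(" [", object@reason, "]", sep = "")
  cat("\n")
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", length(object@variantIds), "variants\n")
  print(round(object@pp, 4))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %.4g (%d sims)\n",
              object@globalRSS, object@globalPval, object@nSim))
  cat("  outliers:", if (length(object@outlierIds))
    paste(object@outlierIds, collapse = ", ") else "none", "\n")
})

setMethod("show", "RadialResult", function(object) {
  cat(sprintf("Radial MR: theta = %.4f, Q = %.3f, %d outlier(s), %d iteration(s)\n",
              object@theta, object@qTotal, length(object@outlierIds),
              object@iterations))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult '%s':\n", object@mediator))
  cat(sprintf("  beta1 = %.4f (SE %.4f); beta2 = %.4f (SE %.4f); total = %.4f\n",
              object@beta1, object@se1, object@beta2, object@se2, object@total))
  cat(sprintf("  indirect = %.4f (SE %.4f)\n", object@indirect, object@seIndirect))
  cat(sprintf("  mediated proportion = %.2f%% [%.2f%%, %.2f%%], p = %.3g\n",
              100 * object@proportion, 100 * object@ciLow,
              100 * object@ciHigh, object@pval))
})
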