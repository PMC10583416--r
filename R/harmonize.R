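COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics to a common allele
#'
#' Aligns every trait's effect to the first exposure's effect allele so
#' that all betas are expressed per copy of the same allele — the
#' precondition for every two-sample MR estimator.  For each shared
#' variant: an exact allele match is kept as-is; swapped effect/other
#' alleles negate the beta and mirror the eaf; strand-complement matches
#' are resolved by complementing before aligning; palindromic variants
#' (A/T or C/G), whose strand cannot be resolved from alleles, are handled
#' per `palindrome_policy`; any other allele pair is dropped with a reason.
#'
#' All traits are assumed reported on the forward strand unless alleles
#' only match by complement; complement resolution is attempted before
#' dropping.
#'
#' @param exposures a [SummaryStats-class] or list of them (>= 1), already
#'   restricted to the instrument variants; the first is the reference.
#' @param outcome a [SummaryStats-class] for the outcome trait.
#' @param palindrome_policy `"drop_all"` drops every palindromic variant;
#'   `"infer_by_eaf"` keeps one when every trait's eaf lies outside the
#'   ambiguity window and orients it by frequency agreement (both traits'
#'   eaf on the same side of 0.5 means same strand), otherwise drops it.
#'   A palindromic variant with any missing eaf is always dropped.
#' @param eaf_window ambiguity window on the eaf for palindromic variants;
#'   default `c(0.42, 0.58)`.
#' @return A [HarmonizedSet-class].  The attribute `"aligned"` holds the
#'   post-alignment [SummaryStats-class] objects (reference alleles,
#'   flipped betas/eafs), on which `harmonize` is idempotent.
#' @examples
#' ex <- SummaryStats(data.frame(
#'   variant_id = "rs1", chrom = "1", pos = 100, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.01,
#'   pval = 1e-10, n = 1e5), "exposure")
#' out <- SummaryStats(data.frame(
#'   variant_id = "rs1", chrom = "1", pos = 100, effect_allele = "G",
#'   other_allele = "A", eaf = 0.7, beta = -0.05, se = 0.02,
#'   pval = 0.01, n = 1e5), "outcome", "binary")
#' h <- harmonize(ex, out)
#' betaOut(h)  # sign-flipped to +0.05
#' @export
harmonize <- function(exposures, outcome,
                      palindrome_policy = c("drop_all", "infer_by_eaf"),
                      eaf_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (is(exposures, "SummaryStats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1L, is(outcome, "SummaryStats"))
  traits <- c(exposures, list(outcome))
  k <- length(exposures)

  shared <- Reduce(intersect, lapply(traits, variantIds))
  if (!length(shared)) stop("zero shared variants across traits")

  ref <- records(subsetStats(exposures[[1L]], shared))
  recs <- lapply(traits, function(s) records(subsetStats(s, shared)))

  J <- length(shared)
  nT <- length(traits)
  keep <- rep(TRUE, J)
  reason <- character(J)
  # flip[j, t]: negate trait t's beta (and mirror eaf) at variant j
  flip <- matrix(FALSE, J, nT)

  palin <- isPalindromic(ref$effect_allele, ref$other_allele)

  for (t in seq_len(nT)) {
    r <- recs[[t]]
    ea <- r$effect_allele; oa <- r$other_allele
    cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
    exact    <- ea == ref$effect_allele & oa == ref$other_allele
    swapped  <- ea == ref$other_allele  & oa == ref$effect_allele
    cexact   <- cea == ref$effect_allele & coa == ref$other_allele
    cswapped <- cea == ref$other_allele  & coa == ref$effect_allele
    compatible <- exact | swapped | cexact | cswapped
    bad <- keep & !compatible & !palin
    keep[bad] <- FALSE
    reason[bad] <- "incompatible alleles"
    flip[, t] <- flip[, t] | (!palin & (swapped | (cswapped & !exact)))
  }

  if (any(palin)) {
    if (palindrome_policy == "drop_all") {
      drop_p <- keep & palin
      keep[drop_p] <- FALSE
      reason[drop_p] <- "palindromic"
    } else {
      eafs <- vapply(recs, function(r) r$eaf, numeric(J))
      if (J == 1L) eafs <- matrix(eafs, nrow = 1L)
      miss <- keep & palin & apply(eafs, 1L, anyNA)
      keep[miss] <- FALSE
      reason[miss] <- "palindromic missing eaf"
      amb <- keep & palin &
        apply(eafs, 1L, function(e)
          any(e >= eaf_window[1L] & e <= eaf_window[2L]))
      keep[amb] <- FALSE
      reason[amb] <- "palindromic ambiguous"
      ok <- which(keep & palin)
      # same side of 0.5 as the reference eaf => same strand orientation
      for (j in ok) {
        for (t in seq_len(nT))
          flip[j, t] <- (eafs[j, t] < 0.5) != (eafs[j, 1L] < 0.5)
      }
    }
  }

  # apply flips to build aligned per-trait records
  aligned <- vector("list", nT)
  for (t in seq_len(nT)) {
    r <- recs[[t]]
    f <- flip[, t]
    r$beta[f] <- -r$beta[f]
    r$eaf[f] <- 1 - r$eaf[f]
    r$effect_allele <- ref$effect_allele
    r$other_allele <- ref$other_allele
    aligned[[t]] <- r
  }

  # drop rows with any non-finite retained numerics (defensive; validated
  # SummaryStats should not contain them)
  for (t in seq_len(nT)) {
    bad <- keep & (!is.finite(aligned[[t]]$beta) | !is.finite(aligned[[t]]$se))
    keep[bad] <- FALSE
    reason[bad] <- "missing effect"
  }

  idx <- which(keep)
  dropped <- data.frame(variant_id = shared[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (!length(idx))
    stop("no variants retained after harmonization (",
         paste(unique(dropped$reason), collapse = "; "), ")")

  betaE <- vapply(aligned[seq_len(k)], function(r) r$beta[idx],
                  numeric(length(idx)))
  seE <- vapply(aligned[seq_len(k)], function(r) r$se[idx],
                numeric(length(idx)))
  if (length(idx) == 1L) {
    betaE <- matrix(betaE, nrow = 1L)
    seE <- matrix(seE, nrow = 1L)
  }
  expNames <- vapply(exposures, traitName, character(1))
  colnames(betaE) <- colnames(seE) <- expNames

  h <- new("HarmonizedSet",
           variantIds = shared[idx],
           exposureNames = expNames,
           betaExp = betaE, seExp = seE,
           betaOut = aligned[[nT]]$beta[idx],
           seOut = aligned[[nT]]$se[idx],
           effectAllele = ref$effect_allele[idx],
           otherAllele = ref$other_allele[idx],
           outcomeName = traitName(outcome),
           outcomeType = traitType(outcome),
           dropped = dropped)
  attr(h, "aligned") <- lapply(seq_len(nT), function(t) {
    r <- aligned[[t]][idx, , drop = FALSE]
    rownames(r) <- NULL
    new("SummaryStats", traitName = traitName(traits[[t]]),
        traitType = traitType(traits[[t]]), records = r)
  })
  h
}

# Restrict a HarmonizedSet to a subset of variants (MR-PRESSO / radial
# refits); keeps exposure columns.
subsetHarmonized <- function(h, ids) {
  idx <- match(ids, h@variantIds)
  if (anyNA(idx)) stop("unknown variant id(s) in subset")
  new("HarmonizedSet",
      variantIds = h@variantIds[idx],
      exposureNames = h@exposureNames,
      betaExp = h@betaExp[idx, , drop = FALSE],
      seExp = h@seExp[idx, , drop = FALSE],
      betaOut = h@betaOut[idx], seOut = h@seOut[idx],
      effectAllele = h@effectAllele[idx], otherAllele = h@otherAllele[idx],
      outcomeName = h@outcomeName, outcomeType = h@outcomeType,
      dropped = h@dropped)
}

# Build a HarmonizedSet directly from aligned numeric vectors/matrices;
# used by the simulator and tests where alleles are already consistent.
makeHarmonizedSet <- function(beta_exp, se_exp, beta_out, se_out,
                              variant_ids = NULL,
                              exposure_names = NULL,
                              outcome_name = "outcome",
                              outcome_type = "binary") {
  beta_exp <- as.matrix(beta_exp)
  se_exp <- as.matrix(se_exp)
  J <- nrow(beta_exp); k <- ncol(beta_exp)
  if (is.null(variant_ids)) variant_ids <- paste0("rs", seq_len(J))
  if (is.null(exposure_names))
    exposure_names <- if (k == 1L) "exposure" else paste0("exposure", seq_len(k))
  colnames(beta_exp) <- colnames(se_exp) <- exposure_names
  new("HarmonizedSet",
      variantIds = as.character(variant_ids),
      exposureNames = exposure_names,
      betaExp = beta_exp, seExp = se_exp,
      betaOut = as.numeric(beta_out), seOut = as.numeric(se_out),
      effectAllele = rep("A", J), otherAllele = rep("G", J),
      outcomeName = outcome_name, outcomeType = outcome_type,
      dropped = data.frame(variant_id = character(), reason = character(),
                           stringsAsFactors = FALSE))
}
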