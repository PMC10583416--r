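makeInstrumentSet <- function(exposure_name, variants, selection_log,
                              reason = "") {
  f <- if (nrow(variants)) (variants$beta / variants$se)^2 else numeric()
  rownames(variants) <- NULL
  new("InstrumentSet",
      exposureName = exposure_name,
      variants = variants,
      fStats = f,
      weakFlags = unname(f < 10),
      selectionLog = selection_log,
      reason = reason)
}

logStep <- function(log, step, n_before, n_after) {
  rbind(log, data.frame(step = step, n_before = n_before, n_after = n_after,
                        stringsAsFactors = FALSE))
}

emptyLog <- function() {
  data.frame(step = character(), n_before = integer(), n_after = integer(),
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping of variants by p-value
#'
#' Standard clumping semantics: repeatedly keep the not-yet-removed variant
#' with the smallest p-value (ties broken by lexicographic variant id) and
#' remove all unkept variants that are BOTH in LD with it (r^2 at or above
#' `r2_threshold`) AND within `window_kb` of it.  Correlated variants
#' further apart than the window are retained.  Any two kept variants
#' within the window have r^2 below the threshold.
#'
#' @param variants data.frame with columns `variant_id`, `pos`, `pval`.
#' @param ld an [LDMatrix-class] covering all variants.
#' @param r2_threshold r-squared threshold in (0, 1].
#' @param window_kb distance window in kilobases (> 0).
#' @return Character vector of kept variant ids, in selection order.
#' @export
clumpVariants <- function(variants, ld, r2_threshold, window_kb) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  if (!nrow(variants)) return(character())
  missing_ld <- setdiff(variants$variant_id, variantIds(ld))
  if (length(missing_ld))
    stop("variant(s) absent from LD matrix: ",
         paste(missing_ld, collapse = ", "))
  r2 <- ldValues(ld)[variants$variant_id, variants$variant_id, drop = FALSE]^2
  ord <- order(variants$pval, variants$variant_id)
  pos <- variants$pos
  active <- rep(TRUE, nrow(variants))
  kept <- integer()
  for (i in ord) {
    if (!active[i]) next
    kept <- c(kept, i)
    hit <- active & r2[i, ] >= r2_threshold &
      abs(pos - pos[i]) <= window_kb * 1000
    active[hit] <- FALSE
  }
  variants$variant_id[kept]
}

#' Select genome-wide significant, LD-independent instruments
#'
#' Instrument selection for a biomarker or metabolite exposure: keep
#' variants below the significance threshold, clump the survivors, and
#' attach per-variant F statistics (F = (beta/se)^2) with weak-instrument
#' flags at F < 10.  Defaults follow genome-wide convention for metabolite
#' GWAS: p < 5e-8, clumping r^2 < 0.01 within 10,000 kb.
#'
#' @param stats exposure [SummaryStats-class].
#' @param ld [LDMatrix-class] covering the candidate variants.
#' @param p_threshold significance threshold in (0, 1).
#' @param r2_threshold,window_kb clumping parameters (see [clumpVariants()]).
#' @return An [InstrumentSet-class]; empty (with the selection log) when no
#'   variant survives.
#' @export
selectBiomarkerInstruments <- function(stats, ld, p_threshold = 5e-8,
                                       r2_threshold = 0.01,
                                       window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  r <- records(stats)
  log <- emptyLog()
  sig <- r[r$pval < p_threshold, , drop = FALSE]
  log <- logStep(log, "p_filter", nrow(r), nrow(sig))
  if (!nrow(sig))
    return(makeInstrumentSet(traitName(stats), sig, log))
  kept <- clumpVariants(sig[, c("variant_id", "pos", "pval")], ld,
                        r2_threshold, window_kb)
  out <- sig[match(kept, sig$variant_id), , drop = FALSE]
  log <- logStep(log, "clump", nrow(sig), nrow(out))
  makeInstrumentSet(traitName(stats), out, log)
}

#' Select drug-target instruments via eQTL region, biomarker filter,
#' colocalization gate, and permissive clumping
#'
#' Instrument selection for a genetically proxied drug target: restrict to
#' eQTL variants inside the target gene's region, require association with
#' the downstream biomarker below `p_threshold`, optionally gate the whole
#' locus on colocalization evidence (posterior probability of a shared
#' causal variant at or above `pp_threshold`), then clump permissively.
#' With `invert_sign = TRUE` the retained exposure betas are negated so the
#' exposure axis reads as biomarker DECREASE — one SD lowering of the
#' biomarker proxies pharmacological inhibition of the target.
#'
#' The retained `variants` are the biomarker associations (the exposure is
#' scaled in biomarker SD units); defaults follow drug-target practice:
#' biomarker p < 1e-4, clumping r^2 < 0.8 within 250 kb.  The permissive
#' r^2 means retained instruments may be correlated; downstream estimators
#' use the independent-instrument working model regardless (documented
#' limitation).
#'
#' @param eqtl eQTL [SummaryStats-class] for the target gene's expression.
#' @param biomarker downstream-biomarker [SummaryStats-class].
#' @param gene_region list/vector with `chrom`, `start`, `end` (1-based bp).
#' @param ld [LDMatrix-class].
#' @param p_threshold biomarker significance threshold.
#' @param coloc_gate optional [ColocResult-class] for the locus.
#' @param pp_threshold minimal PP.H4 for the gate (default 0.7).
#' @param r2_threshold,window_kb clumping parameters.
#' @param invert_sign negate exposure betas (biomarker-lowering axis).
#' @return An [InstrumentSet-class]; empty with a recorded reason when no
#'   eQTL variant falls in the region or the colocalization gate fails.
#' @export
selectDrugTargetInstruments <- function(eqtl, biomarker, gene_region, ld,
                                        p_threshold = 1e-4,
                                        coloc_gate = NULL,
                                        pp_threshold = 0.7,
                                        r2_threshold = 0.8,
                                        window_kb = 250,
                                        invert_sign = TRUE) {
  stopifnot(pp_threshold > 0, pp_threshold < 1)
  region <- as.list(gene_region)
  stopifnot(!is.null(region$chrom), !is.null(region$start), !is.null(region$end),
            region$start <= region$end)
  e <- records(eqtl)
  log <- emptyLog()
  in_region <- e$chrom == as.character(region$chrom) &
    e$pos >= region$start & e$pos <= region$end
  log <- logStep(log, "eqtl_region", nrow(e), sum(in_region))
  empty <- function(log, why) {
    makeInstrumentSet(traitName(biomarker),
                      records(biomarker)[0, , drop = FALSE], log, reason = why)
  }
  if (!any(in_region)) return(empty(log, "no eQTL variants in gene region"))

  b <- records(biomarker)
  cand <- b[b$variant_id %in% e$variant_id[in_region] &
              b$pval < p_threshold, , drop = FALSE]
  log <- logStep(log, "biomarker_p", sum(in_region), nrow(cand))
  if (!nrow(cand)) return(empty(log, "no biomarker-significant eQTL variants"))

  if (!is.null(coloc_gate)) {
    pp4 <- unname(posteriorProbs(coloc_gate)["PP.H4"])
    pass <- pp4 >= pp_threshold
    log <- logStep(log, "coloc_gate", nrow(cand), if (pass) nrow(cand) else 0L)
    if (!pass) return(empty(log, "colocalization failed"))
  }

  kept <- clumpVariants(cand[, c("variant_id", "pos", "pval")], ld,
                        r2_threshold, window_kb)
  out <- cand[match(kept, cand$variant_id), , drop = FALSE]
  log <- logStep(log, "clump", nrow(cand), nrow(out))
  if (invert_sign) out$beta <- -out$beta
  makeInstrumentSet(traitName(biomarker), out, log)
}
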