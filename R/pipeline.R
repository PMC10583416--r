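# Adler-style checksum of a serialized object; provenance
# change-detection only, not cryptographic.
configHash <- function(x) {
  b <- as.numeric(serialize(x, NULL, version = 2L))
  n <- length(b)
  s1 <- (1 + sum(b)) %% 65521
  s2 <- (n + sum(b * (n:1))) %% 65521
  sprintf("%04x%04x", as.integer(s2), as.integer(s1))
}

flipTraitSign <- function(stats) {
  r <- records(stats)
  r$beta <- -r$beta
  new("SummaryStats", traitName = traitName(stats),
      traitType = traitType(stats), records = r)
}

statsFromInstruments <- function(instr) {
  new("SummaryStats", traitName = instr@exposureName,
      traitType = "quantitative", records = records(instr))
}

loadTrait <- function(x, name, type) {
  if (is(x, "SummaryStats")) return(x)
  readSummaryStats(x, trait_name = name, trait_type = type)
}

#' Configuration for the two-step mediation MR pipeline
#'
#' Inputs may be in-memory objects ([SummaryStats-class] / [LDMatrix-class],
#' e.g. from [simulateMRStudy()]) or TSV file paths.
#'
#' @param exposure exposure biomarker stats (object or path).
#' @param mediators named list of mediator stats (objects or paths).
#' @param outcome outcome stats (object or path).
#' @param ld LD matrix (object or path).
#' @param eqtl optional eQTL stats for drug-target instrument selection;
#'   when given, `gene_region` is required and the colocalization gate is
#'   applied over the region with `pp_threshold`.
#' @param gene_region list(`chrom`, `start`, `end`) for the target gene.
#' @param exposure_p,exposure_r2,exposure_window_kb exposure instrument
#'   selection thresholds.  Defaults are genome-wide (5e-8, 0.01,
#'   10,000 kb); drug-target selection conventionally relaxes these to
#'   1e-4, 0.8, 250 kb.
#' @param mediator_p,mediator_r2,mediator_window_kb mediator instrument
#'   selection thresholds (genome-wide defaults).
#' @param pp_threshold colocalization gate on PP.H4 (default 0.7).
#' @param invert_sign negate exposure betas so the exposure axis is
#'   biomarker decrease ("per 1 SD lowering"); default TRUE.
#' @param methods univariable estimators for the main table; subset of
#'   `ivw`, `egger`, `weighted_median`, `simple_mode`, `weighted_mode`,
#'   `presso`.
#' @param alpha family-wise error rate for the Bonferroni cascade.
#' @param outlier_filter remove the union of MR-PRESSO and radial-MR
#'   outliers before every MR fit (default TRUE).
#' @param palindrome_policy passed to [harmonize()].
#' @param n_boot,n_sim bootstrap / simulation sizes.
#' @param seed master seed; all stage seeds derive from it.
#' @return Validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(exposure, mediators, outcome, ld,
                           eqtl = NULL, gene_region = NULL,
                           exposure_p = 5e-8, exposure_r2 = 0.01,
                           exposure_window_kb = 10000,
                           mediator_p = 5e-8, mediator_r2 = 0.01,
                           mediator_window_kb = 10000,
                           pp_threshold = 0.7,
                           invert_sign = TRUE,
                           methods = c("ivw", "egger", "weighted_median",
                                       "simple_mode", "weighted_mode",
                                       "presso"),
                           alpha = 0.05,
                           outlier_filter = TRUE,
                           palindrome_policy = "drop_all",
                           n_boot = 1000L, n_sim = 1000L,
                           seed) {
  known <- c("ivw", "egger", "weighted_median", "simple_mode",
             "weighted_mode", "presso")
  stopifnot(all(methods %in% known), "ivw" %in% methods,
            alpha > 0, alpha < 1, length(mediators) >= 1)
  if (is.null(names(mediators)) || any(!nzchar(names(mediators))))
    stop("mediators must be a named list")
  if (!is.null(eqtl) && is.null(gene_region))
    stop("gene_region required for drug-target selection")
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(exposure = exposure, mediators = mediators,
                 outcome = outcome, ld = ld,
                 eqtl = eqtl, gene_region = gene_region,
                 exposure_p = exposure_p, exposure_r2 = exposure_r2,
                 exposure_window_kb = exposure_window_kb,
                 mediator_p = mediator_p, mediator_r2 = mediator_r2,
                 mediator_window_kb = mediator_window_kb,
                 pp_threshold = pp_threshold,
                 invert_sign = invert_sign, methods = methods,
                 alpha = alpha, outlier_filter = outlier_filter,
                 palindrome_policy = palindrome_policy,
                 n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

estimateRow <- function(est) {
  qv <- cochranQStat(est)
  ic <- eggerIntercept(est)
  binary <- est@outcomeBinary
  data.frame(method = est@method, exposure = est@exposure,
             nsnp = est@nSNP, theta = theta(est), se = stdError(est),
             ci_low = est@ciLow, ci_high = est@ciHigh, pval = pValue(est),
             or = if (binary) exp(theta(est)) else NA_real_,
             or_low = if (binary) exp(est@ciLow) else NA_real_,
             or_high = if (binary) exp(est@ciHigh) else NA_real_,
             q = qv[["q"]], q_pval = qv[["q_pval"]],
             egger_intercept = ic[["intercept"]],
             egger_intercept_pval = ic[["pval"]],
             stringsAsFactors = FALSE)
}

runBattery <- function(h, methods, n_boot, n_sim, seed) {
  rows <- list()
  for (m in methods) {
    est <- switch(m,
      ivw = mrIVW(h),
      egger = if (nVariants(h) >= 3L) mrEgger(h) else NULL,
      weighted_median = if (nVariants(h) >= 3L)
        mrWeightedMedian(h, n_boot, seed + 11L) else NULL,
      simple_mode = if (nVariants(h) >= 3L)
        mrMode(h, weighted = FALSE, n_boot = n_boot, seed = seed + 12L)
        else NULL,
      weighted_mode = if (nVariants(h) >= 3L)
        mrMode(h, weighted = TRUE, n_boot = n_boot, seed = seed + 13L)
        else NULL,
      presso = if (nVariants(h) >= 4L) {
        pr <- mrPresso(h, n_sim, seed + 14L)
        est <- pr@corrected
        est@method <- "ivw"      # corrected IVW; relabel row below
        row <- estimateRow(est)
        row$method <- "presso"
        row$q <- pr@globalRSS
        row$q_pval <- pr@globalPval
        rows[[m]] <- row
        NULL
      } else NULL)
    if (!is.null(est)) rows[[m]] <- estimateRow(est)
  }
  do.call(rbind, rows)
}

screenOne <- function(instr_stats, target_stats, cfg, seed_off) {
  h <- harmonize(instr_stats, target_stats,
                 palindrome_policy = cfg$palindrome_policy)
  outliers <- character()
  if (cfg$outlier_filter && nVariants(h) >= 3L) {
    fo <- filterOutliers(h, cfg$n_sim, cfg$seed + seed_off, cfg$alpha)
    h <- fo$kept
    outliers <- fo$outliers
  }
  est <- mrIVW(h)
  list(h = h, est = est, outliers = outliers)
}

#' Run the two-step mediation MR pipeline end-to-end
#'
#' Orchestrates: exposure instrument selection (drug-target route with the
#' colocalization gate when `eqtl` is configured, biomarker route
#' otherwise) -> outlier pre-filtering -> the univariable estimator
#' battery for the total exposure-outcome effect -> mediator screen 1
#' (exposure -> each of M mediators, Bonferroni alpha/M on IVW) -> screen 2
#' (each survivor -> outcome with its own instruments, alpha/m1) -> MVMR
#' adjusting the mediator effect for the exposure (alpha/m2) -> mediation
#' proportions with delta-method CIs.  Bonferroni thresholds always use
#' the realized family sizes.  An empty stage stops the cascade and is
#' recorded in `skipped`.
#'
#' @param config a [pipelineConfig()] list.
#' @return List of class `PipelineReport`: data.frames `table1`,
#'   `screen1`, `screen2`, `table2`, `mediation`; `mediationResults`
#'   ([MediationResult-class] list); `instruments`
#'   ([InstrumentSet-class]); `thresholds`; `outliers`; `skipped`;
#'   `provenance` (config hash, seed, package version).
#' @export
runTwoStepPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  exposure <- loadTrait(cfg$exposure, "exposure", "quantitative")
  outcome <- loadTrait(cfg$outcome, "outcome", "binary")
  mediators <- lapply(seq_along(cfg$mediators), function(i)
    loadTrait(cfg$mediators[[i]], names(cfg$mediators)[i], "quantitative"))
  names(mediators) <- names(cfg$mediators)
  ld <- if (is(cfg$ld, "LDMatrix")) cfg$ld else readLDMatrix(cfg$ld)

  if (cfg$invert_sign) exposure <- flipTraitSign(exposure)
  skipped <- character()
  report <- list(table1 = NULL, screen1 = NULL, screen2 = NULL,
                 table2 = NULL, mediation = NULL, mediationResults = list(),
                 thresholds = list(), outliers = list(), skipped = character(),
                 provenance = list(
                   config_hash = configHash(cfg), seed = cfg$seed,
                   version = as.character(utils::packageVersion("medimr"))))
  class(report) <- "PipelineReport"

  # --- stage 1: exposure instruments -------------------------------------
  instr <- if (!is.null(cfg$eqtl)) {
    eqtl <- loadTrait(cfg$eqtl, "eqtl", "quantitative")
    gr <- as.list(cfg$gene_region)
    er <- records(eqtl)
    rg <- er$variant_id[er$chrom == as.character(gr$chrom) &
                          er$pos >= gr$start & er$pos <= gr$end]
    gate <- if (length(rg) >= 1L)
      colocalize(subsetStats(eqtl, rg), subsetStats(exposure, rg)) else NULL
    selectDrugTargetInstruments(eqtl, exposure, gr, ld,
                                p_threshold = cfg$exposure_p,
                                coloc_gate = gate,
                                pp_threshold = cfg$pp_threshold,
                                r2_threshold = cfg$exposure_r2,
                                window_kb = cfg$exposure_window_kb,
                                invert_sign = FALSE)
  } else {
    selectBiomarkerInstruments(exposure, ld, p_threshold = cfg$exposure_p,
                               r2_threshold = cfg$exposure_r2,
                               window_kb = cfg$exposure_window_kb)
  }
  report$instruments <- instr
  if (nVariants(instr) < 2L) {
    report$skipped <- c("uvmr", "screen1", "screen2", "mvmr", "mediation")
    return(report)
  }
  instr_stats <- statsFromInstruments(instr)

  # --- stage 2: total effect (UVMR battery) ------------------------------
  h_main <- harmonize(instr_stats, outcome,
                      palindrome_policy = cfg$palindrome_policy)
  if (cfg$outlier_filter && nVariants(h_main) >= 3L) {
    fo <- filterOutliers(h_main, cfg$n_sim, cfg$seed + 1L, cfg$alpha)
    h_main <- fo$kept
    report$outliers$main <- fo$outliers
  }
  report$table1 <- runBattery(h_main, cfg$methods, cfg$n_boot, cfg$n_sim,
                              cfg$seed + 100L)
  total_est <- mrIVW(h_main)

  # --- stage 3: screen 1, exposure -> mediators --------------------------
  M <- length(mediators)
  thr1 <- bonferroniThreshold(cfg$alpha, M)
  s1 <- lapply(seq_len(M), function(i) {
    sc <- screenOne(instr_stats, mediators[[i]], cfg, 200L + i)
    data.frame(candidate = names(mediators)[i],
               nsnp = nVariants(sc$h),
               beta1 = theta(sc$est), se1 = stdError(sc$est),
               pval = pValue(sc$est),
               bonferroni_threshold = thr1,
               passed = pValue(sc$est) < thr1,
               stringsAsFactors = FALSE)
  })
  report$screen1 <- do.call(rbind, s1)
  report$thresholds <- list(M = M, thr1 = thr1)
  surv1 <- report$screen1$candidate[report$screen1$passed]
  if (!length(surv1)) {
    report$skipped <- c("screen2", "mvmr", "mediation")
    return(report)
  }

  # --- stage 4: screen 2, survivors -> outcome ---------------------------
  m1 <- length(surv1)
  thr2 <- bonferroniThreshold(cfg$alpha, m1)
  med_instr <- list()
  s2 <- lapply(seq_along(surv1), function(i) {
    nm <- surv1[i]
    mi <- selectBiomarkerInstruments(mediators[[nm]], ld,
                                     p_threshold = cfg$mediator_p,
                                     r2_threshold = cfg$mediator_r2,
                                     window_kb = cfg$mediator_window_kb)
    med_instr[[nm]] <<- mi
    if (nVariants(mi) < 2L)
      return(data.frame(candidate = nm, nsnp = nVariants(mi),
                        beta = NA_real_, se = NA_real_, pval = NA_real_,
                        bonferroni_threshold = thr2, passed = FALSE,
                        stringsAsFactors = FALSE))
    sc <- screenOne(statsFromInstruments(mi), outcome, cfg, 300L + i)
    data.frame(candidate = nm, nsnp = nVariants(sc$h),
               beta = theta(sc$est), se = stdError(sc$est),
               pval = pValue(sc$est), bonferroni_threshold = thr2,
               passed = pValue(sc$est) < thr2, stringsAsFactors = FALSE)
  })
  report$screen2 <- do.call(rbind, s2)
  report$thresholds$m1 <- m1
  report$thresholds$thr2 <- thr2
  surv2 <- report$screen2$candidate[report$screen2$passed]
  if (!length(surv2)) {
    report$skipped <- c("mvmr", "mediation")
    return(report)
  }

  # --- stage 5: MVMR + mediation -----------------------------------------
  m2 <- length(surv2)
  thr3 <- bonferroniThreshold(cfg$alpha, m2)
  report$thresholds$m2 <- m2
  report$thresholds$thr3 <- thr3
  t2rows <- list()
  for (nm in surv2) {
    union_ids <- union(variantIds(instr), variantIds(med_instr[[nm]]))
    hm <- harmonize(list(subsetStats(exposure, union_ids),
                         subsetStats(mediators[[nm]], union_ids)),
                    outcome, palindrome_policy = cfg$palindrome_policy)
    mv <- mvmrIVW(hm)
    b2 <- mv[[traitName(mediators[[nm]])]]
    rows <- data.frame(candidate = nm, rbind(estimateRow(b2)))
    if (nVariants(hm) >= length(exposureNames(hm)) + 2L) {
      mve <- mvmrEgger(hm, orient_to = exposureNames(hm)[1L])
      rows <- rbind(rows,
                    data.frame(candidate = nm,
                               rbind(estimateRow(mve[[traitName(mediators[[nm]])]]))))
    }
    t2rows[[nm]] <- rows
    passed <- pValue(b2) < thr3
    if (passed) {
      i1 <- match(nm, report$screen1$candidate)
      med <- mediationProportion(
        beta1 = report$screen1$beta1[i1], se1 = report$screen1$se1[i1],
        beta2 = theta(b2), se2 = stdError(b2),
        total = theta(total_est), se_total = stdError(total_est),
        mediator = nm)
      report$mediationResults[[nm]] <- med
    }
  }
  report$table2 <- do.call(rbind, t2rows)
  rownames(report$table2) <- NULL

  if (length(report$mediationResults)) {
    report$mediation <- do.call(rbind, lapply(report$mediationResults,
      function(m) data.frame(
        mediator = m@mediator, beta1 = m@beta1, se1 = m@se1,
        beta2 = m@beta2, se2 = m@se2, total = m@total,
        indirect = m@indirect, se_indirect = m@seIndirect,
        indirect_or = exp(m@indirect),
        proportion_pct = 100 * m@proportion,
        ci_low_pct = 100 * m@ciLow, ci_high_pct = 100 * m@ciHigh,
        pval = m@pval, stringsAsFactors = FALSE)))
    rownames(report$mediation) <- NULL
  } else {
    report$skipped <- c(report$skipped, "mediation")
  }
  report
}

#' Write a pipeline report as a set of TSV files plus provenance JSON
#'
#' Emits `table1.tsv`, `screen1.tsv`, `screen2.tsv`, `table2.tsv`,
#' `mediation.tsv` (percentage-scale proportions), `forest_data.tsv`
#' (per-method OR/CI rows for forest plotting) and `run.json`.  Output is
#' byte-stable for an identical report.
#'
#' @param report a `PipelineReport` from [runTwoStepPipeline()].
#' @param out_dir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
writeReport <- function(report, out_dir) {
  stopifnot(inherits(report, "PipelineReport"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  emptyWith <- function(cols)
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  tabs <- list(
    table1 = if (is.null(report$table1))
      emptyWith(c("method", "exposure", "nsnp", "theta", "se", "ci_low",
                  "ci_high", "pval", "or", "or_low", "or_high", "q",
                  "q_pval", "egger_intercept", "egger_intercept_pval"))
      else report$table1,
    screen1 = if (is.null(report$screen1))
      emptyWith(c("candidate", "nsnp", "beta1", "se1", "pval",
                  "bonferroni_threshold", "passed")) else report$screen1,
    screen2 = if (is.null(report$screen2))
      emptyWith(c("candidate", "nsnp", "beta", "se", "pval",
                  "bonferroni_threshold", "passed")) else report$screen2,
    table2 = if (is.null(report$table2))
      emptyWith(c("candidate", "method", "exposure", "nsnp", "theta", "se",
                  "ci_low", "ci_high", "pval", "or", "or_low", "or_high",
                  "q", "q_pval", "egger_intercept", "egger_intercept_pval"))
      else report$table2,
    mediation = if (is.null(report$mediation))
      emptyWith(c("mediator", "beta1", "se1", "beta2", "se2", "total",
                  "indirect", "se_indirect", "indirect_or",
                  "proportion_pct", "ci_low_pct", "ci_high_pct", "pval"))
      else report$mediation)
  paths <- character()
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tabs[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  forest <- tabs$table1[, c("method", "exposure", "nsnp", "or", "or_low",
                            "or_high", "pval")]
  fp <- file.path(out_dir, "forest_data.tsv")
  write.table(forest, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  rp <- file.path(out_dir, "run.json")
  jsonlite::write_json(
    list(provenance = report$provenance,
         thresholds = report$thresholds,
         skipped = report$skipped,
         outliers = report$outliers),
    rp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, fp, rp))
}

#' One-call mediation estimate on a synthetic study
#'
#' Thin wrapper running [runTwoStepPipeline()] on a [simulateMRStudy()]
#' output with IVW-only screening, and returning the true mediator's
#' [MediationResult-class] (or `NULL` when it does not survive the
#' cascade).  Used for parameter-recovery simulation.
#'
#' @param study a `SyntheticStudy`.
#' @param outlier_filter,n_sim passed to the pipeline.
#' @param methods estimator battery for the main table.
#' @return A [MediationResult-class] or `NULL`.
#' @export
estimateMediation <- function(study, outlier_filter = FALSE,
                              n_sim = 1000L, methods = "ivw") {
  stopifnot(inherits(study, "SyntheticStudy"))
  cfg <- pipelineConfig(
    exposure = study$exposure_stats,
    mediators = study$mediator_stats,
    outcome = study$outcome_stats,
    ld = study$ld,
    invert_sign = FALSE,
    methods = methods,
    outlier_filter = outlier_filter,
    n_sim = n_sim,
    seed = study$config$seed)
  rep <- runTwoStepPipeline(cfg)
  rep$mediationResults[[study$truth$true_mediator]]
}
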