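#' Configuration for the synthetic two-sample MR study generator
#'
#' Collects and validates the ground-truth parameters of the simulated
#' X -> M -> Y causal chain.  Defaults echo the magnitude of a drug-target
#' analysis of an inhibition exposure on a binary cardiovascular outcome
#' mediated by a circulating metabolite: beta1 = 0.42 SD mediator per SD
#' exposure, beta2 = log(0.88) log-odds per SD mediator, and a direct
#' effect chosen so the total effect is log(0.51) — a true mediated
#' proportion near 8%.
#'
#' @param n_snps exposure instrument SNPs (default 10).
#' @param maf_range effect-allele frequency range, within (0, 0.5].
#' @param n_exp,n_med,n_out GWAS sample sizes per trait (default 3e5).
#' @param beta1_true exposure-to-mediator effect (SD per SD).
#' @param beta2_true mediator-to-outcome effect (log-odds per SD).
#' @param theta_direct direct exposure-to-outcome effect (log-odds); the
#'   total effect is `theta_direct + beta1_true * beta2_true`.
#' @param pleiotropy `list(type = "none")`, `list(type = "balanced", sd =)`
#'   or `list(type = "directional", mean =, sd =)`: per-SNP horizontal
#'   pleiotropy added to the mediator and outcome effects of the exposure
#'   instruments.
#' @param n_mediator_panel total mediators; the first carries the causal
#'   chain, the rest are null (beta1 = beta2 = 0).
#' @param n_med_snps instrument SNPs per mediator (each mediator gets its
#'   own independent instruments with no exposure effect).
#' @param h2_exp,h2_med variance explained by the instruments in the
#'   exposure / each mediator (must stay below 0.10).
#' @param n_outliers exposure instruments given an extra outcome
#'   displacement of `outlier_scale` outcome SEs (planted outliers).
#' @param outlier_scale displacement in units of the outcome SE.
#' @param sample_overlap_rho correlation of estimation noise between
#'   traits (0 = non-overlapping samples, the default two-sample design).
#' @param seed RNG seed; the whole study is a deterministic function of
#'   the config.
#' @return Validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_snps = 10L,
                             maf_range = c(0.1, 0.4),
                             n_exp = 3e5, n_med = 3e5, n_out = 3e5,
                             beta1_true = 0.42,
                             beta2_true = log(0.88),
                             theta_direct = log(0.51) - 0.42 * log(0.88),
                             pleiotropy = list(type = "none"),
                             n_mediator_panel = 1L,
                             n_med_snps = 10L,
                             h2_exp = 0.03, h2_med = 0.03,
                             n_outliers = 0L, outlier_scale = 10,
                             sample_overlap_rho = 0,
                             seed = 1L) {
  stopifnot(n_snps >= 1, n_med_snps >= 1, n_mediator_panel >= 1,
            n_exp > 0, n_med > 0, n_out > 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            sample_overlap_rho >= 0, sample_overlap_rho < 1,
            n_outliers >= 0, n_outliers <= n_snps,
            pleiotropy$type %in% c("none", "balanced", "directional"))
  if (h2_exp >= 0.10 || h2_med >= 0.10)
    stop("infeasible variance budget: instrument h2 must stay below 10%")
  structure(list(n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 beta1_true = beta1_true, beta2_true = beta2_true,
                 theta_direct = theta_direct, pleiotropy = pleiotropy,
                 n_mediator_panel = as.integer(n_mediator_panel),
                 n_med_snps = as.integer(n_med_snps),
                 h2_exp = h2_exp, h2_med = h2_med,
                 n_outliers = as.integer(n_outliers),
                 outlier_scale = outlier_scale,
                 sample_overlap_rho = sample_overlap_rho,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# analytic SE of a standardized marginal GWAS effect at maf p, sample n
gwasSE <- function(p, n) 1 / sqrt(2 * p * (1 - p) * n)

clampP <- function(p) pmax(p, 1e-300)

drawPleiotropy <- function(spec, n) {
  switch(spec$type,
         none = rep(0, n),
         balanced = rnorm(n, 0, spec$sd),
         directional = rnorm(n, spec$mean, spec$sd))
}

#' Simulate a two-sample summary-statistic MR study with known truth
#'
#' Generates GWAS summary statistics directly on the summary scale (no
#' individual-level genotypes) for an exposure, a mediator panel, and a
#' binary outcome under the chain X -> M -> Y.  The exposure's instruments
#' get true effects sized to an explained-variance budget; the first
#' mediator receives beta1 * beta_x at those SNPs plus its own independent
#' instruments; the outcome receives
#' (theta_direct + beta1 * beta2) * beta_x at the exposure instruments and
#' beta2 * beta_m at the true mediator's instruments.  Null mediators have
#' their own instruments but no place in the chain.  Observed effects add
#' N(0, se) noise with the analytic se = 1 / sqrt(2 p (1 - p) n); binary
#' traits are generated on the log-odds scale with the same form.  All
#' draws flow from the single config seed.
#'
#' @param config a [simulationConfig()] list.
#' @return List of class `SyntheticStudy`: `exposure_stats`,
#'   `mediator_stats` (named list over the panel), `outcome_stats`,
#'   `ld` (identity [LDMatrix-class] over all SNPs), `truth` (true
#'   parameters, per-SNP effects, pleiotropy draws, planted outlier ids),
#'   and the `config`.
#' @export
simulateMRStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cf <- config
  set.seed(cf$seed)
  theta_total <- cf$theta_direct + cf$beta1_true * cf$beta2_true

  nE <- cf$n_snps
  nM <- cf$n_med_snps
  nP <- cf$n_mediator_panel
  med_names <- sprintf("mediator_%02d", seq_len(nP))

  ids_exp <- sprintf("rsX%03d", seq_len(nE))
  ids_med <- lapply(seq_len(nP), function(i)
    sprintf("rsM%02d_%03d", i, seq_len(nM)))
  all_ids <- c(ids_exp, unlist(ids_med))
  n_all <- length(all_ids)
  chrom <- c(rep("1", nE), rep(as.character(1 + seq_len(nP)), each = nM))
  pos <- c(seq_len(nE), unlist(lapply(seq_len(nP), function(i) seq_len(nM)))) * 1e6

  maf <- runif(n_all, cf$maf_range[1], cf$maf_range[2])
  idx_exp <- seq_len(nE)
  idx_med <- split(nE + seq_len(nP * nM), rep(seq_len(nP), each = nM))

  effectSize <- function(h2, n_inst, p)
    sample(c(-1, 1), length(p), replace = TRUE) *
      sqrt(h2 / n_inst / (2 * p * (1 - p)))

  beta_x <- numeric(n_all)
  beta_x[idx_exp] <- effectSize(cf$h2_exp, nE, maf[idx_exp])
  beta_m_own <- lapply(seq_len(nP), function(i)
    effectSize(cf$h2_med, nM, maf[idx_med[[i]]]))

  pleio_med <- drawPleiotropy(cf$pleiotropy, nE)
  pleio_out <- drawPleiotropy(cf$pleiotropy, nE)

  # true marginal effects on each trait over the whole SNP universe
  true_exp <- beta_x
  true_med <- lapply(seq_len(nP), function(i) {
    b <- numeric(n_all)
    b1 <- if (i == 1L) cf$beta1_true else 0
    b[idx_exp] <- b1 * beta_x[idx_exp] + if (i == 1L) pleio_med else 0
    b[idx_med[[i]]] <- beta_m_own[[i]]
    b
  })
  true_out <- numeric(n_all)
  true_out[idx_exp] <- theta_total * beta_x[idx_exp] + pleio_out
  true_out[idx_med[[1L]]] <- cf$beta2_true * beta_m_own[[1L]]

  se_exp <- gwasSE(maf, cf$n_exp)
  se_med <- gwasSE(maf, cf$n_med)
  se_out <- gwasSE(maf, cf$n_out)

  outlier_ids <- character()
  if (cf$n_outliers > 0L) {
    pick <- sample(idx_exp, cf$n_outliers)
    true_out[pick] <- true_out[pick] +
      sample(c(-1, 1), cf$n_outliers, replace = TRUE) *
        cf$outlier_scale * se_out[pick]
    outlier_ids <- all_ids[pick]
  }

  rho <- cf$sample_overlap_rho
  shared <- rnorm(n_all)
  noiseFor <- function(se) {
    eps <- sqrt(1 - rho) * rnorm(n_all) + sqrt(rho) * shared
    eps * se
  }

  mk <- function(beta_true, se, n, name, type) {
    beta_obs <- beta_true + noiseFor(se)
    z <- beta_obs / se
    SummaryStats(data.frame(
      variant_id = all_ids, chrom = chrom, pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta_obs, se = se, pval = clampP(2 * pnorm(-abs(z))),
      n = n, stringsAsFactors = FALSE), name, type)
  }

  exposure_stats <- mk(true_exp, se_exp, cf$n_exp, "exposure", "quantitative")
  mediator_stats <- setNames(lapply(seq_len(nP), function(i)
    mk(true_med[[i]], se_med, cf$n_med, med_names[i], "quantitative")),
    med_names)
  outcome_stats <- mk(true_out, se_out, cf$n_out, "outcome", "binary")

  ld <- LDMatrix(diag(n_all), variant_ids = all_ids)

  truth <- list(
    theta_total = theta_total,
    theta_direct = cf$theta_direct,
    beta1_true = cf$beta1_true,
    beta2_true = cf$beta2_true,
    proportion_true = cf$beta1_true * cf$beta2_true / theta_total,
    beta_x = setNames(beta_x[idx_exp], ids_exp),
    pleiotropy_mediator = setNames(pleio_med, ids_exp),
    pleiotropy_outcome = setNames(pleio_out, ids_exp),
    outlier_ids = outlier_ids,
    true_mediator = med_names[1L],
    exposure_instrument_ids = ids_exp,
    mediator_instrument_ids = setNames(ids_med, med_names))

  structure(list(exposure_stats = exposure_stats,
                 mediator_stats = mediator_stats,
                 outcome_stats = outcome_stats,
                 ld = ld, truth = truth, config = cf),
            class = "SyntheticStudy")
}

#' Simulate an LD-structured region for colocalization tests
#'
#' Builds an AR(1) LD matrix (r between neighbours = `ld_rho`) over `m`
#' variants and draws the two traits' marginal z-scores from
#' N(R lambda_vec, R) — the standard summary-statistic model in which a
#' causal variant of non-centrality `lambda` casts LD-proportional shadows
#' on its neighbours.  The causal configuration follows `scenario`: H0
#' none, H1/H2 one trait only, H3 two distinct causal variants, H4 one
#' shared variant.  z-scores are converted to beta/se with the analytic
#' per-variant SEs.
#'
#' @param m number of variants (>= 2).
#' @param ld_rho AR(1) neighbour correlation, |ld_rho| < 1.
#' @param scenario one of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param n1,n2 per-trait sample sizes.
#' @param lambda causal-variant non-centrality (z-score units).
#' @param maf_range effect-allele frequency range.
#' @param seed RNG seed.
#' @return list(`trait1`, `trait2` [SummaryStats-class], `ld`
#'   [LDMatrix-class], `truth` with the causal indices).
#' @export
simulateColocRegion <- function(m = 50L, ld_rho = 0.8,
                                scenario = c("H0", "H1", "H2", "H3", "H4"),
                                n1 = 10000, n2 = 10000, lambda = 6,
                                maf_range = c(0.1, 0.5), seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(m >= 2L, abs(ld_rho) < 1)
  set.seed(seed)
  R <- ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ids <- sprintf("rsC%03d", seq_len(m))

  causal1 <- causal2 <- NA_integer_
  if (scenario %in% c("H1", "H3", "H4")) causal1 <- sample.int(m, 1L)
  if (scenario == "H2") causal2 <- sample.int(m, 1L)
  if (scenario == "H4") causal2 <- causal1
  if (scenario == "H3") {
    causal2 <- sample.int(m, 1L)
    while (causal2 == causal1) causal2 <- sample.int(m, 1L)
  }

  L <- chol(R)
  drawZ <- function(causal) {
    lam <- numeric(m)
    if (!is.na(causal)) lam[causal] <- lambda
    drop(R %*% lam) + drop(t(L) %*% rnorm(m))
  }
  z1 <- drawZ(causal1)
  z2 <- drawZ(causal2)

  maf <- runif(m, maf_range[1], maf_range[2])
  mk <- function(z, n, name) {
    se <- gwasSE(maf, n)
    SummaryStats(data.frame(
      variant_id = ids, chrom = "5", pos = seq_len(m) * 1e4,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = z * se, se = se, pval = clampP(2 * pnorm(-abs(z))),
      n = n, stringsAsFactors = FALSE), name, "quantitative")
  }
  list(trait1 = mk(z1, n1, "trait1"),
       trait2 = mk(z2, n2, "trait2"),
       ld = LDMatrix(R, variant_ids = ids),
       truth = list(scenario = scenario, causal1 = causal1,
                    causal2 = causal2, lambda = lambda))
}
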