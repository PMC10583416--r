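ar1LD <- function(ids, rho) {
  m <- length(ids)
  LDMatrix(rho^abs(outer(seq_len(m), seq_len(m), "-")), variant_ids = ids)
}

test_that("clumping follows the greedy rule on forced cases", {
  ld1 <- ar1LD("rs1", 0)
  one <- data.frame(variant_id = "rs1", pos = 100, pval = 1e-8)
  expect_identical(clumpVariants(one, ld1, 0.1, 250), "rs1")

  ld2 <- LDMatrix(matrix(c(1, 1, 1, 1), 2), variant_ids = c("rs1", "rs2"))
  two <- data.frame(variant_id = c("rs1", "rs2"), pos = c(100, 100),
                    pval = c(1e-8, 1e-6))
  expect_identical(clumpVariants(two, ld2, 0.8, 250), "rs1")

  # correlated but beyond the window: both kept (distance AND r2 must trip)
  far <- data.frame(variant_id = c("rs1", "rs2"), pos = c(0, 1e6),
                    pval = c(1e-8, 1e-6))
  expect_setequal(clumpVariants(far, ld2, 0.8, 250), c("rs1", "rs2"))

  expect_error(clumpVariants(
    data.frame(variant_id = "rsX", pos = 1, pval = 0.1), ld1, 0.5, 10),
    "rsX")
})

test_that("clumping matches the brute-force greedy oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- sample(4:9, 1)
    ids <- paste0("rs", sample(100, m))
    ld <- ar1LD(ids, runif(1, 0.3, 0.95))
    v <- data.frame(variant_id = ids,
                    pos = sort(sample(1e6, m)) ,
                    pval = 10^runif(m, -12, -2))
    r2t <- runif(1, 0.05, 0.9)
    win <- sample(c(50, 250, 1000), 1)
    got <- clumpVariants(v, ld, r2t, win)
    expect_identical(got, clumpOracle(v, ld, r2t, win),
                     info = paste("seed", seed))
    # kept set property: no two kept variants within window share r2 >= t
    r2 <- ldValues(ld)[got, got, drop = FALSE]^2
    pos <- v$pos[match(got, v$variant_id)]
    for (i in seq_along(got)) for (j in seq_along(got)) {
      if (i != j && abs(pos[i] - pos[j]) <= win * 1000)
        expect_lt(r2[i, j], r2t)
    }
  }
})

test_that("clumping is order-invariant and monotone in the r2 threshold", {
  set.seed(42)
  ids <- paste0("rs", 1:8)
  ld <- ar1LD(ids, 0.85)
  v <- data.frame(variant_id = ids, pos = (1:8) * 5e4,
                  pval = 10^runif(8, -10, -3))
  base <- clumpVariants(v, ld, 0.3, 500)
  shuf <- v[sample(8), ]
  expect_identical(clumpVariants(shuf, ld, 0.3, 500), base)
  sizes <- vapply(c(0.05, 0.2, 0.5, 0.9),
                  function(t) length(clumpVariants(v, ld, t, 500)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("biomarker instrument selection filters, clumps and computes F", {
  # all nonsignificant: empty set with a log, not an error
  ld <- ar1LD(paste0("rs", 1:3), 0)
  s <- makeStats(variant_id = paste0("rs", 1:3), beta = rep(0.01, 3),
                 se = rep(0.01, 3), pval = rep(0.5, 3))
  empty <- selectBiomarkerInstruments(s, ld)
  expect_equal(nVariants(empty), 0L)
  expect_equal(selectionLog(empty)$n_after[1], 0L)

  s2 <- makeStats(variant_id = "rs1", beta = 0.04, se = 0.01, pval = 1e-9)
  one <- selectBiomarkerInstruments(s2, ar1LD("rs1", 0))
  expect_equal(unname(fStatistics(one)), 16)
  expect_false(any(weakFlags(one)))

  # three independent genome-wide signals among noise
  st <- simulateMRStudy(simulationConfig(seed = 3, n_snps = 3,
                                         n_mediator_panel = 2))
  sel <- selectBiomarkerInstruments(st$exposure_stats, st$ld)
  expect_setequal(variantIds(sel), st$truth$exposure_instrument_ids)
})

test_that("F statistics are (beta/se)^2 and invariant to sign inversion", {
  s <- makeStats(variant_id = paste0("rs", 1:4),
                 beta = c(0.04, -0.02, 0.1, 0.005), se = rep(0.01, 4),
                 pval = rep(1e-9, 4))
  sel <- selectBiomarkerInstruments(s, ar1LD(paste0("rs", 1:4), 0))
  expect_equal(fStatistics(sel),
               (records(sel)$beta / records(sel)$se)^2, tolerance = 1e-12)
  expect_identical(weakFlags(sel), unname(fStatistics(sel) < 10))
  flipped <- s
  flipped@records$beta <- -flipped@records$beta
  sel2 <- selectBiomarkerInstruments(flipped, ar1LD(paste0("rs", 1:4), 0))
  expect_equal(sort(fStatistics(sel2)), sort(fStatistics(sel)))
})

test_that("drug-target selection gates on region, significance and coloc", {
  ids <- paste0("rs", 1:6)
  ld <- ar1LD(ids, 0.5)
  eqtl <- makeStats(variant_id = ids, beta = rep(0.2, 6), se = rep(0.02, 6),
                    pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 9e6),
                    trait_name = "eqtl")
  bio <- makeStats(variant_id = ids, beta = c(0.1, 0.12, 0.09, 0.11, 0.01, 0.2),
                   se = rep(0.01, 6),
                   pval = c(1e-8, 1e-7, 1e-6, 1e-9, 0.2, 1e-12),
                   pos = c(1e5, 2e5, 3e5, 4e5, 5e5, 9e6),
                   trait_name = "hba1c")
  region <- list(chrom = "1", start = 1, end = 1e6)

  # coloc gate below threshold: empty with recorded reason
  fake_gate <- new("ColocResult", variantIds = ids,
                   labf1 = rep(0, 6), labf2 = rep(0, 6),
                   pp = setNames(c(0.5, 0, 0, 0, 0.5), paste0("PP.H", 0:4)),
                   priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5))
  gated <- selectDrugTargetInstruments(eqtl, bio, region, ld,
                                       coloc_gate = fake_gate,
                                       pp_threshold = 0.7)
  expect_equal(nVariants(gated), 0L)
  expect_match(gated@reason, "colocalization failed")

  sel <- selectDrugTargetInstruments(eqtl, bio, region, ld,
                                     r2_threshold = 0.8, window_kb = 250)
  # rs6 outside region, rs5 not significant; clumping over the rest
  expect_true(all(variantIds(sel) %in% paste0("rs", 1:4)))
  oracle <- clumpOracle(
    data.frame(variant_id = paste0("rs", 1:4),
               pos = c(1e5, 2e5, 3e5, 4e5),
               pval = c(1e-8, 1e-7, 1e-6, 1e-9)), ld, 0.8, 250)
  expect_identical(variantIds(sel), oracle)
  # inhibition sign convention: betas negated
  expect_equal(records(sel)$beta,
               -records(bio)$beta[match(variantIds(sel), ids)])

  none <- selectDrugTargetInstruments(eqtl, bio,
                                      list(chrom = "7", start = 1, end = 100),
                                      ld)
  expect_equal(nVariants(none), 0L)
  expect_match(none@reason, "no eQTL")
})
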