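test_that("summary statistics round-trip through TSV bit-for-bit", {
  s <- makeStats(variant_id = c("rs1", "rs2"), beta = c(0.123456789012,
                 -0.05), se = c(0.01, 0.02), eaf = c(0.3, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSummaryStats(s, path)
  s2 <- readSummaryStats(path, trait_name = "trait")
  expect_identical(records(s2)$variant_id, records(s)$variant_id)
  expect_identical(records(s2)$effect_allele, records(s)$effect_allele)
  expect_identical(records(s2)$other_allele, records(s)$other_allele)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    expect_equal(records(s2)[[col]], records(s)[[col]], tolerance = 1e-12)
})

test_that("invalid rows are rejected with per-row reasons", {
  df <- statsDF(variant_id = c("rs1", "rs2", "rs3"),
                beta = c(0.1, 0.2, 0.1), se = c(0.01, 0, 0.01))
  df$eaf[3] <- 1.5
  s <- SummaryStats(df, "t", on_invalid = "drop")
  rep <- attr(s, "load_report")
  expect_equal(nVariants(s), 1L)
  expect_setequal(rep$variant_id, c("rs2", "rs3"))
  expect_match(rep$reason[rep$variant_id == "rs2"], "nonpositive se")
  expect_match(rep$reason[rep$variant_id == "rs3"], "eaf outside")
  expect_error(SummaryStats(df, "t", on_invalid = "error"), "nonpositive se")
})

test_that("a missing mandatory column is a format error naming it", {
  df <- statsDF("rs1", beta = 0.1, se = 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df[, setdiff(names(df), "beta")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(path, trait_name = "t"), "beta")
})

test_that("LD matrix IO enforces shape, bounds and symmetry tolerance", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- LDMatrix(r)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLDMatrix(m, path)
  m2 <- readLDMatrix(path)
  expect_equal(ldValues(m2), ldValues(m), tolerance = 1e-12)

  expect_s4_class(LDMatrix(matrix(1, 1, 1, dimnames = list("x", "x"))),
                  "LDMatrix")
  bad <- r; bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(LDMatrix(bad), "\\[-1, 1\\]")
  # tiny asymmetry is symmetrized, not rejected
  asym <- r; asym[1, 2] <- 0.5 + 1e-12
  m3 <- LDMatrix(asym)
  expect_identical(ldValues(m3)[1, 2], ldValues(m3)[2, 1])
  nonsq <- matrix(0.1, 2, 3)
  expect_error(LDMatrix(nonsq), "square")
})

test_that("harmonize aligns exact, swapped and complemented alleles", {
  ex <- makeStats(variant_id = c("rs1", "rs2", "rs3"),
                  beta = c(0.1, 0.2, 0.3), se = rep(0.01, 3),
                  effect_allele = c("A", "A", "A"),
                  other_allele = c("G", "G", "G"), eaf = 0.3)
  # rs1 identical; rs2 swapped; rs3 strand-complement (T/C matches A/G)
  out <- makeStats(variant_id = c("rs1", "rs2", "rs3"),
                   beta = c(0.05, 0.08, 0.02), se = rep(0.02, 3),
                   effect_allele = c("A", "G", "T"),
                   other_allele = c("G", "A", "C"),
                   eaf = c(0.3, 0.7, 0.3), trait_name = "out",
                   trait_type = "binary")
  h <- harmonize(ex, out)
  expect_identical(variantIds(h), c("rs1", "rs2", "rs3"))
  expect_equal(betaOut(h), c(0.05, -0.08, 0.02))
  expect_equal(unname(betaExp(h)[, 1]), c(0.1, 0.2, 0.3))
})

test_that("palindromic variants follow the stated policy", {
  ex <- makeStats(variant_id = c("rs1", "rs2", "rs3"),
                  beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3),
                  effect_allele = "A", other_allele = "T",
                  eaf = c(0.50, 0.20, 0.20))
  out <- makeStats(variant_id = c("rs1", "rs2", "rs3"),
                   beta = c(0.05, 0.05, 0.05), se = rep(0.02, 3),
                   effect_allele = "A", other_allele = "T",
                   eaf = c(0.50, 0.20, 0.85), trait_name = "out")
  expect_error(harmonize(ex, out, palindrome_policy = "drop_all"),
               "no variants retained")
  h <- harmonize(ex, out, palindrome_policy = "infer_by_eaf")
  # rs1 ambiguous (eaf 0.5); rs2 frequency-concordant kept as-is;
  # rs3 frequency-discordant => flipped
  expect_identical(variantIds(h), c("rs2", "rs3"))
  expect_equal(betaOut(h), c(0.05, -0.05))
  expect_match(droppedVariants(h)$reason[
    droppedVariants(h)$variant_id == "rs1"], "palindromic ambiguous")

  # missing eaf on a palindromic variant: always dropped
  out2 <- out
  out2@records$eaf[2] <- NA
  h2 <- harmonize(ex, out2, palindrome_policy = "infer_by_eaf")
  expect_false("rs2" %in% variantIds(h2))
})

test_that("harmonize is idempotent on its own aligned output", {
  ex <- makeStats(variant_id = paste0("rs", 1:4),
                  beta = c(0.1, -0.2, 0.15, 0.3), se = rep(0.01, 4),
                  effect_allele = c("A", "C", "G", "A"),
                  other_allele = c("G", "A", "T", "C"),
                  eaf = c(0.2, 0.8, 0.4, 0.25))
  out <- makeStats(variant_id = paste0("rs", 1:4),
                   beta = c(0.05, 0.04, -0.02, 0.01), se = rep(0.02, 4),
                   effect_allele = c("G", "C", "G", "A"),
                   other_allele = c("A", "A", "T", "C"),
                   eaf = c(0.8, 0.8, 0.4, 0.25), trait_name = "out")
  h1 <- harmonize(ex, out)
  al <- attr(h1, "aligned")
  h2 <- harmonize(al[[1]], al[[2]])
  expect_equal(betaExp(h2), betaExp(h1))
  expect_equal(betaOut(h2), betaOut(h1))
  expect_identical(variantIds(h2), variantIds(h1))
})

test_that("jointly negating a trait's betas and swapping its allele labels
           leaves the harmonized set unchanged", {
  ex <- makeStats(variant_id = paste0("rs", 1:3),
                  beta = c(0.1, 0.2, 0.3), se = rep(0.01, 3),
                  effect_allele = "A", other_allele = "G", eaf = 0.3)
  out <- makeStats(variant_id = paste0("rs", 1:3),
                   beta = c(0.02, -0.05, 0.04), se = rep(0.02, 3),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   trait_name = "out")
  h1 <- harmonize(ex, out)
  r <- records(out)
  r$beta <- -r$beta
  tmp <- r$effect_allele; r$effect_allele <- r$other_allele
  r$other_allele <- tmp
  r$eaf <- 1 - r$eaf
  out_flipped <- SummaryStats(r, "out")
  h2 <- harmonize(ex, out_flipped)
  expect_equal(betaOut(h2), betaOut(h1))
  expect_equal(betaExp(h2), betaExp(h1))
})

test_that("zero shared variants is an error", {
  ex <- makeStats("rs1", beta = 0.1, se = 0.01)
  out <- makeStats("rs9", beta = 0.1, se = 0.01, trait_name = "out")
  expect_error(harmonize(ex, out), "zero shared")
})
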