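# Small in-code fixtures shared across test files.

statsDF <- function(variant_id, beta, se, pval = NULL,
                    effect_allele = "A", other_allele = "G",
                    eaf = 0.3, chrom = "1", pos = NULL, n = 1e5) {
  J <- length(variant_id)
  if (is.null(pos)) pos <- seq_len(J) * 1e5
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

makeStats <- function(..., trait_name = "trait",
                      trait_type = "quantitative") {
  SummaryStats(statsDF(...), trait_name, trait_type)
}

# random single- or multi-exposure harmonized instance for oracle tests
randHarm <- function(J, k = 1, seed) {
  set.seed(seed)
  bx <- matrix(runif(J * k, 0.05, 0.3) * sample(c(-1, 1), J * k, TRUE), J, k)
  sx <- matrix(runif(J * k, 0.005, 0.02), J, k)
  by <- rnorm(J, 0.1 * rowSums(bx), 0.05)
  sy <- runif(J, 0.01, 0.05)
  medimr:::makeHarmonizedSet(bx, sx, by, sy,
    exposure_names = paste0("e", seq_len(k)))
}

# independent greedy-clumping oracle: literal restatement of the rule with
# nested loops, no shared code with clumpVariants
clumpOracle <- function(variants, ld, r2_threshold, window_kb) {
  r2 <- ldValues(ld)[variants$variant_id, variants$variant_id, drop = FALSE]^2
  remaining <- variants[order(variants$pval, variants$variant_id), ]
  kept <- character()
  removed <- character()
  for (i in seq_len(nrow(remaining))) {
    id <- remaining$variant_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(remaining))) {
      other <- remaining$variant_id[j]
      if (other == id || other %in% removed || other %in% kept) next
      dpos <- abs(remaining$pos[j] - remaining$pos[i])
      if (r2[id, other] >= r2_threshold && dpos <= window_kb * 1000)
        removed <- c(removed, other)
    }
  }
  kept
}

# bracket-scan weighted-median oracle: examine every adjacent pair of
# cumulative midpoints for the 0.5 crossing
weightedMedianOracle <- function(ratios, weights) {
  ord <- order(ratios)
  th <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  J <- length(th)
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[J]) return(th[J])
  for (j in seq_len(J - 1)) {
    if (s[j] <= 0.5 && 0.5 <= s[j + 1]) {
      return(th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j]))
    }
  }
  stop("no bracket found")
}

# exhaustive configuration-sum colocalization oracle for small m
colocOracle <- function(labf1, labf2, p1, p2, p12) {
  a1 <- exp(labf1); a2 <- exp(labf2)
  m <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j != k) h3 <- h3 + p1 * p2 * a1[j] * a2[k]
  }
  h4 <- p12 * sum(a1 * a2)
  pp <- c(h0, h1, h2, h3, h4)
  setNames(pp / sum(pp), paste0("PP.H", 0:4))
}

# exposure-instrument harmonized slice of a synthetic study
studyMainHarm <- function(st) {
  ids <- st$truth$exposure_instrument_ids
  harmonize(medimr:::subsetStats(st$exposure_stats, ids),
            medimr:::subsetStats(st$outcome_stats, ids))
}
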