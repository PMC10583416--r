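test_that("Wald ratio arithmetic and symmetry", {
  e <- waldRatio(0.1, 0.01, 0.05, 0.02)
  expect_equal(theta(e), 0.5)
  expect_equal(stdError(e), 0.2)
  expect_equal(theta(waldRatio(0.2, 0.01, 0, 0.02)), 0)
  expect_equal(theta(waldRatio(-0.1, 0.01, -0.05, 0.02)), 0.5)
  expect_error(waldRatio(0, 0.01, 0.05, 0.02), "beta_x = 0")
})

test_that("IVW degrades to the Wald ratio for one variant", {
  h <- medimr:::makeHarmonizedSet(0.1, 0.01, 0.05, 0.02)
  expect_warning(e <- mrIVW(h), "single variant")
  expect_equal(theta(e), 0.5, tolerance = 1e-15)
  expect_equal(stdError(e), 0.2, tolerance = 1e-15)
})

test_that("IVW on collinear data has zero Q and the dispersion floor holds", {
  h <- medimr:::makeHarmonizedSet(c(0.1, 0.2), rep(0.01, 2),
                                  c(0.05, 0.10), c(0.1, 0.1))
  e <- mrIVW(h)
  expect_equal(theta(e), 0.5, tolerance = 1e-12)
  expect_equal(unname(cochranQStat(e)["q"]), 0, tolerance = 1e-12)
  expect_equal(stdError(e), stdError(mrIVW(h, "fixed")))
})

test_that("IVW and Q match the hand-solved two-variant normal equations", {
  h <- medimr:::makeHarmonizedSet(c(1, 1), rep(0.01, 2), c(0, 1), c(1, 1))
  e <- mrIVW(h)
  expect_equal(theta(e), 0.5, tolerance = 1e-12)
  expect_equal(unname(cochranQStat(e)["q"]), 0.5, tolerance = 1e-12)
})

test_that("IVW and Egger match weighted least squares via lm on random instances", {
  for (seed in 1:30) {
    h <- randHarm(J = sample(4:12, 1), seed = seed)
    bx <- betaExp(h)[, 1]; by <- betaOut(h); w <- 1 / seOut(h)^2
    fit0 <- lm(by ~ 0 + bx, weights = w)
    expect_equal(theta(mrIVW(h)), unname(coef(fit0)), tolerance = 1e-10)

    flip <- bx < 0
    fit1 <- lm(ifelse(flip, -by, by) ~ ifelse(flip, -bx, bx), weights = w)
    eg <- mrEgger(h)
    expect_equal(theta(eg), unname(coef(fit1)[2]), tolerance = 1e-10)
    expect_equal(unname(eggerIntercept(eg)["intercept"]),
                 unname(coef(fit1)[1]), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact intercept + slope construction", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  by <- 0.1 + 0.5 * bx
  h <- medimr:::makeHarmonizedSet(bx, rep(0.01, 5), by, rep(0.02, 5))
  eg <- mrEgger(h)
  expect_equal(theta(eg), 0.5, tolerance = 1e-10)
  expect_equal(unname(eggerIntercept(eg)["intercept"]), 0.1,
               tolerance = 1e-10)
  expect_equal(unname(cochranQStat(eg)["q"]), 0, tolerance = 1e-10)
})

test_that("Egger is invariant to joint negation of a variant's effects", {
  h <- randHarm(8, seed = 99)
  e1 <- mrEgger(h)
  bx <- betaExp(h)[, 1]; by <- betaOut(h)
  bx[3] <- -bx[3]; by[3] <- -by[3]
  h2 <- medimr:::makeHarmonizedSet(bx, seExp(h)[, 1], by, seOut(h))
  e2 <- mrEgger(h2)
  expect_equal(theta(e2), theta(e1), tolerance = 1e-12)
  expect_equal(eggerIntercept(e2), eggerIntercept(e1), tolerance = 1e-12)
})

test_that("Cochran's Q: perfect fit, and inverse-square scaling in se", {
  h <- medimr:::makeHarmonizedSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                  c(0.05, 0.10, 0.15), rep(0.02, 3))
  q <- cochranQ(h, 0.5)
  expect_equal(unname(q["q"]), 0)
  expect_equal(unname(q["q_pval"]), 1)

  h1 <- randHarm(6, seed = 4)
  th <- theta(mrIVW(h1))
  q1 <- cochranQ(h1, th)
  h2 <- medimr:::makeHarmonizedSet(betaExp(h1)[, 1], seExp(h1)[, 1],
                                   betaOut(h1), 2 * seOut(h1))
  # same theta target: scaling all outcome SEs by 2 divides Q by 4
  expect_equal(unname(cochranQ(h2, th)["q"]), unname(q1["q"]) / 4,
               tolerance = 1e-12)
})

test_that("weighted median equals the bracket-scan oracle and the simple cases", {
  h <- medimr:::makeHarmonizedSet(c(1, 1, 1), rep(0.01, 3), c(1, 2, 3),
                                  rep(1, 3))
  e <- mrWeightedMedian(h, n_boot = 50, seed = 1)
  expect_equal(theta(e), 2)

  # dominant-weight ratio pulls the estimate to itself
  hd <- medimr:::makeHarmonizedSet(c(10, 1, 1), c(0.01, 0.01, 0.01),
                                   c(7, 2, 3), rep(1, 3))
  expect_equal(theta(mrWeightedMedian(hd, n_boot = 50, seed = 1)), 0.7,
               tolerance = 0.05)

  for (seed in 1:20) {
    h7 <- randHarm(7, seed = seed + 200)
    d <- list(bx = betaExp(h7)[, 1], by = betaOut(h7), sy = seOut(h7))
    oracle <- weightedMedianOracle(d$by / d$bx, (d$bx / d$sy)^2)
    expect_equal(theta(mrWeightedMedian(h7, n_boot = 20, seed = 1)), oracle,
                 tolerance = 1e-10)
  }
})

test_that("mode estimators find the right cluster and match a 10x-finer grid", {
  # identical ratios: mode is the common value even with zero bandwidth
  hc <- medimr:::makeHarmonizedSet(c(0.1, 0.2, 0.4), rep(0.01, 3),
                                   c(0.05, 0.10, 0.20), rep(0.02, 3))
  expect_equal(theta(mrMode(hc, n_boot = 20, seed = 1)), 0.5,
               tolerance = 1e-12)

  # 6 variants at ratio 0.5, 3 at 2.0; simple mode prefers the larger
  # cluster, outcome-precision weights can prefer the smaller
  bx <- rep(1, 9)
  by <- c(rep(0.5, 6), rep(2, 3))
  sy <- c(rep(0.30, 6), rep(0.03, 3))
  hb <- medimr:::makeHarmonizedSet(bx + rnorm(9, 0, 1e-4), rep(0.01, 9),
                                   by + rnorm(9, 0, 1e-3), sy)
  sm <- mrMode(hb, weighted = FALSE, n_boot = 20, seed = 1)
  wm <- mrMode(hb, weighted = TRUE, n_boot = 20, seed = 1)
  expect_lt(abs(theta(sm) - 0.5), 0.1)
  expect_lt(abs(theta(wm) - 2.0), 0.1)

  # grid argmax agrees with a 10x-resolution density within one coarse step
  for (seed in c(3, 17)) {
    h <- randHarm(9, seed = seed)
    d <- list(bx = betaExp(h)[, 1], by = betaOut(h), sy = seOut(h))
    ratios <- d$by / d$bx
    coarse <- theta(mrMode(h, n_boot = 20, seed = 1))
    fine <- medimr:::modePoint(ratios, NULL, 1, grid_n = 10000L)
    b <- 0.9 * min(sd(ratios), mad(ratios)) * 9^(-1 / 5)
    step <- (diff(range(ratios)) + 6 * b) / 999
    expect_lt(abs(coarse - fine), step + 1e-12)
  }
})

test_that("estimators are invariant under joint sign-flip of one variant", {
  h <- randHarm(8, seed = 31)
  flipOne <- function(h, j) {
    bx <- betaExp(h)[, 1]; by <- betaOut(h)
    bx[j] <- -bx[j]; by[j] <- -by[j]
    medimr:::makeHarmonizedSet(bx, seExp(h)[, 1], by, seOut(h))
  }
  h2 <- flipOne(h, 5)
  expect_equal(theta(mrIVW(h2)), theta(mrIVW(h)), tolerance = 1e-12)
  expect_equal(theta(mrEgger(h2)), theta(mrEgger(h)), tolerance = 1e-12)
  expect_equal(theta(mrWeightedMedian(h2, n_boot = 10, seed = 2)),
               theta(mrWeightedMedian(h, n_boot = 10, seed = 2)),
               tolerance = 1e-12)
  expect_equal(theta(mrMode(h2, n_boot = 10, seed = 2)),
               theta(mrMode(h, n_boot = 10, seed = 2)), tolerance = 1e-12)
})

test_that("multiplicative random-effects SE never falls below the fixed SE", {
  for (seed in 1:15) {
    h <- randHarm(sample(3:10, 1), seed = seed + 50)
    expect_gte(stdError(mrIVW(h)), stdError(mrIVW(h, "fixed")) - 1e-15)
  }
})

test_that("weighted median tolerates 40% directionally pleiotropic instruments", {
  hits <- 0L
  truth <- log(0.51)
  for (seed in 1:20) {
    set.seed(seed)
    bx <- runif(10, 0.05, 0.15)
    sy <- rep(0.01, 10)
    pleio <- c(rep(0, 6), rep(0.01, 4))
    by <- truth * bx + pleio + rnorm(10, 0, sy)
    h <- medimr:::makeHarmonizedSet(bx, rep(0.001, 10), by, sy)
    e <- mrWeightedMedian(h, n_boot = 200, seed = seed)
    if (abs(theta(e) - truth) <= 2 * stdError(e)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
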