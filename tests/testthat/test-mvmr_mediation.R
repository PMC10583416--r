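test_that("single-exposure MVMR equals univariable IVW", {
  for (seed in 1:10) {
    h <- randHarm(sample(4:9, 1), seed = seed + 400)
    mv <- mvmrIVW(h)[[1]]
    uv <- mrIVW(h)
    expect_equal(theta(mv), theta(uv), tolerance = 1e-12)
    expect_equal(stdError(mv), stdError(uv), tolerance = 1e-12)
  }
})

test_that("MVMR solves exact and weight-orthogonal constructions", {
  bx1 <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  bx2 <- c(0.05, -0.1, 0.2, 0.3, -0.05)
  y <- 0.3 * bx1 + 0.7 * bx2
  h <- medimr:::makeHarmonizedSet(cbind(e1 = bx1, e2 = bx2),
                                  matrix(0.01, 5, 2), y, rep(0.02, 5),
                                  exposure_names = c("e1", "e2"))
  mv <- mvmrIVW(h)
  expect_equal(theta(mv$e1), 0.3, tolerance = 1e-12)
  expect_equal(theta(mv$e2), 0.7, tolerance = 1e-12)
  expect_equal(unname(cochranQStat(mv$e1)["q"]), 0, tolerance = 1e-10)

  # second exposure orthogonal to the first under the outcome weights:
  # the first coefficient equals its univariable value
  set.seed(8)
  sy <- runif(6, 0.01, 0.05)
  w <- 1 / sy^2
  b1 <- runif(6, 0.05, 0.3)
  raw <- rnorm(6)
  b2 <- raw - b1 * sum(w * b1 * raw) / sum(w * b1^2)
  stopifnot(abs(sum(w * b1 * b2)) < 1e-10)
  y2 <- rnorm(6, 0.2 * b1, 0.02)
  h2 <- medimr:::makeHarmonizedSet(cbind(e1 = b1, e2 = b2),
                                   matrix(0.01, 6, 2), y2, sy,
                                   exposure_names = c("e1", "e2"))
  h2a <- medimr:::makeHarmonizedSet(b1, rep(0.01, 6), y2, sy,
                                    exposure_names = "e1")
  expect_equal(theta(mvmrIVW(h2)$e1), theta(mrIVW(h2a)), tolerance = 1e-10)

  # oracle: generic normal-equations solve via lm
  for (seed in 1:10) {
    h3 <- randHarm(sample(5:10, 1), k = 2, seed = seed + 500)
    X <- betaExp(h3); yy <- betaOut(h3); ww <- 1 / seOut(h3)^2
    fit <- lm(yy ~ 0 + X, weights = ww)
    mv3 <- mvmrIVW(h3)
    expect_equal(unname(c(theta(mv3[[1]]), theta(mv3[[2]]))),
                 unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("MVMR rejects rank-deficient exposure matrices naming a culprit", {
  b1 <- c(0.1, 0.2, 0.3, 0.15)
  h <- medimr:::makeHarmonizedSet(cbind(e1 = b1, e2 = 2 * b1),
                                  matrix(0.01, 4, 2), rnorm(4), rep(0.02, 4),
                                  exposure_names = c("e1", "e2"))
  expect_error(mvmrIVW(h), "collinear")
})

test_that("MVMR-Egger: intercept-free data, orientation invariance, df guard", {
  set.seed(12)
  J <- 12
  bx1 <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE)
  bx2 <- runif(J, 0.05, 0.3)
  sy <- rep(0.02, J)
  y <- 0.4 * bx1 - 0.2 * bx2 + rnorm(J, 0, 0.01)
  h <- medimr:::makeHarmonizedSet(cbind(e1 = bx1, e2 = bx2),
                                  matrix(0.01, J, 2), y, sy,
                                  exposure_names = c("e1", "e2"))
  mve <- mvmrEgger(h)
  mv <- mvmrIVW(h)
  ic <- attr(mve, "intercept")
  expect_lt(abs(ic[["intercept"]]), 0.02)
  expect_lt(abs(theta(mve$e1) - theta(mv$e1)), 2 * stdError(mve$e1))
  expect_lt(abs(theta(mve$e2) - theta(mv$e2)), 2 * stdError(mve$e2))

  # jointly negating a full variant row leaves estimates unchanged
  bx1f <- bx1; bx2f <- bx2; yf <- y
  bx1f[4] <- -bx1f[4]; bx2f[4] <- -bx2f[4]; yf[4] <- -yf[4]
  hf <- medimr:::makeHarmonizedSet(cbind(e1 = bx1f, e2 = bx2f),
                                   matrix(0.01, J, 2), yf, sy,
                                   exposure_names = c("e1", "e2"))
  mvef <- mvmrEgger(hf)
  expect_equal(theta(mvef$e1), theta(mve$e1), tolerance = 1e-12)
  expect_equal(attr(mvef, "intercept"), ic, tolerance = 1e-12)

  h4 <- medimr:::makeHarmonizedSet(matrix(runif(12, 0.1, 0.3), 4, 3),
                                   matrix(0.01, 4, 3), rnorm(4), rep(0.02, 4),
                                   exposure_names = c("a", "b", "c"))
  expect_error(mvmrEgger(h4), "exposures \\+ 2")
})

test_that("mediated proportion reproduces the printed worked examples", {
  m1 <- mediationProportion(0.42, 0.0995, log(0.88), 0.0433,
                            log(0.51), 0.328, mediator = "total lipoprotein")
  p1 <- mediatedProportion(m1)
  expect_equal(100 * p1[["proportion"]], 8.03, tolerance = 0.2)
  m2 <- mediationProportion(0.43, 0.0995, log(0.89), 0.0428,
                            log(0.51), 0.328)
  expect_equal(100 * mediatedProportion(m2)[["proportion"]], 7.59,
               tolerance = 0.2)
  # null mediator: zero indirect effect, p = 1
  m0 <- mediationProportion(0.42, 0.1, 0, 0.04, log(0.51), 0.328)
  expect_equal(m0@indirect, 0)
  expect_equal(m0@proportion, 0)
  expect_equal(m0@pval, 1)
  expect_error(mediationProportion(0.4, 0.1, 0.2, 0.1, 0, 0.1), "total")
})

test_that("mediation proportion is invariant to a scale swap between steps", {
  m <- mediationProportion(0.42, 0.1, -0.12, 0.04, -0.67, 0.3)
  ms <- mediationProportion(0.42 * 3, 0.1, -0.12 / 3, 0.04, -0.67, 0.3)
  expect_equal(ms@indirect, m@indirect, tolerance = 1e-12)
  expect_equal(ms@proportion, m@proportion, tolerance = 1e-12)
})

test_that("delta-method CI agrees with Monte Carlo on the worked example", {
  m <- mediationProportion(0.42, 0.0995, log(0.88), 0.0433,
                           log(0.51), 0.328)
  set.seed(1)
  b1 <- rnorm(1e5, 0.42, 0.0995)
  b2 <- rnorm(1e5, log(0.88), 0.0433)
  prop <- b1 * b2 / log(0.51)
  mc_ci <- mean(prop) + c(-1, 1) * 1.96 * sd(prop)
  delta_ci <- c(m@ciLow, m@ciHigh)
  width <- diff(delta_ci)
  expect_lt(abs(delta_ci[1] - mc_ci[1]), 0.1 * width)
  expect_lt(abs(delta_ci[2] - mc_ci[2]), 0.1 * width)
})

test_that("Bonferroni thresholds", {
  expect_equal(bonferroniThreshold(0.05, 168), 0.05 / 168)
  expect_equal(bonferroniThreshold(0.05, 168), 2.976e-4, tolerance = 1e-3)
  expect_equal(bonferroniThreshold(0.05, 20), 0.0025)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "m")
  expect_error(bonferroniThreshold(1.2, 10), "alpha")
})
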