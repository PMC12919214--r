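# Gibbs kernels, MH kernels and the full chain driver, checked against
# distributional oracles (exact Beta / grid posteriors / closed-form
# Gaussian conditional) and recovery on simulated data.

test_that("the zero-inflation Gibbs draw targets Beta(alpha+Z, beta+K-Z)", {
  prior <- priorConfig(alpha = 2, beta = 2)
  set.seed(21)
  draws <- replicate(1e5, updatePi(3, 10, prior))
  # conjugate update with K = 10, Z = 3: Beta(5, 9), mean 5/14
  expect_equal(mean(draws), 5 / 14, tolerance = 0.01)
  expect_lt(ksDistance(draws, function(x) pbeta(x, 5, 9)), 0.01)
  # all-zero group shifts mass toward 1
  set.seed(22)
  hi <- replicate(2000, updatePi(10, 10, prior))
  expect_gt(mean(hi), 0.8)
  expect_lt(ksDistance(hi, function(x) pbeta(x, 12, 2)), 0.05)
})

test_that("the variance Gibbs draw matches a brute-force grid posterior", {
  prior <- priorConfig(kappa = 3, theta = 0.4)
  grp <- randomGroup(n = 12, seed = 23)
  obs <- makeObs(grp$vaf, grp$score)
  pars <- list(g1 = groupParams(0.3, 0.4, 0.1))
  set.seed(24)
  draws <- replicate(1e5, updateSigma2(obs, pars, prior))
  # oracle: evaluate likelihood x prior on a fine sigma2 grid using only
  # dnorm and the Inv-Gamma density, never the update formula
  nz <- grp$score != 0
  res <- grp$score[nz] - 0.4 * grp$vaf[nz] - 0.1
  s2Grid <- seq(1e-4, quantile(draws, 0.9999) * 1.5, length.out = 8000)
  logPost <- vapply(s2Grid, function(s2) {
    sum(dnorm(res, 0, sqrt(s2), log = TRUE)) +
      (-prior@kappa - 1) * log(s2) - prior@theta / s2
  }, numeric(1))
  expect_lt(ksDistance(draws, gridCdf(s2Grid, logPost)), 0.01)
})

test_that("zero residuals and no-data cases reduce to the stated laws", {
  prior <- priorConfig(kappa = 2.5, theta = 0.7)
  # scores exactly on the line: conditional is Inv-Gamma(kappa + N1/2, theta)
  v <- c(0.2, 0.5, 0.8)
  obs <- makeObs(v, 0.4 * v + 0.1)
  pars <- list(g1 = groupParams(0.3, 0.4, 0.1))
  set.seed(25)
  draws <- replicate(2e4, updateSigma2(obs, pars, prior))
  igCdf <- function(x, shape, scale) pgamma(1 / x, shape, rate = scale,
                                            lower.tail = FALSE)
  expect_lt(ksDistance(draws, function(x) igCdf(x, 2.5 + 1.5, 0.7)), 0.02)
  # no nonzero records at all: prior draw
  obs0 <- makeObs(runif(5), rep(0, 5))
  set.seed(26)
  draws0 <- replicate(2e4, updateSigma2(obs0, pars, prior))
  expect_lt(ksDistance(draws0, function(x) igCdf(x, 2.5, 0.7)), 0.02)
})

test_that("MH on the slope accepts uphill moves and holds its target law", {
  prior <- priorConfig(alphaA = 2, betaA = 2)
  grp <- randomGroup(n = 10, seed = 27, sigma = 0.5)
  prop <- proposalConfig(stepA = 1.2, adapt = FALSE)
  # stationary law vs the grid-normalised conditional, all else frozen
  b <- 0.1; s2 <- 0.25
  set.seed(28)
  a <- 0.5
  nKeep <- 2e5
  kept <- numeric(nKeep)
  for (i in seq_len(nKeep)) {
    st <- mhStepA(a, grp$vaf, grp$score, b, s2, prior, prop)
    a <- st$value
    kept[i] <- a
  }
  aGrid <- seq(0.0005, 0.9995, length.out = 4000)
  cdf <- gridCdf(aGrid, gridLogPostA(aGrid, grp$vaf, grp$score, b, s2, prior))
  expect_lt(ksDistance(kept, cdf), 0.02)
})

test_that("the Beta independence proposal targets the same conditional", {
  prior <- priorConfig(alphaA = 2, betaA = 2)
  grp <- randomGroup(n = 10, seed = 29, sigma = 0.5)
  prop <- proposalConfig(stepA = 15, modeA = "beta-independence",
                         adapt = FALSE)
  b <- 0.1; s2 <- 0.25
  set.seed(30)
  a <- 0.5
  kept <- numeric(1e5)
  for (i in seq_len(1e5)) {
    a <- mhStepA(a, grp$vaf, grp$score, b, s2, prior, prop)$value
    kept[i] <- a
  }
  aGrid <- seq(0.0005, 0.9995, length.out = 4000)
  cdf <- gridCdf(aGrid, gridLogPostA(aGrid, grp$vaf, grp$score, b, s2, prior))
  expect_lt(ksDistance(kept, cdf), 0.02)
})

test_that("MH on the baseline reproduces the closed-form Gaussian conditional", {
  prior <- priorConfig(sigmaB2 = 0.6)
  grp <- randomGroup(n = 10, seed = 31, sigma = 0.5)
  a <- 0.4; s2 <- 0.25
  nz <- grp$score != 0
  oVar <- 1 / (sum(nz) / s2 + 1 / prior@sigmaB2)
  oMean <- oVar * sum(grp$score[nz] - a * grp$vaf[nz]) / s2
  prop <- proposalConfig(stepB = 2.5 * sqrt(oVar), adapt = FALSE)
  set.seed(32)
  b <- 0
  kept <- numeric(2e5)
  for (i in seq_len(2e5)) {
    b <- mhStepB(b, grp$vaf, grp$score, a, s2, prior, prop)$value
    kept[i] <- b
  }
  expect_lt(abs(mean(kept) - oMean), 0.05 * sqrt(oVar))
  expect_lt(abs(sd(kept) - sqrt(oVar)), 0.05 * sqrt(oVar))
  expect_lt(ksDistance(kept, function(x) pnorm(x, oMean, sqrt(oVar))), 0.02)
})

test_that("uphill proposals are always accepted in symmetric modes", {
  prior <- priorConfig()
  grp <- randomGroup(n = 20, seed = 33)
  prop <- proposalConfig(adapt = FALSE)
  nUp <- 0
  for (s in 1:300) {
    # replay the RNG to learn what the kernel will propose, then assert
    # every uphill move (in the Jacobian-corrected logit target) lands
    a <- runif(1, 0.05, 0.95); b <- 0.1; s2 <- 0.25
    set.seed(s)
    ap <- plogis(qlogis(a) + rnorm(1, 0, prop@stepA))
    lcNew <- logConditionalA(ap, grp$vaf, grp$score, b, s2, prior) +
      log(ap) + log1p(-ap)
    lcOld <- logConditionalA(a, grp$vaf, grp$score, b, s2, prior) +
      log(a) + log1p(-a)
    set.seed(s)
    st <- mhStepA(a, grp$vaf, grp$score, b, s2, prior, prop)
    if (lcNew >= lcOld) {
      nUp <- nUp + 1
      expect_true(st$accepted)
      expect_equal(st$value, ap)
    }
  }
  expect_gt(nUp, 50)  # the assertion above actually fired
  # same for the baseline's symmetric Gaussian walk
  nUp <- 0
  for (s in 301:500) {
    b <- runif(1, -1, 1); a <- 0.4; s2 <- 0.25
    set.seed(s)
    bp <- b + rnorm(1, 0, prop@stepB)
    up <- logConditionalB(bp, grp$vaf, grp$score, a, s2, prior) >=
      logConditionalB(b, grp$vaf, grp$score, a, s2, prior)
    set.seed(s)
    st <- mhStepB(b, grp$vaf, grp$score, a, s2, prior, prop)
    if (up) {
      nUp <- nUp + 1
      expect_true(st$accepted)
      expect_equal(st$value, bp)
    }
  }
  expect_gt(nUp, 30)
})

test_that("chains are bitwise reproducible and sized by the retention rule", {
  grp <- randomGroup(n = 40, seed = 35)
  obs <- makeObs(grp$vaf, grp$score)
  cfg <- mcmcConfig(nIter = 101, burnIn = 100, thin = 1, nChains = 1,
                    seed = 7)
  one <- runChain(obs, priorConfig(), proposalConfig(), cfg, chainSeed = 7)
  expect_equal(nrow(one$draws), 1)
  two <- runChain(obs, priorConfig(), proposalConfig(), cfg, chainSeed = 7)
  expect_identical(one$draws, two$draws)
  # thinning: floor((nIter - burnIn) / thin) retained draws
  cfg2 <- mcmcConfig(nIter = 130, burnIn = 30, thin = 7, nChains = 1, seed = 1)
  expect_equal(nrow(runChain(obs, priorConfig(), proposalConfig(), cfg2,
                             chainSeed = 2)$draws), 14)
  fitA <- runMcmc(obs, config = tinyConfig(seed = 5))
  fitB <- runMcmc(obs, config = tinyConfig(seed = 5))
  expect_identical(chains(fitA), chains(fitB))
  # distinct derived seeds give distinct chains
  expect_false(identical(chains(fitA)[[1]], chains(fitA)[[2]]))
})

test_that("every retained draw respects the parameter supports", {
  for (seed in 1:3) {
    grp <- randomGroup(n = 30, piTrue = c(0.1, 0.5, 0.9)[seed], seed = seed)
    obs <- makeObs(grp$vaf, grp$score)
    fit <- runMcmc(obs, config = tinyConfig(seed = seed),
                   prior = priorConfig(alpha = 1, beta = 5, alphaA = 5,
                                       betaA = 1))
    pool <- pooledDraws(fit)
    piA <- pool[, grepl("^(pi|a)\\[", colnames(pool))]
    expect_true(all(piA > 0 & piA < 1))
    expect_true(all(pool[, "sigma2"] > 0))
  }
})

test_that("posterior means recover simulated truth within 3 posterior SDs", {
  sim <- simulateDataset(simulationSpec(
    nCells = 150, clones = data.frame(pi = 0.3, a = 0.6, b = -0.2),
    mutationsPerCell = 60, sigma = 0.15, seed = 41))
  fit <- runMcmc(sim$observations,
                 config = mcmcConfig(nIter = 2000, burnIn = 1000,
                                     nChains = 2, seed = 42))
  tab <- summaryTable(summarizePosterior(fit))
  truth <- c(pi = 0.3, a = 0.6, b = -0.2)
  for (p in names(truth)) {
    row <- tab[tab$parameter == p & tab$group == "clone1", ]
    expect_lt(abs(row$mean - truth[[p]]), 3 * row$sd + 1e-12)
  }
  s2row <- tab[tab$parameter == "sigma2", ]
  expect_lt(abs(s2row$mean - 0.15^2), 4 * s2row$sd)
})

test_that("with no zero scores the model reduces to Bayesian regression", {
  # pi's posterior collapses toward 0 and b's conditional matches the
  # conjugate normal-linear closed form at the posterior means of (a, s2)
  sim <- simulateDataset(simulationSpec(
    nCells = 200, clones = data.frame(pi = 1e-9, a = 0.5, b = 0.2),
    mutationsPerCell = 30, sigma = 0.2, seed = 43))
  rec <- obsTable(sim$observations)
  expect_true(all(rec$score != 0))
  prior <- priorConfig()
  fit <- runMcmc(sim$observations, prior = prior,
                 config = mcmcConfig(nIter = 2000, burnIn = 1000,
                                     nChains = 2, seed = 44))
  tab <- summaryTable(summarizePosterior(fit))
  piHat <- tab[tab$parameter == "pi", "mean"]
  expect_lt(piHat, prior@alpha / (prior@alpha + prior@beta + nObs(sim$observations)) * 2)
  # the joint (a, b) posterior is ordinary Bayesian linear regression;
  # with the diffuse priors used here lm() supplies the closed form for
  # the intercept's marginal mean and standard error
  ols <- summary(lm(score ~ vaf, data = rec))$coefficients
  bRow <- tab[tab$parameter == "b", ]
  expect_lt(abs(bRow$mean - ols["(Intercept)", 1]),
            3 * ols["(Intercept)", 2])
  expect_lt(abs(bRow$sd - ols["(Intercept)", 2]),
            0.3 * ols["(Intercept)", 2])
  # and the conditional of b given the posterior-mean slope matches the
  # completed-square Gaussian's center
  aHat <- tab[tab$parameter == "a", "mean"]
  s2Hat <- tab[tab$parameter == "sigma2", "mean"]
  cf <- conditionalBGaussian(rec$vaf, rec$score, aHat, s2Hat, prior)
  expect_lt(abs(bRow$mean - cf$mean), 5 * sqrt(cf$var))
})

test_that("the variance trace is stationary after burn-in", {
  sim <- simulateDataset(simulationSpec(
    nCells = 100, clones = data.frame(pi = 0.3, a = 0.4, b = 0),
    mutationsPerCell = 50, sigma = 0.1, seed = 45))
  fit <- runMcmc(sim$observations,
                 config = mcmcConfig(nIter = 3000, burnIn = 1000,
                                     nChains = 2, seed = 46))
  tr <- traceSummary(fit)
  s2 <- tr[tr$parameter == "sigma2", ]
  expect_true(all(s2$slope_p > 0.01))
})

test_that("summaries report pooled moments and exact quantile edge cases", {
  grp <- randomGroup(n = 25, seed = 47)
  obs <- makeObs(grp$vaf, grp$score)
  fit <- runMcmc(obs, config = tinyConfig(seed = 48))
  summ <- summarizePosterior(fit, obs)
  tab <- summaryTable(summ)
  pool <- pooledDraws(fit)
  aRow <- tab[tab$parameter == "a", ]
  expect_equal(aRow$mean, mean(pool[, "a[g1]"]))
  expect_equal(aRow$median, median(pool[, "a[g1]"]))
  expect_true(all(tab$ci_lo <= tab$median & tab$median <= tab$ci_hi))
  # per-cell pressure is the posterior mean slope of the cell's group
  cp <- cellPressure(summ)
  expect_equal(nrow(cp), length(unique(obsTable(obs)$cell)))
  expect_true(all(cp$pressure == aRow$mean))
})
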