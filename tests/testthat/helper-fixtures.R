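# Shared fixtures and independent oracles.

# Build a CloneObservations directly from vectors (single group "g1" by
# default).
makeObs <- function(vaf, score, group = "g1", cell = NULL, mutation = NULL) {
  n <- length(vaf)
  if (is.null(cell)) cell <- sprintf("c%03d", seq_len(n))
  if (is.null(mutation)) mutation <- sprintf("m%03d", seq_len(n))
  df <- data.frame(cell = cell, clone = rep_len(group, n),
                   mutation = mutation, vaf = vaf, score = score)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  on.exit(unlink(p))
  readObservations(p)
}

# A reproducible random group of records with a fixed zero fraction.
randomGroup <- function(n = 10, piTrue = 0.3, a = 0.4, b = 0.1,
                        sigma = 0.3, seed = 1) {
  set.seed(seed)
  vaf <- runif(n)
  z <- rbinom(n, 1, 1 - piTrue)
  score <- ifelse(z == 0, 0, rnorm(n, a * vaf + b, sigma))
  list(vaf = vaf, score = score)
}

# Independent grid oracle: unnormalised log likelihood x prior for the
# slope, computed record by record with dnorm/dbeta (never through the
# package's conditionals).
gridLogPostA <- function(aGrid, vaf, score, b, sigma2, prior) {
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  vapply(aGrid, function(a) {
    sum(dnorm(n, a * v + b, sqrt(sigma2), log = TRUE)) +
      dbeta(a, prior@alphaA, prior@betaA, log = TRUE)
  }, numeric(1))
}

gridLogPostB <- function(bGrid, vaf, score, a, sigma2, prior) {
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  vapply(bGrid, function(b) {
    sum(dnorm(n, a * v + b, sqrt(sigma2), log = TRUE)) +
      dnorm(b, 0, sqrt(prior@sigmaB2), log = TRUE)
  }, numeric(1))
}

# Kolmogorov-Smirnov distance between draws and a CDF on a grid.
ksDistance <- function(draws, cdf) {
  draws <- sort(draws)
  n <- length(draws)
  theo <- cdf(draws)
  max(abs(theo - seq_len(n) / n), abs(theo - (seq_len(n) - 1) / n))
}

# Normalised CDF from an unnormalised log-density tabulated on a grid.
gridCdf <- function(grid, logDens) {
  w <- exp(logDens - max(logDens))
  # trapezoid weights
  d <- diff(grid)
  wt <- c(d / 2, 0) + c(0, d / 2)
  p <- cumsum(w * wt)
  p <- p / p[length(p)]
  function(x) approx(grid, p, xout = x, yleft = 0, yright = 1)$y
}

tinyConfig <- function(seed = 1, nChains = 2) {
  mcmcConfig(nIter = 600, burnIn = 300, thin = 1, nChains = nChains,
             seed = seed)
}
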