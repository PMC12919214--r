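#' Conjugate Gibbs draw for a zero-inflation probability
#'
#' With a Beta(alpha, beta) prior and Z exact-zero scores among K records,
#' the full conditional of pi is Beta(alpha + Z, beta + K - Z); one draw
#' is returned. Uses R's global RNG stream.
#'
#' @param zeroCount number of zero-score records Z in the group.
#' @param totalCount total number of records K in the group.
#' @param prior a [PriorConfig-class] object.
#' @return one draw from the conditional Beta.
#' @export
updatePi <- function(zeroCount, totalCount, prior) {
  stopifnot(zeroCount >= 0, totalCount >= zeroCount)
  rbeta(1, prior@alpha + zeroCount, prior@beta + totalCount - zeroCount)
}

#' Conjugate Gibbs draw for the shared residual variance
#'
#' Standard Normal/Inverse-Gamma conjugacy restricted to the nonzero-score
#' records: with N1 such records across all groups and residual sum of
#' squares RSS under the current per-group (a, b), the conditional is
#' Inverse-Gamma(kappa + N1/2, theta + RSS/2). With no nonzero records the
#' draw falls back to the prior.
#'
#' @param obs a [CloneObservations-class] object.
#' @param params named list of [GroupParams-class] per group.
#' @param prior a [PriorConfig-class] object.
#' @return one draw of sigma2 (> 0).
#' @export
updateSigma2 <- function(obs, params, prior) {
  stopifnot(is(obs, "CloneObservations"))
  rec <- obs@records
  nz <- rec$score != 0
  if (!any(nz)) return(1 / rgamma(1, shape = prior@kappa, rate = prior@theta))
  g <- rec$group[nz]
  a <- vapply(params[g], function(p) p@a, numeric(1))
  b <- vapply(params[g], function(p) p@b, numeric(1))
  res <- rec$score[nz] - a * rec$vaf[nz] - b
  .drawSigma2(sum(nz), sum(res * res), prior)
}

.drawSigma2 <- function(n1, rss, prior) {
  1 / rgamma(1, shape = prior@kappa + n1 / 2,
             rate = prior@theta + max(rss, 0) / 2)
}

# One MH move for the slope given the group's sufficient statistics.
# logit-walk: symmetric on the logit scale once the Jacobian a(1-a) is
# folded into the target ratio. beta-independence: proposal
# Beta(c*a, c*(1-a)) centred on the current value with concentration c;
# its asymmetry requires the explicit Hastings ratio q(a|a')/q(a'|a) --
# omitting it would target the wrong distribution.
.mhA <- function(a, Sv2, Svn, Sv, b, sigma2, alphaA, betaA, step, mode) {
  if (mode == "logit-walk") {
    la <- qlogis(a)
    lp <- la + rnorm(1, 0, step)
    ap <- plogis(lp)
    logR <- .logCondAStat(ap, Sv2, Svn, Sv, b, sigma2, alphaA, betaA) -
      .logCondAStat(a, Sv2, Svn, Sv, b, sigma2, alphaA, betaA) +
      log(ap) + log1p(-ap) - log(a) - log1p(-a)
  } else {
    ap <- rbeta(1, step * a, step * (1 - a))
    if (ap <= 0 || ap >= 1) return(list(value = a, accepted = FALSE))
    logR <- .logCondAStat(ap, Sv2, Svn, Sv, b, sigma2, alphaA, betaA) -
      .logCondAStat(a, Sv2, Svn, Sv, b, sigma2, alphaA, betaA) +
      dbeta(a, step * ap, step * (1 - ap), log = TRUE) -
      dbeta(ap, step * a, step * (1 - a), log = TRUE)
  }
  if (is.finite(logR) && (logR >= 0 || log(runif(1)) < logR))
    list(value = ap, accepted = TRUE)
  else list(value = a, accepted = FALSE)
}

# Symmetric Gaussian random walk for the baseline.
.mhB <- function(b, K1, Sn, Sv, a, sigma2, sigmaB2, step) {
  bp <- b + rnorm(1, 0, step)
  logR <- .logCondBStat(bp, K1, Sn, Sv, a, sigma2, sigmaB2) -
    .logCondBStat(b, K1, Sn, Sv, a, sigma2, sigmaB2)
  if (logR >= 0 || log(runif(1)) < logR) list(value = bp, accepted = TRUE)
  else list(value = b, accepted = FALSE)
}

#' One Metropolis-Hastings move for the selection slope
#'
#' Proposes a new slope value (random walk on the logit scale by default,
#' or a Beta proposal centred on the current value) and accepts with the
#' Metropolis-Hastings probability; uphill moves in symmetric mode are
#' always accepted. Uses R's global RNG stream.
#'
#' @param a current slope in (0, 1).
#' @param vaf,score the group's records.
#' @param b current baseline.
#' @param sigma2 current residual variance.
#' @param prior a [PriorConfig-class] object.
#' @param proposal a [ProposalConfig-class] object.
#' @return list with \code{value} (the new state) and \code{accepted}.
#' @export
mhStepA <- function(a, vaf, score, b, sigma2, prior, proposal) {
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  .mhA(a, sum(v * v), sum(v * n), sum(v), b, sigma2,
       prior@alphaA, prior@betaA, proposal@stepA, proposal@modeA)
}

#' One Metropolis-Hastings move for the baseline
#'
#' Symmetric Gaussian random walk \code{N(b, stepB^2)}; acceptance
#' probability \code{min(1, exp(logcond(b') - logcond(b)))}.
#'
#' @param b current baseline.
#' @param a current slope.
#' @inheritParams mhStepA
#' @return list with \code{value} and \code{accepted}.
#' @export
mhStepB <- function(b, vaf, score, a, sigma2, prior, proposal) {
  nz <- score != 0
  .mhB(b, sum(nz), sum(score[nz]), sum(vaf[nz]), a, sigma2,
       prior@sigmaB2, proposal@stepB)
}

# Initial state per group plus sigma2.
.initState <- function(stats, prior, initMode) {
  G <- nrow(stats)
  if (initMode == "prior-draw") {
    pi0 <- rbeta(G, prior@alpha, prior@beta)
    a0 <- rbeta(G, prior@alphaA, prior@betaA)
    b0 <- rnorm(G, 0, sqrt(prior@sigmaB2))
    s20 <- 1 / rgamma(1, shape = prior@kappa, rate = prior@theta)
    pi0 <- pmin(pmax(pi0, 1e-4), 1 - 1e-4)
    a0 <- pmin(pmax(a0, 1e-4), 1 - 1e-4)
    return(list(pi = pi0, a = a0, b = b0, sigma2 = min(max(s20, 1e-6), 1e3)))
  }
  pi0 <- pmin(pmax(stats$Z / stats$K, 0.01), 0.99)
  a0 <- b0 <- numeric(G)
  rssTot <- 0; n1Tot <- 0
  for (i in seq_len(G)) {
    K1 <- stats$K1[i]
    if (K1 >= 2) {
      sxx <- stats$Sv2[i] - stats$Sv[i]^2 / K1
      sxy <- stats$Svn[i] - stats$Sv[i] * stats$Sn[i] / K1
      slope <- if (sxx > 1e-12) sxy / sxx else 0.5
      a0[i] <- min(max(slope, 0.01), 0.99)
      b0[i] <- (stats$Sn[i] - a0[i] * stats$Sv[i]) / K1
      rssTot <- rssTot + stats$Sn2[i] - 2 * a0[i] * stats$Svn[i] -
        2 * b0[i] * stats$Sn[i] + a0[i]^2 * stats$Sv2[i] +
        2 * a0[i] * b0[i] * stats$Sv[i] + b0[i]^2 * K1
      n1Tot <- n1Tot + K1
    } else {
      a0[i] <- 0.5
      b0[i] <- if (K1 == 1) stats$Sn[i] - 0.5 * stats$Sv[i] else 0
    }
  }
  s20 <- if (n1Tot >= 2) max(rssTot / n1Tot, 1e-6) else 1
  list(pi = pi0, a = a0, b = b0, sigma2 = s20)
}

#' Run one MCMC chain
#'
#' Per iteration the sampler sweeps every group -- Gibbs draw for pi, MH
#' move for a, MH move for b -- then one global Gibbs draw for the shared
#' residual variance. Post-burn-in draws are retained every \code{thin}
#' iterations. The chain is a deterministic function of
#' \code{(obs, prior, proposal, config, chainSeed)}.
#'
#' @param obs a [CloneObservations-class] object.
#' @param prior a [PriorConfig-class] object.
#' @param proposal a [ProposalConfig-class] object.
#' @param config a [McmcConfig-class] object (its \code{seed} slot is
#'   ignored here; \code{chainSeed} rules).
#' @param chainSeed integer seed for this chain.
#' @return list with \code{draws} (matrix retained-draws x parameters),
#'   \code{acceptance} (per group/kernel counts), \code{steps} (final,
#'   possibly burn-in-tuned, proposal scales).
#' @export
runChain <- function(obs, prior, proposal, config, chainSeed) {
  stats <- .groupStats(obs)
  .withSeed(chainSeed,
            .runChainStats(stats, prior, proposal, config))
}

.runChainStats <- function(stats, prior, proposal, config) {
  G <- nrow(stats)
  nIter <- config@nIter; burnIn <- config@burnIn; thin <- config@thin
  nRet <- (nIter - burnIn) %/% thin
  st <- .initState(stats, prior, config@initMode)
  piC <- st$pi; aC <- st$a; bC <- st$b; s2 <- st$sigma2

  cols <- c(paste0("pi[", stats$group, "]"), paste0("a[", stats$group, "]"),
            paste0("b[", stats$group, "]"), "sigma2")
  draws <- matrix(NA_real_, nRet, 3 * G + 1, dimnames = list(NULL, cols))
  accA <- accB <- integer(G)
  stepA <- rep(proposal@stepA, G); stepB <- rep(proposal@stepB, G)
  # Robbins-Monro tuning toward 0.44 acceptance, burn-in only, in batches
  adapt <- proposal@adapt && burnIn > 0
  batch <- 50L
  batA <- batB <- integer(G); batN <- 0L; batIdx <- 0L

  aShape <- prior@kappa; n1Tot <- sum(stats$K1)
  alphaPi <- prior@alpha + stats$Z
  betaPi <- prior@beta + stats$K - stats$Z
  keep <- 0L
  for (it in seq_len(nIter)) {
    for (g in seq_len(G)) {
      piC[g] <- rbeta(1, alphaPi[g], betaPi[g])
      if (stats$K1[g] > 0) {
        mvA <- .mhA(aC[g], stats$Sv2[g], stats$Svn[g], stats$Sv[g], bC[g],
                    s2, prior@alphaA, prior@betaA, stepA[g], proposal@modeA)
        aC[g] <- mvA$value
        if (mvA$accepted) { accA[g] <- accA[g] + 1L; batA[g] <- batA[g] + 1L }
        mvB <- .mhB(bC[g], stats$K1[g], stats$Sn[g], stats$Sv[g], aC[g],
                    s2, prior@sigmaB2, stepB[g])
        bC[g] <- mvB$value
        if (mvB$accepted) { accB[g] <- accB[g] + 1L; batB[g] <- batB[g] + 1L }
      } else {
        # group with no Gaussian records: a, b move under the prior alone
        mvA <- .mhA(aC[g], 0, 0, 0, bC[g], s2, prior@alphaA, prior@betaA,
                    stepA[g], proposal@modeA)
        aC[g] <- mvA$value
        if (mvA$accepted) { accA[g] <- accA[g] + 1L; batA[g] <- batA[g] + 1L }
        mvB <- .mhB(bC[g], 0, 0, 0, aC[g], s2, prior@sigmaB2, stepB[g])
        bC[g] <- mvB$value
        if (mvB$accepted) { accB[g] <- accB[g] + 1L; batB[g] <- batB[g] + 1L }
      }
    }
    rss <- sum(stats$Sn2 - 2 * aC * stats$Svn - 2 * bC * stats$Sn +
                 aC^2 * stats$Sv2 + 2 * aC * bC * stats$Sv + bC^2 * stats$K1)
    s2 <- if (n1Tot > 0) .drawSigma2(n1Tot, rss, prior)
          else 1 / rgamma(1, shape = prior@kappa, rate = prior@theta)

    if (adapt && it <= burnIn) {
      batN <- batN + 1L
      if (batN == batch) {
        batIdx <- batIdx + 1L
        delta <- min(1, 4 / sqrt(batIdx))
        stepA <- stepA * exp((batA / batch - 0.44) * delta)
        stepB <- stepB * exp((batB / batch - 0.44) * delta)
        batA <- batB <- integer(G); batN <- 0L
      }
    }
    if (it > burnIn && (it - burnIn) %% thin == 0) {
      keep <- keep + 1L
      draws[keep, ] <- c(piC, aC, bC, s2)
    }
  }
  acceptance <- data.frame(
    group = rep(stats$group, 2),
    kernel = rep(c("a", "b"), each = G),
    accepted = c(accA, accB), proposed = nIter,
    stringsAsFactors = FALSE)
  list(draws = draws, acceptance = acceptance,
       steps = data.frame(group = stats$group, stepA = stepA, stepB = stepB))
}

#' Run the full multi-chain sampler
#'
#' Runs \code{config@nChains} independent chains with seeds
#' \code{config@seed, config@seed + 1, ...} and aggregates them into a
#' [PosteriorSamples-class] object. Identical inputs give bitwise
#' identical output.
#'
#' @inheritParams runChain
#' @return A [PosteriorSamples-class] object.
#' @examples
#' spec <- simulationSpec(nCells = 40, clones = 2, mutationsPerCell = 20,
#'                        seed = 11)
#' sim <- simulateDataset(spec)
#' fit <- runMcmc(sim$observations,
#'                config = mcmcConfig(nIter = 400, burnIn = 200,
#'                                    nChains = 2, seed = 5))
#' fit
#' @export
runMcmc <- function(obs, prior = priorConfig(), proposal = proposalConfig(),
                    config = mcmcConfig()) {
  stopifnot(is(obs, "CloneObservations"), is(prior, "PriorConfig"),
            is(proposal, "ProposalConfig"), is(config, "McmcConfig"))
  stats <- .groupStats(obs)
  res <- lapply(seq_len(config@nChains), function(ch) {
    .withSeed(config@seed + ch - 1L,
              .runChainStats(stats, prior, proposal, config))
  })
  acc <- do.call(rbind, lapply(seq_along(res), function(ch) {
    cbind(chain = ch, res[[ch]]$acceptance)
  }))
  new("PosteriorSamples",
      chains = lapply(res, `[[`, "draws"),
      acceptance = acc, groups = stats$group,
      prior = prior, proposal = proposal, config = config)
}

#' Summarise posterior draws
#'
#' Pools retained draws across chains and reports, per group and
#' parameter, the posterior mean, median, SD and central 95% credible
#' interval, plus a global row for the residual variance. When the
#' observations are supplied, a per-cell selection pressure is attached:
#' the posterior mean slope of the cell's group, the model's only
#' clone-to-cell map.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param obs optional [CloneObservations-class] used to map cells to
#'   groups for the per-cell pressure table.
#' @return A [PosteriorSummary-class] object.
#' @export
summarizePosterior <- function(samples, obs = NULL) {
  stopifnot(is(samples, "PosteriorSamples"))
  pool <- pooledDraws(samples)
  if (nrow(pool) == 0) stop("no retained draws to summarise")
  grp <- samples@groups
  rows <- list()
  for (g in grp) {
    for (p in c("pi", "a", "b")) {
      x <- pool[, paste0(p, "[", g, "]")]
      rows[[length(rows) + 1L]] <- .sumRow(g, p, x)
    }
  }
  rows[[length(rows) + 1L]] <- .sumRow("(global)", "sigma2", pool[, "sigma2"])
  tab <- do.call(rbind, rows)
  accRates <- stats::aggregate(
    cbind(accepted, proposed) ~ group + kernel, data = samples@acceptance,
    FUN = sum)
  accRates$rate <- accRates$accepted / accRates$proposed
  cellTab <- data.frame(cell = character(0), group = character(0),
                        pressure = numeric(0))
  if (!is.null(obs)) {
    cellGroups <- unique(obs@records[, c("cell", "group")])
    postA <- vapply(grp, function(g) mean(pool[, paste0("a[", g, "]")]),
                    numeric(1))
    cellTab <- data.frame(cell = cellGroups$cell, group = cellGroups$group,
                          pressure = postA[cellGroups$group],
                          row.names = NULL)
  }
  new("PosteriorSummary", table = tab, cellPressure = cellTab,
      acceptanceRates = accRates)
}

.sumRow <- function(group, parameter, x) {
  q <- unname(quantile(x, c(0.025, 0.5, 0.975), type = 7))
  data.frame(group = group, parameter = parameter, mean = mean(x),
             median = q[2], sd = sd(x), ci_lo = q[1], ci_hi = q[3],
             stringsAsFactors = FALSE)
}
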