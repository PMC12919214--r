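# Benchmark drivers reproducing the package's simulation-study protocol:
# posterior recovery of the selection slope, robustness of convergence to
# prior choice, and estimation error of the zero-inflation probability as
# a function of data size and clonal complexity.

# Deterministic per-replicate seed derivation from a master seed; offsets
# stay far below 2^31 for any realistic experiment size.
.repSeed <- function(seed, rep, stratum = 0L) {
  as.integer(seed) + 997L * as.integer(stratum) + 31L * (as.integer(rep) - 1L)
}

#' Posterior recovery of the selection slope
#'
#' Simulates clones with known low/medium/high selection slopes (defaults
#' a = 0.1, 0.3, 0.9), fits the model, and reports per clone and
#' replicate the posterior mean, SD, 95% credible interval, the absolute
#' error against truth and whether the interval covers it.
#'
#' @param trueA true slopes, one clone per value.
#' @param truePi true zero-inflation probability shared by all clones.
#' @param trueB true baselines; by default drawn once per replicate from
#'   Uniform(-0.5, 0.5).
#' @param sigma residual SD of the score noise.
#' @param cellsPerClone,mutationsPerCell data size per replicate.
#' @param nReps number of simulated replicates.
#' @param prior,proposal priors and proposal settings for the fit.
#' @param config MCMC settings; its seed slot is overridden per replicate.
#' @param seed master seed for the whole experiment.
#' @return data.frame with one row per replicate x clone.
#' @export
recoveryExperiment <- function(trueA = c(0.1, 0.3, 0.9), truePi = 0.3,
                               trueB = NULL, sigma = 0.1,
                               cellsPerClone = 300, mutationsPerCell = 200,
                               nReps = 1, prior = priorConfig(),
                               proposal = proposalConfig(),
                               config = mcmcConfig(), seed = 1) {
  G <- length(trueA)
  out <- list()
  for (rep in seq_len(nReps)) {
    simSeed <- .repSeed(seed, rep, 1L)
    b <- if (is.null(trueB)) .withSeed(simSeed + 11L, runif(G, -0.5, 0.5))
         else rep_len(trueB, G)
    spec <- simulationSpec(
      nCells = cellsPerClone * G,
      clones = data.frame(pi = rep_len(truePi, G), a = trueA, b = b),
      mutationsPerCell = mutationsPerCell, sigma = sigma, seed = simSeed)
    sim <- simulateDataset(spec)
    cfg <- config; cfg@seed <- .repSeed(seed, rep, 2L)
    fit <- runMcmc(sim$observations, prior, proposal, cfg)
    tab <- summaryTable(summarizePosterior(fit))
    for (g in seq_len(G)) {
      gid <- sprintf("clone%d", g)
      rowA <- tab[tab$group == gid & tab$parameter == "a", ]
      rowP <- tab[tab$group == gid & tab$parameter == "pi", ]
      out[[length(out) + 1L]] <- data.frame(
        rep = rep, group = gid, trueA = trueA[g], truePi = truePi,
        trueB = b[g],
        postMeanA = rowA$mean, postSdA = rowA$sd,
        ciLoA = rowA$ci_lo, ciHiA = rowA$ci_hi,
        coveredA = rowA$ci_lo <= trueA[g] & trueA[g] <= rowA$ci_hi,
        absErrA = abs(rowA$mean - trueA[g]),
        postMeanPi = rowP$mean, absErrPi = abs(rowP$mean - truePi))
    }
  }
  do.call(rbind, out)
}

# Lighter MCMC settings for the replicated error sweeps: the
# zero-inflation posterior is conjugate-dominated, so short chains carry
# negligible Monte-Carlo error relative to the quantity being measured.
.sweepConfig <- function(seed = 1) {
  mcmcConfig(nIter = 3000, burnIn = 1000, thin = 1, nChains = 2, seed = seed)
}

#' Estimation error of the zero-inflation probability vs. number of cells
#'
#' For each cell count, simulates \code{nReps} single-clone datasets with
#' 200 mutations per cell (by default), fits the model, and reports the
#' mean absolute error of the posterior-mean zero-inflation estimate.
#'
#' @param cellCounts numbers of cells to sweep.
#' @param mutationsPerCell mutations per cell.
#' @param nReps replicates per cell count.
#' @param truePi,trueA true parameters (baseline is redrawn per
#'   replicate from Uniform(-0.5, 0.5)).
#' @param sigma residual SD of the score noise.
#' @param prior,proposal fit settings.
#' @param config MCMC settings (replicate seeds derived from \code{seed}).
#' @param seed master seed.
#' @return data.frame with one row per cell count: \code{nCells},
#'   \code{mae}, \code{se} (standard error of the MAE across replicates),
#'   \code{nReps}.
#' @export
maeVsCells <- function(cellCounts = seq(50, 500, by = 50),
                       mutationsPerCell = 200, nReps = 10, truePi = 0.3,
                       trueA = 0.3, sigma = 0.1, prior = priorConfig(),
                       proposal = proposalConfig(),
                       config = .sweepConfig(), seed = 1) {
  out <- list()
  for (i in seq_along(cellCounts)) {
    nc <- cellCounts[i]
    errs <- numeric(nReps)
    for (rep in seq_len(nReps)) {
      simSeed <- .repSeed(seed, rep, 100L + i)
      b <- .withSeed(simSeed + 11L, runif(1, -0.5, 0.5))
      spec <- simulationSpec(
        nCells = nc, clones = data.frame(pi = truePi, a = trueA, b = b),
        mutationsPerCell = mutationsPerCell, sigma = sigma, seed = simSeed)
      sim <- simulateDataset(spec)
      cfg <- config; cfg@seed <- simSeed + 500L
      fit <- runMcmc(sim$observations, prior, proposal, cfg)
      piHat <- mean(pooledDraws(fit)[, "pi[clone1]"])
      errs[rep] <- abs(piHat - truePi)
    }
    out[[i]] <- data.frame(nCells = nc, mae = mean(errs),
                           se = sd(errs) / sqrt(nReps), nReps = nReps)
  }
  do.call(rbind, out)
}

#' Estimation error of the zero-inflation probability vs. number of clones
#'
#' Sweeps the number of clones; each clone receives a distinct true
#' zero-inflation probability (evenly spaced on [0.2, 0.8]) and baseline
#' (redrawn per replicate), cells are split evenly across clones, and the
#' MAE of the posterior-mean zero-inflation estimates is averaged over
#' clones and replicates.
#'
#' @param cloneCounts numbers of clones to sweep.
#' @param nCells total cells per dataset (split across clones).
#' @inheritParams maeVsCells
#' @return data.frame with one row per clone count: \code{nClones},
#'   \code{mae}, \code{se}, \code{nReps}.
#' @export
maeVsClones <- function(cloneCounts = 1:6, nCells = 300,
                        mutationsPerCell = 200, nReps = 10, sigma = 0.1,
                        prior = priorConfig(), proposal = proposalConfig(),
                        config = .sweepConfig(), seed = 1) {
  out <- list()
  for (i in seq_along(cloneCounts)) {
    G <- cloneCounts[i]
    truePi <- if (G == 1) 0.5 else seq(0.2, 0.8, length.out = G)
    trueA <- if (G == 1) 0.5 else seq(0.1, 0.9, length.out = G)
    errs <- numeric(nReps)
    for (rep in seq_len(nReps)) {
      simSeed <- .repSeed(seed, rep, 200L + i)
      b <- .withSeed(simSeed + 11L, runif(G, -0.5, 0.5))
      spec <- simulationSpec(
        nCells = nCells,
        clones = data.frame(pi = truePi, a = trueA, b = b),
        mutationsPerCell = mutationsPerCell, sigma = sigma, seed = simSeed)
      sim <- simulateDataset(spec)
      cfg <- config; cfg@seed <- simSeed + 500L
      fit <- runMcmc(sim$observations, prior, proposal, cfg)
      pool <- pooledDraws(fit)
      piHat <- vapply(seq_len(G), function(g)
        mean(pool[, sprintf("pi[clone%d]", g)]), numeric(1))
      errs[rep] <- mean(abs(piHat - truePi))
    }
    out[[i]] <- data.frame(nClones = G, mae = mean(errs),
                           se = sd(errs) / sqrt(nReps), nReps = nReps)
  }
  do.call(rbind, out)
}

#' Default prior configurations for the robustness sweep
#'
#' The five configurations exercised by [priorRobustness()]: symmetric
#' Beta(2, 2), left-skewed Beta(1, 5) and right-skewed Beta(5, 1) shapes
#' on both the zero-inflation probability and the slope, plus two widths
#' of the Normal baseline prior, N(0, 0.5) and N(0, 2).
#'
#' @return named list of [PriorConfig-class] objects.
#' @export
priorGrid <- function() {
  list(
    "Beta(2,2)" = priorConfig(alpha = 2, beta = 2, alphaA = 2, betaA = 2),
    "Beta(1,5)" = priorConfig(alpha = 1, beta = 5, alphaA = 1, betaA = 5),
    "Beta(5,1)" = priorConfig(alpha = 5, beta = 1, alphaA = 5, betaA = 1),
    "N(0,0.5)" = priorConfig(sigmaB2 = 0.5),
    "N(0,2)"   = priorConfig(sigmaB2 = 2)
  )
}

#' Convergence robustness to prior choice
#'
#' Simulates one three-clone dataset (recovery-experiment defaults), then
#' refits it under each prior configuration with chains started from
#' independent prior draws (overdispersed starts) and reports the
#' Gelman-Rubin PSRF of the zero-inflation probability, slope and
#' baseline -- the maximum across clones -- per configuration.
#'
#' @param priors named list of [PriorConfig-class] objects; defaults to
#'   [priorGrid()].
#' @param trueA,truePi,sigma,cellsPerClone,mutationsPerCell simulated
#'   dataset settings (recovery defaults).
#' @param config MCMC settings; \code{initMode} is forced to
#'   \code{"prior-draw"}.
#' @param seed master seed.
#' @return data.frame with one row per configuration x parameter:
#'   \code{config}, \code{parameter}, \code{psrf}.
#' @export
priorRobustness <- function(priors = priorGrid(), trueA = c(0.1, 0.3, 0.9),
                            truePi = 0.3, sigma = 0.1, cellsPerClone = 300,
                            mutationsPerCell = 200,
                            config = mcmcConfig(), seed = 1) {
  G <- length(trueA)
  simSeed <- .repSeed(seed, 1, 300L)
  b <- .withSeed(simSeed + 11L, runif(G, -0.5, 0.5))
  spec <- simulationSpec(
    nCells = cellsPerClone * G,
    clones = data.frame(pi = rep_len(truePi, G), a = trueA, b = b),
    mutationsPerCell = mutationsPerCell, sigma = sigma, seed = simSeed)
  sim <- simulateDataset(spec)
  cfg <- config
  cfg@initMode <- "prior-draw"
  out <- list()
  for (nm in names(priors)) {
    cfg@seed <- simSeed + 500L + match(nm, names(priors))
    fit <- runMcmc(sim$observations, priors[[nm]], proposalConfig(), cfg)
    for (p in c("pi", "a", "b")) {
      vals <- vapply(sprintf("%s[clone%d]", p, seq_len(G)), function(col)
        psrf(lapply(fit@chains, function(m) m[, col])), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        config = nm, parameter = p, psrf = max(vals))
    }
  }
  do.call(rbind, out)
}
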