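#' Construct a prior configuration
#'
#' Defaults place a symmetric Beta(2, 2) prior on both the zero-inflation
#' probability and the selection slope, a standard Normal prior on the
#' baseline, and a weakly informative Inverse-Gamma(2, 0.5) prior on the
#' residual variance (prior mean 0.5). With realistic data sizes the
#' likelihood dominates all four.
#'
#' @param alpha,beta Beta prior shapes for the zero-inflation probability.
#' @param alphaA,betaA Beta prior shapes for the selection slope.
#' @param sigmaB2 variance of the Normal(0, sigmaB2) prior on the baseline.
#' @param kappa,theta Inverse-Gamma shape and scale for the residual
#'   variance.
#' @return A [PriorConfig-class] object.
#' @export
priorConfig <- function(alpha = 2, beta = 2, alphaA = 2, betaA = 2,
                        sigmaB2 = 1, kappa = 2, theta = 0.5) {
  new("PriorConfig", alpha = as.numeric(alpha), beta = as.numeric(beta),
      alphaA = as.numeric(alphaA), betaA = as.numeric(betaA),
      sigmaB2 = as.numeric(sigmaB2), kappa = as.numeric(kappa),
      theta = as.numeric(theta))
}

#' Construct a proposal configuration
#'
#' @param stepA random-walk scale for the slope on the logit scale
#'   (\code{modeA = "logit-walk"}), or the Beta proposal concentration
#'   (\code{modeA = "beta-independence"}).
#' @param stepB Gaussian random-walk standard deviation for the baseline.
#' @param modeA proposal family for the slope.
#' @param adapt tune both scales toward 44\% acceptance during burn-in,
#'   then freeze.
#' @return A [ProposalConfig-class] object.
#' @export
proposalConfig <- function(stepA = 0.5, stepB = 0.5,
                           modeA = c("logit-walk", "beta-independence"),
                           adapt = TRUE) {
  new("ProposalConfig", stepA = as.numeric(stepA), stepB = as.numeric(stepB),
      modeA = match.arg(modeA), adapt = isTRUE(adapt))
}

#' Construct an MCMC run configuration
#'
#' @param nIter iterations per chain.
#' @param burnIn discarded initial iterations (< nIter).
#' @param thin keep every thin-th post-burn-in draw.
#' @param nChains number of independent chains; chain c is seeded with
#'   \code{seed + c - 1}.
#' @param seed master seed making the whole run reproducible.
#' @param initMode \code{"data-driven"} (moment-based starts) or
#'   \code{"prior-draw"} (overdispersed starts from the priors).
#' @return A [McmcConfig-class] object.
#' @export
mcmcConfig <- function(nIter = 5000, burnIn = 2000, thin = 1, nChains = 4,
                       seed = 1, initMode = c("data-driven", "prior-draw")) {
  new("McmcConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), nChains = as.integer(nChains),
      seed = as.integer(seed), initMode = match.arg(initMode))
}

#' Construct per-group parameters
#'
#' @param pi zero-inflation probability in (0, 1).
#' @param a selection slope in (0, 1).
#' @param b finite baseline.
#' @export
groupParams <- function(pi, a, b) {
  new("GroupParams", pi = as.numeric(pi), a = as.numeric(a),
      b = as.numeric(b))
}

#' Construct a simulation specification
#'
#' @param nCells number of cells; partitioned evenly across clones.
#' @param clones data.frame with columns \code{pi}, \code{a}, \code{b}
#'   (one row per clone), or a number of clones to fill with defaults:
#'   \code{pi} evenly spaced on [0.2, 0.8], \code{a} evenly spaced on
#'   [0.1, 0.9] (both 0.5 for a single clone) and \code{b} drawn once from
#'   Uniform(-0.5, 0.5) under \code{seed}.
#' @param mutationsPerCell mutations simulated per cell.
#' @param sigma residual standard deviation of the Gaussian score
#'   component.
#' @param seed seed making the generated dataset reproducible.
#' @return A [SimulationSpec-class] object.
#' @export
simulationSpec <- function(nCells, clones, mutationsPerCell = 200,
                           sigma = 0.1, seed = 1) {
  if (is.numeric(clones) && length(clones) == 1) {
    g <- as.integer(clones)
    stopifnot(g >= 1)
    clones <- data.frame(
      pi = if (g == 1) 0.5 else seq(0.2, 0.8, length.out = g),
      a  = if (g == 1) 0.5 else seq(0.1, 0.9, length.out = g),
      b  = .withSeed(as.integer(seed) + 7L, runif(g, -0.5, 0.5))
    )
  }
  new("SimulationSpec", nCells = as.integer(nCells),
      clones = as.data.frame(clones),
      mutationsPerCell = as.integer(mutationsPerCell),
      sigma = as.numeric(sigma), seed = as.integer(seed))
}

# ---- accessors -------------------------------------------------------------

#' @describeIn CloneObservations-class number of records
#' @param object,x a \code{CloneObservations} object
#' @export
nObs <- function(x) nrow(x@records)

#' @describeIn CloneObservations-class record table (one row per
#'   (cell, clone, mutation) observation)
#' @export
obsTable <- function(x) x@records

#' @describeIn CloneObservations-class group identifiers, sorted
#' @export
groupNames <- function(x) {
  if (is(x, "CloneObservations")) sort(unique(x@records$group))
  else if (is(x, "PosteriorSamples")) x@groups
  else stop("no groups in object of class ", class(x))
}

#' @describeIn PosteriorSamples-class list of per-chain draw matrices
#' @param x a \code{PosteriorSamples} object
#' @export
chains <- function(x) x@chains

#' @describeIn PosteriorSamples-class all chains stacked into one matrix
#' @export
pooledDraws <- function(x) do.call(rbind, x@chains)

#' @describeIn PosteriorSummary-class the group/parameter summary table
#' @param x a \code{PosteriorSummary} object
#' @export
summaryTable <- function(x) x@table

#' @describeIn PosteriorSummary-class per-cell selection pressure (the
#'   posterior mean slope of the cell's group)
#' @export
cellPressure <- function(x) x@cellPressure

# ---- show methods ----------------------------------------------------------

setMethod("show", "CloneObservations", function(object) {
  rec <- object@records
  cat("CloneObservations:", nrow(rec), "records |",
      length(unique(rec$cell)), "cells |",
      length(unique(rec$group)), "groups\n")
  cat("  zero-score fraction:",
      format(mean(rec$score == 0), digits = 3), "\n")
})

setMethod("show", "PosteriorSamples", function(object) {
  n <- nrow(object@chains[[1]])
  cat("PosteriorSamples:", length(object@chains), "chains x", n,
      "retained draws |", length(object@groups), "groups\n")
  cat("  nIter", object@config@nIter, "| burnIn", object@config@burnIn,
      "| thin", object@config@thin, "| seed", object@config@seed, "\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary over", length(unique(object@table$group)) - 1,
      "groups\n")
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", object@nCells, "cells x",
      object@mutationsPerCell, "mutations |", nrow(object@clones),
      "clones | sigma", object@sigma, "| seed", object@seed, "\n")
})
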