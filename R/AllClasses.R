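#' @import methods
#' @importFrom stats dnorm rnorm runif rbeta rbinom rgamma quantile var sd
#'   acf plogis qlogis dbeta setNames aggregate lm
NULL

#' Long-format heteroplasmy observations
#'
#' A validated container for (cell, clone, mutation) observation triples.
#' Each record pairs the variant allele frequency (VAF) of one mitochondrial
#' mutation in one cell with that cell's scalar disease-relevance score.
#' Records are grouped by clone (the default) or by cell-within-clone; the
#' group is the unit that receives its own zero-inflation probability
#' \eqn{\pi}, selection slope \eqn{a} and baseline \eqn{b} in the model.
#'
#' A record contributes to the zero-inflated point mass exactly when its
#' score equals 0: the continuous Gaussian component hits zero with
#' probability zero, so exact equality is an unambiguous encoding of the
#' latent indicator and no tolerance is applied.
#'
#' @slot records data.frame with columns \code{cell}, \code{group},
#'   \code{clone}, \code{mutation}, \code{vaf}, \code{score}.
#'
#' @seealso [readObservations()], [assembleObservations()],
#'   [simulateDataset()]
#' @export
setClass("CloneObservations", slots = c(records = "data.frame"))

setValidity("CloneObservations", function(object) {
  rec <- object@records
  need <- c("cell", "group", "clone", "mutation", "vaf", "score")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(rec) == 0)
    return("no observations")
  if (!is.numeric(rec$vaf) || anyNA(rec$vaf) ||
      any(rec$vaf < 0 | rec$vaf > 1))
    return("every vaf must lie in [0, 1]")
  if (!is.numeric(rec$score) || any(!is.finite(rec$score)))
    return("every score must be finite")
  key <- paste(rec$cell, rec$clone, rec$mutation, sep = "\r")
  if (anyDuplicated(key))
    return("(cell, clone, mutation) triples must be unique")
  TRUE
})

#' Hyperparameters of the hierarchical priors
#'
#' Collects every hyperparameter of the model: \code{alpha}, \code{beta}
#' shape the Beta prior on the zero-inflation probability \eqn{\pi};
#' \code{alphaA}, \code{betaA} shape the Beta prior on the selection slope
#' \eqn{a} (which confines \eqn{a} to (0, 1)); \code{sigmaB2} is the
#' variance of the mean-zero Normal prior on the baseline \eqn{b}; and
#' \code{kappa}, \code{theta} are the shape and scale of the Inverse-Gamma
#' prior on the residual variance \eqn{\sigma^2}. All strictly positive.
#'
#' @export
setClass("PriorConfig", slots = c(
  alpha = "numeric", beta = "numeric",
  alphaA = "numeric", betaA = "numeric",
  sigmaB2 = "numeric",
  kappa = "numeric", theta = "numeric"
))

setValidity("PriorConfig", function(object) {
  vals <- c(object@alpha, object@beta, object@alphaA, object@betaA,
            object@sigmaB2, object@kappa, object@theta)
  if (length(vals) != 7 || any(!is.finite(vals)) || any(vals <= 0))
    return("all hyperparameters must be single strictly positive numbers")
  TRUE
})

#' Per-group model parameters
#'
#' One group's (clone's) parameter triple: zero-inflation probability
#' \code{pi} in (0, 1), selection slope \code{a} in (0, 1) (support imposed
#' by its Beta prior) and finite baseline \code{b}.
#'
#' @export
setClass("GroupParams", slots = c(pi = "numeric", a = "numeric", b = "numeric"))

setValidity("GroupParams", function(object) {
  if (length(object@pi) != 1 || !is.finite(object@pi) ||
      object@pi <= 0 || object@pi >= 1)
    return("pi must lie strictly inside (0, 1)")
  if (length(object@a) != 1 || !is.finite(object@a) ||
      object@a <= 0 || object@a >= 1)
    return("a must lie strictly inside (0, 1)")
  if (length(object@b) != 1 || !is.finite(object@b))
    return("b must be a finite number")
  TRUE
})

#' Metropolis-Hastings proposal settings
#'
#' \code{stepA} scales the proposal for the selection slope: in
#' \code{"logit-walk"} mode (default) it is the standard deviation of a
#' Gaussian random walk on logit(a), symmetric after the Jacobian
#' correction; in \code{"beta-independence"} mode it is the concentration
#' of a Beta proposal centred on the current value, whose asymmetry is
#' compensated by the explicit Hastings ratio. \code{stepB} is the standard
#' deviation \eqn{\tau} of the Gaussian random walk on the baseline.
#' With \code{adapt = TRUE} both scales are tuned toward a 44\% acceptance
#' rate during burn-in only, then frozen so retained draws come from a
#' fixed kernel.
#'
#' @export
setClass("ProposalConfig", slots = c(
  stepA = "numeric", stepB = "numeric", modeA = "character",
  adapt = "logical"
))

setValidity("ProposalConfig", function(object) {
  if (length(object@stepA) != 1 || !is.finite(object@stepA) || object@stepA <= 0)
    return("stepA must be a single positive number")
  if (length(object@stepB) != 1 || !is.finite(object@stepB) || object@stepB <= 0)
    return("stepB must be a single positive number")
  if (!object@modeA %in% c("logit-walk", "beta-independence"))
    return("modeA must be 'logit-walk' or 'beta-independence'")
  if (length(object@adapt) != 1 || is.na(object@adapt))
    return("adapt must be TRUE or FALSE")
  TRUE
})

#' MCMC run settings
#'
#' Iteration counts, burn-in, thinning, number of chains, master seed and
#' initialisation mode. \code{initMode = "data-driven"} starts each chain
#' at moment-based estimates (zero fraction, least-squares slope/intercept,
#' residual variance); \code{"prior-draw"} starts from independent prior
#' draws, giving the overdispersed starts used for convergence testing.
#'
#' @export
setClass("McmcConfig", slots = c(
  nIter = "integer", burnIn = "integer", thin = "integer",
  nChains = "integer", seed = "integer", initMode = "character"
))

setValidity("McmcConfig", function(object) {
  if (object@burnIn < 0 || object@burnIn >= object@nIter)
    return("need 0 <= burnIn < nIter")
  if (object@thin < 1) return("thin must be >= 1")
  if ((object@nIter - object@burnIn) %/% object@thin < 1)
    return("no draws would be retained; lower burnIn or thin")
  if (object@nChains < 1) return("nChains must be >= 1")
  if (!object@initMode %in% c("data-driven", "prior-draw"))
    return("initMode must be 'data-driven' or 'prior-draw'")
  TRUE
})

#' Posterior draws from one or more chains
#'
#' Multi-chain MCMC output. Each element of \code{chains} is a numeric
#' matrix of retained (post burn-in, thinned) draws with one column per
#' parameter (\code{pi[g]}, \code{a[g]}, \code{b[g]} per group \code{g},
#' plus the shared \code{sigma2}). \code{acceptance} counts
#' Metropolis-Hastings acceptances per chain, group and kernel over all
#' iterations. The prior, proposal and run configuration are carried along
#' so a fit is self-describing.
#'
#' @export
setClass("PosteriorSamples", slots = c(
  chains = "list", acceptance = "data.frame", groups = "character",
  prior = "PriorConfig", proposal = "ProposalConfig", config = "McmcConfig"
))

setValidity("PosteriorSamples", function(object) {
  if (length(object@chains) < 1) return("need at least one chain")
  ok <- vapply(object@chains, function(m) is.matrix(m) && nrow(m) >= 1,
               logical(1))
  if (!all(ok)) return("each chain must be a matrix with >= 1 retained draw")
  nc <- vapply(object@chains, ncol, integer(1))
  if (length(unique(nc)) != 1)
    return("chains must share one parameter layout")
  if (nrow(object@acceptance) > 0 &&
      any(object@acceptance$accepted > object@acceptance$proposed))
    return("acceptance counters cannot exceed proposal counts")
  TRUE
})

#' Posterior summary tables
#'
#' Reporting layer of a fit: per group and parameter the pooled posterior
#' mean, median, SD and central 95% credible interval; a per-cell selection
#' pressure (the posterior mean slope of the cell's group); and MH
#' acceptance rates.
#'
#' @export
setClass("PosteriorSummary", slots = c(
  table = "data.frame", cellPressure = "data.frame",
  acceptanceRates = "data.frame"
))

setValidity("PosteriorSummary", function(object) {
  tab <- object@table
  need <- c("group", "parameter", "mean", "median", "sd", "ci_lo", "ci_hi")
  if (!all(need %in% names(tab))) return("malformed summary table")
  if (any(tab$ci_lo > tab$median + 1e-12) ||
      any(tab$median > tab$ci_hi + 1e-12))
    return("need ci_lo <= median <= ci_hi for every parameter")
  unitPar <- tab$parameter %in% c("pi", "a")
  if (any(tab$mean[unitPar] <= 0 | tab$mean[unitPar] >= 1))
    return("pi and a summaries must lie in (0, 1)")
  s2 <- tab$parameter == "sigma2"
  if (any(tab$mean[s2] <= 0)) return("sigma2 summaries must be positive")
  TRUE
})

#' Ground-truth settings for the synthetic-data generator
#'
#' \code{clones} is a data.frame with one row per clone and columns
#' \code{pi}, \code{a}, \code{b}: the true zero-inflation probability,
#' selection slope and baseline. Cells are partitioned evenly across
#' clones (one clonal population per cell), each cell carries
#' \code{mutationsPerCell} mutations, and \code{sigma} is the residual
#' standard deviation of the Gaussian score component.
#'
#' @export
setClass("SimulationSpec", slots = c(
  nCells = "integer", clones = "data.frame", mutationsPerCell = "integer",
  sigma = "numeric", seed = "integer"
))

setValidity("SimulationSpec", function(object) {
  if (object@nCells < 1) return("nCells must be >= 1")
  if (object@mutationsPerCell < 1) return("mutationsPerCell must be >= 1")
  cl <- object@clones
  if (nrow(cl) < 1 || !all(c("pi", "a", "b") %in% names(cl)))
    return("clones must have >= 1 row and columns pi, a, b")
  # pi = 1 is allowed in simulation only (all-zero clone, boundary case)
  if (any(cl$pi < 0 | cl$pi > 1)) return("true pi must lie in [0, 1]")
  if (any(cl$a <= 0 | cl$a >= 1)) return("true a must lie in (0, 1)")
  if (any(!is.finite(cl$b))) return("true b must be finite")
  if (!is.finite(object@sigma) || object@sigma < 0)
    return("sigma must be >= 0")
  TRUE
})
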