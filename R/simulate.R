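#' Generate a synthetic heteroplasmy dataset
#'
#' Follows the model's own generative process. Cells are partitioned
#' evenly across the clones of the spec (one clonal population per cell).
#' For every mutation of every cell: the VAF is drawn Uniform(0, 1); a
#' latent indicator z is drawn Bernoulli(1 - pi) for the cell's clone;
#' when z = 0 the score is exactly 0, otherwise the score is drawn
#' Normal(a * vaf + b, sigma^2). The result is deterministic given the
#' spec's seed and leaves the caller's RNG state untouched.
#'
#' @param spec a [SimulationSpec-class] object.
#' @return list with \code{observations} (a [CloneObservations-class])
#'   and \code{truth}: the per-group true (pi, a, b), the true sigma2,
#'   and the per-record latent z.
#' @examples
#' sim <- simulateDataset(simulationSpec(nCells = 30, clones = 3,
#'                                       mutationsPerCell = 10, seed = 2))
#' sim$observations
#' sim$truth$groups
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  .withSeed(spec@seed, {
    G <- nrow(spec@clones)
    nC <- spec@nCells; K <- spec@mutationsPerCell
    cloneOf <- rep(rep_len(seq_len(G), nC), each = K)
    nRec <- nC * K
    cellIdx <- rep(seq_len(nC), each = K)
    cell <- sprintf("cell%05d", cellIdx)
    mutation <- sprintf("mut%04d", rep(seq_len(K), nC))
    groupIds <- sprintf("clone%d", seq_len(G))

    v <- runif(nRec)
    piR <- spec@clones$pi[cloneOf]
    z <- rbinom(nRec, 1L, 1 - piR)
    score <- numeric(nRec)
    on <- z == 1L
    mu <- spec@clones$a[cloneOf[on]] * v[on] + spec@clones$b[cloneOf[on]]
    score[on] <- if (spec@sigma > 0) rnorm(sum(on), mu, spec@sigma) else mu

    obs <- .makeObservations(cell = cell, clone = groupIds[cloneOf],
                             mutation = mutation, vaf = v, score = score,
                             groupBy = "clone")
    truth <- list(
      groups = data.frame(group = groupIds, pi = spec@clones$pi,
                          a = spec@clones$a, b = spec@clones$b,
                          stringsAsFactors = FALSE),
      sigma2 = spec@sigma^2, z = z)
    list(observations = obs, truth = truth)
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the standard long-format observation CSV next to a
#' \code{truth.csv} recording the generating parameters, so simulation
#' outputs are self-describing.
#'
#' @param sim result of [simulateDataset()].
#' @param outDir output directory, created if needed.
#' @return invisibly, the two paths.
#' @export
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  obsPath <- file.path(outDir, "observations.csv")
  writeObservations(sim$observations, obsPath)
  truthPath <- file.path(outDir, "truth.csv")
  tr <- sim$truth$groups
  tr$sigma2 <- sim$truth$sigma2
  for (cc in c("pi", "a", "b", "sigma2")) tr[[cc]] <- .fmtNum(tr[[cc]])
  utils::write.csv(tr, truthPath, row.names = FALSE, quote = FALSE)
  invisible(c(obsPath, truthPath))
}
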