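#' Write a fit to disk
#'
#' Emits into \code{outDir}: \code{summary.csv} (one row per group and
#' parameter), one \code{chains_<c>.csv} per chain holding the full
#' thinned draws, and \code{run_meta.json} recording the seed, priors,
#' proposal, iteration plan and acceptance counters. Numeric values are
#' written with 17 significant digits so a read-back reproduces every
#' draw bitwise.
#'
#' @param summary a [PosteriorSummary-class] object.
#' @param samples the [PosteriorSamples-class] object it was computed
#'   from (same groups).
#' @param outDir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
writePosterior <- function(summary, samples, outDir) {
  stopifnot(is(summary, "PosteriorSummary"), is(samples, "PosteriorSamples"))
  if (length(samples@chains) == 0 || nrow(samples@chains[[1]]) == 0)
    stop("refusing to write empty samples")
  sGroups <- setdiff(unique(summary@table$group), "(global)")
  if (!setequal(sGroups, samples@groups))
    stop("summary and samples refer to different groups")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)

  paths <- character(0)
  sumPath <- file.path(outDir, "summary.csv")
  tab <- summary@table
  for (cc in c("mean", "median", "sd", "ci_lo", "ci_hi"))
    tab[[cc]] <- .fmtNum(tab[[cc]])
  utils::write.csv(tab, sumPath, row.names = FALSE, quote = FALSE)
  paths <- c(paths, sumPath)

  for (ch in seq_along(samples@chains)) {
    m <- samples@chains[[ch]]
    df <- as.data.frame(apply(m, 2, .fmtNum), check.names = FALSE)
    df <- cbind(iteration = seq_len(nrow(m)), df)
    p <- file.path(outDir, sprintf("chains_%d.csv", ch))
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }

  cfg <- samples@config; pr <- samples@prior; pp <- samples@proposal
  meta <- list(
    package = "mitoSelect",
    version = as.character(utils::packageVersion("mitoSelect")),
    seed = cfg@seed, nIter = cfg@nIter, burnIn = cfg@burnIn,
    thin = cfg@thin, nChains = cfg@nChains, initMode = cfg@initMode,
    prior = list(alpha = pr@alpha, beta = pr@beta, alphaA = pr@alphaA,
                 betaA = pr@betaA, sigmaB2 = pr@sigmaB2, kappa = pr@kappa,
                 theta = pr@theta),
    proposal = list(stepA = pp@stepA, stepB = pp@stepB, modeA = pp@modeA,
                    adapt = pp@adapt),
    groups = samples@groups,
    acceptance = samples@acceptance)
  metaPath <- file.path(outDir, "run_meta.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, metaPath))
}

#' Read back a written fit
#'
#' Inverse of [writePosterior()]: returns the summary table, the per-chain
#' draw matrices (bitwise identical to what was written) and the run
#' metadata.
#'
#' @param outDir directory previously passed to [writePosterior()].
#' @return list with elements \code{summary} (data.frame), \code{chains}
#'   (list of matrices) and \code{meta} (list).
#' @export
readPosterior <- function(outDir) {
  sumPath <- file.path(outDir, "summary.csv")
  if (!file.exists(sumPath)) stop("no summary.csv under ", outDir)
  summary <- utils::read.csv(sumPath, stringsAsFactors = FALSE)
  chainFiles <- sort(list.files(outDir, pattern = "^chains_[0-9]+\\.csv$",
                                full.names = TRUE))
  chains <- lapply(chainFiles, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    as.matrix(df[, setdiff(names(df), "iteration"), drop = FALSE])
  })
  meta <- jsonlite::read_json(file.path(outDir, "run_meta.json"),
                              simplifyVector = TRUE)
  list(summary = summary, chains = chains, meta = meta)
}

#' Write an observation set as long-format CSV
#'
#' @param obs a [CloneObservations-class] object.
#' @param path output file (.csv or .tsv).
#' @return invisibly, \code{path}.
#' @export
writeObservations <- function(obs, path) {
  stopifnot(is(obs, "CloneObservations"))
  rec <- obs@records
  out <- data.frame(cell = rec$cell, clone = rec$clone,
                    mutation = rec$mutation,
                    vaf = .fmtNum(rec$vaf), score = .fmtNum(rec$score))
  sep <- .tableSep(path, "auto")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
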