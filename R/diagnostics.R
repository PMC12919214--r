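#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF over whole post-burn-in chains. With m chains
#' of length n, W is the mean within-chain variance, B/n the variance of
#' the chain means, and the pooled variance estimate is
#' \eqn{\hat V = \frac{n-1}{n} W + B/n}; the statistic is
#' \eqn{\sqrt{\hat V / W}}. Values near 1 (conventionally below 1.1)
#' indicate the chains have mixed into a common distribution. A
#' split-chain variant (each chain halved, doubling m) is available.
#'
#' @param x a numeric matrix with one chain per column, or a list of
#'   equal-length numeric vectors.
#' @param split halve each chain before computing (split-Rhat).
#' @return the PSRF (scalar).
#' @export
psrf <- function(x, split = FALSE) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) stop("chains must have equal length")
    x <- do.call(cbind, x)
  }
  if (!is.matrix(x) || ncol(x) < 2)
    stop("PSRF needs at least 2 chains")
  if (split) {
    n2 <- nrow(x) %/% 2
    x <- cbind(x[seq_len(n2), , drop = FALSE],
               x[nrow(x) - n2 + seq_len(n2), , drop = FALSE])
  }
  n <- nrow(x)
  if (n < 2) stop("each chain needs at least 2 draws")
  W <- mean(apply(x, 2, var))
  Bn <- var(colMeans(x))          # B/n
  if (W == 0) return(if (Bn == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Autocorrelation-based effective sample size
#'
#' ESS = n / IACT with the integrated autocorrelation time estimated from
#' the empirical autocorrelations using Geyer's initial-monotone rule:
#' consecutive lag pairs \eqn{\Gamma_m = \rho_{2m} + \rho_{2m+1}} are
#' summed while positive, after enforcing that the sequence is
#' non-increasing. Negative autocorrelation (antithetic chains) can push
#' the ESS above n; that is reported as is.
#'
#' @param draws numeric vector of at least 10 draws.
#' @return the effective sample size (scalar).
#' @export
effectiveSampleSize <- function(draws) {
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws")
  if (var(draws) == 0) {
    warning("degenerate (constant) chain; reporting ESS = n")
    return(n)
  }
  rho <- drop(acf(draws, lag.max = n - 1, plot = FALSE,
                  demean = TRUE)$acf)
  nPairs <- length(rho) %/% 2
  gam <- rho[2 * seq_len(nPairs) - 1] + rho[2 * seq_len(nPairs)]
  pos <- which(gam <= 0)
  m <- if (length(pos) > 0) pos[1] - 1 else nPairs
  if (m == 0) {
    # immediate negative pair: keep only the (clipped) first pair
    tau <- max(2 * max(gam[1], 0) - 1, 1 / n)
  } else {
    gam <- cummin(gam[seq_len(m)])  # initial-monotone enforcement
    tau <- max(2 * sum(gam) - 1, 1 / n)
  }
  n / tau
}

#' Per-kernel Metropolis-Hastings acceptance rates
#'
#' @param samples a [PosteriorSamples-class] object.
#' @param perChain report each chain separately instead of pooling.
#' @return data.frame with columns \code{group}, \code{kernel}
#'   (and \code{chain} if \code{perChain}), \code{accepted},
#'   \code{proposed}, \code{rate}.
#' @export
acceptanceReport <- function(samples, perChain = FALSE) {
  stopifnot(is(samples, "PosteriorSamples"))
  acc <- samples@acceptance
  if (!perChain) {
    acc <- stats::aggregate(cbind(accepted, proposed) ~ group + kernel,
                            data = acc, FUN = sum)
  }
  acc$rate <- acc$accepted / acc$proposed
  acc
}

#' Convergence diagnostics table for a fit
#'
#' One row per model parameter with the across-chain PSRF (NA for a
#' single chain, with a warning) and the pooled effective sample size
#' (summed over chains). Suitable for writing to \code{diagnostics.csv}.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @return data.frame with columns \code{parameter}, \code{psrf},
#'   \code{ess}.
#' @export
diagnosticsTable <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  ch <- samples@chains
  pars <- colnames(ch[[1]])
  single <- length(ch) < 2
  if (single)
    warning("PSRF needs at least 2 chains; reporting NA")
  out <- data.frame(parameter = pars, psrf = NA_real_, ess = NA_real_)
  for (i in seq_along(pars)) {
    cols <- lapply(ch, function(m) m[, pars[i]])
    if (!single) {
      out$psrf[i] <- psrf(cols)
    }
    ess <- vapply(cols, function(x) {
      if (length(x) >= 10 && var(x) > 0) effectiveSampleSize(x)
      else length(x)
    }, numeric(1))
    out$ess[i] <- sum(ess)
  }
  out
}

#' Per-chain trace summaries
#'
#' Post-burn-in mean and least-squares linear trend slope (with its
#' p-value) of each parameter trace; a stationary, well-mixed chain shows
#' no significant trend.
#'
#' @param samples a [PosteriorSamples-class] object.
#' @return data.frame with columns \code{chain}, \code{parameter},
#'   \code{mean}, \code{slope}, \code{slope_p}.
#' @export
traceSummary <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  out <- list()
  for (ch in seq_along(samples@chains)) {
    m <- samples@chains[[ch]]
    it <- seq_len(nrow(m))
    for (p in colnames(m)) {
      x <- m[, p]
      if (var(x) > 0 && length(x) >= 3) {
        fit <- summary(lm(x ~ it))$coefficients
        slope <- fit[2, 1]; pval <- fit[2, 4]
      } else {
        slope <- 0; pval <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, parameter = p, mean = mean(x), slope = slope,
        slope_p = pval)
    }
  }
  do.call(rbind, out)
}
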