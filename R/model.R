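#' Mean of the Gaussian score component
#'
#' The continuous component of the score model is Normal with mean
#' \eqn{a v + b}: the selection slope \eqn{a} scales the mutation's variant
#' allele frequency \eqn{v}, the baseline \eqn{b} is the clone's score
#' offset at zero heteroplasmy.
#'
#' @param vaf variant allele frequency (vectorised), in \[0, 1\].
#' @param params a [GroupParams-class] object.
#' @return numeric vector \code{params@a * vaf + params@b}.
#' @export
mixtureMean <- function(vaf, params) {
  stopifnot(is(params, "GroupParams"))
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  params@a * vaf + params@b
}

#' Log-density of one observation under the zero-inflated Gaussian
#'
#' A score of exactly 0 falls on the point mass and contributes
#' \eqn{\log \pi}; any other score contributes
#' \eqn{\log(1-\pi) + \log N(score \mid a v + b, \sigma^2)}.
#'
#' @param score observed disease-relevance score (vectorised).
#' @inheritParams mixtureMean
#' @param sigma2 residual variance of the Gaussian component (> 0).
#' @return numeric vector of log-densities.
#' @export
logDensityOne <- function(score, vaf, params, sigma2) {
  stopifnot(is(params, "GroupParams"), sigma2 > 0)
  mu <- mixtureMean(vaf, params)
  ifelse(score == 0, log(params@pi),
         log1p(-params@pi) + dnorm(score, mu, sqrt(sigma2), log = TRUE))
}

#' Joint log-likelihood over all records
#'
#' Sums [logDensityOne()] over every record of the observation set, each
#' record evaluated under its own group's parameters and the shared
#' residual variance.
#'
#' @param obs a [CloneObservations-class] object.
#' @param params named list of [GroupParams-class], one entry per group
#'   appearing in \code{obs}.
#' @inheritParams logDensityOne
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(obs, params, sigma2) {
  stopifnot(is(obs, "CloneObservations"))
  grp <- groupNames(obs)
  miss <- setdiff(grp, names(params))
  if (length(miss) > 0)
    stop("missing group parameters for: ", paste(miss, collapse = ", "))
  rec <- obs@records
  total <- 0
  for (g in grp) {
    j <- rec$group == g
    total <- total +
      sum(logDensityOne(rec$score[j], rec$vaf[j], params[[g]], sigma2))
  }
  total
}

# Stats-level log-conditionals: O(1) given the group's sufficient
# statistics over nonzero-score records. These are what the sampler calls.
.logCondAStat <- function(a, Sv2, Svn, Sv, b, sigma2, alphaA, betaA) {
  out <- rep(-Inf, length(a))
  ok <- a > 0 & a < 1
  av <- a[ok]
  out[ok] <- -(av * av * Sv2 - 2 * av * (Svn - b * Sv)) / (2 * sigma2) +
    (alphaA - 1) * log(av) + (betaA - 1) * log1p(-av)
  out
}

.logCondBStat <- function(b, K1, Sn, Sv, a, sigma2, sigmaB2) {
  -(b * b * K1 - 2 * b * (Sn - a * Sv)) / (2 * sigma2) -
    b * b / (2 * sigmaB2)
}

#' Unnormalised log full-conditional of the selection slope
#'
#' Combines the Gaussian likelihood of the group's nonzero-score records
#' with the Beta(alphaA, betaA) prior:
#' \deqn{-\frac{1}{2\sigma^2}\left[a^2 \sum v^2 - 2a\sum v (n - b)\right]
#'   + (\alpha_a - 1)\log a + (\beta_a - 1)\log(1 - a)}
#' up to an additive constant. Zero-score records carry no Gaussian term
#' and are excluded from the sums. Values of \code{a} outside (0, 1)
#' return \code{-Inf} (log-density convention), including the boundaries
#' when the Beta prior is not flat.
#'
#' @param a slope value(s) at which to evaluate (vectorised).
#' @param vaf,score the group's records (all of them; the zero-score ones
#'   are filtered internally).
#' @param b current baseline.
#' @param sigma2 current residual variance.
#' @param prior a [PriorConfig-class] object.
#' @return numeric vector of unnormalised log-densities.
#' @export
logConditionalA <- function(a, vaf, score, b, sigma2, prior) {
  stopifnot(is(prior, "PriorConfig"), sigma2 > 0)
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  .logCondAStat(a, sum(v * v), sum(v * n), sum(v), b, sigma2,
                prior@alphaA, prior@betaA)
}

#' Unnormalised log full-conditional of the baseline
#'
#' Gaussian likelihood of the group's nonzero-score records (count
#' \eqn{K_1}) with the Normal(0, sigmaB2) prior:
#' \deqn{-\frac{1}{2\sigma^2}\left[b^2 K_1 - 2b\sum (n - a v)\right]
#'   - \frac{b^2}{2\sigma_b^2}}
#' up to an additive constant. This is an exactly Gaussian log-density in
#' \code{b}; the sampler nevertheless updates \code{b} by
#' Metropolis-Hastings, and the closed form serves as an internal check.
#'
#' @param b baseline value(s) at which to evaluate (vectorised).
#' @param a current slope.
#' @inheritParams logConditionalA
#' @return numeric vector of unnormalised log-densities.
#' @export
logConditionalB <- function(b, vaf, score, a, sigma2, prior) {
  stopifnot(is(prior, "PriorConfig"), sigma2 > 0)
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  .logCondBStat(b, sum(nz), sum(n), sum(v), a, sigma2, prior@sigmaB2)
}

#' Closed-form Gaussian parameters of the baseline conditional
#'
#' Completing the square in [logConditionalB()] gives a Normal
#' distribution with variance \eqn{(K_1/\sigma^2 + 1/\sigma_b^2)^{-1}} and
#' mean \eqn{variance \cdot \sum(n - a v)/\sigma^2}. Used as the
#' independent oracle for the MH kernel on \code{b}.
#'
#' @inheritParams logConditionalB
#' @return list with elements \code{mean} and \code{var}.
#' @export
conditionalBGaussian <- function(vaf, score, a, sigma2, prior) {
  nz <- score != 0
  v <- vaf[nz]; n <- score[nz]
  prec <- sum(nz) / sigma2 + 1 / prior@sigmaB2
  list(mean = sum(n - a * v) / sigma2 / prec, var = 1 / prec)
}
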