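# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Per-group sufficient statistics of an ObservationSet. All Gaussian-component
# sums run over nonzero-score records only: zero-score records carry no
# Gaussian term, so including them would inject spurious residuals.
.groupStats <- function(obs) {
  rec <- obs@records
  grp <- sort(unique(rec$group))
  out <- data.frame(group = grp, K = 0L, Z = 0L, K1 = 0L,
                    Sv = 0, Sv2 = 0, Svn = 0, Sn = 0, Sn2 = 0,
                    stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(rec)), factor(rec$group, levels = grp))
  for (i in seq_along(grp)) {
    j <- idx[[i]]
    v <- rec$vaf[j]; n <- rec$score[j]
    nz <- n != 0
    out$K[i] <- length(j)
    out$Z[i] <- sum(!nz)
    out$K1[i] <- sum(nz)
    v1 <- v[nz]; n1 <- n[nz]
    out$Sv[i] <- sum(v1);  out$Sv2[i] <- sum(v1 * v1)
    out$Svn[i] <- sum(v1 * n1)
    out$Sn[i] <- sum(n1);  out$Sn2[i] <- sum(n1 * n1)
  }
  out
}

.fmtNum <- function(x) sprintf("%.17g", x)

.stopValidation <- function(msg) {
  stop(structure(class = c("mitoSelectValidationError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
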