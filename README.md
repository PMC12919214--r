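# mitoSelect

Hierarchical Bayesian inference of clone-specific selection pressure from
single-cell mitochondrial heteroplasmy.

## What it is for

Single cells carry mixtures of mutant and wild-type mitochondrial
genomes; the fraction of mutant copies at a site is the variant allele
frequency (VAF), and cells sharing a set of mtDNA mutations form a
mitochondrial clone. Given (i) per-cell VAFs of mtDNA mutations, (ii) a
cell-to-clone assignment from upstream lineage analysis, and (iii) a
per-cell scalar disease-relevance score (e.g. an scDRS polygenic score),
mitoSelect estimates, per clone, how strongly heteroplasmy predicts the
disease score — a quantitative *selection coefficient* for that clone in
the diseased cell state. The intended users are single-cell genomics
analysts who already have variant calls, clone assignments and cell
scores, and want the inferential step between them.

## The model

Each observation couples a mutation's VAF $v$ with the cell's score $n$
under a zero-inflated Gaussian mixture with clone-level parameters:

$$
n \;\sim\;
\begin{cases}
\delta_0 & \text{with probability } \pi_c \\
\mathcal N\!\left(a_c\, v + b_c,\; \sigma^2\right) & \text{with probability } 1 - \pi_c
\end{cases}
$$

with priors $\pi_c \sim \mathrm{Beta}(\alpha,\beta)$,
$a_c \sim \mathrm{Beta}(\alpha_a,\beta_a)$ (slope confined to $(0,1)$),
$b_c \sim \mathcal N(0,\sigma_b^2)$,
$\sigma^2 \sim \mathrm{Inv\text{-}Gamma}(\kappa,\theta)$. Posterior
inference is MH-within-Gibbs: conjugate Beta draws for each $\pi_c$,
a conjugate Inverse-Gamma draw for the shared $\sigma^2$, and
Metropolis–Hastings kernels (burn-in-tuned random walks) for each
$a_c, b_c$. Multi-chain Gelman–Rubin PSRF and autocorrelation-based
effective sample sizes come built in, as does a synthetic-data generator
following the model's generative process and benchmark drivers for
recovery, prior-robustness and estimation-error experiments. See the
vignette `vignettes/clone-selection-inference.Rmd` for the full account.

## Worked example

Simulate two clones — weak (a = 0.2) and strong (a = 0.8) selection —
and fit:

```r
library(mitoSelect)

sim <- simulateDataset(simulationSpec(
  nCells = 60, clones = data.frame(pi = 0.3, a = c(0.2, 0.8), b = c(0.1, -0.1)),
  mutationsPerCell = 40, sigma = 0.1, seed = 1))
fit <- runMcmc(sim$observations,
               config = mcmcConfig(nIter = 1500, burnIn = 500,
                                   nChains = 2, seed = 1))
summarizePosterior(fit, sim$observations)
```

```
PosteriorSummary over 2 groups
    group parameter     mean   median        sd    ci_lo    ci_hi
   clone1        pi  0.31411  0.31378 0.0130019  0.28901  0.34011
   clone1         a  0.20459  0.20484 0.0117891  0.18107  0.22749
   clone1         b  0.09409  0.09456 0.0067945  0.08130  0.10664
   clone2        pi  0.30272  0.30246 0.0131954  0.27736  0.32807
   clone2         a  0.80861  0.80781 0.0120741  0.78574  0.83216
   clone2         b -0.09691 -0.09720 0.0070497 -0.11132 -0.08380
 (global)    sigma2  0.01132  0.01132 0.0003843  0.01057  0.01208
```

Each clone's `a` row is its selection coefficient: the posterior means
0.205 and 0.809 recover the generating values 0.2 and 0.8, with 95%
credible intervals of width ±0.02 covering them; `pi` recovers the 30%
zero-inflation and `sigma2` the 0.01 score noise variance. Convergence
is checked with `diagnosticsTable(fit)` (PSRF below 1.1 for every
parameter here) and `acceptanceReport(fit)`.

Real data enter either as a long-format table
(`readObservations("obs.csv")` with columns
`cell,clone,mutation,vaf,score`) or as a cell×mutation VAF matrix plus
cell→clone and cell→score tables via `assembleObservations()`.

A small CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/mitoselect.R", package="mitoSelect"))') \
  simulate --cells 100 --clones 3 --out sim_out --seed 1
# subcommands: simulate | fit | diagnose | benchmark
```

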