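---
title: "Model, priors, and sampling methods in jsdmgibbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, priors, and sampling methods in jsdmgibbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsdmgibbs)
```

# The model

`jsdmgibbs` fits hierarchical joint species distribution models by block-Gibbs
sampling.  For a community matrix $Y$ ($n_y$ sampling units by $n_s$ species),
covariates $X$ ($n_y \times n_c$) and optional species traits $T$
($n_s \times n_t$), the latent continuous response is

$$
Z = X B + \sum_r \Pi_r H_r \Lambda_r + \varepsilon,
\qquad \varepsilon_{ij} \sim N(0, \sigma_j^2),
$$

where each *random level* $r$ maps sampling units to level units through the
indicator matrix $\Pi_r$, with latent factor scores $H_r$
($n_{u,r} \times n_{f,r}$) and species loadings $\Lambda_r$
($n_{f,r} \times n_s$).  Presence-absence data use the probit link
$Y = \mathbf{1}(Z > 0)$ with $\sigma_j \equiv 1$; Gaussian data model $Z = Y$
on observed entries and sample $\sigma_j^2$.

Species coefficients share information through traits and, optionally, a
species correlation matrix $C$ (from a taxonomy or a phylogenetic tree):

$$
\operatorname{vec}(B) \sim N\!\big(\operatorname{vec}(\Gamma T'),\;
  [\rho C + (1 - \rho) I] \otimes V\big),
$$

with a matrix-normal prior on $\Gamma$, an inverse-Wishart prior on $V$, and a
discrete-grid prior on the phylogenetic weight $\rho$.  Loadings carry the
multiplicative-gamma shrinkage prior
$\lambda_{hj} \mid \psi_{hj}, \tau_h \sim N(0, \psi_{hj}^{-1}\tau_h^{-1})$
with $\tau_h = \prod_{l \le h} \delta_l$, which orders the factors by
decreasing importance and makes the factor count forgiving: extra factors are
shrunk towards zero rather than overfitting.

Spatial random levels place a Gaussian-process prior with exponential kernel
$k(d) = \exp(-d / \alpha)$ on each factor's score vector.  The range $\alpha$
has a discrete-grid prior spanning zero (no spatial structure) to roughly a
third of the domain extent, with half the prior mass on zero so the data must
earn the spatial structure.

# The Gibbs cycle

One cycle sweeps the exact full conditionals:

1. `update_z` — truncated-normal (probit) or imputation (normal) draws of $Z$
   by inverse CDF, with no rejection loops.
2. `update_beta_lambda` — joint Gaussian draw of $[B; \Lambda]$; the system
   factorizes per species unless $\rho > 0$ couples species through
   $Q = \rho C + (1-\rho) I$, in which case the full cross-species normal
   equation is solved densely.
3. `update_gamma_v` — conjugate matrix-normal draw of $\Gamma$ followed by an
   inverse-Wishart draw of $V$.
4. `update_rho` — enumeration of the grid conditional using the cached
   eigensystem of $C$, normalized by log-sum-exp, so each grid point costs
   $O(n_s)$ instead of a dense determinant.
5. `update_shrinkage` — gamma draws of $\psi$ and each $\delta_h$ in sequence.
6. `update_eta` — non-spatial levels draw all factors of a level unit jointly;
   spatial levels draw each factor's score vector across units from the GP
   conditional (see below).
7. `update_alpha` — per-factor enumeration of the range grid using the
   precomputed spatial structures.
8. `update_sigma` — conjugate gamma precision draws (normal response only).

# Spatial structures

Three interchangeable representations support the GP conditional draw and the
log-density evaluation needed by the range update:

* **Full GP** (`gp`): dense covariance with a cached Cholesky factor; exact but
  $O(n_u^3)$ once per structure and $O(n_u^2)$ per draw.
* **Predictive process** (`pgp`): a low-rank-plus-diagonal approximation
  $\tilde K = U U' + \operatorname{diag}(d)$ built from $m$ knots (by default a
  hexagonal grid over the bounding box), with
  $d = \max(1 - \operatorname{rowSums}(U^2), 0)$ restoring unit marginal
  variances.  Conditional draws cost $O(n_u m^2)$ via the Woodbury identity.
* **Nearest-neighbour GP** (`nngp`): the Vecchia factorization in a fixed
  lexicographic coordinate order; the sparse precision
  $(I - A)' D^{-1} (I - A)$ is factored once per structure with a fill-reducing
  permutation, making draws and log-densities near-linear in $n_u$.

Both approximations recover the full GP exactly in their limits (knots = sites;
neighbours = all previous points), which the test suite verifies numerically.

## Numerical policies

* **Jitter once, then fail.**  If a spatial covariance or conditional precision
  is not positive definite, a single jitter of `1e-8` on the diagonal is
  attempted; a second failure raises an error naming the offending block.
  Silent repeated inflation would change the model being fit.
* **Predictive-process diagonal floor.**  The residual variances $d$ are
  floored at `1e-10` before inversion.  The floor matters in the knots = sites
  limit where $d \to 0$; `1e-10` keeps the implied covariance within
  $10^{-8}$ (Frobenius) of the dense kernel, whereas a smaller floor amplifies
  round-off in the Woodbury solve and a larger one biases the approximation.
* **Per-factor spatial draws.**  Spatial factors are updated one at a time
  against the residual of the other factors, so the spatial solve never grows
  with the factor count; non-spatial levels batch units with equal replication
  counts to share Cholesky factors.
* **Log-sum-exp everywhere.**  Both discrete grid updates ($\rho$, $\alpha$)
  normalize in log space, so weights are exact up to floating-point rounding
  even when the grid spans hundreds of log-likelihood units.

# Reproducibility

Every Gibbs block draws its random numbers from a dedicated stream seeded by a
counter-based hash of (run seed, chain index, cycle, block).  Consequently:

* chains are independent of execution order — running four chains in parallel
  or sequentially yields bit-identical posterior containers;
* a checkpointed chain resumed from the serialized state continues exactly the
  uninterrupted trajectory;
* posterior containers are pure functions of (model, configuration, chain
  index).  Wall-clock timings are therefore written to a separate CSV log
  (`write_timings_csv`, `cli_fit --timings`), never into the container.

Model and posterior containers are versioned JSON documents; numbers are
serialized with 17 significant digits, which round-trips IEEE doubles exactly.

# Synthetic data

`generate_dataset` draws every parameter from the model prior (with optional
pinned overrides), then simulates $Y$ forward.  Sampling parameters from the
prior rather than fixing ad-hoc values makes the generator usable in
simulator-consistency checks, where the distribution of generated data must
match the model exactly.  `subsample_grid` produces nested subsets of sites
and species so benchmark timings across sizes measure scaling rather than
dataset idiosyncrasies; `filter_rare_species` applies a strict
occurrence-count threshold.

# Benchmarking

`run_benchmark` times single Gibbs cycles over a grid of community sizes for
five variants (non-spatial, full GP, predictive process, NNGP, and
phylogenetic).  Two measurement policies keep the numbers meaningful:

* cycles are timed in consecutive batches after a warm-up, and the *fastest*
  batch rate is reported — scheduler and garbage-collector noise only ever
  adds time, so the batch minimum estimates the intrinsic cost;
* the harness grid of spatial ranges excludes zero, because a factor sitting
  at $\alpha = 0$ takes a trivial identity code path and the cycle cost would
  otherwise depend on the sampled ranges instead of on the variant.

# Diagnostics

`potential_scale_reduction` computes split-$\widehat R$ (each chain halved, so
within-chain drift registers as between-chain variance).
`effective_sample_size` uses the initial-positive-sequence estimator on paired
autocorrelations.  `trace_summary` tabulates both over a parameter selection
and can write trace plots.  Degenerate inputs (constant chains, a single
chain) are flagged rather than silently returning optimistic values.

# Limitations

* The probit link is the only non-Gaussian observation model.
* The spatial kernel is exponential; other Matérn smoothnesses are not
  implemented.
* The dense full-GP path is memory-bound near a few thousand level units; use
  `pgp` or `nngp` beyond that.
* The cross-species joint update under $\rho > 0$ solves a dense
  $n_s(n_c + n_f)$ system and is intended for communities up to a few hundred
  species.

# A worked example

```{r example, eval = FALSE}
ds <- generate_dataset(n_y = 200, n_s = 20, n_c = 3, n_t = 2,
                       level_spec = list(spatial_method = "nngp",
                                         n_factors = 2, alpha = 0.2,
                                         n_neighbours = 10),
                       response = "probit", seed = 1, use_taxonomy = TRUE)
model <- build_model(ds$data$Y, ds$data$X, ds$data$Tr, ds$data$C,
                     list(ds$level), response = "probit")
cfg <- mcmc_config(samples = 250, thin = 4, transient = 1000, n_chains = 4,
                   seed = 7)
chains <- run_chains_parallel(model, cfg, cores = 2)
trace_summary(chains, c("Beta", "rho"))
```
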