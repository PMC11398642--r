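# Chain orchestration: initialization, the full Gibbs cycle, multi-chain runs
# with transient/thinning, per-cycle timing, and checkpoint/resume.

# Fixed block ids for counter-based seeding (see utils-rng.R).
.BLOCK_INIT <- 0L
.BLOCK_Z <- 1L
.BLOCK_BETA_LAMBDA <- 2L
.BLOCK_GAMMA_V <- 3L
.BLOCK_RHO <- 4L
.BLOCK_SIGMA <- 9L
.block_level <- function(r, what) 10L * r + switch(what, shrink = 5L, eta = 6L, alpha = 7L)

#' MCMC configuration
#'
#' @param samples retained samples per chain.
#' @param thin retain every \code{thin}-th cycle after the transient.
#' @param transient discarded initial cycles (burn-in).
#' @param n_chains number of chains.
#' @param seed integer run seed; every chain derives its own streams from it.
#' @param verbose_every print progress every this many cycles (0 = silent).
#' @param retain_eta keep factor-score samples in the posterior (memory grows
#'   with \code{n_u}).
#' @return an object of class \code{jsdm_mcmc_config}.
#' @export
mcmc_config <- function(samples, thin = 1L, transient = 0L, n_chains = 1L,
                        seed = 1L, verbose_every = 0L, retain_eta = TRUE) {
  stopifnot(samples >= 1, thin >= 1, transient >= 0, n_chains >= 1,
            verbose_every >= 0)
  structure(list(samples = as.integer(samples), thin = as.integer(thin),
                 transient = as.integer(transient), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), verbose_every = as.integer(verbose_every),
                 retain_eta = isTRUE(retain_eta)),
            class = "jsdm_mcmc_config")
}

#' Total Gibbs cycles per chain implied by a configuration
#'
#' \code{transient + samples * thin}.
#'
#' @param config a \code{jsdm_mcmc_config}.
#' @return integer cycle count.
#' @export
total_cycles <- function(config) config$transient + config$samples * config$thin

#' Initialize one chain
#'
#' Deterministic given \code{(seed, chain_index)}: Beta = 0, Gamma = 0,
#' V = V0, rho at the grid point nearest 0, Lambda drawn from its shrinkage
#' prior, Eta = 0, Delta at its prior mean, Psi = 1, alpha at the index of 0,
#' sigma fixed at 1 (probit) or at its prior mean (normal), and Z drawn
#' sign-consistently with Y.
#'
#' @param model a validated \code{jsdm_model}.
#' @param seed integer run seed.
#' @param chain_index zero-based chain index.
#' @return an object of class \code{jsdm_state}.
#' @export
init_chain <- function(model, seed, chain_index = 0L) {
  rep <- validate_model(model)
  if (length(rep)) stop("invalid model:\n  - ", paste(rep, collapse = "\n  - "))
  pr <- model$priors
  set.seed(block_seed(seed, chain_index, 0L, .BLOCK_INIT))
  n_c <- model$n_c; n_s <- model$n_s; n_t <- model$n_t
  rho_idx <- which.min(abs(pr$rho_grid$values))
  levels <- lapply(seq_along(model$levels), function(r) {
    lev <- model$levels[[r]]
    n_f <- lev$n_factors
    sh <- pr$shrinkage
    Delta <- c(sh$a1 / sh$b1, rep(sh$a2 / sh$b2, n_f - 1))[seq_len(n_f)]
    Psi <- matrix(1, n_f, n_s)
    tau <- cumprod(Delta)
    Lambda <- matrix(stats::rnorm(n_f * n_s), n_f, n_s) / sqrt(Psi * tau)
    ag <- pr$alpha_grid[[r]]
    a0 <- if (is.null(ag)) 1L else which.min(abs(ag$values))
    list(Eta = matrix(0, lev$n_units, n_f), Lambda = Lambda, Psi = Psi,
         Delta = Delta, alpha_idx = rep(a0, n_f))
  })
  sigma2 <- if (model$response == "probit") rep(1, n_s)
            else rep(pr$sigma_prior$bSigma / pr$sigma_prior$aSigma, n_s)
  u <- matrix(stats::runif(model$n_y * n_s), model$n_y, n_s)
  L0 <- matrix(0, model$n_y, n_s)
  Z <- .draw_z(L0, model$Y, sigma2, model$response, u)
  structure(list(
    Beta = matrix(0, n_c, n_s), Gamma = matrix(0, n_c, n_t), V = pr$V0,
    rho_idx = rho_idx, rho = pr$rho_grid$values[rho_idx],
    levels = levels, sigma2 = sigma2, Z = Z,
    cycle = 0L, chain_index = as.integer(chain_index), seed = as.integer(seed)
  ), class = "jsdm_state")
}

#' One full Gibbs cycle
#'
#' Advances the state by one sweep over the blocks in fixed order:
#' Z, (Beta, Lambda), (Gamma, V), rho, then per level shrinkage, Eta, alpha,
#' and finally sigma.  Each block reseeds the RNG from
#' (seed, chain, cycle, block), so cycles are exactly reproducible and
#' independent of scheduling.  One call is the unit of the per-cycle
#' benchmark.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the advanced state (cycle counter incremented).
#' @export
gibbs_cycle <- function(state, model, runtime = NULL) {
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  state$cycle <- state$cycle + 1L
  step <- function(st, block, fun, name) {
    .seed_block(st, block)
    tryCatch(fun(st), error = function(e)
      stop(sprintf("Gibbs block '%s' failed at cycle %d: %s",
                   name, st$cycle, conditionMessage(e)), call. = FALSE))
  }
  state <- step(state, .BLOCK_Z, function(s) update_z(s, model, runtime), "z")
  state <- step(state, .BLOCK_BETA_LAMBDA,
                function(s) update_beta_lambda(s, model, runtime), "beta_lambda")
  state <- step(state, .BLOCK_GAMMA_V,
                function(s) update_gamma_v(s, model, runtime), "gamma_v")
  state <- step(state, .BLOCK_RHO, function(s) update_rho(s, model, runtime), "rho")
  for (r in seq_along(model$levels)) {
    state <- step(state, .block_level(r, "shrink"),
                  function(s) update_shrinkage(s, model, r), "shrinkage")
    state <- step(state, .block_level(r, "eta"),
                  function(s) update_eta(s, model, r, runtime), "eta")
    state <- step(state, .block_level(r, "alpha"),
                  function(s) update_alpha(s, model, r, runtime), "alpha")
  }
  state <- step(state, .BLOCK_SIGMA, function(s) update_sigma(s, model, runtime), "sigma")
  state
}

.alloc_chain_arrays <- function(model, config) {
  n <- config$samples
  arr <- list(
    Beta = array(NA_real_, c(n, model$n_c, model$n_s)),
    Gamma = array(NA_real_, c(n, model$n_c, model$n_t)),
    V = array(NA_real_, c(n, model$n_c, model$n_c)),
    rho = rep(NA_real_, n),
    sigma2 = array(NA_real_, c(n, model$n_s)))
  arr$levels <- lapply(model$levels, function(lev) {
    l <- list(
      Lambda = array(NA_real_, c(n, lev$n_factors, model$n_s)),
      Delta = array(NA_real_, c(n, lev$n_factors)),
      Psi = array(NA_real_, c(n, lev$n_factors, model$n_s)),
      alpha = array(NA_real_, c(n, lev$n_factors)))
    if (config$retain_eta)
      l$Eta <- array(NA_real_, c(n, lev$n_units, lev$n_factors))
    l
  })
  arr
}

.snapshot <- function(arr, state, model, s, config) {
  arr$Beta[s, , ] <- state$Beta
  arr$Gamma[s, , ] <- state$Gamma
  arr$V[s, , ] <- state$V
  arr$rho[s] <- state$rho
  arr$sigma2[s, ] <- state$sigma2
  for (r in seq_along(state$levels)) {
    sl <- state$levels[[r]]
    arr$levels[[r]]$Lambda[s, , ] <- sl$Lambda
    arr$levels[[r]]$Delta[s, ] <- sl$Delta
    arr$levels[[r]]$Psi[s, , ] <- sl$Psi
    ag <- model$priors$alpha_grid[[r]]
    arr$levels[[r]]$alpha[s, ] <-
      if (is.null(ag)) 0 else ag$values[sl$alpha_idx]
    if (config$retain_eta) arr$levels[[r]]$Eta[s, , ] <- sl$Eta
  }
  arr
}

#' Run one MCMC chain
#'
#' Executes \code{transient + samples * thin} Gibbs cycles seeded
#' deterministically from \code{(config$seed, chain_index)}, retaining every
#' \code{thin}-th state after the transient and recording per-cycle wall
#' time.  With \code{dry_run = TRUE} only the cycle bookkeeping is returned.
#' Passing a previous (partial) chain as \code{checkpoint} resumes it; the
#' counter-based seeding makes an interrupted-and-resumed run identical to an
#' uninterrupted one.
#'
#' @param model a validated \code{jsdm_model}.
#' @param config a \code{jsdm_mcmc_config}.
#' @param chain_index zero-based chain index (must be < \code{n_chains}).
#' @param runtime optional precomputed runtime cache.
#' @param dry_run if TRUE, return the scheduled cycle accounting only.
#' @param checkpoint a partial \code{jsdm_chain} to resume.
#' @param stop_after execute at most this many cycles in this call (for
#'   checkpointing), then return the partial chain.
#' @return an object of class \code{jsdm_chain}.
#' @export
run_chain <- function(model, config, chain_index = 0L, runtime = NULL,
                      dry_run = FALSE, checkpoint = NULL, stop_after = NULL) {
  if (chain_index < 0 || chain_index >= config$n_chains)
    stop("chain_index must be in [0, n_chains)")
  n_cycles <- total_cycles(config)
  if (dry_run) {
    return(structure(list(cycles_scheduled = n_cycles,
                          transient = config$transient, thin = config$thin,
                          samples = config$samples, chain_index = chain_index),
                     class = "jsdm_dryrun"))
  }
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  if (is.null(checkpoint)) {
    state <- init_chain(model, config$seed, chain_index)
    arr <- .alloc_chain_arrays(model, config)
    done <- 0L
    timings <- numeric(0)
  } else {
    stopifnot(inherits(checkpoint, "jsdm_chain"),
              checkpoint$chain_index == chain_index)
    state <- checkpoint$state
    arr <- checkpoint$draws
    done <- checkpoint$cycles_done
    timings <- checkpoint$timings
  }
  last <- if (is.null(stop_after)) n_cycles
          else as.integer(min(n_cycles, done + stop_after))
  new_t <- numeric(max(0, last - done))
  ti <- 0L
  for (cyc in seq_len(last - done) + done) {
    t0 <- proc.time()[["elapsed"]]
    state <- gibbs_cycle(state, model, runtime)
    ti <- ti + 1L
    new_t[ti] <- proc.time()[["elapsed"]] - t0
    if (cyc > config$transient && (cyc - config$transient) %% config$thin == 0) {
      s <- (cyc - config$transient) %/% config$thin
      arr <- .snapshot(arr, state, model, s, config)
    }
    if (config$verbose_every > 0 && cyc %% config$verbose_every == 0)
      message(sprintf("chain %d: cycle %d / %d", chain_index, cyc, n_cycles))
  }
  structure(list(
    chain_index = as.integer(chain_index), config = config,
    draws = arr, n_retained = max(0L, min((last - config$transient) %/% config$thin,
                                          config$samples)),
    cycles_done = last, cycles_scheduled = n_cycles,
    complete = (last == n_cycles),
    state = state, timings = c(timings, new_t)
  ), class = "jsdm_chain")
}

#' Run all chains of a configuration
#'
#' Chains are statistically and computationally independent; with
#' \code{cores > 1} they are executed with \code{parallel::mclapply}.  The
#' counter-based seeding guarantees bit-identical results regardless of
#' scheduling, so parallel and sequential execution agree exactly.
#'
#' @param model a validated \code{jsdm_model}.
#' @param config a \code{jsdm_mcmc_config}.
#' @param cores worker processes (1 = sequential).
#' @param runtime optional precomputed runtime cache.
#' @return list of \code{jsdm_chain}, ordered by chain index.
#' @export
run_chains_parallel <- function(model, config, cores = 1L, runtime = NULL) {
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  idx <- seq_len(config$n_chains) - 1L
  runner <- function(i) tryCatch(run_chain(model, config, i, runtime),
                                 error = function(e) e)
  res <- if (cores > 1 && .Platform$OS.type == "unix")
    parallel::mclapply(idx, runner, mc.cores = cores)
  else lapply(idx, runner)
  failed <- vapply(res, inherits, logical(1), what = "error")
  if (any(failed))
    stop("chain(s) failed:\n", paste(sprintf("  chain %d: %s", idx[failed],
         vapply(res[failed], conditionMessage, character(1))), collapse = "\n"))
  res
}
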