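# Per-cycle timing harness.
#
# Measures the wall time of single Gibbs cycles for the five benchmarked model
# variants (non-spatial; full-GP, predictive-process and nearest-neighbour
# spatial latent factors; non-spatial with a taxonomy-derived species
# correlation) over a grid of community sizes.  The first cycles are excluded
# as warm-up; the rest are timed in consecutive batches (the wall clock has
# millisecond resolution, coarser than a single small-model cycle) and the
# fastest per-cycle rate across batches is reported: scheduler and GC noise
# only ever adds time, so the batch minimum estimates the intrinsic cost.

.benchmark_variants <- c("nonspatial", "gp", "pgp", "nngp", "phylo")

.variant_model <- function(variant, sub, n_factors = 10L, alpha_grid_n = 20L) {
  spatial <- switch(variant, gp = "gp", pgp = "pgp", nngp = "nngp", "none")
  lev0 <- sub$level
  lev <- random_level(sub$design$level_unit, spatial,
                      coords = lev0$coords,
                      n_knots = lev0$n_knots,
                      n_neighbours = min(lev0$n_neighbours, lev0$n_units - 1L),
                      n_factors = n_factors, name = lev0$name)
  C <- if (variant == "phylo") sub$data$C else NULL
  priors <- default_priors(ncol(sub$data$X), ncol(sub$data$Tr),
                           lev$n_units, list(lev$coords),
                           alpha_grid_n = alpha_grid_n)
  if (spatial != "none") {
    # Exclude the zero range from the harness grid: a factor sitting at
    # alpha = 0 takes the trivial identity code path, so the per-cycle cost
    # would otherwise depend on the sampled ranges instead of the variant.
    ag <- priors$alpha_grid[[1]]
    pos <- ag$values[ag$values > 0]
    priors$alpha_grid[[1]] <- list(values = pos,
                                   weights = rep(1 / length(pos), length(pos)))
  }
  build_model(sub$data$Y, sub$data$X, sub$data$Tr, C, list(lev),
              response = "probit", priors = priors)
}

#' Time single Gibbs cycles for one model variant and size
#'
#' @param variant one of "nonspatial", "gp", "pgp", "nngp", "phylo".
#' @param sub a sub-dataset from \code{\link{subsample_grid}} (with taxonomy
#'   when \code{variant = "phylo"}).
#' @param cycles Gibbs cycles to execute (> warm-up).
#' @param seed chain seed.
#' @param n_factors latent factors (default 10).
#' @param warmup leading cycles excluded from the timing.
#' @param alpha_grid_n spatial-range grid size used by the harness.
#' @param max_gp_units full-GP models above this unit count are recorded as
#'   infeasible (dense covariance memory).
#' @return one-row data frame: variant, n_s, n_y, seconds_per_cycle, cycles,
#'   feasible.
#' @export
benchmark_cycles <- function(variant, sub, cycles = 10L, seed = 1L,
                             n_factors = 10L, warmup = 5L,
                             alpha_grid_n = 20L, max_gp_units = 4000L) {
  variant <- match.arg(variant, .benchmark_variants)
  if (cycles < 1) stop("cycles must be >= 1")
  n_y <- nrow(sub$data$Y); n_s <- ncol(sub$data$Y)
  row <- data.frame(variant = variant, n_s = n_s, n_y = n_y,
                    seconds_per_cycle = NA_real_, cycles = as.integer(cycles),
                    feasible = TRUE, stringsAsFactors = FALSE)
  if (variant == "gp" && n_y > max_gp_units) {
    row$feasible <- FALSE
    return(row)
  }
  model <- .variant_model(variant, sub, n_factors, alpha_grid_n)
  runtime <- prepare_runtime(model)
  state <- init_chain(model, seed, 0L)
  if (cycles > warmup) {
    for (i in seq_len(warmup)) state <- gibbs_cycle(state, model, runtime)
    n <- cycles - warmup
  } else {
    n <- cycles
  }
  n_batches <- max(1L, n %/% 5L)
  sizes <- diff(round(seq(0, n, length.out = n_batches + 1)))
  rates <- numeric(n_batches)
  for (k in seq_len(n_batches)) {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(sizes[k])) state <- gibbs_cycle(state, model, runtime)
    rates[k] <- (proc.time()[["elapsed"]] - t0) / sizes[k]
  }
  row$seconds_per_cycle <- min(rates)
  row
}

#' Run the per-cycle benchmark grid
#'
#' Generates one synthetic community at the largest requested size (with
#' taxonomy and binary traits), builds the nested sub-dataset grid, and times
#' every (variant, n_s, n_y) combination.
#'
#' @param variants subset of the five variants.
#' @param n_s_list,n_y_list grid of community sizes.
#' @param cycles Gibbs cycles per combination.
#' @param seed generator/chain seed.
#' @param n_c,n_t covariate and trait counts of the synthetic community.
#' @param ... passed to \code{\link{benchmark_cycles}}.
#' @return data frame of timing rows.
#' @export
run_benchmark <- function(variants = .benchmark_variants,
                          n_s_list = c(40L), n_y_list = c(100L, 200L, 400L),
                          cycles = 10L, seed = 1L, n_c = 4L, n_t = 3L, ...) {
  variants <- match.arg(variants, .benchmark_variants, several.ok = TRUE)
  master <- generate_dataset(max(n_y_list), max(n_s_list), n_c = n_c, n_t = n_t,
                             level_spec = list(spatial_method = "gp", alpha = 0.2,
                                               n_factors = 10L),
                             response = "probit", seed = seed,
                             use_taxonomy = TRUE)
  subs <- subsample_grid(master, n_s_list, n_y_list, seed = seed)
  out <- list()
  for (v in variants) for (sub in subs) {
    out[[length(out) + 1]] <- benchmark_cycles(v, sub, cycles = cycles,
                                               seed = seed, ...)
  }
  do.call(rbind, out)
}
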