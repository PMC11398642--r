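# Synthetic community generator.
#
# Emulates the structure of a large presence-absence plant survey (hundreds of
# species at thousands of georeferenced sites with binary traits and a
# taxonomy-derived species correlation) with the exact statistical structure
# the model assumes, so every component is testable without any download.
# Every dataset carries a TruthRecord of its generating parameters.

.default_level_spec <- function() {
  list(name = "site", spatial_method = "none", n_factors = 10L,
       alpha = 0.2, n_neighbours = 10L, n_knots = 55L)
}

#' Generate a synthetic community dataset
#'
#' Draws site coordinates uniformly on a rectangle, covariates and binary
#' traits (fair coin, plus intercepts), a 3-rank random taxonomy and its
#' correlation matrix C, trait effects Gamma, coefficients
#' \code{Beta ~ MN(Gamma t(Tr), V, rho C + (1 - rho) I)}, factor scores Eta from
#' the requested spatial structure, loadings Lambda from the
#' multiplicative-gamma shrinkage prior, and responses through the probit or
#' normal link - all from a single seed.
#'
#' Generator defaults (chosen as a realistic community: moderate prevalence,
#' decaying factor relevance, intermediate phylogenetic signal): Gamma entries
#' N(0, 0.5^2), V = 0.25 I, rho = 0.5 when a correlation is used, shrinkage
#' (2, 1, 3, 1), residual sd 0.5 for normal responses.  All can be pinned via
#' \code{truth_overrides}.
#'
#' @param n_y sampling units (sites).
#' @param n_s species.
#' @param n_c covariates including intercept.
#' @param n_t traits including intercept.
#' @param level_spec list describing the single random level: \code{name},
#'   \code{spatial_method} ("none"/"gp"/"pgp"/"nngp"), \code{n_factors},
#'   \code{alpha} (true spatial range), \code{n_neighbours}, \code{n_knots};
#'   \code{NULL} for no random level.
#' @param response "probit" or "normal".
#' @param seed integer seed; same seed, same dataset, bit for bit.
#' @param use_taxonomy generate a taxonomy and species correlation.
#' @param truth_overrides named list pinning any of Gamma, V, rho, Beta,
#'   Lambda, Eta, alpha, sigma2.
#' @return list with \code{data} (Y, X, Tr, C, taxonomy), \code{design}
#'   (unit, level unit, x, y), \code{level} (a \code{jsdm_level} or NULL) and
#'   \code{truth} (class \code{jsdm_truth}).
#' @export
generate_dataset <- function(n_y, n_s, n_c = 3L, n_t = 2L,
                             level_spec = .default_level_spec(),
                             response = c("probit", "normal"), seed = 1L,
                             use_taxonomy = FALSE, truth_overrides = list()) {
  response <- match.arg(response)
  stopifnot(n_y >= 1, n_s >= 1, n_c >= 1, n_t >= 1)
  ov <- truth_overrides
  set.seed(block_seed(seed, 0L, 0L, 101L))
  unit_names <- sprintf("site_%05d", seq_len(n_y))
  species <- sprintf("sp_%04d", seq_len(n_s))
  coords <- cbind(x = stats::runif(n_y), y = stats::runif(n_y))
  rownames(coords) <- unit_names
  X <- cbind(1, matrix(stats::rnorm(n_y * (n_c - 1)), n_y, n_c - 1))
  dimnames(X) <- list(unit_names,
                      c("intercept", if (n_c > 1) paste0("env_", seq_len(n_c - 1))))
  Tr <- cbind(1, matrix(stats::rbinom(n_s * (n_t - 1), 1, 0.5), n_s, n_t - 1))
  dimnames(Tr) <- list(species,
                       c("intercept", if (n_t > 1) paste0("trait_", seq_len(n_t - 1))))
  taxonomy <- NULL; C <- NULL
  if (use_taxonomy) {
    n_fam <- max(2L, ceiling(n_s / 16))
    n_gen <- max(n_fam + 1L, ceiling(n_s / 4))
    fam_of_gen <- sample(n_fam, n_gen, replace = TRUE)
    gen <- sample(n_gen, n_s, replace = TRUE)
    taxonomy <- data.frame(family = sprintf("fam_%03d", fam_of_gen[gen]),
                           genus = sprintf("gen_%03d", gen),
                           species = species, stringsAsFactors = FALSE)
    C <- taxonomy_to_correlation(taxonomy)
  }
  rho <- ov$rho %||% if (use_taxonomy) 0.5 else 0
  V <- ov$V %||% diag(0.25, n_c)
  Gamma <- ov$Gamma %||% matrix(stats::rnorm(n_c * n_t, 0, 0.5), n_c, n_t)
  # Beta ~ MN(Gamma Tr', V (covariates), Q (species))
  Beta <- ov$Beta %||% {
    Q <- if (is.null(C) || rho == 0) diag(n_s) else rho * C + (1 - rho) * diag(n_s)
    Rq <- chol(Q); Rv <- chol(V)
    Gamma %*% t(Tr) + t(Rv) %*% matrix(stats::rnorm(n_c * n_s), n_c, n_s) %*% Rq
  }
  lin <- X %*% Beta
  level <- NULL; Eta <- NULL; Lambda <- NULL; alpha_true <- NULL
  if (!is.null(level_spec)) {
    ls <- utils::modifyList(.default_level_spec(), level_spec)
    n_f <- as.integer(ls$n_factors)
    level <- random_level(unit_names, ls$spatial_method, coords = coords,
                          n_knots = ls$n_knots, n_neighbours = ls$n_neighbours,
                          n_factors = n_f, name = ls$name)
    alpha_true <- ov$alpha %||% if (ls$spatial_method == "none") 0 else ls$alpha
    sh <- ov$shrinkage %||% list(a1 = 2, b1 = 1, a2 = 3, b2 = 1)
    Lambda <- ov$Lambda %||% {
      Delta <- c(stats::rgamma(1, sh$a1, sh$b1),
                 stats::rgamma(n_f - 1, sh$a2, sh$b2))[seq_len(n_f)]
      tau <- cumprod(Delta)
      matrix(stats::rnorm(n_f * n_s), n_f, n_s) / sqrt(rep(tau, n_s))
    }
    Eta <- ov$Eta %||% {
      st <- build_spatial_structure(level, alpha_true)
      sapply(seq_len(nrow(Lambda)), function(h) .draw_gp_prior(st))
    }
    lin <- lin + Eta[level$assignment, , drop = FALSE] %*% Lambda
  }
  sigma2 <- ov$sigma2 %||% rep(if (response == "probit") 1 else 0.25, n_s)
  eps <- matrix(stats::rnorm(n_y * n_s), n_y, n_s) %*% diag(sqrt(sigma2), n_s)
  Zt <- lin + eps
  Y <- if (response == "probit") (Zt > 0) + 0 else Zt
  dimnames(Y) <- list(unit_names, species)
  truth <- structure(list(Beta = Beta, Gamma = Gamma, V = V, rho = rho,
                          Lambda = Lambda, Eta = Eta, alpha = alpha_true,
                          sigma2 = sigma2, seed = as.integer(seed),
                          response = response), class = "jsdm_truth")
  list(data = list(Y = Y, X = X, Tr = Tr, C = C, taxonomy = taxonomy),
       design = data.frame(unit = unit_names, level_unit = unit_names,
                           x = coords[, 1], y = coords[, 2],
                           stringsAsFactors = FALSE),
       level = level, truth = truth)
}

# one zero-mean draw from the structure's implied covariance
.draw_gp_prior <- function(st) {
  n <- st$n
  if (st$identity) return(stats::rnorm(n))
  switch(st$method,
    gp = as.numeric(st$L %*% stats::rnorm(n)),
    pgp = as.numeric(st$U %*% stats::rnorm(ncol(st$U)) + sqrt(st$d) * stats::rnorm(n)),
    nngp = {
      z <- stats::rnorm(n) * sqrt(st$d)
      # solve (I - A) x = z by forward substitution on the sparse triangle
      x <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - st$A, z))
      x[order(st$order)]
    })
}

#' Drop rare species
#'
#' Removes species columns with fewer than \code{min_occurrences} nonzero
#' (present) entries; the inequality is strict, so a species with exactly
#' \code{min_occurrences} occurrences is kept.
#'
#' @param Y community matrix (binary or counts; NA ignored).
#' @param min_occurrences occurrence threshold.
#' @return list with \code{Y} (filtered) and \code{kept} (original column
#'   indices, in order).
#' @export
filter_rare_species <- function(Y, min_occurrences) {
  stopifnot(min_occurrences >= 0)
  occ <- colSums(Y != 0, na.rm = TRUE)
  kept <- which(occ >= min_occurrences)
  if (!length(kept)) stop("all species fall below the occurrence threshold")
  list(Y = Y[, kept, drop = FALSE], kept = kept)
}

#' Nested sub-dataset grid
#'
#' Builds the benchmark grid of sub-datasets over requested species and site
#' counts.  Subsampling is nested: each smaller site (species) set is a subset
#' of each larger one.  Sites are drawn uniformly without replacement; species
#' are prevalence-stratified (quintile bins, round-robin) so small subsets are
#' not dominated by rare species.
#'
#' @param dataset output of \code{\link{generate_dataset}} (or a compatible
#'   list with \code{data$Y} etc.).
#' @param n_s_list species counts.
#' @param n_y_list site counts.
#' @param seed subsampling seed.
#' @return list of sub-datasets, one per (n_s, n_y) combination (species
#'   varying fastest), each with the same layout as the input plus
#'   \code{$sub} recording the sizes and kept indices.
#' @export
subsample_grid <- function(dataset, n_s_list, n_y_list, seed = 1L) {
  Y <- dataset$data$Y
  n_y <- nrow(Y); n_s <- ncol(Y)
  if (max(n_y_list) > n_y) stop("requested more sites than available")
  if (max(n_s_list) > n_s) stop("requested more species than available")
  set.seed(block_seed(seed, 0L, 0L, 202L))
  site_order <- sample.int(n_y)
  # prevalence-stratified species ordering: quintile bins, round-robin
  prev <- colMeans(Y != 0, na.rm = TRUE)
  bins <- cut(rank(prev, ties.method = "first"), breaks = 5, labels = FALSE)
  by_bin <- lapply(split(seq_len(n_s), bins), sample)
  sp_order <- integer(0)
  while (any(lengths(by_bin) > 0)) {
    for (b in seq_along(by_bin)) {
      if (length(by_bin[[b]])) {
        sp_order <- c(sp_order, by_bin[[b]][1])
        by_bin[[b]] <- by_bin[[b]][-1]
      }
    }
  }
  out <- list()
  for (ny in n_y_list) for (ns in n_s_list) {
    rows <- sort(site_order[seq_len(ny)])
    cols <- sort(sp_order[seq_len(ns)])
    sub <- dataset
    sub$data$Y <- dataset$data$Y[rows, cols, drop = FALSE]
    sub$data$X <- dataset$data$X[rows, , drop = FALSE]
    sub$data$Tr <- dataset$data$Tr[cols, , drop = FALSE]
    if (!is.null(dataset$data$C))
      sub$data$C <- dataset$data$C[cols, cols, drop = FALSE]
    if (!is.null(dataset$data$taxonomy))
      sub$data$taxonomy <- dataset$data$taxonomy[cols, , drop = FALSE]
    sub$design <- dataset$design[rows, , drop = FALSE]
    if (!is.null(dataset$level)) {
      lev <- dataset$level
      sub$level <- random_level(sub$design$level_unit, lev$spatial_method,
                                coords = lev$coords, n_knots = lev$n_knots,
                                n_neighbours = min(lev$n_neighbours,
                                                   length(unique(sub$design$level_unit)) - 1L),
                                n_factors = lev$n_factors, name = lev$name)
    }
    sub$truth <- NULL
    sub$sub <- list(n_y = ny, n_s = ns, rows = rows, cols = cols)
    out[[sprintf("ns%d_ny%d", ns, ny)]] <- sub
  }
  out
}
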