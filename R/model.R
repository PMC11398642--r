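# Model definition: data matrices, random levels, priors, response.
#
# The model object is a validated, immutable bundle: community matrix Y
# (sampling units x species), covariates X (with leading intercept), traits Tr
# (species x traits, leading intercept), an optional species correlation C
# (phylogeny- or taxonomy-derived), one or more latent-factor random levels,
# and the full set of prior hyperparameters of the conditionally conjugate
# hierarchy.

#' Define a latent-factor random level
#'
#' A random level groups sampling units into level units (e.g. sites, plots,
#' years) that carry latent factor scores.  Spatially structured levels attach
#' 2-D coordinates to the level units and pick one of three Gaussian-process
#' representations for the factor scores.
#'
#' @param assignment vector of length \code{n_y} (character, factor or
#'   integer) mapping each sampling unit to a level unit.
#' @param spatial_method one of \code{"none"}, \code{"gp"} (full Gaussian
#'   process), \code{"pgp"} (predictive process), \code{"nngp"}
#'   (nearest-neighbour GP).
#' @param coords numeric matrix \code{n_u x 2} of level-unit coordinates
#'   (planar/projected; required unless \code{spatial_method = "none"}).  Row
#'   order follows the level units in order of first appearance in
#'   \code{assignment}, or rownames matching unit labels.
#' @param knots numeric matrix \code{m x 2} of predictive-process knots
#'   (\code{"pgp"} only; defaults to a hexagonal grid of \code{n_knots}).
#' @param n_knots target knot count used when \code{knots} is missing.
#' @param n_neighbours neighbour count for \code{"nngp"}.
#' @param n_factors number of latent factors at this level.
#' @param name level label.
#' @return an object of class \code{jsdm_level}.
#' @export
random_level <- function(assignment, spatial_method = c("none", "gp", "pgp", "nngp"),
                         coords = NULL, knots = NULL, n_knots = 55L,
                         n_neighbours = 10L, n_factors = 10L, name = "level") {
  spatial_method <- match.arg(spatial_method)
  units <- unique(as.character(assignment))
  idx <- match(as.character(assignment), units)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (!is.null(rownames(coords)) && all(units %in% rownames(coords)))
      coords <- coords[units, , drop = FALSE]
  }
  lev <- structure(list(
    name = name,
    assignment = idx,
    units = units,
    n_units = length(units),
    spatial_method = spatial_method,
    coords = coords,
    knots = if (!is.null(knots)) {k <- as.matrix(knots); storage.mode(k) <- "double"; k},
    n_knots = as.integer(n_knots),
    n_neighbours = as.integer(n_neighbours),
    n_factors = as.integer(n_factors)
  ), class = "jsdm_level")
  if (spatial_method == "pgp" && is.null(lev$knots) && !is.null(coords))
    lev$knots <- hex_knot_grid(coords, lev$n_knots)$knots
  lev
}

#' Default prior hyperparameters
#'
#' Builds the complete prior set of the hierarchy: inverse-Wishart prior on
#' the covariance V of species coefficients across covariates, Gaussian prior
#' on the trait effects Gamma, a discrete grid prior on the phylogenetic
#' signal rho, multiplicative-gamma shrinkage on the factor loadings, a
#' discrete grid prior on each spatial range alpha (scaled to the extent of
#' the coordinates), and a gamma prior on residual precision for
#' normal-response models.
#'
#' Defaults: \code{V0 = I}, \code{f0 = n_c + 1}, \code{mGamma = 0},
#' \code{UGamma = I}, shrinkage \code{(a1, b1, a2, b2) = (50, 1, 50, 1)},
#' \code{nu = 3}, \code{sigma} prior \code{(1, 0.3)}, \code{rho} grid of 101
#' equally spaced points on \code{[0, 1]} with uniform weights, and per
#' spatial level an \code{alpha} grid of \code{{0}} plus 100 equally spaced
#' points up to 0.35 times the maximum inter-unit distance, with half the
#' prior mass on 0.
#'
#' @param n_c number of covariates (including intercept).
#' @param n_t number of traits (including intercept).
#' @param n_u_per_level integer vector of level-unit counts, one per level.
#' @param coords_per_level list of coordinate matrices (or \code{NULL} for
#'   non-spatial levels), one per level.
#' @param alpha_grid_n number of nonzero points in each alpha grid.
#' @return an object of class \code{jsdm_priors}.
#' @export
default_priors <- function(n_c, n_t, n_u_per_level = integer(),
                           coords_per_level = vector("list", length(n_u_per_level)),
                           alpha_grid_n = 100L) {
  if (n_c < 1 || n_t < 1) stop("n_c and n_t must be positive")
  alpha_grid <- lapply(coords_per_level, function(co) {
    if (is.null(co)) return(NULL)
    D <- max(stats::dist(co))
    if (D <= 0) stop("coordinates have zero extent; cannot scale alpha grid")
    amax <- 0.35 * D
    values <- c(0, seq(amax / alpha_grid_n, amax, length.out = alpha_grid_n))
    weights <- c(0.5, rep(0.5 / alpha_grid_n, alpha_grid_n))
    list(values = values, weights = weights)
  })
  structure(list(
    V0 = diag(n_c), f0 = n_c + 1,
    mGamma = rep(0, n_c * n_t), UGamma = diag(n_c * n_t),
    rho_grid = list(values = seq(0, 1, length.out = 101),
                    weights = rep(1 / 101, 101)),
    shrinkage = list(a1 = 50, b1 = 1, a2 = 50, b2 = 1),
    nu = 3,
    alpha_grid = alpha_grid,
    sigma_prior = list(aSigma = 1, bSigma = 0.3)
  ), class = "jsdm_priors")
}

.is_intercept <- function(col) all(is.finite(col)) && all(col == 1)

#' Assemble and validate a model definition
#'
#' @param Y response matrix \code{n_y x n_s}: binary presence/absence for
#'   \code{response = "probit"}, real-valued for \code{"normal"}.  \code{NA}
#'   entries are allowed and handled by data augmentation.
#' @param X covariate matrix \code{n_y x n_c} with a leading column of ones.
#' @param Tr trait matrix \code{n_s x n_t} with a leading column of ones;
#'   defaults to intercept only.
#' @param C optional species correlation matrix \code{n_s x n_s} (symmetric
#'   positive definite, unit diagonal); identity assumed when absent.
#' @param levels list of \code{\link{random_level}} objects.
#' @param response \code{"probit"} or \code{"normal"}.
#' @param priors a \code{jsdm_priors} object; \code{\link{default_priors}}
#'   when omitted.
#' @return a validated object of class \code{jsdm_model}.
#' @export
build_model <- function(Y, X, Tr = NULL, C = NULL, levels = list(),
                        response = c("probit", "normal"), priors = NULL) {
  response <- match.arg(response)
  Y <- as.matrix(Y); X <- as.matrix(X)
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  if (is.null(Tr)) Tr <- matrix(1, ncol(Y), 1, dimnames = list(colnames(Y), "intercept"))
  Tr <- as.matrix(Tr); storage.mode(Tr) <- "double"
  if (nrow(Y) != nrow(X))
    stop(sprintf("dimension mismatch: Y has %d rows but X has %d", nrow(Y), nrow(X)))
  if (ncol(Y) != nrow(Tr))
    stop(sprintf("dimension mismatch: Y has %d species but Tr has %d rows", ncol(Y), nrow(Tr)))
  if (!is.null(C)) {
    C <- as.matrix(C); storage.mode(C) <- "double"
    if (!all(dim(C) == ncol(Y)))
      stop(sprintf("dimension mismatch: C is %dx%d but Y has %d species",
                   nrow(C), ncol(C), ncol(Y)))
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10)
      stop(sprintf("C is not positive definite (smallest eigenvalue %.3e)", ev))
  }
  if (response == "probit") {
    obs <- Y[!is.na(Y)]
    if (!all(obs %in% c(0, 1)))
      stop("probit response requires all non-missing Y entries in {0, 1}")
  }
  if (inherits(levels, "jsdm_level")) levels <- list(levels)
  if (is.null(priors)) {
    priors <- default_priors(
      ncol(X), ncol(Tr),
      vapply(levels, function(l) l$n_units, integer(1)),
      lapply(levels, function(l) l$coords))
  }
  # one alpha-grid slot per level (NULL for non-spatial levels), so that
  # per-level indexing is always defined
  while (length(priors$alpha_grid) < length(levels))
    priors$alpha_grid[length(priors$alpha_grid) + 1] <- list(NULL)
  model <- structure(list(
    Y = Y, X = X, Tr = Tr, C = C,
    levels = levels, priors = priors, response = response,
    n_y = nrow(Y), n_s = ncol(Y), n_c = ncol(X), n_t = ncol(Tr),
    unit_names = rownames(Y) %||% paste0("unit_", seq_len(nrow(Y))),
    species_names = colnames(Y) %||% paste0("sp_", seq_len(ncol(Y))),
    covariate_names = colnames(X) %||% c("intercept", paste0("x", seq_len(ncol(X) - 1))),
    trait_names = colnames(Tr) %||% c("intercept", paste0("t", seq_len(ncol(Tr) - 1)))
  ), class = "jsdm_model")
  rep <- validate_model(model)
  if (length(rep)) stop("invalid model:\n  - ", paste(rep, collapse = "\n  - "))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model definition
#'
#' Checks every structural invariant of the model object and returns the list
#' of violations (empty when the model is valid).  Never raises and never
#' mutates its input.
#'
#' @param model a \code{jsdm_model} object (possibly hand-assembled).
#' @return character vector of violation messages.
#' @export
validate_model <- function(model) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  with(model, {
    if (!.is_intercept(X[, 1])) add("first column of X must be an intercept of ones")
    if (!.is_intercept(Tr[, 1])) add("first column of Tr must be an intercept of ones")
    if (!is.null(C)) {
      if (max(abs(C - t(C))) > 1e-8) add("C is not symmetric")
      if (max(abs(diag(C) - 1)) > 1e-8) add("C does not have unit diagonal")
    }
    for (lev in levels) {
      if (length(lev$assignment) != n_y)
        add(sprintf("level '%s': assignment length %d != n_y = %d",
                    lev$name, length(lev$assignment), n_y))
      if (anyNA(lev$assignment) || any(lev$assignment < 1 | lev$assignment > lev$n_units))
        add(sprintf("level '%s': assignment maps outside 1..n_u", lev$name))
      if (lev$spatial_method != "none") {
        if (is.null(lev$coords))
          add(sprintf("level '%s': spatial method '%s' requires coordinates",
                      lev$name, lev$spatial_method))
        else if (nrow(lev$coords) != lev$n_units || ncol(lev$coords) != 2)
          add(sprintf("level '%s': coords must be %d x 2", lev$name, lev$n_units))
        else if (!all(is.finite(lev$coords)))
          add(sprintf("level '%s': coords contain non-finite values", lev$name))
      }
      if (lev$spatial_method == "nngp" &&
          (lev$n_neighbours < 1 || lev$n_neighbours >= lev$n_units))
        add(sprintf("level '%s': need 1 <= n_neighbours < n_u, got %d (n_u = %d)",
                    lev$name, lev$n_neighbours, lev$n_units))
      if (lev$spatial_method == "pgp" && (is.null(lev$knots) || nrow(lev$knots) < 1))
        add(sprintf("level '%s': pgp requires at least one knot", lev$name))
      if (lev$n_factors < 1)
        add(sprintf("level '%s': n_factors must be >= 1", lev$name))
    }
    pr <- priors
    if (!isTRUE(all.equal(sum(pr$rho_grid$weights), 1)) ||
        any(pr$rho_grid$weights < 0))
      add("rho_grid weights must be non-negative and sum to 1")
    if (any(pr$rho_grid$values < 0 | pr$rho_grid$values > 1))
      add("rho_grid values must lie in [0, 1]")
    for (i in seq_along(pr$alpha_grid)) {
      ag <- pr$alpha_grid[[i]]
      if (is.null(ag)) next
      if (!isTRUE(all.equal(sum(ag$weights), 1)) || any(ag$weights < 0))
        add(sprintf("alpha_grid for level %d: weights must be non-negative and sum to 1", i))
      if (any(ag$values < 0))
        add(sprintf("alpha_grid for level %d: values must be >= 0", i))
    }
    sh <- pr$shrinkage
    if (any(unlist(sh) <= 0)) add("shrinkage hyperparameters must be positive")
    if (pr$nu <= 0) add("nu must be positive")
    if (pr$f0 <= n_c - 1) add("f0 must exceed n_c - 1")
    if (any(unlist(pr$sigma_prior) <= 0)) add("sigma prior hyperparameters must be positive")
    ug <- pr$UGamma
    if (max(abs(ug - t(ug))) > 1e-8 ||
        min(eigen(ug, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      add("UGamma must be symmetric positive definite")
  })
  v
}

#' @export
print.jsdm_model <- function(x, ...) {
  cat(sprintf("jsdm_model: %d units x %d species, %d covariates, %d traits, %s response\n",
              x$n_y, x$n_s, x$n_c, x$n_t, x$response))
  cat(sprintf("  species correlation: %s\n", if (is.null(x$C)) "identity (none)" else "supplied"))
  for (lev in x$levels)
    cat(sprintf("  level '%s': %d units, %d factors, spatial method %s\n",
                lev$name, lev$n_units, lev$n_factors, lev$spatial_method))
  invisible(x)
}
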