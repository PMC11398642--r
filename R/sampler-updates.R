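# Full-conditional block updates of the Gibbs sampler.
#
# The model is Z = X Beta + sum_r Pi_r Eta_r Lambda_r + eps with
# eps_ij ~ N(0, sigma_j^2); for presence-absence data Y = 1(Z > 0) and
# sigma_j = 1 (probit augmentation).  Species coefficients have the
# trait/phylogeny hierarchy vec(Beta) ~ N(vec(Gamma Tr'), Q x V) with
# Q = rho C + (1 - rho) I, and loadings carry the multiplicative-gamma
# shrinkage prior.  Every block below samples from its exact conditional.

#' Precompute fixed quantities for a model
#'
#' Builds the runtime cache used by the update functions: the eigensystem of
#' the species correlation, missingness masks, and - for each spatial level -
#' the spatial structure at every point of its alpha grid (factor caches, not
#' dense matrices, for pgp/nngp).
#'
#' @param model a \code{jsdm_model}.
#' @return a runtime cache (list), reusable across chains.
#' @export
prepare_runtime <- function(model) {
  rt <- list()
  if (!is.null(model$C)) {
    e <- eigen(model$C, symmetric = TRUE)
    rt$eigC <- list(U = e$vectors, d = e$values)
  }
  rt$miss <- is.na(model$Y)
  rt$any_miss <- any(rt$miss)
  rt$structures <- lapply(seq_along(model$levels), function(r) {
    lev <- model$levels[[r]]
    if (lev$spatial_method == "none") return(NULL)
    ag <- model$priors$alpha_grid[[r]]
    if (is.null(ag)) stop(sprintf("level '%s' is spatial but has no alpha grid", lev$name))
    lapply(ag$values, function(a) build_spatial_structure(lev, a))
  })
  rt$counts <- lapply(model$levels, function(lev) tabulate(lev$assignment, lev$n_units))
  rt
}

# Q^-1 for Q = rho C + (1 - rho) I via the cached eigensystem (identity
# when the model has no species correlation).
.Qinv <- function(model, runtime, rho) {
  if (is.null(model$C) || rho == 0) return(diag(model$n_s))
  U <- runtime$eigC$U
  w <- 1 / (rho * runtime$eigC$d + 1 - rho)
  U %*% (w * t(U))
}

#' Linear predictor of the current state
#'
#' \code{X Beta} plus the latent-factor contributions of every level.
#'
#' @param state a \code{jsdm_state}.
#' @param model the model.
#' @return matrix \code{n_y x n_s}.
#' @export
linear_predictor <- function(state, model) {
  L <- model$X %*% state$Beta
  for (r in seq_along(model$levels)) {
    lev <- model$levels[[r]]
    sl <- state$levels[[r]]
    L <- L + sl$Eta[lev$assignment, , drop = FALSE] %*% sl$Lambda
  }
  L
}

# Draw Z given the linear predictor, observations and one uniform per entry.
# Truncated entries use the inverse-CDF (no rejection loops): for y = 1 the
# residual is drawn from the upper tail beyond -L, for y = 0 from the lower
# tail below -L, and missing entries are untruncated.
.draw_z <- function(L, Y, sigma2, response, u) {
  n_y <- nrow(L); n_s <- ncol(L)
  if (response == "probit") {
    Z <- L
    miss <- is.na(Y)
    i1 <- !miss & Y == 1
    i0 <- !miss & Y == 0
    if (any(i1)) {
      p <- pmax(u[i1] * stats::pnorm(L[i1]), 1e-320)
      Z[i1] <- L[i1] + stats::qnorm(p, lower.tail = FALSE)
    }
    if (any(i0)) {
      p <- pmax(u[i0] * stats::pnorm(-L[i0]), 1e-320)
      Z[i0] <- L[i0] + stats::qnorm(p)
    }
    if (any(miss)) Z[miss] <- L[miss] + stats::qnorm(u[miss])
    Z
  } else {
    Z <- Y
    miss <- is.na(Y)
    if (any(miss)) {
      sd_m <- sqrt(sigma2)[col(L)[miss]]
      Z[miss] <- L[miss] + sd_m * stats::qnorm(u[miss])
    }
    Z
  }
}

#' Update the latent continuous responses Z
#'
#' Probit: each observed entry is drawn from N(L, 1) truncated to the side
#' implied by Y; missing entries are drawn untruncated.  Normal: observed
#' entries equal Y; missing entries are imputed from N(L, sigma_j^2).
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the state with updated \code{Z}.
#' @export
update_z <- function(state, model, runtime = NULL) {
  L <- linear_predictor(state, model)
  if (!all(is.finite(L))) {
    bad <- which(!is.finite(L), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite linear predictor at unit %d, species %d", bad[1], bad[2]))
  }
  u <- matrix(stats::runif(model$n_y * model$n_s), model$n_y, model$n_s)
  state$Z <- .draw_z(L, model$Y, state$sigma2, model$response, u)
  state
}

# Stack the per-level loading precisions (Psi * cumprod(Delta)) into one
# (q - n_c) x n_s matrix ordered like the W columns.
.lambda_precisions <- function(state) {
  out <- lapply(state$levels, function(sl) {
    tau <- cumprod(sl$Delta)
    sl$Psi * tau
  })
  if (!length(out)) return(matrix(0, 0, 0))
  do.call(rbind, out)
}

.factor_design <- function(state, model) {
  cols <- lapply(seq_along(model$levels), function(r)
    state$levels[[r]]$Eta[model$levels[[r]]$assignment, , drop = FALSE])
  do.call(cbind, c(list(model$X), cols))
}

#' Joint update of Beta and the loadings Lambda
#'
#' Samples the stacked coefficient matrix [Beta; Lambda] from its exact
#' Gaussian conditional.  When the species are a priori independent
#' (no correlation matrix, or rho = 0) the draw factorizes per species;
#' otherwise the full cross-species system with prior precision
#' \code{(rho C + (1 - rho) I)^-1 x V^-1} on the Beta block is solved densely.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the state with updated \code{Beta} and per-level \code{Lambda}.
#' @export
update_beta_lambda <- function(state, model, runtime = NULL) {
  n_c <- model$n_c; n_s <- model$n_s
  nf <- vapply(state$levels, function(sl) nrow(sl$Lambda), integer(1))
  q <- n_c + sum(nf)
  W <- .factor_design(state, model)
  lamprec <- .lambda_precisions(state)
  Vinv <- chol2inv(chol(state$V))
  Mb <- state$Gamma %*% t(model$Tr)          # prior mean of Beta, n_c x n_s
  WtW <- crossprod(W)
  WtZ <- crossprod(W, state$Z)
  out <- matrix(0, q, n_s)
  if (is.null(model$C) || state$rho == 0) {
    prior_info_b <- Vinv %*% Mb
    for (j in seq_len(n_s)) {
      P <- WtW / state$sigma2[j]
      P[seq_len(n_c), seq_len(n_c)] <- P[seq_len(n_c), seq_len(n_c)] + Vinv
      if (q > n_c) {
        idx <- (n_c + 1):q
        P[cbind(idx, idx)] <- P[cbind(idx, idx)] + lamprec[, j]
      }
      b <- WtZ[, j] / state$sigma2[j]
      b[seq_len(n_c)] <- b[seq_len(n_c)] + prior_info_b[, j]
      R <- tryCatch(chol(P), error = function(e)
        stop(sprintf("singular conditional precision for species %d (rcond ~ %.2e)",
                     j, Matrix::rcond(P))))
      mean_j <- backsolve(R, backsolve(R, b, transpose = TRUE))
      out[, j] <- mean_j + backsolve(R, stats::rnorm(q))
    }
  } else {
    if (is.null(runtime)) runtime <- prepare_runtime(model)
    Qinv <- .Qinv(model, runtime, state$rho)
    nq <- n_s * q
    P <- matrix(0, nq, nq)
    bpos <- as.vector(outer(seq_len(n_c), (seq_len(n_s) - 1) * q, "+"))
    P[bpos, bpos] <- kronecker(Qinv, Vinv)
    b <- numeric(nq)
    info_b <- Vinv %*% Mb %*% Qinv
    for (j in seq_len(n_s)) {
      idx <- (j - 1) * q + seq_len(q)
      P[idx, idx] <- P[idx, idx] + WtW / state$sigma2[j]
      if (q > n_c) {
        li <- idx[(n_c + 1):q]
        P[cbind(li, li)] <- P[cbind(li, li)] + lamprec[, j]
      }
      b[idx] <- WtZ[, j] / state$sigma2[j]
      b[idx[seq_len(n_c)]] <- b[idx[seq_len(n_c)]] + info_b[, j]
    }
    R <- tryCatch(chol(P), error = function(e)
      stop("singular joint conditional precision in the Beta/Lambda block"))
    mean_v <- backsolve(R, backsolve(R, b, transpose = TRUE))
    out <- matrix(mean_v + backsolve(R, stats::rnorm(nq)), q, n_s)
  }
  state$Beta <- out[seq_len(n_c), , drop = FALSE]
  ofs <- n_c
  for (r in seq_along(state$levels)) {
    state$levels[[r]]$Lambda <- out[ofs + seq_len(nf[r]), , drop = FALSE]
    ofs <- ofs + nf[r]
  }
  state
}

#' Update the trait effects Gamma and covariance V
#'
#' Conjugate draws from the regression of the Beta columns on the traits
#' under species covariance \code{Q = rho C + (1 - rho) I}: a multivariate
#' normal for \code{vec(Gamma)} followed by an inverse-Wishart for \code{V}.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the state with updated \code{Gamma} and \code{V}.
#' @export
update_gamma_v <- function(state, model, runtime = NULL) {
  if (is.null(runtime) && !is.null(model$C)) runtime <- prepare_runtime(model)
  pr <- model$priors
  n_c <- model$n_c; n_t <- model$n_t; n_s <- model$n_s
  Tr <- model$Tr
  Qinv <- .Qinv(model, runtime, state$rho)
  Vinv <- chol2inv(chol(state$V))
  UGi <- chol2inv(chol(pr$UGamma))
  # Gamma | V, Beta
  Prec <- UGi + kronecker(crossprod(Tr, Qinv %*% Tr), Vinv)
  info <- as.numeric(UGi %*% pr$mGamma) + as.numeric(Vinv %*% state$Beta %*% Qinv %*% Tr)
  R <- chol(Prec)
  mean_g <- backsolve(R, backsolve(R, info, transpose = TRUE))
  state$Gamma <- matrix(mean_g + backsolve(R, stats::rnorm(n_c * n_t)), n_c, n_t)
  # V | Gamma, Beta
  E <- state$Beta - state$Gamma %*% t(Tr)
  S <- E %*% Qinv %*% t(E)
  df <- pr$f0 + n_s
  if (df <= n_c - 1) stop("inverse-Wishart degrees of freedom insufficient")
  Scale <- pr$V0 + S
  W <- stats::rWishart(1, df, chol2inv(chol(Scale)))[, , 1]
  state$V <- chol2inv(chol(W))
  state
}

# Normalized conditional weights of the rho grid (exposed for enumeration
# tests).  Uses the eigensystem of C so each grid point costs O(n_s).
.rho_logweights <- function(state, model, runtime) {
  pr <- model$priors$rho_grid
  E <- state$Beta - state$Gamma %*% t(model$Tr)
  Vinv <- chol2inv(chol(state$V))
  U <- runtime$eigC$U; dval <- runtime$eigC$d
  EU <- E %*% U
  a <- colSums(EU * (Vinv %*% EU))
  vapply(seq_along(pr$values), function(g) {
    rho <- pr$values[g]
    ev <- rho * dval + 1 - rho
    if (pr$weights[g] <= 0) return(-Inf)
    log(pr$weights[g]) - 0.5 * (model$n_c * sum(log(ev)) + sum(a / ev))
  }, numeric(1))
}

.rho_weights <- function(state, model, runtime = NULL) {
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  lw <- .rho_logweights(state, model, runtime)
  m <- max(lw)
  if (!is.finite(m)) stop("all rho-grid weights underflow; rescale the grid")
  w <- exp(lw - m)
  w / sum(w)
}

#' Update the phylogenetic-signal weight rho
#'
#' Draws rho from its discrete conditional on the prior grid,
#' \code{w(g) proportional to prior(g) N(vec(Beta - Gamma t(Tr)); 0,
#' (g C + (1 - g) I) x V)}, normalized by log-sum-exp.  A model without a
#' species correlation matrix leaves rho untouched.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the state with updated \code{rho}.
#' @export
update_rho <- function(state, model, runtime = NULL) {
  if (is.null(model$C)) return(state)
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  w <- .rho_weights(state, model, runtime)
  g <- findInterval(stats::runif(1), cumsum(w)) + 1L
  g <- min(g, length(w))
  state$rho_idx <- g
  state$rho <- model$priors$rho_grid$values[g]
  state
}

#' Update the multiplicative-gamma shrinkage block of one level
#'
#' Local precisions \code{Psi[h, j] ~ Gamma((nu + 1) / 2,
#' (nu + tau_h Lambda[h, j]^2) / 2)} with \code{tau_h = prod(Delta[1:h])},
#' followed by each shrinkage increment \code{Delta[h]} from its gamma
#' conditional aggregating over factors \code{>= h}.
#'
#' @param state,model current state and model.
#' @param level_index which level to update.
#' @return the state with updated \code{Psi} and \code{Delta}.
#' @export
update_shrinkage <- function(state, model, level_index = 1L) {
  sl <- state$levels[[level_index]]
  sh <- model$priors$shrinkage
  nu <- model$priors$nu
  Lam2 <- sl$Lambda^2
  if (anyNA(Lam2)) stop("NaN loadings in shrinkage update")
  n_f <- nrow(Lam2); n_s <- ncol(Lam2)
  tau <- cumprod(sl$Delta)
  sl$Psi <- matrix(stats::rgamma(n_f * n_s, shape = (nu + 1) / 2,
                                 rate = (nu + tau * Lam2) / 2), n_f, n_s)
  m <- rowSums(sl$Psi * Lam2)
  for (h in seq_len(n_f)) {
    a <- if (h == 1) sh$a1 else sh$a2
    b <- if (h == 1) sh$b1 else sh$b2
    tau <- cumprod(sl$Delta)
    tl <- tau[h:n_f] / sl$Delta[h]
    shape <- a + n_s * (n_f - h + 1) / 2
    rate <- b + 0.5 * sum(tl * m[h:n_f])
    sl$Delta[h] <- stats::rgamma(1, shape = shape, rate = rate)
  }
  state$levels[[level_index]] <- sl
  state
}

#' Update the latent factor scores Eta of one level
#'
#' Non-spatial levels draw all factors of each level unit jointly from the
#' conjugate Gaussian.  Spatial levels draw each factor's score vector
#' jointly across units from the Gaussian-process conditional, using the
#' dense covariance (full GP), the low-rank-plus-diagonal predictive-process
#' representation at cost O(n_u m^2), or the sparse NNGP factorization.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @param level_index which level to update.
#' @return the state with updated \code{Eta}.
#' @export
update_eta <- function(state, model, level_index = 1L, runtime = NULL) {
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  lev <- model$levels[[level_index]]
  sl <- state$levels[[level_index]]
  n_u <- lev$n_units; n_f <- nrow(sl$Lambda)
  counts <- runtime$counts[[level_index]]
  Dsig <- 1 / state$sigma2
  # residual with this level's contribution removed
  S <- state$Z - model$X %*% state$Beta
  for (r in seq_along(model$levels)) {
    if (r == level_index) next
    S <- S - state$levels[[r]]$Eta[model$levels[[r]]$assignment, , drop = FALSE] %*%
      state$levels[[r]]$Lambda
  }
  asg <- lev$assignment
  if (lev$spatial_method == "none") {
    LamD <- sweep(sl$Lambda, 2, Dsig, "*")
    A <- tcrossprod(LamD, sl$Lambda)                # n_f x n_f
    info <- rowsum(S %*% t(LamD), asg)              # n_u x n_f (units sorted 1..n_u)
    Zmat <- matrix(stats::rnorm(n_u * n_f), n_u, n_f)
    Eta <- matrix(0, n_u, n_f)
    for (m in unique(counts)) {
      us <- which(counts == m)
      R <- chol(diag(n_f) + m * A)
      mu <- backsolve(R, backsolve(R, t(info[us, , drop = FALSE]), transpose = TRUE))
      dev <- backsolve(R, t(Zmat[us, , drop = FALSE]))
      Eta[us, ] <- t(mu + dev)
    }
    sl$Eta <- Eta
  } else {
    structures <- runtime$structures[[level_index]]
    Fcur <- sl$Eta[asg, , drop = FALSE] %*% sl$Lambda
    for (h in seq_len(n_f)) {
      lam <- sl$Lambda[h, ]
      c_h <- sum(lam^2 * Dsig)
      w <- counts * c_h
      Sh <- S - Fcur + outer(sl$Eta[asg, h], lam)
      v <- as.numeric(Sh %*% (Dsig * lam))
      b <- as.numeric(rowsum(v, asg))
      st <- structures[[sl$alpha_idx[h]]]
      if (is.null(st)) stop("missing spatial structure for this level/alpha")
      eta_new <- draw_gp_conditional(st, w, b)
      Fcur <- Fcur + outer((eta_new - sl$Eta[, h])[asg], lam)
      sl$Eta[, h] <- eta_new
    }
  }
  state$levels[[level_index]] <- sl
  state
}

.alpha_logweights <- function(state, model, level_index, h, runtime) {
  ag <- model$priors$alpha_grid[[level_index]]
  structures <- runtime$structures[[level_index]]
  eta <- state$levels[[level_index]]$Eta[, h]
  vapply(seq_along(ag$values), function(g) {
    if (ag$weights[g] <= 0) return(-Inf)
    log(ag$weights[g]) + gp_logdensity(structures[[g]], eta)
  }, numeric(1))
}

.alpha_weights <- function(state, model, level_index, h, runtime = NULL) {
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  lw <- .alpha_logweights(state, model, level_index, h, runtime)
  m <- max(lw)
  if (!is.finite(m)) stop("all alpha-grid weights underflow")
  w <- exp(lw - m)
  w / sum(w)
}

#' Update the spatial ranges alpha of one level
#'
#' Per factor, draws the grid index from the discrete conditional
#' proportional to \code{prior(g) N(Eta[, h]; 0, K(g))}, evaluated under each
#' precomputed spatial structure and normalized by log-sum-exp.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @param level_index which level to update.
#' @return the state with updated \code{alpha_idx}.
#' @export
update_alpha <- function(state, model, level_index = 1L, runtime = NULL) {
  lev <- model$levels[[level_index]]
  if (lev$spatial_method == "none") return(state)
  if (is.null(runtime)) runtime <- prepare_runtime(model)
  ag <- model$priors$alpha_grid[[level_index]]
  if (is.null(ag) || !length(ag$values)) stop("empty alpha grid")
  n_f <- nrow(state$levels[[level_index]]$Lambda)
  for (h in seq_len(n_f)) {
    w <- .alpha_weights(state, model, level_index, h, runtime)
    g <- findInterval(stats::runif(1), cumsum(w)) + 1L
    state$levels[[level_index]]$alpha_idx[h] <- min(g, length(w))
  }
  state
}

#' Update the residual variances sigma
#'
#' Normal response only: per species the precision is drawn from
#' \code{Gamma(aSigma + n/2, bSigma + RSS/2)} with RSS the squared residuals
#' of the (complete, augmented) Z against the full linear predictor.  Probit
#' models keep sigma fixed at 1.
#'
#' @param state,model,runtime current state, model, runtime cache.
#' @return the state with updated \code{sigma2}.
#' @export
update_sigma <- function(state, model, runtime = NULL) {
  if (model$response != "normal") return(state)
  pr <- model$priors$sigma_prior
  Rres <- state$Z - linear_predictor(state, model)
  rss <- colSums(Rres^2)
  prec <- stats::rgamma(model$n_s, shape = pr$aSigma + model$n_y / 2,
                        rate = pr$bSigma + rss / 2)
  state$sigma2 <- 1 / prec
  state
}
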