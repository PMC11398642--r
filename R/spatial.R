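# Spatial covariance structures for latent factors.
#
# Three representations of an exponential-kernel Gaussian process over the
# level units: the exact dense GP ("gp"), the predictive-process low-rank
# approximation with a diagonal correction that preserves unit marginal
# variances ("pgp"), and a Vecchia-type nearest-neighbour factorization
# ("nngp") whose implied precision is (I - A)' D^-1 (I - A) with A sparse
# strictly lower triangular.  A spatial range of 0 degenerates every method to
# the identity covariance.

#' Exponential covariance kernel
#'
#' \code{K[i, j] = exp(-d(i, j) / alpha)} with Euclidean distance \code{d};
#' the identity matrix when \code{alpha = 0}.
#'
#' @param coords numeric matrix \code{n x 2}.
#' @param alpha spatial range, \code{>= 0}.
#' @return covariance matrix \code{n x n} with unit diagonal.
#' @export
exp_covariance <- function(coords, alpha) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (alpha < 0) stop("alpha must be >= 0")
  n <- nrow(coords)
  if (alpha == 0) return(diag(n))
  K <- exp(-as.matrix(stats::dist(coords)) / alpha)
  diag(K) <- 1
  dimnames(K) <- NULL
  K
}

.cross_exp_cov <- function(a, b, alpha) {
  # exp(-|a_i - b_j| / alpha), n_a x n_b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-sqrt(pmax(d2, 0)) / alpha)
}

.chol_jitter <- function(K, what = "covariance") {
  # one bounded jitter retry, then error (standard GP hygiene)
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(K + 1e-8 * diag(nrow(K))), error = function(e) NULL)
    if (is.null(R))
      stop(sprintf("Cholesky of %s failed even with 1e-8 jitter; check for duplicate coordinates", what))
  }
  R
}

#' Hexagonal knot grid
#'
#' Places predictive-process knots on a uniform hexagonal (triangular) lattice
#' spanning the bounding box of the data, with the lattice spacing chosen by
#' bisection so the number of knots inside the box is as close as possible to
#' \code{target_m} (within +/- 3 for attainable counts).  Deterministic.
#'
#' @param coords data coordinates \code{n x 2}.
#' @param target_m requested knot count.
#' @return a list with \code{knots} (matrix \code{m x 2}) and \code{spacing}.
#' @export
hex_knot_grid <- function(coords, target_m) {
  coords <- as.matrix(coords)
  if (target_m < 1) stop("target_m must be >= 1")
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  if (diff(xr) <= 0 || diff(yr) <= 0)
    stop("degenerate (zero-area) bounding box")
  if (target_m == 1) {
    kn <- matrix(c(mean(xr), mean(yr)), 1, 2)
    return(list(knots = kn, spacing = max(diff(xr), diff(yr))))
  }
  lattice <- function(s) {
    ys <- seq(yr[1], yr[2], by = s * sqrt(3) / 2)
    pts <- lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(xr[1] + off, xr[2], by = s)
      if (!length(xs)) return(NULL)
      cbind(xs, ys[i])
    })
    do.call(rbind, pts)
  }
  diag_len <- sqrt(diff(xr)^2 + diff(yr)^2)
  lo <- diag_len / (4 * sqrt(target_m) + 50)   # dense: count >= target
  hi <- 2 * diag_len                            # sparse: count <= target
  best <- NULL; best_err <- Inf
  for (it in seq_len(60)) {
    s <- (lo + hi) / 2
    kn <- lattice(s)
    m <- if (is.null(kn)) 0 else nrow(kn)
    err <- abs(m - target_m)
    if (err < best_err) { best <- list(knots = kn, spacing = s); best_err <- err }
    if (m == target_m) break
    if (m > target_m) lo <- s else hi <- s
  }
  best
}

# ---- structure constructors -------------------------------------------------

.identity_structure <- function(n, method) {
  structure(list(method = method, alpha = 0, n = n, identity = TRUE,
                 env = new.env(parent = emptyenv())),
            class = "jsdm_spatial")
}

.gp_structure <- function(coords, alpha) {
  K <- exp_covariance(coords, alpha)
  R <- .chol_jitter(K, "the GP covariance")
  structure(list(method = "gp", alpha = alpha, n = nrow(K), identity = FALSE,
                 L = t(R), env = new.env(parent = emptyenv())),
            class = "jsdm_spatial")
}

#' Predictive-process spatial structure
#'
#' Low-rank-plus-diagonal representation of the predictive-process
#' approximation: \code{K~ = K_uk K_kk^-1 K_ku + diag(K_uu - K_uk K_kk^-1
#' K_ku)}.  The diagonal correction keeps every marginal variance equal to 1.
#' Draws and density evaluations cost \code{O(n_u m^2)} via Woodbury
#' identities.
#'
#' @param coords unit coordinates \code{n_u x 2}.
#' @param knots knot coordinates \code{m x 2}.
#' @param alpha spatial range, \code{> 0}.
#' @return a \code{jsdm_spatial} object.
#' @export
pgp_structure <- function(coords, knots, alpha) {
  coords <- as.matrix(coords); knots <- as.matrix(knots)
  if (alpha <= 0) stop("pgp_structure requires alpha > 0")
  if (nrow(knots) > nrow(coords)) stop("knot count must not exceed unit count")
  Kkk <- exp_covariance(knots, alpha)
  R <- .chol_jitter(Kkk, "the knot covariance (ill-conditioned K_kk; add jitter or reduce knot density)")
  Kuk <- .cross_exp_cov(coords, knots, alpha)
  U <- t(backsolve(R, t(Kuk), transpose = TRUE))   # K_uk R^-1, so U U' = K_uk K_kk^-1 K_ku
  d <- pmax(1 - rowSums(U^2), 0)
  structure(list(method = "pgp", alpha = alpha, n = nrow(coords), identity = FALSE,
                 U = U, d = d, d_safe = pmax(d, 1e-10), knots = knots,
                 env = new.env(parent = emptyenv())),
            class = "jsdm_spatial")
}

#' Nearest-neighbour GP spatial structure
#'
#' Vecchia-type sequential factorization: units are ordered lexicographically
#' on (x, y) and each conditions on up to \code{n_neighbours} nearest
#' previously ordered units, giving a sparse strictly-lower-triangular
#' \code{A} and diagonal \code{D} with implied precision
#' \code{t(I - A) D^-1 (I - A)} (in the ordered frame).
#'
#' @param coords unit coordinates \code{n_u x 2}.
#' @param alpha spatial range, \code{> 0}.
#' @param n_neighbours conditioning-set size, \code{1 <= k < n_u}.
#' @return a \code{jsdm_spatial} object.
#' @export
nngp_structure <- function(coords, alpha, n_neighbours) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (alpha <= 0) stop("nngp_structure requires alpha > 0")
  if (n_neighbours < 1 || n_neighbours >= n)
    stop("need 1 <= n_neighbours < n_u")
  ord <- order(coords[, 1], coords[, 2])
  co <- coords[ord, , drop = FALSE]
  ii <- jj <- xx <- vector("list", n)
  d <- numeric(n); d[1] <- 1
  for (i in 2:n) {
    di <- sqrt((co[seq_len(i - 1), 1] - co[i, 1])^2 +
               (co[seq_len(i - 1), 2] - co[i, 2])^2)
    nb <- order(di)[seq_len(min(n_neighbours, i - 1))]
    Knb <- exp(-as.matrix(stats::dist(co[nb, , drop = FALSE])) / alpha)
    diag(Knb) <- 1
    k_in <- exp(-di[nb] / alpha)
    a <- tryCatch(solve(Knb, k_in), error = function(e) NULL)
    if (is.null(a)) {
      a <- tryCatch(solve(Knb + 1e-8 * diag(nrow(Knb)), k_in), error = function(e) NULL)
      if (is.null(a))
        stop("singular NNGP conditioning set (duplicate coordinates?); jitter did not help")
    }
    d[i] <- 1 - sum(k_in * a)
    if (d[i] <= 0) {
      d[i] <- 1 - sum(k_in * solve(Knb + 1e-8 * diag(nrow(Knb)), k_in))
      if (d[i] <= 0) stop("non-positive NNGP conditional variance (duplicate coordinates?)")
    }
    ii[[i]] <- rep.int(i, length(nb)); jj[[i]] <- nb; xx[[i]] <- a
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  structure(list(method = "nngp", alpha = alpha, n = n, identity = FALSE,
                 A = A, d = d, order = ord, n_neighbours = n_neighbours,
                 env = new.env(parent = emptyenv())),
            class = "jsdm_spatial")
}

#' Build the spatial structure for a level at a given range
#'
#' Dispatches on the level's spatial method; \code{alpha = 0} yields the
#' identity structure for every method.
#'
#' @param level a \code{jsdm_level}.
#' @param alpha spatial range.
#' @return a \code{jsdm_spatial} object.
#' @export
build_spatial_structure <- function(level, alpha) {
  if (alpha == 0 || level$spatial_method == "none")
    return(.identity_structure(level$n_units, level$spatial_method))
  switch(level$spatial_method,
    gp = .gp_structure(level$coords, alpha),
    pgp = pgp_structure(level$coords, level$knots, alpha),
    nngp = nngp_structure(level$coords, alpha, level$n_neighbours))
}

# Lazily computed/cached dense precision for the full-GP structure.
.gp_Kinv <- function(st) {
  if (is.null(st$env$Kinv)) st$env$Kinv <- chol2inv(t(st$L))
  st$env$Kinv
}

# NNGP sparse precision (I - A)' D^-1 (I - A) in the ordered frame, cached.
.nngp_Q <- function(st) {
  if (is.null(st$env$Q)) {
    IA <- Matrix::Diagonal(st$n) - st$A
    st$env$Q <- Matrix::crossprod(IA, IA / st$d)
  }
  st$env$Q
}

#' Gaussian log-density under a spatial structure
#'
#' \code{log N(v; 0, K)} where \code{K} is the structure's implied covariance:
#' exact for the full GP, exact under the approximation's own covariance for
#' the predictive-process and nearest-neighbour structures.
#'
#' @param structure a \code{jsdm_spatial}.
#' @param v numeric vector of length \code{n_u}.
#' @return scalar log-density.
#' @export
gp_logdensity <- function(structure, v) {
  n <- structure$n
  if (length(v) != n) stop("dimension mismatch between structure and vector")
  if (structure$identity)
    return(-0.5 * (n * log(2 * pi) + sum(v^2)))
  switch(structure$method,
    gp = {
      w <- forwardsolve(structure$L, v)
      -0.5 * n * log(2 * pi) - sum(log(diag(structure$L))) - 0.5 * sum(w^2)
    },
    pgp = {
      Di <- 1 / structure$d_safe
      U <- structure$U
      t1 <- crossprod(U, Di * v)
      M <- diag(ncol(U)) + crossprod(U, Di * U)
      Rm <- chol(M)
      quad <- sum(v^2 * Di) - sum(backsolve(Rm, t1, transpose = TRUE)^2)
      logdet <- sum(log(structure$d_safe)) + 2 * sum(log(diag(Rm)))
      -0.5 * (n * log(2 * pi) + logdet + quad)
    },
    nngp = {
      vp <- v[structure$order]
      w <- vp - as.numeric(structure$A %*% vp)
      -0.5 * (n * log(2 * pi) + sum(log(structure$d)) + sum(w^2 / structure$d))
    })
}

#' Implied covariance matrix of a spatial structure
#'
#' Materializes the dense covariance the structure represents.  Intended for
#' inspection and testing at small \code{n_u}; cost and memory are quadratic.
#'
#' @param structure a \code{jsdm_spatial}.
#' @return dense \code{n_u x n_u} covariance matrix.
#' @export
implied_covariance <- function(structure) {
  n <- structure$n
  if (structure$identity) return(diag(n))
  switch(structure$method,
    gp = tcrossprod(structure$L),
    pgp = {
      K <- tcrossprod(structure$U)
      diag(K) <- diag(K) + structure$d
      K
    },
    nngp = {
      Q <- as.matrix(.nngp_Q(structure))
      K <- solve(Q)
      io <- order(structure$order)    # ordered frame -> original frame
      K[io, io]
    })
}

# Draw one sample from N(P^-1 b, P^-1) with P = K^-1 + diag(w), where K is the
# structure's implied covariance.  Consumes RNG deterministically (n draws,
# plus m for pgp); with mean_only = TRUE returns the exact conditional mean
# and consumes no RNG.
draw_gp_conditional <- function(structure, w, b, mean_only = FALSE) {
  n <- structure$n
  if (structure$identity) {
    v <- 1 / (1 + w)
    if (mean_only) return(b * v)
    return(b * v + stats::rnorm(n) * sqrt(v))
  }
  switch(structure$method,
    gp = {
      P <- .gp_Kinv(structure)
      diag(P) <- diag(P) + w
      R <- chol(P)
      mean <- backsolve(R, backsolve(R, b, transpose = TRUE))
      if (mean_only) return(as.numeric(mean))
      as.numeric(mean + backsolve(R, stats::rnorm(n)))
    },
    pgp = {
      U <- structure$U
      m <- ncol(U)
      Di <- 1 / structure$d_safe
      M <- diag(m) + crossprod(U, Di * U)
      Rm <- chol(M)
      G <- Di * t(backsolve(Rm, t(U), transpose = TRUE))   # D^-1 U Rm^-1
      D2 <- Di + w
      B <- G / D2
      N <- diag(m) - crossprod(G, B)
      t0 <- b / D2
      mean <- t0 + B %*% solve(N, crossprod(G, t0))
      if (mean_only) return(as.numeric(mean))
      Rn <- chol(N)
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(m)
      as.numeric(mean + z1 / sqrt(D2) + B %*% backsolve(Rn, z2))
    },
    nngp = {
      Q <- .nngp_Q(structure)
      ord <- structure$order
      P <- Q + Matrix::Diagonal(x = w[ord])
      ch <- Matrix::Cholesky(P, LDL = FALSE, perm = TRUE)
      mean <- Matrix::solve(ch, b[ord])
      if (mean_only) return(as.numeric(mean)[order(ord)])
      z <- stats::rnorm(n)
      dev <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt")
      out <- as.numeric(mean) + as.numeric(dev)
      out[order(ord)]
    })
}

#' Export a knot grid or NNGP neighbour graph as CSV
#'
#' @param structure a \code{jsdm_spatial} (pgp or nngp) or a knot-grid list.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_spatial_csv <- function(structure, path) {
  if (is.list(structure) && !is.null(structure$knots) && is.null(structure$method)) {
    utils::write.csv(data.frame(x = structure$knots[, 1], y = structure$knots[, 2]),
                     path, row.names = FALSE)
  } else if (structure$method == "pgp") {
    utils::write.csv(data.frame(x = structure$knots[, 1], y = structure$knots[, 2]),
                     path, row.names = FALSE)
  } else if (structure$method == "nngp") {
    s <- Matrix::summary(structure$A)
    io <- structure$order
    utils::write.csv(data.frame(unit = io[s$i], neighbour = io[s$j], weight = s$x),
                     path, row.names = FALSE)
  } else stop("no exportable spatial graph for this structure")
  invisible(path)
}
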