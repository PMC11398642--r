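# Spatial covariance structures: exact GP, predictive process, NNGP.

test_that("exponential kernel values, diagonal and degenerate cases", {
  co <- rbind(c(0, 0), c(3, 4))   # distance 5
  K <- exp_covariance(co, 2)
  expect_equal(K[1, 2], exp(-5 / 2))
  expect_equal(diag(K), c(1, 1))
  expect_equal(exp_covariance(co, 0), diag(2))
  expect_error(exp_covariance(co, -1), "alpha")
  expect_error(exp_covariance(rbind(c(0, 0), c(NA, 1)), 1), "finite")
})

test_that("the exponential kernel is positive definite on distinct points", {
  set.seed(21)
  co <- cbind(runif(30), runif(30))
  for (a in c(0.05, 0.3, 2)) {
    ev <- eigen(exp_covariance(co, a), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("hex_knot_grid hits the requested count and is translation-equivariant", {
  set.seed(22)
  co <- cbind(runif(200), runif(200))
  for (m in c(10, 55, 100)) {
    kg <- hex_knot_grid(co, m)
    expect_lte(abs(nrow(kg$knots) - m), 3)
  }
  kg1 <- hex_knot_grid(co, 40)
  kg2 <- hex_knot_grid(co + matrix(c(5, -3), 200, 2, byrow = TRUE), 40)
  expect_equal(kg2$knots - matrix(c(5, -3), nrow(kg2$knots), 2, byrow = TRUE),
               kg1$knots)
  # determinism and the single-knot centroid case
  expect_identical(hex_knot_grid(co, 40), hex_knot_grid(co, 40))
  kg0 <- hex_knot_grid(co, 1)
  expect_equal(kg0$knots, matrix(c(mean(range(co[, 1])), mean(range(co[, 2]))), 1, 2))
  expect_error(hex_knot_grid(matrix(1, 4, 2), 5), "bounding box")
})

test_that("pgp with knots = sites reproduces the exact GP covariance", {
  set.seed(23)
  co <- cbind(runif(25), runif(25))
  st <- pgp_structure(co, co, 0.3)
  K <- exp_covariance(co, 0.3)
  expect_lt(sqrt(sum((implied_covariance(st) - K)^2)), 1e-8)
})

test_that("pgp keeps unit marginal variances under a coarse knot grid", {
  set.seed(24)
  co <- cbind(runif(120), runif(120))
  kn <- hex_knot_grid(co, 20)$knots
  st <- pgp_structure(co, kn, 0.25)
  expect_equal(diag(implied_covariance(st)), rep(1, 120), tolerance = 1e-12)
  expect_error(pgp_structure(co, rbind(co, co), 0.25), "knot count")
  expect_error(pgp_structure(co, kn, 0), "alpha > 0")
})

test_that("nngp on a line with one neighbour matches the hand-computed AR factorization", {
  co <- rbind(c(0, 0), c(1, 0), c(2, 0))
  st <- nngp_structure(co, 1, 1)
  A <- as.matrix(st$A)
  expect_equal(A[2, 1], exp(-1))
  expect_equal(A[3, 2], exp(-1))
  expect_equal(A[3, 1], 0)
  expect_equal(st$d, c(1, 1 - exp(-2), 1 - exp(-2)))
  # the exponential kernel is Markov on a line, so 1 neighbour is exact
  expect_equal(implied_covariance(st), exp_covariance(co, 1), tolerance = 1e-12)
})

test_that("nngp with all predecessors as neighbours is the exact GP", {
  set.seed(25)
  co <- cbind(runif(25), runif(25))
  st <- nngp_structure(co, 0.3, 24)
  K <- exp_covariance(co, 0.3)
  v <- rnorm(25)
  expect_equal(gp_logdensity(st, v), dmvnorm_log(v, rep(0, 25), K),
               tolerance = 1e-6)
  expect_equal(implied_covariance(st), K, tolerance = 1e-8)
  expect_error(nngp_structure(co, 0.3, 25), "n_neighbours")
  expect_error(nngp_structure(co, 0, 5), "alpha > 0")
})

test_that("gp_logdensity agrees with the dense oracle under each method's own covariance", {
  set.seed(26)
  co <- cbind(runif(20), runif(20))
  kn <- hex_knot_grid(co, 8)$knots
  v <- rnorm(20)
  for (st in list(jsdmgibbs:::.gp_structure(co, 0.4),
                  pgp_structure(co, kn, 0.4),
                  nngp_structure(co, 0.4, 6))) {
    expect_equal(gp_logdensity(st, v),
                 dmvnorm_log(v, rep(0, 20), implied_covariance(st)),
                 tolerance = 1e-8)
  }
  idst <- jsdmgibbs:::.identity_structure(20, "gp")
  expect_equal(gp_logdensity(idst, v), dmvnorm_log(v, rep(0, 20), diag(20)))
  expect_error(gp_logdensity(idst, rnorm(3)), "dimension mismatch")
})

test_that("alpha = 0 degenerates every method to the identity structure", {
  set.seed(27)
  co <- cbind(runif(12), runif(12))
  for (method in c("gp", "pgp", "nngp")) {
    lev <- random_level(seq_len(12), method, coords = co, n_knots = 4,
                        n_neighbours = 3)
    st <- build_spatial_structure(lev, 0)
    expect_true(st$identity)
    expect_equal(implied_covariance(st), diag(12))
  }
})

test_that("draw_gp_conditional returns the exact conditional mean of N(P^-1 b, P^-1)", {
  set.seed(28)
  co <- cbind(runif(25), runif(25))
  kn <- hex_knot_grid(co, 10)$knots
  w <- runif(25) + 0.5
  b <- rnorm(25)
  oracle <- function(K) solve(solve(K) + diag(w), b)
  stg <- jsdmgibbs:::.gp_structure(co, 0.3)
  expect_equal(jsdmgibbs:::draw_gp_conditional(stg, w, b, mean_only = TRUE),
               as.numeric(oracle(implied_covariance(stg))), tolerance = 1e-9)
  stn <- nngp_structure(co, 0.3, 8)
  expect_equal(jsdmgibbs:::draw_gp_conditional(stn, w, b, mean_only = TRUE),
               as.numeric(oracle(implied_covariance(stn))), tolerance = 1e-9)
  # pgp is exact up to the 1e-10 floor on the diagonal correction, which at
  # knots = sites perturbs the conditional mean at the ~1e-6 level
  stp <- pgp_structure(co, kn, 0.3)
  expect_equal(jsdmgibbs:::draw_gp_conditional(stp, w, b, mean_only = TRUE),
               as.numeric(oracle(implied_covariance(stp))), tolerance = 1e-5)
  sti <- jsdmgibbs:::.identity_structure(25, "gp")
  expect_equal(jsdmgibbs:::draw_gp_conditional(sti, w, b, mean_only = TRUE),
               b / (1 + w))
})

test_that("draw_gp_conditional sampling moments match N(P^-1 b, P^-1)", {
  set.seed(29)
  co <- cbind(runif(10), runif(10))
  w <- runif(10) + 0.5
  b <- rnorm(10, 0, 2)
  st <- jsdmgibbs:::.gp_structure(co, 0.4)
  P <- solve(implied_covariance(st)) + diag(w)
  m_true <- solve(P, b)
  S_true <- solve(P)
  draws <- t(replicate(20000, jsdmgibbs:::draw_gp_conditional(st, w, b)))
  expect_lt(rel_err(colMeans(draws), m_true), 0.05)
  expect_lt(rel_err(cov(draws), S_true), 0.1)
})

test_that("write_spatial_csv exports knots and neighbour graphs", {
  set.seed(30)
  co <- cbind(runif(15), runif(15))
  kn <- hex_knot_grid(co, 5)$knots
  f1 <- tempfile(fileext = ".csv")
  write_spatial_csv(pgp_structure(co, kn, 0.3), f1)
  tab <- read.csv(f1)
  expect_identical(names(tab), c("x", "y"))
  expect_identical(nrow(tab), nrow(kn))
  f2 <- tempfile(fileext = ".csv")
  write_spatial_csv(nngp_structure(co, 0.3, 4), f2)
  g <- read.csv(f2)
  expect_identical(names(g), c("unit", "neighbour", "weight"))
  expect_true(all(g$unit != g$neighbour))
  unlink(c(f1, f2))
})
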