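# Model assembly, priors, and validation.

test_that("build_model assembles a valid model and prints a summary", {
  set.seed(1)
  Y <- matrix(rbinom(40, 1, 0.5), 10, 4,
              dimnames = list(NULL, paste0("sp", 1:4)))
  X <- cbind(1, rnorm(10))
  lev <- random_level(rep(1:5, each = 2), "none", n_factors = 2)
  m <- build_model(Y, X, levels = list(lev))
  expect_s3_class(m, "jsdm_model")
  expect_identical(c(m$n_y, m$n_s, m$n_c, m$n_t), c(10L, 4L, 2L, 1L))
  expect_identical(validate_model(m), character(0))
  expect_output(print(m), "10 units x 4 species")
  # a bare jsdm_level (not wrapped in a list) is accepted too
  m2 <- build_model(Y, X, levels = lev)
  expect_identical(m2$levels[[1]]$n_units, 5L)
})

test_that("dimension mismatches are reported naming both operands", {
  Y <- matrix(0, 10, 4); X <- cbind(1, rnorm(9))
  expect_error(build_model(Y, X), "Y has 10 rows but X has 9")
  X <- cbind(1, rnorm(10))
  Tr <- matrix(1, 3, 1)
  expect_error(build_model(Y, X, Tr), "4 species but Tr has 3 rows")
  C <- diag(3)
  expect_error(build_model(Y, X, C = C), "C is 3x3 but Y has 4 species")
})

test_that("non-positive-definite C is rejected with its smallest eigenvalue", {
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  X <- cbind(1, rnorm(10))
  C <- matrix(1, 3, 3)   # rank 1, eigenvalues (3, 0, 0)
  expect_error(build_model(Y, X, C = C), "not positive definite")
  expect_error(build_model(Y, X, C = C), "smallest eigenvalue")
})

test_that("probit response demands binary observed entries", {
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  Y[3, 2] <- 2
  X <- cbind(1, rnorm(10))
  expect_error(build_model(Y, X, response = "probit"), "\\{0, 1\\}")
  Y[3, 2] <- NA   # missing entries are allowed
  expect_s3_class(build_model(Y, X, response = "probit"), "jsdm_model")
})

test_that("default_priors has the documented shape", {
  pr <- default_priors(3, 2)
  expect_equal(pr$V0, diag(3))
  expect_equal(pr$f0, 4)
  expect_equal(pr$mGamma, rep(0, 6))
  expect_equal(pr$UGamma, diag(6))
  expect_length(pr$rho_grid$values, 101)
  expect_equal(pr$rho_grid$values[c(1, 51, 101)], c(0, 0.5, 1))
  expect_equal(sum(pr$rho_grid$weights), 1)
  expect_true(all(pr$rho_grid$weights == pr$rho_grid$weights[1]))
  expect_equal(pr$shrinkage, list(a1 = 50, b1 = 1, a2 = 50, b2 = 1))
  expect_equal(pr$nu, 3)
  expect_equal(pr$sigma_prior, list(aSigma = 1, bSigma = 0.3))
})

test_that("alpha grid spans 0.35 x the coordinate extent with half the mass at 0", {
  set.seed(2)
  co <- cbind(runif(20), runif(20))
  pr <- default_priors(2, 1, 20L, list(co), alpha_grid_n = 10)
  ag <- pr$alpha_grid[[1]]
  expect_length(ag$values, 11)
  expect_identical(ag$values[1], 0)
  expect_equal(max(ag$values), 0.35 * max(dist(co)))
  expect_equal(diff(ag$values[-1]), rep(ag$values[2], 9))   # equal spacing
  expect_equal(ag$weights[1], 0.5)
  expect_equal(sum(ag$weights), 1)
})

test_that("the alpha grid is invariant to translating and rotating the coordinates", {
  set.seed(3)
  co <- cbind(runif(15), runif(15))
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  co2 <- co %*% rot + matrix(c(100, -40), 15, 2, byrow = TRUE)
  a1 <- default_priors(2, 1, 15L, list(co))$alpha_grid[[1]]
  a2 <- default_priors(2, 1, 15L, list(co2))$alpha_grid[[1]]
  expect_equal(a1$values, a2$values)
  expect_equal(a1$weights, a2$weights)
})

test_that("degenerate coordinates cannot scale an alpha grid", {
  co <- matrix(1, 5, 2)
  expect_error(default_priors(2, 1, 5L, list(co)), "zero extent")
})

test_that("random_level maps units by first appearance and reorders coords by rownames", {
  asg <- c("b", "a", "b", "c", "a")
  lev <- random_level(asg, "none")
  expect_identical(lev$units, c("b", "a", "c"))
  expect_identical(lev$assignment, c(1L, 2L, 1L, 3L, 2L))
  co <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  lev2 <- random_level(asg, "gp", coords = co)
  expect_identical(rownames(lev2$coords), c("b", "a", "c"))
  expect_equal(lev2$coords["a", ], co["a", ])
})

test_that("a pgp level without explicit knots gets a hexagonal default grid", {
  set.seed(4)
  co <- cbind(runif(80), runif(80))
  lev <- random_level(seq_len(80), "pgp", coords = co, n_knots = 20)
  expect_false(is.null(lev$knots))
  expect_lte(abs(nrow(lev$knots) - 20), 3)
})

test_that("validate_model reports each violation without raising", {
  set.seed(5)
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  X <- cbind(1, rnorm(10))
  m <- build_model(Y, X)
  bad <- m
  bad$X[1, 1] <- 2
  expect_match(validate_model(bad), "intercept", all = FALSE)
  bad <- m
  bad$priors$rho_grid$weights <- rep(1, 101)
  expect_match(validate_model(bad), "sum to 1", all = FALSE)
  bad <- m
  bad$priors$f0 <- 0
  expect_match(validate_model(bad), "f0", all = FALSE)
  bad <- m
  bad$priors$shrinkage$a1 <- -1
  expect_match(validate_model(bad), "shrinkage", all = FALSE)
  bad <- m
  bad$priors$UGamma <- matrix(0, 2, 2)
  expect_match(validate_model(bad), "UGamma", all = FALSE)
  # spatial level without coordinates
  lev <- random_level(seq_len(10), "none", n_factors = 1)
  lev$spatial_method <- "gp"
  bad <- m
  bad$levels <- list(lev)
  expect_match(validate_model(bad), "requires coordinates", all = FALSE)
  # nngp neighbour bound
  co <- cbind(runif(10), runif(10))
  lev <- random_level(seq_len(10), "nngp", coords = co, n_neighbours = 10)
  bad <- m
  bad$levels <- list(lev)
  expect_match(validate_model(bad), "n_neighbours", all = FALSE)
})
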