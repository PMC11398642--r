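# Sampler mechanics: initialization, truncated-normal draws, bookkeeping,
# determinism, stream separation, and checkpoint/resume.  Distributional
# correctness of the conditional updates is covered in test-acceptance.R.

test_that("mcmc_config validates and total_cycles obeys the counting contract", {
  cfg <- mcmc_config(samples = 3, thin = 2, transient = 4)
  expect_identical(total_cycles(cfg), 10L)
  expect_identical(total_cycles(mcmc_config(1000, 100, 100000)), 200000L)
  expect_error(mcmc_config(0), "samples")
  expect_error(mcmc_config(10, thin = 0))
  expect_error(mcmc_config(10, transient = -1))
})

test_that("init_chain is deterministic and distinct across chain indices", {
  model <- tiny_probit_model()
  s1 <- init_chain(model, 5, 0)
  s2 <- init_chain(model, 5, 0)
  expect_identical(s1, s2)
  s3 <- init_chain(model, 5, 1)
  expect_false(identical(s1$levels[[1]]$Lambda, s3$levels[[1]]$Lambda))
  expect_false(identical(s1$Z, s3$Z))
  # documented initial values
  expect_equal(s1$Beta, matrix(0, model$n_c, model$n_s))
  expect_equal(s1$V, model$priors$V0)
  expect_equal(s1$sigma2, rep(1, model$n_s))
  expect_equal(s1$rho, 0)
  # Z is sign-consistent with Y
  obs <- !is.na(model$Y)
  expect_true(all((s1$Z[obs] > 0) == (model$Y[obs] == 1)))
})

test_that("truncated-normal Z draws have the analytic mean and respect the sign", {
  n <- 2e5
  L <- matrix(0, n, 1)
  u <- matrix(runif(n), n, 1)
  set.seed(31)
  z1 <- jsdmgibbs:::.draw_z(L, matrix(1, n, 1), 1, "probit", u)
  expect_true(all(z1 > 0))
  # E[Z | Z > 0] for Z ~ N(0,1) is dnorm(0)/pnorm(0) = sqrt(2/pi)
  expect_equal(mean(z1), sqrt(2 / pi), tolerance = 0.01)
  z0 <- jsdmgibbs:::.draw_z(L, matrix(0, n, 1), 1, "probit", u)
  expect_true(all(z0 < 0))
  expect_equal(mean(z0), -sqrt(2 / pi), tolerance = 0.01)
  # truncation holds away from zero too
  L2 <- matrix(-3, n, 1)
  expect_true(all(jsdmgibbs:::.draw_z(L2, matrix(1, n, 1), 1, "probit", u) > 0))
  # missing entries are untruncated around L
  zm <- jsdmgibbs:::.draw_z(L2, matrix(NA_real_, n, 1), 1, "probit", u)
  expect_equal(mean(zm), -3, tolerance = 0.01)
  expect_equal(sd(zm), 1, tolerance = 0.01)
})

test_that("normal-response Z equals Y where observed and is imputed where missing", {
  model <- tiny_probit_model()
  Y <- matrix(rnorm(model$n_y * model$n_s), model$n_y, model$n_s)
  Y[1, 1] <- NA
  m2 <- build_model(Y, model$X, model$Tr, NULL, model$levels, response = "normal")
  st <- init_chain(m2, 3, 0)
  st <- update_z(st, m2)
  obs <- !is.na(Y)
  expect_identical(st$Z[obs], Y[obs])
  expect_true(is.finite(st$Z[1, 1]))
})

test_that("run_chain executes the documented schedule and snapshots", {
  model <- tiny_probit_model()
  cfg <- mcmc_config(samples = 3, thin = 2, transient = 4, seed = 9)
  ch <- run_chain(model, cfg)
  expect_identical(ch$cycles_done, 10L)
  expect_identical(ch$n_retained, 3L)
  expect_true(ch$complete)
  expect_identical(dim(ch$draws$Beta), c(3L, model$n_c, model$n_s))
  expect_false(anyNA(ch$draws$Beta))
  expect_length(ch$timings, 10)
  # snapshots are distinct states
  expect_false(identical(ch$draws$Beta[1, , ], ch$draws$Beta[2, , ]))
  dr <- run_chain(model, cfg, dry_run = TRUE)
  expect_identical(dr$cycles_scheduled, 10L)
})

test_that("identical configuration reruns are bit-identical; chains are distinct streams", {
  model <- tiny_probit_model()
  cfg <- mcmc_config(samples = 5, thin = 1, transient = 2, n_chains = 2, seed = 4)
  a <- run_chain(model, cfg, 0)
  b <- run_chain(model, cfg, 0)
  expect_identical(a$draws, b$draws)
  expect_identical(a$state, b$state)
  c2 <- run_chain(model, cfg, 1)
  expect_false(identical(a$draws$Beta, c2$draws$Beta))
  expect_false(identical(init_chain(model, 4, 0)$Z, init_chain(model, 4, 1)$Z))
  expect_error(run_chain(model, cfg, 2), "chain_index")
})

test_that("an interrupted-and-resumed chain equals an uninterrupted one", {
  model <- tiny_probit_model()
  cfg <- mcmc_config(samples = 6, thin = 2, transient = 3, seed = 12)
  full <- run_chain(model, cfg)
  part <- run_chain(model, cfg, stop_after = 7)
  expect_false(part$complete)
  expect_identical(part$cycles_done, 7L)
  resumed <- run_chain(model, cfg, checkpoint = part)
  expect_identical(resumed$draws, full$draws)
  expect_identical(resumed$state, full$state)
  expect_identical(resumed$cycles_done, 15L)
})

test_that("run_chains_parallel returns chains ordered by index and propagates failures", {
  model <- tiny_probit_model()
  cfg <- mcmc_config(samples = 3, thin = 1, transient = 1, n_chains = 3, seed = 2)
  chains <- run_chains_parallel(model, cfg)
  expect_length(chains, 3)
  expect_identical(vapply(chains, function(ch) ch$chain_index, integer(1)), 0:2)
  expect_identical(chains[[2]]$draws, run_chain(model, cfg, 1)$draws)
})

test_that("a failing Gibbs block is named in the error", {
  model <- tiny_probit_model()
  st <- init_chain(model, 1, 0)
  st$Beta[1, 1] <- Inf
  expect_error(gibbs_cycle(st, model), "Gibbs block 'z' failed at cycle 1")
  expect_error(gibbs_cycle(st, model), "non-finite linear predictor")
})

test_that("probit models keep sigma fixed at 1 and rho untouched without C", {
  model <- tiny_probit_model()
  cfg <- mcmc_config(samples = 4, thin = 1, transient = 2, seed = 3)
  ch <- run_chain(model, cfg)
  expect_true(all(ch$draws$sigma2 == 1))
  expect_true(all(ch$draws$rho == 0))
})

test_that("rho moves across its grid when a species correlation is present", {
  model <- tiny_probit_model(n_y = 40, n_s = 8, with_C = TRUE, seed = 14)
  cfg <- mcmc_config(samples = 30, thin = 1, transient = 5, seed = 8)
  ch <- run_chain(model, cfg)
  expect_true(all(ch$draws$rho %in% model$priors$rho_grid$values))
  expect_gt(length(unique(ch$draws$rho)), 1)
})

test_that("normal response updates sigma from its inverse-gamma conditional", {
  set.seed(33)
  ds <- generate_dataset(50, 4, level_spec = list(spatial_method = "none",
                                                  n_factors = 1),
                         response = "normal", seed = 20)
  model <- build_model(ds$data$Y, ds$data$X, ds$data$Tr, NULL, list(ds$level),
                       response = "normal")
  cfg <- mcmc_config(samples = 10, thin = 1, transient = 5, seed = 6)
  ch <- run_chain(model, cfg)
  expect_true(all(ch$draws$sigma2 > 0))
  expect_gt(length(unique(as.numeric(ch$draws$sigma2))), 1)
})

test_that("spatial levels run end to end for every method and alpha stays on the grid", {
  for (method in c("gp", "pgp", "nngp")) {
    model <- tiny_spatial_model(method)
    cfg <- mcmc_config(samples = 5, thin = 1, transient = 3, seed = 10)
    ch <- run_chain(model, cfg)
    ag <- model$priors$alpha_grid[[1]]
    expect_true(all(ch$draws$levels[[1]]$alpha %in% ag$values))
    expect_false(anyNA(ch$draws$levels[[1]]$Eta))
  }
})

test_that("update_eta leaves other blocks untouched and matches dimensions", {
  model <- tiny_spatial_model("nngp")
  st <- init_chain(model, 2, 0)
  st <- update_z(st, model)
  st2 <- update_eta(st, model, 1)
  expect_identical(st2$Beta, st$Beta)
  expect_identical(dim(st2$levels[[1]]$Eta),
                   c(model$levels[[1]]$n_units, model$levels[[1]]$n_factors))
  expect_false(identical(st2$levels[[1]]$Eta, st$levels[[1]]$Eta))
})
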