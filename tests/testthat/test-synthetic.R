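# Synthetic community generator, rare-species filter, nested subsampling.

test_that("the same seed reproduces the dataset bit for bit", {
  a <- generate_dataset(40, 6, seed = 99, use_taxonomy = TRUE)
  b <- generate_dataset(40, 6, seed = 99, use_taxonomy = TRUE)
  expect_identical(a, b)
  c2 <- generate_dataset(40, 6, seed = 100, use_taxonomy = TRUE)
  expect_false(identical(a$data$Y, c2$data$Y))
})

test_that("generated probit data have the documented shape and range", {
  ds <- generate_dataset(100, 40, response = "probit", seed = 1)
  expect_identical(dim(ds$data$Y), c(100L, 40L))
  expect_true(all(ds$data$Y %in% c(0, 1)))
  expect_identical(ds$data$X[, 1], setNames(rep(1, 100), rownames(ds$data$X)))
  expect_true(all(ds$data$Tr[, -1] %in% c(0, 1)))
  expect_s3_class(ds$truth, "jsdm_truth")
  prev <- mean(ds$data$Y)
  expect_gt(prev, 0); expect_lt(prev, 1)
})

test_that("prevalence matches the probit link for pinned intercepts", {
  for (b in c(-1, 0, 1)) {
    n_y <- 500; n_s <- 20
    Beta <- rbind(rep(b, n_s), matrix(0, 2, n_s))
    ds <- generate_dataset(n_y, n_s, n_c = 3,
                           level_spec = list(spatial_method = "none",
                                             n_factors = 1),
                           response = "probit", seed = 7 + b,
                           truth_overrides = list(
                             Beta = Beta,
                             Lambda = matrix(0, 1, n_s),
                             sigma2 = rep(1, n_s)))
    prev <- mean(ds$data$Y)
    se <- sqrt(pnorm(b) * (1 - pnorm(b)) / (n_y * n_s))
    # entries share no structure here, so binomial error applies
    expect_lt(abs(prev - pnorm(b)), 5 * se + 0.005)
  }
})

test_that("taxonomy-driven coefficients show the prior's correlation ordering", {
  # many covariate rows so empirical cross-species correlations of the
  # centred coefficients are estimable; V = I isolates the species factor
  n_c <- 60; n_s <- 30
  ds <- generate_dataset(10, n_s, n_c = n_c, n_t = 1,
                         level_spec = NULL, response = "normal", seed = 17,
                         use_taxonomy = TRUE,
                         truth_overrides = list(V = diag(n_c), rho = 0.5))
  E <- ds$truth$Beta - ds$truth$Gamma %*% t(ds$data$Tr)
  R <- cor(E)
  C <- ds$data$C
  same_gen <- C == 2 / 3 & upper.tri(C)
  same_fam <- abs(C - 1 / 3) < 1e-12 & upper.tri(C)
  diff_fam <- C == 0 & upper.tri(C)
  expect_gt(sum(same_gen), 0); expect_gt(sum(same_fam), 0); expect_gt(sum(diff_fam), 0)
  # expected correlations: rho * C = 1/3, 1/6, 0 (absolute tolerances;
  # per-pair sample correlations over 60 rows have s.e. ~ 0.13)
  expect_lt(abs(mean(R[same_gen]) - 0.5 * 2 / 3), 0.1)
  expect_lt(abs(mean(R[same_fam]) - 0.5 * 1 / 3), 0.1)
  expect_lt(abs(mean(R[diff_fam])), 0.1)
  expect_gt(mean(R[same_gen]), mean(R[same_fam]))
  expect_gt(mean(R[same_fam]), mean(R[diff_fam]))
})

test_that("filter_rare_species applies a strict 'fewer than' rule", {
  Y <- cbind(c(1, 1, 1, 1, 1, 0),   # 5 occurrences
             c(1, 1, 1, 1, 0, 0),   # 4
             c(0, 0, 0, 0, 0, 0))   # 0
  out <- filter_rare_species(Y, 5)
  expect_identical(out$kept, 1L)
  expect_identical(ncol(out$Y), 1L)
  out0 <- filter_rare_species(Y, 0)
  expect_identical(out0$kept, 1:3)
  expect_identical(out0$Y, Y)
  expect_error(filter_rare_species(Y, 10), "below the occurrence threshold")
  # NA entries are ignored in the count: column 1 drops to 4 occurrences
  Yna <- Y; Yna[1, 1] <- NA
  expect_error(filter_rare_species(Yna, 5), "below the occurrence threshold")
  expect_identical(filter_rare_species(Yna, 4)$kept, c(1L, 2L))
})

test_that("subsample_grid is nested, exact-sized, and keeps alignment", {
  ds <- generate_dataset(200, 60, seed = 5, use_taxonomy = TRUE,
                         level_spec = list(spatial_method = "gp", alpha = 0.2,
                                           n_factors = 2))
  subs <- subsample_grid(ds, n_s_list = c(20, 40), n_y_list = c(50, 100),
                         seed = 3)
  expect_length(subs, 4)
  s1 <- subs[["ns20_ny50"]]; s2 <- subs[["ns40_ny100"]]
  expect_identical(dim(s1$data$Y), c(50L, 20L))
  expect_identical(dim(s2$data$Y), c(100L, 40L))
  expect_true(all(s1$sub$rows %in% s2$sub$rows))
  expect_true(all(s1$sub$cols %in% s2$sub$cols))
  # alignment: traits, taxonomy and C follow the species subset
  expect_identical(colnames(s1$data$Y), rownames(s1$data$Tr))
  expect_identical(colnames(s1$data$Y), s1$data$taxonomy$species)
  expect_equal(unname(s1$data$C),
               unname(taxonomy_to_correlation(s1$data$taxonomy)))
  # coordinates follow the site subset
  expect_identical(rownames(s1$data$Y), s1$design$unit)
  expect_identical(s1$level$n_units, 50L)
  # requesting the full sizes returns the dataset itself
  full <- subsample_grid(ds, 60, 200, seed = 3)[[1]]
  expect_identical(full$data$Y, ds$data$Y)
  expect_error(subsample_grid(ds, 61, 200), "more species")
  expect_error(subsample_grid(ds, 60, 201), "more sites")
})

test_that("fitting generated data is consistent: model builds and validates", {
  ds <- generate_dataset(60, 10, seed = 8, use_taxonomy = TRUE,
                         level_spec = list(spatial_method = "nngp",
                                           n_factors = 2, alpha = 0.25,
                                           n_neighbours = 8))
  m <- build_model(ds$data$Y, ds$data$X, ds$data$Tr, ds$data$C,
                   list(ds$level), response = "probit")
  expect_identical(validate_model(m), character(0))
})
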