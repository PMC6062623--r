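# Synthetic generator: covariance construction, PSD repair, sampling
# fidelity and determinism.

test_that("state covariance reproduces the requested block structure", {
  part <- rep(1:2, each = 3)
  spec <- state_spec("s", rho_within = 0.6, rho_between = 0.1)
  cmat <- build_state_covariance(part, spec)
  expect_equal(diag(cmat), rep(1, 6))
  within <- cmat[1:3, 1:3][upper.tri(diag(3))]
  between <- cmat[1:3, 4:6]
  expect_true(all(abs(within - 0.6) < 1e-12))
  expect_true(all(abs(between - 0.1) < 1e-12))
  expect_identical(cmat, t(cmat))
})

test_that("zero-correlation spec yields the identity", {
  part <- rep(1:2, each = 3)
  spec <- state_spec("null", 0, 0, hub_cross = 0, hub_local = 0)
  cmat <- build_state_covariance(part, spec, hub_nodes = 1L)
  expect_equal(unclass(cmat), diag(6), ignore_attr = TRUE)
  expect_equal(attr(cmat, "ridge"), 0)
})

test_that("hub rows split correlation mass by hub_cross", {
  part <- rep(1:2, each = 4)
  spec <- state_spec("s", 0.5, 0.1, hub_cross = 0.8, hub_local = 0.5)
  cmat <- build_state_covariance(part, spec, hub_nodes = 1L)
  expect_equal(unname(cmat[1, 2]), (1 - 0.8) * 0.5)   # own module
  expect_equal(unname(cmat[1, 5]), 0.8 * 0.5)         # foreign module
})

test_that("every emitted covariance is PSD after ridge repair", {
  specs <- list(
    state_spec("a", 0.9, 0.0, 0.9, 0.9),
    state_spec("b", 0.7, 0.65, 0.5, 0.8),
    state_spec("c", 0.99, 0.99, 1.0, 0.99))
  part <- rep(1:4, each = 5)
  for (sp in specs) {
    cmat <- try(build_state_covariance(part, sp, hub_nodes = c(1L, 6L)),
                silent = TRUE)
    if (inherits(cmat, "try-error")) next  # rejected as infeasible: allowed
    ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(diag(cmat), rep(1, 20))
  }
})

test_that("degenerate module layouts are rejected", {
  spec <- state_spec("s", 0.5, 0.1)
  expect_error(build_state_covariance(rep(1, 6), spec), "2 modules")
  expect_error(build_state_covariance(c(1, 1, 1, 2), spec), "at least 2 nodes")
  expect_error(build_state_covariance(rep(1:2, 3), spec, hub_nodes = 99L),
               "hub_nodes")
})

test_that("in-block samples follow the planted correlation", {
  # long single-condition design, no noise: empirical within-module r ~ 0.6
  blocks <- data.frame(onset = 0, duration = 4000, trial_type = "low",
                       rating = 2L)
  design <- as_design(blocks, tr = 2, n_volumes = 2000)
  states <- list(low = state_spec("low", 0.6, 0.0))
  d <- simulate_subject(design, states, n_nodes = 12, n_modules = 2,
                        hub_nodes = integer(), noise_sd = 0,
                        drift_amplitude = 0, seed = 5)
  r <- cor(d$series)
  within <- c(r[1:6, 1:6][upper.tri(diag(6))], r[7:12, 7:12][upper.tri(diag(6))])
  expect_lt(abs(mean(within) - 0.6), 0.05)
})

test_that("identity covariance gives near-zero sample correlations", {
  blocks <- data.frame(onset = 0, duration = 1000, trial_type = "low",
                       rating = 2L)
  design <- as_design(blocks, tr = 2, n_volumes = 500)
  states <- list(low = state_spec("low", 0, 0))
  d <- simulate_subject(design, states, n_nodes = 10, n_modules = 2,
                        hub_nodes = integer(), noise_sd = 0,
                        drift_amplitude = 0, seed = 11)
  r <- cor(d$series)
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)
})

test_that("simulation is a pure function of configuration and seed", {
  design <- default_design(n_volumes = 120)
  a <- simulate_subject(design, seed = 33, n_nodes = 20, n_modules = 2)
  b <- simulate_subject(design, seed = 33, n_nodes = 20, n_modules = 2)
  expect_identical(a$series, b$series)
  expect_identical(a$noise_sources, b$noise_sources)
  c2 <- simulate_subject(design, seed = 34, n_nodes = 20, n_modules = 2)
  expect_false(identical(a$series, c2$series))
})

test_that("unknown block condition is reported by name", {
  blocks <- data.frame(onset = 0, duration = 30, trial_type = "mystery",
                       rating = 2L)
  design <- as_design(blocks, tr = 2, n_volumes = 60)
  expect_error(simulate_subject(design, seed = 1), "mystery")
})

test_that("cohorts share ground truth but differ per subject", {
  coh <- tiny_cohort(n_subjects = 3, seed = 77)
  expect_length(coh, 3)
  expect_identical(coh[[1]]$partition_truth, coh[[2]]$partition_truth)
  expect_identical(coh[[1]]$hub_nodes, coh[[3]]$hub_nodes)
  expect_false(identical(coh[[1]]$series, coh[[2]]$series))
  # derived seeds reproducible, and forcing equal seeds gives equal data
  expect_identical(derive_seeds(77, 3), derive_seeds(77, 3))
  d1 <- simulate_subject(coh[[1]]$design, seed = 123, n_nodes = 24,
                         n_modules = 3)
  d2 <- simulate_subject(coh[[2]]$design, seed = 123, n_nodes = 24,
                         n_modules = 3)
  expect_identical(d1$series, d2$series)
})

test_that("design validation enforces block geometry and ratings", {
  expect_error(as_design(data.frame(onset = c(0, 10), duration = 20,
                                    trial_type = "low", rating = 2L),
                         tr = 2, n_volumes = 100), "overlap")
  expect_error(as_design(data.frame(onset = 0, duration = 300,
                                    trial_type = "low", rating = 2L),
                         tr = 2, n_volumes = 100), "past the end")
  expect_error(as_design(data.frame(onset = 0, duration = 10,
                                    trial_type = "low", rating = 7L),
                         tr = 2, n_volumes = 100), "ratings")
})
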