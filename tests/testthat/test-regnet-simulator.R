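# one calibrated model shared across the file (construction is checked once)
model <- build_regnet_model()

test_that("model construction enforces the eigenvalue crossing at p = 0", {
  expect_s3_class(model, "regnet_model")
  expect_lt(regnet_lambda_max(model, -0.5), 0)
  expect_lt(abs(regnet_lambda_max(model, 0)), 1e-3)
  # monotone approach to the crossing
  expect_gt(regnet_lambda_max(model, -0.01), regnet_lambda_max(model, -0.4))
  lam <- model$lambda_check
  expect_true(all(lam$lambda_max[lam$p < -0.05] < 0))
})

test_that("equilibrium matches the scalar core reduction", {
  # symmetric core: z solves (n_core-1)*beta*H(z) + b - (d_core - p)*z = 0
  for (p in c(-0.5, -0.2, -0.05)) {
    z <- regnet_equilibrium(model, p)
    d <- model$d_core - p
    root <- uniroot(function(u) {
      2 * model$beta * u^2 / (model$S^2 + u^2) + 0.1 - d * u
    }, c(1e-6, model$z_fold), tol = 1e-14)$root
    expect_equal(unname(z[1]), root, tolerance = 1e-6)
    expect_equal(z[1], z[2], tolerance = 1e-8)
    # drift vanishes at the equilibrium
    expect_lt(max(abs(regnet_drift(model, z, p))), 1e-6)
  }
})

test_that("stationary sampler is exact when noiseless and reproducible", {
  z_star <- regnet_equilibrium(model, -0.3)
  s0 <- stationary_sample(model, -0.3, 5, seed = 1, noise_sd = 0)
  expect_equal(unname(s0), matrix(rep(z_star, each = 5), nrow = 5),
               tolerance = 1e-12)
  s1 <- stationary_sample(model, -0.3, 100, seed = 2)
  s2 <- stationary_sample(model, -0.3, 100, seed = 2)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0))
  expect_error(stationary_sample(model, 0.1, 10, seed = 1), "lambda_max")
})

test_that("core variance inflates near the tipping point", {
  far <- stationary_sample(model, -0.5, 200, seed = 3)
  near <- stationary_sample(model, -0.05, 200, seed = 3)
  expect_gt(mean(apply(near[, 1:3], 2, var)),
            2 * mean(apply(far[, 1:3], 2, var)))
})

test_that("stationary covariance matches a large empirical sample", {
  z_star <- regnet_equilibrium(model, -0.3)
  J <- miwe:::.regnet_jacobian(model, z_star, -0.3)
  Sigma <- miwe:::.solve_lyapunov(J, model$noise_sd^2 * diag(model$n))
  s <- stationary_sample(model, -0.3, 10000, seed = 4)
  emp <- cov(s)
  rel <- norm(emp - Sigma, "F") / norm(Sigma, "F")
  expect_lt(rel, 0.1)
})

test_that("Euler-Maruyama integrates to the equilibrium and past the tipping", {
  z_star <- regnet_equilibrium(model, -0.5)
  end <- euler_maruyama_sample(model, -0.5, 3, seed = 5, dt = 0.005,
                               burn_in = 80, noise_sd = 0)
  expect_lt(max(abs(sweep(end, 2, z_star))), 1e-4)

  e1 <- euler_maruyama_sample(model, 0.2, 20, seed = 6)
  e2 <- euler_maruyama_sample(model, 0.2, 20, seed = 6)
  expect_identical(e1, e2)
  # past the tipping point the core settles far above the old low state
  expect_gt(mean(e1[, 1:3]), 5 * z_star[1])
  expect_lt(suppressWarnings(
    t.test(e1[, 1], mu = z_star[1])$p.value), 1e-6)
})

test_that("sweep produces a staged set on the default grid", {
  sw <- sweep_parameter(model, n = 10, seed = 7)
  expect_identical(length(sw$set$stages), 16L)
  expect_identical(ncol(sw$set$values), 160L)
  expect_true(0 %in% sw$p_values)
  expect_true(all(sw$set$values >= 0))
  expect_identical(unname(sw$backend_used[sw$p_values < -0.01]),
                   rep("stationary", sum(sw$p_values < -0.01)))
  # a grid spanning 0 without containing it is rejected
  expect_error(sweep_parameter(model, grid = c(-0.2, -0.1, 0.1), n = 5),
               "include p = 0")
  # observation noise adds variance but keeps values nonnegative
  swo <- sweep_parameter(model, n = 10, seed = 7, obs_noise_sd = 0.2)
  expect_true(all(swo$set$values >= 0))
  expect_gt(var(as.numeric(swo$set$values[, 1:10])),
            var(as.numeric(sw$set$values[, 1:10])))
})

test_that("pipeline recovers the tipping point and stays quiet off-transition", {
  sw <- sweep_parameter(model, n = 50, seed = 11)
  out <- run_sweep_pipeline(sw)
  expect_identical(out$detected_p, 0)

  # scores are strictly larger at the tipping stage than deep in the
  # sub-critical regime
  series <- out$fit$series
  expect_gt(series[names(which(sw$p_values == 0))],
            series[names(which(sw$p_values == -0.5))])

  # sub-critical sweeps rarely trigger a detection (statistical property)
  quiet <- vapply(1:6, function(r) {
    sub <- sweep_parameter(model, grid = (-10:-6) / 20, n = 50,
                           seed = 30 + r)
    is.na(run_sweep_pipeline(sub)$detected_p)
  }, logical(1L))
  expect_gte(mean(quiet), 5 / 6)
})

test_that("robustness harness reports success fractions without error", {
  rb <- robustness_harness(model, noise_levels = c(0, 10),
                           replicates = 2, seed = 21, n = 30)
  expect_identical(rb$success_fraction[rb$noise_sd == 0], 1)
  expect_true(all(rb$success_fraction >= 0 & rb$success_fraction <= 1))
  expect_identical(rb$replicates, rep(2L, 2L))
})
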