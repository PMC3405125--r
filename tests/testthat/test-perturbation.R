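test_that("the tangent system is exactly linear in the initial impulse", {
  spec <- lattice_spec(8)
  nt <- noise_spec(0.3, seed = 21)
  a <- tangent_propagate(spec, nt, T = 2, amplitude = 1, save_delta = FALSE)
  b <- tangent_propagate(spec, nt, T = 2, amplitude = 3, save_delta = FALSE)
  expect_equal(b$site_max, 3 * a$site_max, tolerance = 1e-12)
  expect_equal(b$delta_norms, 3 * a$delta_norms, tolerance = 1e-12)
})

test_that("with a quiescent background the perturbation is the linear response", {
  spec <- lattice_spec(16)
  run <- tangent_propagate(spec, noise_spec(0, dt = 1e-3), T = 2, stride = 2000L)
  ref <- linear_propagate(spec, impulse_state(spec), 2)
  expect_lt(max(abs(run$delta[nrow(run$delta), ] - ref)), 2e-3)
})

test_that("frozen uniform background gives the exp(-3vt)-damped linear response", {
  spec <- lattice_spec(16)
  v <- 0.2
  run <- tangent_propagate(spec, noise_spec(0, dt = 1e-4), T = 1,
                           frozen_sq = v, stride = 2500L)
  d0 <- impulse_state(spec)
  for (i in 2:nrow(run$delta)) {
    t <- run$delta_save_times[i]
    ref <- exp(-3 * v * t) * linear_propagate(spec, d0, t)
    expect_lt(max(abs(run$delta[i, ] - ref)) / max(abs(ref)), 1e-3)
  }
  # nonnegative damping can only shrink the perturbation norm
  expect_lte(max(run$delta_norms), run$delta_norms[1] + 1e-12)
})

test_that("twin-trajectory differencing agrees with the tangent system", {
  spec <- lattice_spec(16)
  nt <- noise_spec(0.2, seed = 11)
  a <- tangent_propagate(spec, nt, T = 4, save_delta = FALSE)
  b <- tangent_propagate(spec, nt, T = 4, save_delta = FALSE,
                         method = "twin", eps = 1e-5)
  expect_lt(max(abs(a$site_max - b$site_max)) / max(a$site_max), 1e-6)
})

test_that("perturbations stay bounded over the horizon in stochastic runs", {
  spec <- lattice_spec(16)
  run <- tangent_propagate(spec, noise_spec(0.4, seed = 3), save_delta = FALSE)
  expect_true(all(is.finite(run$delta_norms)))
  expect_lte(max(run$delta_norms), run$delta_norms[1] * 1.5)
})

test_that("attenuation profiles average runs and keep the impulse at the centre", {
  spec <- lattice_spec(16)
  sh <- distance_shells(spec)
  r1 <- tangent_propagate(spec, noise_spec(0.2, seed = 1), save_delta = FALSE)
  r2 <- tangent_propagate(spec, noise_spec(0.2, seed = 2), save_delta = FALSE)
  p1 <- attenuation_profile(r1, sh)
  p2 <- attenuation_profile(r2, sh)
  p12 <- attenuation_profile(list(r1, r2), sh)
  expect_equal(p12$M, (p1$M + p2$M) / 2)        # definitionally the mean
  expect_gte(p1$M[1], 1)                        # centre includes t = 0 impulse
  lin <- tangent_propagate(spec, noise_spec(0), save_delta = FALSE)
  expect_true(all(attenuation_profile(lin, sh)$M > 0))
  r3 <- tangent_propagate(spec, noise_spec(0.4, seed = 1), save_delta = FALSE)
  expect_error(attenuation_profile(list(r1, r3), sh), "share")
})

test_that("exponential profiles are recovered exactly and power laws identified", {
  r <- 1:30
  fe <- fit_attenuation(synthetic_profile(r, exp(-r / 5)))
  expect_equal(fe$lam, 5, tolerance = 1e-6)
  expect_equal(fe$kappa, 0.2, tolerance = 1e-6)
  expect_identical(fe$preferred, "exponential")
  fp <- fit_attenuation(synthetic_profile(r, r^(-0.5)))
  expect_lt(fp$r_squared, fp$r_squared_power)
  expect_identical(fp$preferred, "power")
  expect_equal(fp$alpha, 0.5, tolerance = 1e-6)
})

test_that("degenerate profiles raise diagnostics instead of silent fits", {
  expect_error(fit_attenuation(synthetic_profile(1:30, rep(1e-15, 30))),
               "floor")
  expect_error(fit_attenuation(synthetic_profile(1:3, exp(-(1:3)))),
               "fewer than 4")
})

test_that("per-eta seeding isolates rows from grid order", {
  spec <- lattice_spec(16)
  fwd <- range_vs_input(spec, c(0.1, 0.3), n_realizations = 1, seed = 5,
                        burn_in = 10)
  rev <- range_vs_input(spec, c(0.3, 0.1), n_realizations = 1, seed = 5,
                        burn_in = 10)
  for (eta in c(0.1, 0.3)) {
    i <- which(fwd$summary$eta == eta)
    j <- which(rev$summary$eta == eta)
    expect_identical(fwd$summary$lambda[i], rev$summary$lambda[j])
    expect_identical(fwd$summary$kappa[i], rev$summary$kappa[j])
  }
})

test_that("the decay-rate estimator recovers a frozen damping coefficient", {
  spec <- lattice_spec(16)
  run <- tangent_propagate(spec, noise_spec(0, dt = 1e-3), T = 2,
                           frozen_sq = 0.3, save_delta = FALSE)
  dr <- delta_decay_rate(run)
  expect_equal(dr$rate, 3 * 0.3, tolerance = 0.02)
  expect_gt(dr$r_squared, 0.99)
})
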