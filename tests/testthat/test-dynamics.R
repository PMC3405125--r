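test_that("noise and step validation guard the integrator", {
  expect_error(noise_spec(-0.1), ">= 0")
  expect_error(noise_spec(0.1, dt = 0), "positive")
  expect_error(simulate_lattice(lattice_spec(4), noise_spec(0, dt = 0.2), T = 1),
               "dt")
  # overflow guard names dt and g
  expect_error(simulate_lattice(lattice_spec(4), noise_spec(0, dt = 0.01),
                                x0 = rep(1e4, 16), T = 1),
               "unstable")
})

test_that("the quiescent lattice is a fixed point and seeds give determinism", {
  spec <- lattice_spec(8)
  tr <- simulate_lattice(spec, noise_spec(0, seed = 3), T = 2)
  expect_true(all(tr$states == 0))
  a <- simulate_lattice(spec, noise_spec(0.3, seed = 9), T = 2)
  b <- simulate_lattice(spec, noise_spec(0.3, seed = 9), T = 2)
  expect_identical(a$states, b$states)          # bit-identical under same seed
  c2 <- simulate_lattice(spec, noise_spec(0.3, seed = 10), T = 2)
  expect_false(identical(a$states, c2$states))
  expect_false(anyNA(a$states))
  expect_equal(diff(a$times), rep(a$noise$dt * 10, length(a$times) - 1))
})

test_that("small-amplitude nonlinear evolution matches the spectral oracle", {
  spec <- lattice_spec(16)
  amp <- 0.01
  x0 <- impulse_state(spec, amplitude = amp)
  tr <- simulate_lattice(spec, noise_spec(0, dt = 2e-4), x0 = x0, T = 2,
                         stride = 10000L)
  ref <- amp * linear_propagate(spec, impulse_state(spec), 2)
  expect_lt(max(abs(tr$states[2, ] - ref)), 1e-3 * amp)
})

test_that("response is linear in the impulse while amplitudes stay small", {
  spec <- lattice_spec(16)
  t1 <- simulate_lattice(spec, noise_spec(0, dt = 1e-3),
                         x0 = impulse_state(spec, 1e-2), T = 2, stride = 2000L)
  t2 <- simulate_lattice(spec, noise_spec(0, dt = 1e-3),
                         x0 = impulse_state(spec, 1e-3), T = 2, stride = 2000L)
  rel <- max(abs(t1$states[2, ] - 10 * t2$states[2, ])) / max(abs(t1$states[2, ]))
  expect_lt(rel, 0.01)
})

test_that("halving dt shrinks the endpoint error consistently (strong order 1)", {
  spec <- lattice_spec(8)
  x0 <- impulse_state(spec)
  ref <- linear_propagate(spec, x0, 2)
  errs <- sapply(c(4e-3, 2e-3), function(dt) {
    tr <- simulate_lattice(spec, noise_spec(0, dt = dt), x0 = x0, T = 2,
                           stride = round(2 / dt), cubic = FALSE)
    max(abs(tr$states[2, ] - ref))
  })
  expect_lt(errs[2], errs[1])
  expect_gt(errs[1] / errs[2], 1.5)
  expect_lt(errs[1] / errs[2], 3)
})

test_that("with the cubic term on and no input the norm never grows", {
  spec <- lattice_spec(8)
  tr <- simulate_lattice(spec, noise_spec(0, dt = 5e-3),
                         x0 = impulse_state(spec, 2), T = 5, stride = 20L)
  norms <- sqrt(rowSums(tr$states^2))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("stationary variance averages correctly and grows with input", {
  spec <- lattice_spec(16)
  zero <- simulate_lattice(spec, noise_spec(0), T = 60)
  expect_identical(stationary_variance(zero)$variance, 0)
  const <- structure(list(times = seq(0, 60, by = 1),
                          states = matrix(0.7, 61, spec$n_sites),
                          spec = spec, noise = noise_spec(0)),
                     class = "lattice_trajectory")
  expect_equal(stationary_variance(const)$variance, 0.49)
  expect_error(stationary_variance(zero, burn_in = 100), "burn_in")
  vs <- sapply(c(0.05, 0.1, 0.2, 0.4), function(eta) {
    tr <- simulate_lattice(spec, noise_spec(eta, seed = 5), T = 120,
                           stride = 20L)
    stationary_variance(tr)$variance
  })
  expect_true(all(diff(vs) > 0))
  expect_gt(vs[4] / vs[1], 1)
})

test_that("impulse response decays with distance and flags wrap-around", {
  spec <- lattice_spec(16)
  tr <- impulse_response(spec)
  expect_false(tr$wrap_warning)
  sh <- distance_shells(spec)
  final <- abs(tr$states[nrow(tr$states), ])
  peak <- vapply(sh$shells, function(idx) max(abs(tr$states[, idx])), numeric(1))
  inner <- sh$radii <= 4
  outer <- sh$radii >= max(sh$radii) - 2
  expect_gt(mean(peak[inner]), mean(peak[outer]))   # locality + finite speed
  long <- impulse_response(spec, T = 20)
  expect_true(long$wrap_warning)
})
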