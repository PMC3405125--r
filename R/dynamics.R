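#' Specify the spatiotemporal white-noise input
#'
#' The drive is Gaussian white noise of amplitude `eta`, independent
#' across sites and time steps: each Euler-Maruyama step adds
#' `eta * sqrt(dt) * N(0,1)` per site. Because the noise is additive the
#' Ito and Stratonovich interpretations coincide.
#'
#' @param eta Input amplitude (state units per sqrt(time)), >= 0.
#' @param seed RNG seed (integer); trajectories are deterministic given
#'   the seed.
#' @param dt Integration time step; must satisfy `dt * 4g < 0.5` for
#'   the explicit scheme to stay well inside the stability region of
#'   the fastest lattice mode (band edge `4g`).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(eta, seed = 1L, dt = 0.01) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0)
    stop("eta must be a single number >= 0")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be positive")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  structure(list(eta = as.numeric(eta), seed = as.integer(seed),
                 dt = as.numeric(dt)),
            class = "noise_spec")
}

check_step <- function(spec, noise) {
  if (noise$dt * 4 * spec$g >= 0.5)
    stop(sprintf("time step too large: dt * 4g = %.3f >= 0.5 (dt = %g, g = %g)",
                 noise$dt * 4 * spec$g, noise$dt, spec$g))
}

new_trajectory <- function(times, states, spec, noise, extra = list()) {
  structure(c(list(times = times, states = states, spec = spec,
                   noise = noise), extra),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf("<lattice_trajectory> %d sites, %d saved times in [%g, %g], eta = %g\n",
              ncol(x$states), length(x$times), min(x$times), max(x$times),
              x$noise$eta))
  invisible(x)
}

#' Integrate the nonlinear stochastic lattice dynamics
#'
#' Integrates `xdot_i = sum_j A[i,j] x_j - x_i^3 + I_i(t)` by
#' Euler-Maruyama, where `I` is spatiotemporal Gaussian white noise of
#' amplitude `eta` (see [noise_spec()]). The antisymmetric coupling
#' conserves the state norm; the local cubic term strictly dissipates
#' it; the noise injects energy — their balance sets the stationary
#' activity variance.
#'
#' @param spec A [lattice_spec()].
#' @param noise A [noise_spec()].
#' @param x0 Initial state (length `N^2`), default all zeros.
#' @param T Total integration time, > 0.
#' @param stride Save every `stride`-th step (the initial state is
#'   always saved).
#' @param cubic If `FALSE`, drop the cubic term and integrate the bare
#'   linear flow (used in convergence checks against the spectral
#'   propagator).
#' @param method `"euler"` (Euler-Maruyama; default) or `"heun"`
#'   (deterministic Heun predictor-corrector, only valid with
#'   `eta = 0`).
#' @return A `lattice_trajectory`: `times`, a `[n_times x N^2]` state
#'   matrix `states`, and the specs in `spec`, `noise`.
#' @export
simulate_lattice <- function(spec, noise, x0 = NULL, T, stride = 10L,
                             cubic = TRUE, method = c("euler", "heun")) {
  stopifnot_lattice(spec)
  method <- match.arg(method)
  check_step(spec, noise)
  if (!is.numeric(T) || T <= 0) stop("T must be positive")
  if (method == "heun" && noise$eta > 0)
    stop("heun method is only available for eta = 0")
  n <- spec$n_sites
  if (is.null(x0)) x0 <- numeric(n)
  if (length(x0) != n) stop("x0 has wrong length")
  A <- build_coupling(spec)
  dt <- noise$dt
  n_steps <- max(1L, as.integer(round(T / dt)))
  stride <- max(1L, as.integer(stride))
  save_at <- seq(0L, n_steps, by = stride)
  states <- matrix(NA_real_, length(save_at), n)
  x <- as.numeric(x0)
  states[1L, ] <- x
  set.seed(noise$seed)
  sn <- noise$eta * sqrt(dt)
  save_ptr <- 2L
  for (step in seq_len(n_steps)) {
    drift <- as.numeric(A %*% x)
    if (cubic) drift <- drift - x^3
    if (method == "euler") {
      x <- x + dt * drift
      if (sn > 0) x <- x + sn * stats::rnorm(n)
    } else {
      xp <- x + dt * drift
      driftp <- as.numeric(A %*% xp)
      if (cubic) driftp <- driftp - xp^3
      x <- x + dt * 0.5 * (drift + driftp)
    }
    m <- max(abs(x))
    if (!is.finite(m) || m > 1e6)
      stop(sprintf("integration unstable (|x| > 1e6): reduce dt (= %g) for g = %g",
                   dt, spec$g))
    if (save_ptr <= length(save_at) && step == save_at[save_ptr]) {
      states[save_ptr, ] <- x
      save_ptr <- save_ptr + 1L
    }
  }
  new_trajectory(save_at * dt, states, spec, noise,
                 extra = list(cubic = cubic, method = method))
}

#' Stationary activity variance of a trajectory
#'
#' Time- and site-averaged squared activity after discarding a burn-in,
#' the quantity that enters the perturbation dynamics as the effective
#' damping coefficient (times 3).
#'
#' @param traj A `lattice_trajectory`.
#' @param burn_in Time to discard from the start (default `50/g`).
#' @return A list: `variance` (scalar mean of `x^2`), `per_site` (site
#'   map of time-averaged `x^2`), `window` (times used).
#' @export
stationary_variance <- function(traj, burn_in = NULL) {
  if (!inherits(traj, "lattice_trajectory")) stop("expected a lattice_trajectory")
  if (is.null(burn_in)) burn_in <- 50 / traj$spec$g
  keep <- traj$times >= burn_in
  if (!any(keep)) stop("burn_in >= trajectory length: nothing to average")
  S2 <- traj$states[keep, , drop = FALSE]^2
  list(variance = mean(S2),
       per_site = colMeans(S2),
       window = range(traj$times[keep]))
}

#' Zero-input impulse response of the lattice
#'
#' Places a delta perturbation of given amplitude on a single site of a
#' quiescent, input-free lattice and integrates forward. The response
#' expands outward at asymptotically constant speed with wave-like
#' ripples that attenuate algebraically with distance — the signature
#' of the critically balanced coupling. The default horizon keeps the
#' front from wrapping around the periodic lattice; if a longer `T` is
#' requested a `wrap_warning` flag is recorded in the trajectory.
#'
#' @param spec A [lattice_spec()].
#' @param center Impulse site: state index or 0-based `(col, row)` pair;
#'   defaults to the lattice centre.
#' @param T Horizon; default `0.8 * r_max / front_speed_scale(spec)`.
#' @param amplitude Impulse height (default 1).
#' @param dt Time step (default `0.01/g`).
#' @param stride Save stride (default 10 steps).
#' @param linear If `TRUE`, evolve with the exact spectral propagator
#'   (no cubic term) instead of the nonlinear integrator.
#' @return A `lattice_trajectory`.
#' @export
impulse_response <- function(spec, center = NULL, T = NULL, amplitude = 1,
                             dt = NULL, stride = 10L, linear = FALSE) {
  stopifnot_lattice(spec)
  sh <- distance_shells(spec, center)
  center <- sh$center
  rmax <- max(sh$radii)
  if (is.null(T)) T <- 0.8 * rmax / front_speed_scale(spec)
  if (is.null(dt)) dt <- 0.01 / spec$g
  wrap_warning <- T > rmax / front_speed_scale(spec)
  x0 <- numeric(spec$n_sites)
  x0[center] <- amplitude
  if (linear) {
    times <- seq(0, T, by = dt * stride)
    states <- t(vapply(times, function(t) linear_propagate(spec, x0, t),
                       numeric(spec$n_sites)))
    traj <- new_trajectory(times, states, spec, noise_spec(0, dt = dt),
                           extra = list(cubic = FALSE, method = "spectral"))
  } else {
    traj <- simulate_lattice(spec, noise_spec(0, dt = dt), x0 = x0, T = T,
                             stride = stride)
  }
  traj$center <- center
  traj$wrap_warning <- wrap_warning
  traj
}
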