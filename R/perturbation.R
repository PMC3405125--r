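#' Propagate a tangent-linear perturbation on a noise-driven background
#'
#' Co-integrates the background dynamics
#' `xdot = A x - x^3 + I(t)` and the tangent-linear system
#' `deltadot = A delta - 3 x^2 delta`, with the same noise realisation
#' driving only the background. The perturbation starts as a unit
#' impulse confined to a single site. The squared background activity
#' enters the perturbation equation as an effective damping
#' coefficient, so the stronger the input drive, the faster the
#' perturbation is damped as it propagates outward — the mechanism
#' behind input-dependent wave attenuation.
#'
#' The background is first equilibrated for `burn_in` time units before
#' the impulse is injected, so the damping field is statistically
#' stationary during the measurement.
#'
#' @param spec A [lattice_spec()].
#' @param noise A [noise_spec()].
#' @param center Impulse site (state index or 0-based `(col, row)`);
#'   defaults to the lattice centre.
#' @param T Measurement horizon after the impulse; default
#'   `0.8 * r_max / front_speed_scale(spec)` so the front reaches the
#'   outer shells without wrapping the periodic lattice.
#' @param burn_in Background equilibration time (default `50/g`;
#'   ignored when `frozen_sq` is given).
#' @param amplitude Initial impulse height (default 1; the tangent
#'   system is exactly linear in it).
#' @param stride Save stride for the stored `delta` snapshots.
#' @param save_delta If `TRUE` (default) store `delta` snapshots every
#'   `stride` steps; the per-site running maximum is tracked every step
#'   regardless.
#' @param frozen_sq Test hook: a fixed squared-background field (scalar
#'   or per-site vector). When given, the background is not integrated
#'   and the damping is exactly `3 * frozen_sq`; with a uniform value
#'   `v` the solution is `exp(-3 v t)` times the free linear response.
#' @param method `"tangent"` (default) evolves the linearised system;
#'   `"twin"` cross-checks it by evolving two full nonlinear
#'   trajectories from `x0 +/- (eps/2) * impulse` under common noise
#'   and differencing them, `delta = (x_plus - x_minus)/eps`.
#' @param eps Twin-trajectory impulse separation (only for
#'   `method = "twin"`).
#' @return An object of class `perturbation_run`: `site_max` (per-site
#'   max over time of `|delta|`, including the initial condition),
#'   `delta_times` / `delta_norms` (Euclidean norm history of the
#'   perturbation), `x2_bar` (mean squared background over the
#'   measurement window, `NA` for frozen backgrounds), optional `delta`
#'   snapshot matrix, and the run metadata.
#' @export
tangent_propagate <- function(spec, noise, center = NULL, T = NULL,
                              burn_in = NULL, amplitude = 1, stride = 10L,
                              save_delta = TRUE, frozen_sq = NULL,
                              method = c("tangent", "twin"), eps = 1e-6) {
  stopifnot_lattice(spec)
  method <- match.arg(method)
  check_step(spec, noise)
  sh_center <- distance_shells(spec, center)$center
  if (is.null(T)) {
    rmax <- max(distance_shells(spec, sh_center)$radii)
    T <- 0.8 * rmax / front_speed_scale(spec)
  }
  if (is.null(burn_in)) burn_in <- 50 / spec$g
  n <- spec$n_sites
  A <- build_coupling(spec)
  dt <- noise$dt
  sn <- noise$eta * sqrt(dt)
  frozen <- !is.null(frozen_sq)
  if (frozen) {
    damp_sq <- rep_len(as.numeric(frozen_sq), n)
    if (any(damp_sq < 0)) stop("frozen_sq must be nonnegative")
  }
  set.seed(noise$seed)

  x <- numeric(n)
  if (!frozen && burn_in > 0) {
    for (step in seq_len(as.integer(round(burn_in / dt)))) {
      x <- x + dt * (as.numeric(A %*% x) - x^3)
      if (sn > 0) x <- x + sn * stats::rnorm(n)
      if (max(abs(x)) > 1e6)
        stop("background integration unstable during burn-in: reduce dt")
    }
  }

  delta <- numeric(n)
  delta[sh_center] <- amplitude
  if (method == "twin") {
    xp <- x; xm <- x
    xp[sh_center] <- xp[sh_center] + eps * amplitude / 2
    xm[sh_center] <- xm[sh_center] - eps * amplitude / 2
  }

  n_steps <- max(1L, as.integer(round(T / dt)))
  stride <- max(1L, as.integer(stride))
  save_at <- seq(0L, n_steps, by = stride)
  dsnap <- if (save_delta) matrix(NA_real_, length(save_at), n) else NULL
  if (save_delta) dsnap[1L, ] <- delta
  site_max <- abs(delta)
  norms <- numeric(n_steps + 1L)
  norms[1L] <- sqrt(sum(delta^2))
  x2_acc <- 0
  save_ptr <- 2L

  for (step in seq_len(n_steps)) {
    if (method == "twin") {
      z <- if (sn > 0) stats::rnorm(n) else NULL
      fp <- as.numeric(A %*% xp) - xp^3
      fm <- as.numeric(A %*% xm) - xm^3
      xp <- xp + dt * fp
      xm <- xm + dt * fm
      if (!is.null(z)) {
        xp <- xp + sn * z
        xm <- xm + sn * z
      }
      delta <- (xp - xm) / eps
      x2_acc <- x2_acc + mean(((xp + xm) / 2)^2)
    } else {
      sq <- if (frozen) damp_sq else x^2
      dnew <- delta + dt * (as.numeric(A %*% delta) - 3 * sq * delta)
      if (!frozen) {
        x <- x + dt * (as.numeric(A %*% x) - x^3)
        if (sn > 0) x <- x + sn * stats::rnorm(n)
        x2_acc <- x2_acc + mean(x^2)
      }
      delta <- dnew
    }
    if (max(abs(delta)) > 1e6 || (!frozen && method == "tangent" && max(abs(x)) > 1e6))
      stop("integration unstable: reduce dt")
    site_max <- pmax(site_max, abs(delta))
    norms[step + 1L] <- sqrt(sum(delta^2))
    if (save_delta && save_ptr <= length(save_at) && step == save_at[save_ptr]) {
      dsnap[save_ptr, ] <- delta
      save_ptr <- save_ptr + 1L
    }
  }

  structure(list(site_max = site_max,
                 delta_times = (0:n_steps) * dt,
                 delta_norms = norms,
                 delta = dsnap,
                 delta_save_times = save_at * dt,
                 x2_bar = if (frozen || method == "twin" && sn == 0) NA_real_
                          else x2_acc / n_steps,
                 spec = spec, noise = noise, center = sh_center,
                 eta = noise$eta, amplitude = amplitude, T = T,
                 burn_in = if (frozen) 0 else burn_in,
                 method = method, frozen = frozen),
            class = "perturbation_run")
}

#' @export
print.perturbation_run <- function(x, ...) {
  cat(sprintf("<perturbation_run> N = %d, eta = %g, center %d, T = %g (%s)\n",
              x$spec$N, x$eta, x$center, x$T, x$method))
  invisible(x)
}

#' Temporal decay rate of the perturbation norm
#'
#' Fits a line to `log ||delta||_2` versus time over a window (by
#' default the middle 10%-90% of the horizon, skipping the initial
#' reorganisation of the impulse). In the mean-field picture the decay
#' rate equals three times the background activity variance.
#'
#' @param run A [tangent_propagate()] result.
#' @param window Length-2 time window; default `c(0.1, 0.9) * T`.
#' @return A list with `rate` (1/time), `r_squared`, and `window`.
#' @export
delta_decay_rate <- function(run, window = NULL) {
  if (!inherits(run, "perturbation_run")) stop("expected a perturbation_run")
  if (is.null(window)) window <- c(0.1, 0.9) * run$T
  keep <- run$delta_times >= window[1L] & run$delta_times <= window[2L] &
    run$delta_norms > 0
  if (sum(keep) < 4L) stop("decay window too short")
  tt <- run$delta_times[keep]
  fit <- stats::lm(log(run$delta_norms[keep]) ~ tt)
  list(rate = -unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       window = window)
}

#' Distance profile of the maximal perturbation amplitude
#'
#' For each site, takes the maximum of `|delta|` over the whole run
#' (including time zero, so the centre shell is at least the impulse
#' amplitude); shell values are the mean (default) or max over the
#' sites of each distance shell; profiles from several realisations are
#' averaged arithmetically. This is the wave profile M(r) whose tail
#' slope defines the attenuation length.
#'
#' @param runs A single [tangent_propagate()] run or a list of runs
#'   sharing spec, centre and eta.
#' @param shells A [distance_shells()] around the common centre.
#' @param stat `"mean"` (default, variance-reducing) or `"max"` over
#'   the sites of a shell.
#' @return An object of class `attenuation_profile`: `radii`, `M`,
#'   `eta`, `n_realizations`, `bc`.
#' @export
attenuation_profile <- function(runs, shells, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (inherits(runs, "perturbation_run")) runs <- list(runs)
  if (!length(runs)) stop("need at least one perturbation run")
  if (!all(vapply(runs, inherits, logical(1), "perturbation_run")))
    stop("runs must be perturbation_run objects")
  if (!inherits(shells, "distance_shells")) stop("expected distance_shells")
  key <- function(r) c(r$spec$N, r$spec$g, r$center, r$eta)
  k0 <- key(runs[[1L]])
  if (!all(vapply(runs, function(r) isTRUE(all.equal(key(r), k0)), logical(1))))
    stop("all runs must share lattice spec, center and eta")
  if (runs[[1L]]$center != shells$center)
    stop("shells center does not match the runs' impulse center")
  shell_stat <- if (stat == "mean") mean else max
  per_run <- vapply(runs, function(r)
    vapply(shells$shells, function(idx) shell_stat(r$site_max[idx]),
           numeric(1)),
    numeric(length(shells$radii)))
  M <- if (is.matrix(per_run)) rowMeans(per_run) else per_run
  # Radii that no wrapped front can have reached within any run's
  # horizon: under periodic boundaries the second-path (around the
  # torus) arrival at minimal-image radius r occurs at (N - r)/v_hat,
  # so shells with r >= N - v_hat * T are contaminated and excluded
  # from attenuation fits.
  spec1 <- runs[[1L]]$spec
  r_reliable <- if (spec1$bc == "periodic") {
    min(vapply(runs, function(r)
      floor(min(spec1$N / 2,
                spec1$N - front_speed_scale(spec1) * r$T)),
      numeric(1)))
  } else Inf
  structure(list(radii = shells$radii, M = unname(M),
                 eta = runs[[1L]]$eta, n_realizations = length(runs),
                 bc = spec1$bc, stat = stat, r_reliable = r_reliable),
            class = "attenuation_profile")
}

#' @export
print.attenuation_profile <- function(x, ...) {
  cat(sprintf("<attenuation_profile> eta = %g, %d shells (r <= %d), %d realization(s)\n",
              x$eta, length(x$radii), max(x$radii), x$n_realizations))
  invisible(x)
}

#' Fit the spatial attenuation of a perturbation profile
#'
#' Fits both an exponential model `log M = a - kappa * r` and a
#' power-law model `log M = a - alpha * log r` by least squares over
#' the outermost `window_frac` of usable radii. Usable radii have `M`
#' above the numeric floor and lie inside the wrap-free reliable radius
#' recorded by [attenuation_profile()] (under periodic boundaries the
#' wave returning around the torus contaminates the outermost shells
#' within the measurement horizon); the outermost two shells are
#' additionally dropped under open boundaries to avoid edge artefacts.
#' The exponential slope gives the attenuation length
#' `lambda = 1/kappa`; the two models' AIC values discriminate
#' finite-range exponential decay (noise-driven background) from the
#' scale-free algebraic decay of the input-free critical lattice.
#'
#' @param profile An [attenuation_profile()].
#' @param window_frac Fraction of usable radii forming the outer fit
#'   window (default 1/3; at least 4 shells are always used).
#' @param floor Numeric floor below which `M` values are considered
#'   clipped (default 1e-12). Clipped values inside the window are an
#'   error, not silently dropped.
#' @return An object of class `attenuation_fit`: `kappa`, `lam`
#'   (`1/kappa`, `Inf` when the exponential slope is nonnegative),
#'   `alpha` (power-law exponent), `r_squared` / `r_squared_power`,
#'   `aic` / `aic_power`, `preferred` (`"exponential"` or
#'   `"power"`), and the fit `window` radii.
#' @examples
#' p <- structure(list(radii = 1:30, M = exp(-(1:30) / 5), eta = 0.1,
#'                     n_realizations = 1, bc = "periodic", stat = "mean"),
#'                class = "attenuation_profile")
#' fit_attenuation(p)$lam  # 5
#' @export
fit_attenuation <- function(profile, window_frac = 1 / 3, floor = 1e-12) {
  if (!inherits(profile, "attenuation_profile"))
    stop("expected an attenuation_profile")
  r <- as.numeric(profile$radii)
  M <- profile$M
  use <- r > 0
  if (!is.null(profile$r_reliable)) use <- use & r <= profile$r_reliable
  if (identical(profile$bc, "open") && sum(use) > 6L) {
    drop_r <- sort(r[use], decreasing = TRUE)[1:2]
    use <- use & !(r %in% drop_r)
  }
  r <- r[use]; M <- M[use]
  usable <- which(M > floor)
  if (!length(usable)) stop("profile entirely below the numeric floor")
  last_usable <- max(usable)
  n_win <- max(4L, as.integer(ceiling(window_frac * last_usable)))
  win <- seq(last_usable - n_win + 1L, last_usable)
  if (win[1L] < 1L) win <- seq_len(last_usable)
  if (length(win) < 4L)
    stop("fewer than 4 shells in the fit window: profile too short")
  if (any(M[win] <= floor))
    stop("fit window contains floor-clipped values; shorten the window or raise the signal")
  rw <- r[win]; lw <- log(M[win])
  fe <- stats::lm(lw ~ rw)
  fp <- stats::lm(lw ~ log(rw))
  kappa <- -unname(stats::coef(fe)[2L])
  # exactly log-linear profiles are legitimate inputs; silence the
  # perfect-fit note from summary.lm
  r2e <- suppressWarnings(summary(fe)$r.squared)
  r2p <- suppressWarnings(summary(fp)$r.squared)
  structure(list(kappa = kappa,
                 lam = if (kappa > 0) 1 / kappa else Inf,
                 alpha = -unname(stats::coef(fp)[2L]),
                 r_squared = r2e,
                 r_squared_power = r2p,
                 aic = stats::AIC(fe),
                 aic_power = stats::AIC(fp),
                 preferred = if (stats::AIC(fp) < stats::AIC(fe)) "power"
                             else "exponential",
                 window = rw,
                 eta = profile$eta),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf(
    "<attenuation_fit> eta = %g: kappa = %.4g, lambda = %.4g (R2 = %.3f); preferred model: %s\n",
    x$eta, x$kappa, x$lam, x$r_squared, x$preferred))
  invisible(x)
}

#' Attenuation length as a function of input strength
#'
#' Runs the full perturbation pipeline for each input amplitude in
#' `eta_grid`: `n_realizations` independent tangent-linear runs on
#' noise-driven backgrounds, realisation-averaged profile, exponential
#' and power-law fits of the outer window. Child RNG seeds are derived
#' from the master seed and the eta *value* (not its position), so the
#' grid can be reordered or extended without changing existing rows.
#'
#' @param spec A [lattice_spec()].
#' @param eta_grid Input amplitudes (>= 0).
#' @param n_realizations Independent runs averaged per eta (default 8).
#' @param seed Master seed for the per-(eta, realisation) derivation.
#' @param dt Integration step (default `0.01/g`).
#' @param window_frac Outer fit window fraction (default 1/3).
#' @param center Impulse site; defaults to the lattice centre.
#' @param burn_in Background equilibration time (default `50/g`).
#' @param stat Shell statistic, `"mean"` or `"max"`.
#' @return A list of class `range_vs_input`: `summary` (data.frame with
#'   `eta`, `lambda`, `kappa`, `r_squared`, `r_squared_power`, `aic`,
#'   `aic_power`, `preferred`, `n_realizations`, `note`) and `profiles`
#'   (one [attenuation_profile()] per eta). Per-eta fit failures are
#'   recorded in `note`, not raised.
#' @export
range_vs_input <- function(spec, eta_grid, n_realizations = 8L, seed = 1L,
                           dt = NULL, window_frac = 1 / 3, center = NULL,
                           burn_in = NULL, stat = "mean") {
  stopifnot_lattice(spec)
  if (!length(eta_grid) || any(eta_grid < 0)) stop("eta_grid must be >= 0")
  if (is.null(dt)) dt <- 0.01 / spec$g
  shells <- distance_shells(spec, center)
  rows <- vector("list", length(eta_grid))
  profiles <- vector("list", length(eta_grid))
  for (ei in seq_along(eta_grid)) {
    eta <- eta_grid[ei]
    runs <- lapply(seq_len(n_realizations), function(rz) {
      tangent_propagate(spec,
                        noise_spec(eta, seed = child_seed(seed, eta, rz),
                                   dt = dt),
                        center = shells$center, burn_in = burn_in,
                        save_delta = FALSE)
    })
    prof <- attenuation_profile(runs, shells, stat = stat)
    profiles[[ei]] <- prof
    fit <- tryCatch(fit_attenuation(prof, window_frac = window_frac),
                    error = function(e) e)
    rows[[ei]] <- if (inherits(fit, "error")) {
      data.frame(eta = eta, lambda = NA_real_, kappa = NA_real_,
                 r_squared = NA_real_, r_squared_power = NA_real_,
                 aic = NA_real_, aic_power = NA_real_,
                 preferred = NA_character_,
                 n_realizations = n_realizations,
                 note = conditionMessage(fit))
    } else {
      data.frame(eta = eta, lambda = fit$lam, kappa = fit$kappa,
                 r_squared = fit$r_squared,
                 r_squared_power = fit$r_squared_power,
                 aic = fit$aic, aic_power = fit$aic_power,
                 preferred = fit$preferred,
                 n_realizations = n_realizations, note = NA_character_)
    }
  }
  structure(list(summary = do.call(rbind, rows), profiles = profiles,
                 spec = spec, seed = seed),
            class = "range_vs_input")
}

#' @export
print.range_vs_input <- function(x, ...) {
  cat("<range_vs_input>\n")
  print(x$summary[, c("eta", "lambda", "r_squared", "preferred")])
  invisible(x)
}
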