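#' Lattice dispersion relation
#'
#' For periodic boundaries the coupling matrix is diagonalised by plane
#' waves on the discrete Brillouin grid `k = 2*pi*(m, n)/N`, and the
#' temporal frequency of the mode at wave vector `k` is
#' `omega(k) = 2*g*(cos(kx) + cos(ky))`. The band is bounded by `4*g`,
#' `omega` is even in `k`, and near `k = 0` it *decreases* as `|k|`
#' grows: increasing spatial frequency goes with decreasing temporal
#' frequency, opposite to an ordinary wave equation. The multiset of
#' `omega` values over the grid equals the multiset of imaginary parts
#' of the eigenvalues of the coupling matrix.
#'
#' @param spec A [lattice_spec()] with periodic boundaries.
#' @return A data.frame of class `dispersion_table` with columns `m`,
#'   `n` (mode numbers), `kx`, `ky` (radians per lattice unit) and
#'   `omega` (radians per unit time).
#' @examples
#' d <- dispersion(lattice_spec(4))
#' d$omega[d$m == 0 & d$n == 0]  # band edge 4g
#' @export
dispersion <- function(spec) {
  stopifnot_lattice(spec)
  if (spec$bc != "periodic")
    stop("dispersion is undefined for open boundaries (no translation invariance)")
  N <- spec$N
  m <- rep(0:(N - 1L), times = N)
  n <- rep(0:(N - 1L), each = N)
  kx <- 2 * pi * m / N
  ky <- 2 * pi * n / N
  out <- data.frame(m = m, n = n, kx = kx, ky = ky,
                    omega = 2 * spec$g * (cos(kx) + cos(ky)))
  class(out) <- c("dispersion_table", "data.frame")
  out
}

#' Write a dispersion table as delimited text
#' @param tab A [dispersion()] table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dispersion <- function(tab, path) {
  utils::write.table(tab[, c("kx", "ky", "omega")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fourier multiplier grid c(k) of the symmetric adjacency C, N x N,
# indexed [m+1, n+1] to match stats::fft on a state matrix whose rows
# run over columns of the lattice (state index = col + N*row + 1).
ck_grid <- function(spec) {
  cosv <- cos(2 * pi * (0:(spec$N - 1L)) / spec$N)
  2 * spec$g * outer(cosv, cosv, `+`)
}

# Apply the symmetric g-weighted adjacency C (sum over 4 neighbours)
# to a state given as an N x N matrix, via FFT.
apply_adjacency <- function(X, cg) {
  Re(stats::fft(cg * stats::fft(X), inverse = TRUE)) / length(X)
}

#' Exact linear propagator exp(A t)
#'
#' Evolves a state under the linear part of the lattice dynamics,
#' `xdot = A x`, exactly in the plane-wave eigenbasis. Writing
#' `A = C S` with `C` the g-weighted adjacency and `S = diag(parity)`,
#' the checkerboard identity `S C S = -C` gives `A^2 = -C^2`, hence
#' `exp(A t) = cos(C t) + A C^{-1} sin(C t)`, where the functions of
#' `C` act as Fourier multipliers `cos(c(k) t)` and `sin(c(k) t)/c(k)`
#' (with the limit `t` at `c(k) = 0`). Because `A` is antisymmetric the
#' flow is orthogonal: the Euclidean norm of the state is conserved to
#' rounding error.
#'
#' @param spec A [lattice_spec()] with periodic boundaries.
#' @param x0 State vector of length `N^2`.
#' @param t Time (>= 0, although the formula is valid for any real t).
#' @return The state `exp(A t) %*% x0` as a numeric vector.
#' @export
linear_propagate <- function(spec, x0, t) {
  stopifnot_lattice(spec)
  if (spec$bc != "periodic")
    stop("linear_propagate requires periodic boundaries")
  if (length(x0) != spec$n_sites) stop("x0 has wrong length")
  N <- spec$N
  cg <- ck_grid(spec)
  X <- matrix(as.numeric(x0), N, N)
  Fx <- stats::fft(X)
  ycos <- Re(stats::fft(cos(cg * t) * Fx, inverse = TRUE)) / (N * N)
  sgrid <- ifelse(abs(cg) < 1e-12, t, sin(cg * t) / cg)
  ysin <- Re(stats::fft(sgrid * Fx, inverse = TRUE)) / (N * N)
  # A ysin = C (S ysin): parity flip then adjacency
  sig <- matrix(site_parity(spec), N, N)
  as.vector(ycos + apply_adjacency(sig * ysin, cg))
}

#' Characteristic front speed of the lattice
#'
#' The group velocity of the mode at wave vector `k` is
#' `2*g*(sin kx, sin ky)`; its magnitude peaks at `2*sqrt(2)*g` along
#' the lattice diagonal and at `2*g` along a lattice axis. The axial
#' value `2*g` is returned as the scale at which the expanding impulse
#' front covers distance, and is the speed used to size measurement
#' horizons.
#'
#' @param spec A [lattice_spec()].
#' @return Speed in lattice units per unit time.
#' @export
front_speed_scale <- function(spec) {
  stopifnot_lattice(spec)
  2 * spec$g
}

#' Estimate the outward front speed from an impulse-response trajectory
#'
#' The front is tracked along the lattice axes through the epicenter —
#' the 1D slice of the 2D array in which the expanding impulse is
#' displayed — because there the group speed is single-valued (`2g`);
#' averaging whole distance shells would mix propagation directions
#' whose group speeds range from `2g` (axial) to `2*sqrt(2)*g`
#' (diagonal) and blur the arrival times. For each axial distance `r`
#' the arrival time is the time of the first local maximum of the mean
#' absolute activity over the (up to 4) on-axis sites at that distance
#' that exceeds 1% of the global maximum, a threshold robust to the
#' ripples of the algebraically decaying tail. A line is fitted to
#' arrival time versus `r` over the outer half of the reached
#' distances; the reciprocal slope is the front speed. Under periodic
#' boundaries, distances the wrapped (around-the-torus) front could
#' reach within the horizon are excluded.
#'
#' @param traj A trajectory from [impulse_response()] or
#'   [simulate_lattice()] with stored states.
#' @param shells A [distance_shells()] around the impulse site (used
#'   for the epicenter and the radius range).
#' @return A list with `speed` (lattice units/time), `r_squared` of the
#'   time-vs-radius fit, and the per-distance `arrival` data.frame.
#' @export
front_speed <- function(traj, shells) {
  if (!inherits(traj, "lattice_trajectory")) stop("expected a lattice_trajectory")
  if (!inherits(shells, "distance_shells")) stop("expected distance_shells")
  spec <- traj$spec
  N <- spec$N
  S <- abs(traj$states)
  gmax <- max(S)
  if (gmax <= 0) stop("trajectory is identically zero: no front to track")
  thr <- 0.01 * gmax
  xy <- site_coords(spec)
  c0 <- xy$col[shells$center]; r0 <- xy$row[shells$center]
  rmax <- if (spec$bc == "periodic") {
    floor(min(N / 2, N - front_speed_scale(spec) * max(traj$times)))
  } else {
    max(c0, N - 1L - c0, r0, N - 1L - r0)
  }
  if (rmax < 4L) stop("horizon leaves fewer than 4 wrap-free axial distances")
  radii <- seq_len(rmax)
  axial_sites <- function(r) {
    cand <- rbind(c(c0 + r, r0), c(c0 - r, r0), c(c0, r0 + r), c(c0, r0 - r))
    if (spec$bc == "periodic") cand <- cand %% N
    cand <- cand[cand[, 1L] >= 0 & cand[, 1L] < N &
                 cand[, 2L] >= 0 & cand[, 2L] < N, , drop = FALSE]
    site_index(spec, cand[, 1L], cand[, 2L])
  }
  arrival <- rep(NA_real_, length(radii))
  for (si in seq_along(radii)) {
    idx <- axial_sites(radii[si])
    y <- if (length(idx) > 1L) rowMeans(S[, idx, drop = FALSE]) else S[, idx]
    nt <- length(y)
    # first interior local maximum above threshold
    cand <- which(y[2:(nt - 1L)] > thr &
                  y[2:(nt - 1L)] >= y[1:(nt - 2L)] &
                  y[2:(nt - 1L)] >= y[3:nt]) + 1L
    if (length(cand)) arrival[si] <- traj$times[cand[1L]]
  }
  ok <- !is.na(arrival)
  if (sum(ok) < 4L)
    stop("front reached fewer than 4 axial distances within the trajectory horizon")
  r <- radii[ok]; tt <- arrival[ok]
  outer_half <- r >= stats::median(r)
  fit <- stats::lm(tt[outer_half] ~ r[outer_half])
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("front arrival times do not increase with radius")
  list(speed = 1 / slope,
       r_squared = summary(fit)$r.squared,
       arrival = data.frame(radius = r, time = tt))
}
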