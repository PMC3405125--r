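#' Specify a critically balanced excitatory/inhibitory lattice
#'
#' Defines the geometry and coupling of a two-dimensional checkerboard
#' network in which excitatory (white, parity +1) and inhibitory (black,
#' parity -1) units alternate and every unit interacts with its four
#' nearest neighbours with identical synaptic strength `g`. The resulting
#' coupling matrix (see [build_coupling()]) is exactly antisymmetric, so
#' the linearised dynamics has purely imaginary eigenvalues: the network
#' is poised at a high-dimensional Hopf bifurcation.
#'
#' @param N Lattice edge length in sites. Must be an even integer >= 4;
#'   evenness makes the checkerboard parity consistent across the
#'   periodic boundary.
#' @param g Synaptic strength (units of 1/time), > 0.
#' @param bc Boundary condition, `"periodic"` (default) or `"open"`.
#'   Periodic boundaries preserve translation invariance, so the
#'   dispersion relation is exact and attenuation fits are free of edge
#'   reflections; open boundaries are supported for robustness checks.
#' @return An object of class `lattice_spec` with fields `N`, `g`, `bc`
#'   and `n_sites = N^2`.
#' @examples
#' spec <- lattice_spec(8, g = 1)
#' spec$n_sites
#' @export
lattice_spec <- function(N, g = 1, bc = c("periodic", "open")) {
  bc <- match.arg(bc)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N != round(N))
    stop("N must be a single integer")
  N <- as.integer(N)
  if (N < 4L) stop("N must be at least 4 (got N = ", N, ")")
  if (N %% 2L != 0L) stop("N must be even for a consistent checkerboard parity (got N = ", N, ")")
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("g must be a single positive number")
  structure(list(N = N, g = as.numeric(g), bc = bc, n_sites = N * N),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d sites, g = %g, %s boundary\n",
              x$N, x$N, x$g, x$bc))
  invisible(x)
}

stopifnot_lattice <- function(spec) {
  if (!inherits(spec, "lattice_spec")) stop("expected a lattice_spec object")
  invisible(spec)
}

#' Site indexing and parity
#'
#' Sites are addressed by 0-based `(col, row)` coordinates; the state
#' vector index (1-based, as usual in R) is `col + N*row + 1`, i.e.
#' row-major over rows with the column varying fastest. The parity of a
#' site is `(-1)^(col + row)`: +1 for excitatory (white) units, -1 for
#' inhibitory (black) units, so nearest neighbours always have opposite
#' parity.
#'
#' @param spec A [lattice_spec()].
#' @param col,row 0-based coordinates (vectors recycle).
#' @return `site_index()`: 1-based indices into the length-`N^2` state
#'   vector. `site_parity()`: the parity vector over all sites, ordered
#'   by state index.
#' @export
site_index <- function(spec, col, row) {
  stopifnot_lattice(spec)
  if (any(col < 0 | col >= spec$N | row < 0 | row >= spec$N))
    stop("site coordinates out of range for N = ", spec$N)
  as.integer(col + spec$N * row + 1L)
}

#' @rdname site_index
#' @export
site_parity <- function(spec) {
  stopifnot_lattice(spec)
  N <- spec$N
  col <- rep(0:(N - 1L), times = N)
  row <- rep(0:(N - 1L), each = N)
  ifelse((col + row) %% 2L == 0L, 1, -1)
}

#' Coordinates of every site, ordered by state index
#' @param spec A [lattice_spec()].
#' @return A data.frame with 0-based `col`, `row` per state index.
#' @export
site_coords <- function(spec) {
  stopifnot_lattice(spec)
  N <- spec$N
  data.frame(col = rep(0:(N - 1L), times = N),
             row = rep(0:(N - 1L), each = N))
}

#' Build the antisymmetric coupling matrix
#'
#' Entry `A[i, j]` is `g * sigma(j)` when `j` is a nearest neighbour of
#' `i` (under the boundary condition) and 0 otherwise: the sign carried
#' by a connection is the parity of the *presynaptic* site, so an
#' inhibitory unit inhibits all of its neighbours. Because neighbours
#' have opposite parity this makes `A` exactly antisymmetric (entries
#' are `+/- g`, no floating-point cancellation involved), hence its
#' eigenvalues are purely imaginary — the critical balance of excitation
#' and inhibition.
#'
#' @param spec A [lattice_spec()].
#' @return A sparse `dgCMatrix` of dimension `N^2 x N^2`. Under periodic
#'   boundaries every row has exactly 4 nonzeros; under open boundaries
#'   2-4 depending on position.
#' @examples
#' A <- build_coupling(lattice_spec(4))
#' max(abs(A + Matrix::t(A)))  # exactly 0
#' @export
build_coupling <- function(spec) {
  stopifnot_lattice(spec)
  N <- spec$N
  xy <- site_coords(spec)
  sigma <- site_parity(spec)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  ii <- jj <- vector("list", 4L)
  for (s in seq_along(shifts)) {
    nc <- xy$col + shifts[[s]][1L]
    nr <- xy$row + shifts[[s]][2L]
    if (spec$bc == "periodic") {
      nc <- nc %% N
      nr <- nr %% N
      keep <- rep(TRUE, spec$n_sites)
    } else {
      keep <- nc >= 0L & nc < N & nr >= 0L & nr < N
    }
    ii[[s]] <- which(keep)
    jj[[s]] <- (nc + N * nr + 1L)[keep]
  }
  i <- unlist(ii); j <- unlist(jj)
  Matrix::sparseMatrix(i = i, j = j, x = spec$g * sigma[j],
                       dims = c(spec$n_sites, spec$n_sites))
}

#' Bin lattice sites into integer distance shells around a centre
#'
#' Sites are assigned to shells by their Euclidean distance (in lattice
#' units) from the centre, rounded to the nearest integer. Under
#' periodic boundaries the minimal-image distance is used. Shell 0
#' contains exactly the centre site; the shells partition the lattice.
#' Distance shells are the spatial bins over which the perturbation
#' profile M(r) is measured.
#'
#' @param spec A [lattice_spec()].
#' @param center Either a 1-based state index or a length-2 vector of
#'   0-based `(col, row)` coordinates. Defaults to the site at
#'   `(N/2, N/2)`.
#' @return An object of class `distance_shells`: list with `center`
#'   (state index), `radii` (sorted integer bins) and `shells` (a list,
#'   named by radius, of 1-based site indices).
#' @export
distance_shells <- function(spec, center = NULL) {
  stopifnot_lattice(spec)
  N <- spec$N
  if (is.null(center)) center <- c(N %/% 2L, N %/% 2L)
  if (length(center) == 2L) {
    center <- site_index(spec, center[1L], center[2L])
  } else if (length(center) == 1L) {
    if (center < 1L || center > spec$n_sites)
      stop("center index out of range [1, ", spec$n_sites, "]")
    center <- as.integer(center)
  } else stop("center must be a site index or (col, row) pair")
  xy <- site_coords(spec)
  c0 <- xy$col[center]; r0 <- xy$row[center]
  dc <- xy$col - c0; dr <- xy$row - r0
  if (spec$bc == "periodic") {
    dc <- ((dc + N %/% 2L) %% N) - N %/% 2L
    dr <- ((dr + N %/% 2L) %% N) - N %/% 2L
  }
  bin <- as.integer(round(sqrt(dc^2 + dr^2)))
  shells <- split(seq_len(spec$n_sites), bin)
  structure(list(center = center,
                 radii = as.integer(names(shells)),
                 shells = shells),
            class = "distance_shells")
}

#' @export
print.distance_shells <- function(x, ...) {
  cat(sprintf("<distance_shells> center site %d, %d shells, max radius %d\n",
              x$center, length(x$radii), max(x$radii)))
  invisible(x)
}

#' Export a coupling matrix as sparse triplets
#'
#' Writes the nonzero entries as tab-separated `(i, j, value)` rows with
#' 1-based indices, a plain-text coordinate format readable by any
#' sparse-matrix tool.
#'
#' @param A A sparse coupling matrix from [build_coupling()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_coupling_triplets <- function(A, path) {
  tr <- Matrix::summary(A)
  utils::write.table(data.frame(i = tr$i, j = tr$j, value = tr$x),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
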