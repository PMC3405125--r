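# shared fixtures built in code

impulse_state <- function(spec, amplitude = 1, center = NULL) {
  x <- numeric(spec$n_sites)
  x[distance_shells(spec, center)$center] <- amplitude
  x
}

dense_eigenvalues <- function(spec) {
  eigen(as.matrix(build_coupling(spec)), only.values = TRUE)$values
}

# analytic dispersion multiset over the Brillouin grid
analytic_omegas <- function(N, g) {
  k <- 2 * pi * (0:(N - 1)) / N
  as.vector(2 * g * outer(cos(k), cos(k), `+`))
}

# hand-built profile object for fit tests
synthetic_profile <- function(radii, M, eta = 0.1, bc = "periodic") {
  structure(list(radii = radii, M = M, eta = eta, n_realizations = 1L,
                 bc = bc, stat = "mean"),
            class = "attenuation_profile")
}
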