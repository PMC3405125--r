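#' Derive a child RNG seed from a master seed
#'
#' Deterministic counter-style derivation used for per-(eta,
#' realisation) seeding: the child depends on the master seed, the eta
#' *value* (via its ninth-decimal rounding) and the realisation index,
#' so extending or permuting an eta grid never reshuffles existing
#' runs. All arithmetic is exact in double precision and the result
#' fits a 32-bit R integer.
#'
#' @param master Master seed (integer).
#' @param eta Input amplitude the run belongs to.
#' @param realization Realisation counter (1-based).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, eta, realization) {
  eta_key <- round(as.numeric(eta) * 1e9) %% 1048573
  # Lehmer-style mixing; every product stays below 2^53 so the
  # arithmetic is exact in doubles
  h <- ((as.numeric(master) %% 2147483647) * 48271) %% 2147483647
  h <- ((h + eta_key) * 69621) %% 2147483647
  h <- (h + as.numeric(realization) * 16807) %% 2147483646
  as.integer(h + 1)
}
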