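# critwave

Simulation and analysis toolkit for a **critically balanced
excitatory–inhibitory lattice model of cortex**, for computational
neuroscientists studying how dynamical criticality shapes the spatial reach
of cortical interactions.

## The model

Neurons occupy the sites of an N × N chessboard: white sites are excitatory,
black sites inhibitory, and each unit couples to its four nearest neighbours
with identical strength *g*, the sign set by the parity
σ<sub>j</sub> = (−1)<sup>col+row</sup> of the presynaptic site. The coupling
matrix **A** (A<sub>ij</sub> = g σ<sub>j</sub> for neighbours) is exactly
antisymmetric, so its spectrum is purely imaginary: the network is poised at
a high-dimensional Hopf bifurcation. The dynamics is

    dx_i/dt = Σ_j A_ij x_j − x_i³ + I_i(t),

with *I* spatiotemporal Gaussian white noise of amplitude η. Its consequences,
all reproduced and tested here:

* **Zero input** — an impulse spreads as a wave whose amplitude decays
  *algebraically* with distance: the susceptibility has infinite range.
  (Eigenmodes obey the lattice dispersion ω(k) = 2g(cos kx + cos ky):
  temporal frequency *falls* as spatial frequency grows, opposite to an
  ordinary wave equation.)
* **Noise-driven input** — the background variance ⟨x²⟩ enters the
  tangent-linear equation for a perturbation δ,
  dδ/dt = Aδ − 3x²δ, as an effective damping, so perturbation waves
  attenuate *exponentially* with distance, with attenuation length
  λ = 1/κ that **decreases as the input grows**.
* **Single forced Hopf oscillator** — at resonance the response amplitude is
  R = F<sup>1/3</sup> and the transient relaxes at rate 3F<sup>2/3</sup>:
  timescales set by the input, not by internal parameters.

## Worked example

```r
library(critwave)

spec <- lattice_spec(64, g = 1)                    # periodic 64 x 64 lattice
rv <- range_vs_input(spec, c(0.05, 0.1, 0.2, 0.4), # noise amplitudes
                     n_realizations = 8, seed = 1)
rv$summary[, c("eta", "lambda", "r_squared", "preferred")]
#>    eta    lambda r_squared   preferred
#> 1 0.05 17.022302 0.9854658       power
#> 2 0.10 12.124588 0.9899661 exponential
#> 3 0.20  7.831006 0.9919833 exponential
#> 4 0.40  4.751187 0.9905850 exponential
```

Each row is the exponential fit of the realisation-averaged wave profile
M(r) — the per-site maximum of |δ| after a unit impulse on a noise-driven
background, averaged over distance shells. The attenuation length `lambda`
falls monotonically from ~17 lattice units at weak drive to ~4.8 at strong
drive (`r_squared` confirms log M(r) is a line on the outer window). At the
weakest drive the profile is still near the scale-free regime, so the
power-law model narrowly wins the AIC comparison; at zero input it wins
decisively:

```r
sh  <- distance_shells(spec)
run <- tangent_propagate(spec, noise_spec(0), save_delta = FALSE)
fit_attenuation(attenuation_profile(run, sh))
#> <attenuation_fit> eta = 0: kappa = 0.01941, lambda = 51.52 (R2 = 0.898); preferred model: power
```

Other entry points: `build_coupling()` / `dispersion()` (the lattice and its
spectrum), `linear_propagate()` (exact FFT matrix exponential, the
integrator's oracle), `simulate_lattice()` / `impulse_response()` /
`front_speed()` (nonlinear dynamics), `hopf_response_table()` (forced
oscillator), and `load_config()` / `run_experiment()` with the
`inst/cli/critwave.R` script for configured runs:

```sh
Rscript inst/cli/critwave.R attenuation --seed 1 --out out/ \
    --override N=32 --override eta_grid=0.1,0.3 --override realizations=4
```

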