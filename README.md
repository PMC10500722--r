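# dressedEPR

Simulation and analysis toolkit for nanometre distance measurement between
electron spins by **dressed-spin (spin-locked) pulsed dipolar EPR** with
phase-modulated pulses.

## The problem

Pulsed dipolar EPR (DEER, DQC, SIFTER, ...) measures the electron–electron
dipole–dipole coupling, which encodes the inter-spin distance through

d(r) = (1/2π) (μ₀/4π) (μ_B² g₁g₂/ħ) r⁻³  — 52.04 MHz at r = 1 nm,

with the orientation dependence ω_dd = 2π d (1 − 3cos²θ). The longest
measurable distance is limited by the phase memory time T_m. For
narrow-line radicals (trityls), the coupling can instead be measured
*during* a strong spin lock: continuous driving decouples the electrons
from the nuclear bath (hyperfine decoupling), so coherence survives on the
much longer rotating-frame scale T_2ρ, while the electron–electron coupling
is only rescaled. Short sinusoidal phase-modulation (PM) intervals at the
Rabi frequency act as π/2 and π pulses on the *dressed* spins and generate
a dressed-spin echo whose amplitude vs the refocusing delay τ₁ oscillates
at **3/4 of the dipolar frequency** (−1/2 from the spin-lock average of the
dipolar tensor × 3/2 from the strong-coupling regime of equivalent dressed
spins). A frozen powder then yields a Pake-type spectrum with the horn at
(3/4)d and the outer edge at twice the horn.

The package is aimed at magnetic-resonance methodologists who want to
simulate this class of experiments, study its finite-drive artifacts, and
process (real or synthetic) time traces into distances.

## What is inside

- `spin_pair()`, `two_spin_hamiltonian()`, `omega_dd()`,
  `dipolar_constant_d()` — two-spin rotating-frame model (MHz/µs surface,
  rad/µs internals).
- `nutating_frame_average()` — first-order average Hamiltonian in the
  drive interaction frame; verifies offset/hyperfine decoupling, the −1/2
  dipolar scaling and exchange invariance with one quadrature mechanism.
- `dressed_echo_closed_form()`, `powder_closed_form_trace()`,
  `pake_analytic()` — the analytic oracle layer.
- `propagate()`, `dressed_echo_trace()`, `dressed_nutation()`,
  `run_phase_cycle()`, `hyperfine_decoupling_demo()` — exact piecewise
  propagation of the full phase-modulated sequence (no small-modulation
  truncation).
- `simulate_pair_echo()`, `ensemble_trace()`, `powder_average_trace()`,
  `ensemble_preset()` — the simplified phase-inversion simulator with a
  compiled Monte-Carlo ensemble kernel (10⁴ draws in seconds).
- `fit_stretched_exponential()`, `fit_background()`, `background_divide()`,
  `to_dipolar_spectrum()`, `find_singularities()`,
  `distance_from_perp_frequency()`, `process_dipolar_trace()` — the
  trace-to-distance pipeline (stretched-exponential background with ξ/3
  convention, FFT, Pake singularity picking).
- `gen_dressed_echo_trace()`, `gen_relaxation_decay()`, `synth_preset()` —
  seeded synthetic-data generators.
- `read_trace()`, `write_trace()`, `write_spectrum()` — plain-text trace
  files with JSON metadata headers; `exec/dressedepr` — a thin CLI
  (`simulate`, `synth`, `process`, `fit-decay`, `pake`, `aht-check`).

See the methods vignette (`vignettes/dressed-echo-methods.Rmd`) for the
model, conventions, numerical choices and limitations.

## Worked example

Simulate a bis-trityl-like ruler at r = 4.1 nm, add a realistic
stretched-exponential background (T = 14.3 µs, ξ = 5.4), 50% modulation
depth and 1% noise, then run the pipeline:

```r
library(dressedEPR)

spec <- synth_trace_spec(r = 4.1, lambda = 0.5, T_bg = 14.3, xi_bg = 5.4,
                         noise = 0.01, seed = 1,
                         tau1_grid = default_tau1_grid(4.1, 768, periods = 12))
trace <- gen_dressed_echo_trace(spec)
res <- process_dipolar_trace(trace, exclude_periods = 1, boxcar_periods = 1)

res$background
#> <decay_fit> A = 0.4994, T = 14.3 us (se 0.00673), xi = 5.423 (se 0.00797)
#>   residual rms = 0.00187
sprintf("nu_perp = %.4f MHz -> r = %.3f nm", res$nu_perp, res$distance_nm)
#> "nu_perp = 0.5538 MHz -> r = 4.131 nm"
```

The background fit recovers the generating parameters (A ≈ (1−λ) = 0.5,
T = 14.3 µs, ξ = 5.4); the spectrum's most prominent singularity is the
perpendicular horn near (3/4)d(4.1 nm) = 0.566 MHz, and inverting it
returns the distance within 1%. The same pipeline runs from the shell:

```sh
dressedepr synth --preset echo-r41 --seed 1
dressedepr process synthetic_echo_r41_trace.dat
```

A note on finite-drive artifacts: Monte-Carlo ensembles with broad offset
distributions (`ensemble_preset("b")`) develop an extra powder singularity
below the horn. In these simulations it sits at 0.50·d — the
weak-coupling horn of pairs with unequal offset magnitudes — with its
intensity shrinking as offsets narrow or the drive strengthens; see the
vignette for the analysis.

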