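---
title: "Dressed-spin dipolar EPR: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dressed-spin dipolar EPR: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dressedEPR)
```

## The measurement this package models

Pulsed dipolar EPR extracts nanometre distances between two electron spins
from their magnetic dipole–dipole coupling, which scales as $r^{-3}$. The
longest measurable distance is normally limited by the phase memory time
$T_m$ of the observed spins, because the dipolar oscillation must be
resolved before the echo decays. For narrow-line radicals such as trityls,
one can instead measure the coupling *during* a strong spin-lock pulse.
Under continuous driving, electron–nuclear couplings are averaged away
(hyperfine decoupling), so the dressed spins dephase on the much longer
rotating-frame time scale $T_{2\rho}$, while the electron–electron coupling
survives with a known scaling. Pulses are applied to the dressed spins by
briefly modulating the carrier phase sinusoidally at the Rabi frequency,
which drives dressed-spin nutation at $\nu_1 a_{PM}/2$; a
$\pi/2-\tau_1-\pi-\tau_2-\pi/2$ train of such phase-modulation (PM) pulses
generates a dressed-spin echo whose amplitude, as a function of $\tau_1$,
oscillates at the scaled dipolar frequency and yields a Pake-type powder
pattern after Fourier transformation.

## Spin model and units

The package works in the electron rotating frame with two coupled
spin-$1/2$ electrons:

$$
H' = \Omega_1 S_{1z} + \Omega_2 S_{2z}
  + \omega_{dd}\Bigl(S_{1z}S_{2z} - \tfrac12(S_{1x}S_{2x}+S_{1y}S_{2y})\Bigr)
  + J\,\mathbf S_1\!\cdot\!\mathbf S_2
  + \omega_1\bigl(\cos\phi\,(S_{1x}{+}S_{2x}) + \sin\phi\,(S_{1y}{+}S_{2y})\bigr),
$$

with
$\omega_{dd} = 2\pi d(r)\,(1-3\cos^2\theta)$ and
$d(r) = \frac{1}{2\pi}\frac{\mu_0}{4\pi}\frac{\mu_B^2 g_1 g_2}{\hbar r^3}$,
which evaluates to 52.04 MHz at $r = 1$ nm for free-electron $g$ factors.
Every user-facing frequency is an ordinary frequency in MHz and every time
is in µs (ns-axis trace files are converted on read); internally all
Hamiltonians are angular frequencies in rad/µs. This split exists to keep
the $2\pi$ bookkeeping in one place (`mhz_to_ang()` / `ang_to_mhz()`),
which is where such bugs usually live. Both $g$ factors default to the
free-electron value 2.00232: the trityl $g \approx 2.003$ changes $d$ only
in the fifth significant figure, and quantization-axis tilts from $g$
anisotropy are neglected throughout. All operators are generated from one
Pauli kernel (`pauli_matrices()`) in the product basis
$|\alpha\alpha\rangle,|\alpha\beta\rangle,|\beta\alpha\rangle,|\beta\beta\rangle$
with spin 1 as the left factor, so sign conventions cannot drift between
modules.

## Nutating-frame averaging

The analytic backbone is first-order average Hamiltonian theory in the
interaction frame of the drive: for a drive operator $A$ (by default
$S_{1x}+S_{2x}$),

$$
\bar H = \frac{1}{T}\int_0^T e^{i\omega_1 A t}\,H\,e^{-i\omega_1 A t}\,dt,
\qquad T = 2\pi/\omega_1 .
$$

`nutating_frame_average()` evaluates this integral by periodic trapezoidal
quadrature (256 nodes by default) and decomposes the result onto a labelled
product-operator basis. One numerical mechanism thereby verifies all four
analytic statements at once: offset terms average to zero; the dipolar
tensor is scaled by $-1/2$ and tilted onto the lock axis; isotropic
exchange is untouched; and a secular hyperfine coupling vanishes when only
the electron is driven. Because the integrand is a trigonometric polynomial
of low order in $\omega_1 t$, the periodic trapezoid rule is exact to
rounding — the test tolerances of $10^{-10}$ are met with huge margin, and
the node count is not a tuning knob.

The dressed-echo modulation frequency carries a factor $3/4$ with two
separately exposed contributions (`dressed_scale_factor()`): the $-1/2$
from the spin-lock average, and a $3/2$ because the two dressed spins are
equivalent (their dressed resonance frequencies coincide within a
molecule), putting them in the strong-coupling regime where the flip-flop
term acts in full.

## The two simulators

**Phase-inversion simulator** (`simulate_pair_echo()`,
`ensemble_trace()`). The dressed refocusing pulse is emulated by starting
both spins along $z$, evolving $\tau_1$ under the Hamiltonian above with
drive $+\nu_1$, another $\tau_1$ with $-\nu_1$, and reading
$\langle S_{1z}+S_{2z}\rangle$. The two segments have constant
Hamiltonians, so each parameter draw costs two 4×4 eigendecompositions that
are reused across the whole $\tau_1$ grid; the ensemble kernel is compiled
(RcppArmadillo) and handles $10^4$ draws over a 400-point grid in a few
seconds. The pure-R `simulate_pair_echo()` is retained as the reference
implementation and the two are required to agree to $10^{-10}$ in the
tests. Monte-Carlo ensembles draw the two offsets (Gaussian, FWHM
$\Gamma_\Omega$, mean 0 — on-resonance irradiation), optionally the
distance (Gaussian, default width 0), and the orientation with
$P(\theta)=\sin\theta$ on $[0,\pi/2]$, all independently. The independence
assumption is a modelling choice, not a fact about rigid molecules; rulers
with restricted relative orientations may violate it.

**Full sequence propagator** (`propagate()`, `dressed_echo_trace()`). The
complete experiment — bare $\pi/2$, spin lock with three PM pulses, lock
tail, and a $\tau_{SL}-\pi-\tau_{SL}$ read-out echo — is propagated
piecewise in the rotating frame. Constant-phase segments use a single
matrix exponential; during PM pulses the phase
$\phi(t)=\phi_{SL}+a_{PM}\cos(\omega_{PM}t+\phi_{PM})$ is sampled at
$dt = 1/(40\max(\nu_1,\nu_{PM}))$ with the full cosine/sine retained, so
rotating-wave-approximation breakdown at large $a_{PM}$ is part of the
model, not an error term. Steps coarser than $1/(20\max(\nu_1,\nu_{PM}))$
are refused rather than silently aliased. The modulation clock runs from
the lock start, keeping successive PM pulses phase-coherent.

Three conventions here were forced by the physics and are worth stating:

* **Constant total lock length.** If the lock grows with $\tau_1$,
  dressed coherence that was never converted back to polarization
  precesses at $\omega_1$ for a $\tau_1$-dependent time and beats against
  the scan grid, scrambling the trace. All $\tau_1$ scans therefore hold
  $T_{SL}$ fixed and move the PM block inside it.
* **Echo position rule.** The back-conversion pulse belongs at
  $\tau_2 = \tau_1 + t_{\pi/2}$ (the PM-$\pi/2$ length). The propagator
  confirms this: the spread of the echo over dressed offsets
  $\Omega_d = \omega_1-\omega_{PM}$ is minimized exactly there.
* **Effective evolution time.** Because the PM pulses have finite length,
  the full-sequence echo equals the ideal phase-inversion result at
  $\tau_1 + t_{\pi/2}$; the offset equals one PM-$\pi/2$ length to within
  1% RMS at $a_{PM}=0.1$ and scales with $1/a_{PM}$ as expected. This is
  the same pulse-centre bookkeeping used for finite pulses in conventional
  dipolar spectroscopy, and `dressed_echo_trace()` reports it in the trace
  metadata rather than silently shifting the axis.

Two read-outs are available. `readout = "lock"` samples the magnetization
component along the lock axis at the end of the lock — the direct analogue
of the simplified simulator's observable, and the right choice for
simulator cross-validation. `readout = "echo"` appends the
$\tau_{SL}-\pi-\tau_{SL}$ block and returns the complex echo amplitude;
dipolar evolution during $2\tau_{SL}$ then admixes two-spin order into the
echo (a $\cos(\omega_{dd}\tau_{SL})$-type filter), which is visible for
single orientations and short distances. The default phase cycle is a
16-step table: two-step inversions of the first and last PM-pulse phases
with receiver sign alternation, times a four-step EXORCYCLE rotation of the
refocusing-pulse phase with an $e^{-2i\phi_3}$ receiver. In a noiseless
simulation a CYCLOPS rotation of the bare pulse phases is inert (it exists
to cancel receiver imperfections), so it is not part of the default; the
measured suppression of $\tau_0$-dependent crossing-echo variation is about
5× for the default table, and the table is fully user-overridable.

## The low-frequency artifact

With offset distributions of realistic width
($\Gamma_\Omega \sim 8$–16 MHz at $\nu_1 = 100$ MHz), the ensemble
spectra develop structure below the $\tfrac34 d$ horn. The simulations
localize its origin sharply: pairs whose two offsets have *equal
magnitude* keep the $\tfrac34 d$ modulation, while pairs with unequal
magnitudes (difference of effective-field magnitudes beyond roughly the
dipolar coupling — a few MHz here) switch to $\tfrac12 d\,(1-3\cos^2\theta)$.
This is the weak-coupling limit: the dressed spins become inequivalent, the
$3/2$ equivalent-spin factor drops to 1, and only the $-1/2$ spin-lock
scaling survives. The powder horn of this subensemble therefore sits at
$0.50\,d$ — i.e. at $2/3$ of the main horn, not at half of it. A naive
estimate that simply halves the $\tfrac34$-scaled frequency would predict
$0.375\,d$; that value does not emerge from the model, and the package's
acceptance checks record the discrepancy rather than paper over it. The
transition is sharp (between 2 and 3 MHz of asymmetry for $r = 5.3$ nm at
$\nu_1 = 100$ MHz), was confirmed against an independent propagator, and
is insensitive to grid density, trace length, windowing and draw count.
The artifact *intensity* behaves as expected of a finite-drive effect: the
integrated band below the horn shrinks monotonically when
$\Gamma_\Omega$ drops from 16 to 8 MHz and further when $\nu_1$ rises to
200 and 400 MHz.

## Processing pipeline

`fit_stretched_exponential()` fits $A\exp(-(t/T)^{\xi/3})$. The $\xi/3$
exponent convention makes fitted $\xi$ of 2.4–5.9 correspond to
conventional stretch exponents 0.8–2.0. Initialization is deterministic
($A = y_1$, $T$ from the interpolated $1/e$ crossing, $\xi = 3$, bounds
$\xi \in [0.3, 12]$), so fits are reproducible; non-convergence is flagged,
never silent. The covariance matrix is reported because it carries real
information: a $T \approx 930$ µs decay observed only to 40 µs returns $T$
with a relative standard error above 10% — the fit is honest about being
ill-conditioned rather than confidently wrong.

For dipolar traces the background envelope is fitted with the oscillation
treated as noise. Two options control the known bias this induces:
excluding the first `exclude_periods` oscillation periods (where the
coherent kernel decays from 1 and drags $T$ and $\xi$ down), and a
one-period boxcar prefilter that cancels the residual oscillation while
leaving the slow envelope intact. Both default to off; with both enabled
on a 12-period trace at 1% noise, $T$ and $\xi$ recover within a few
percent, whereas the naive full-trace fit misses $\xi$ by over 10%. The
spectrum step subtracts the mean, optionally applies a half-Hamming window
over the decay, zero-fills (default 4×, 8× in the pipeline wrapper) and
returns the real part of the FFT — the $t=0$ sample is a pure cosine
reference, so the real part is the absorption-mode dipolar spectrum; a
magnitude mode is available since the choice is not observable-critical.

`find_singularities()` returns local maxima above a prominence threshold
plus the outer spectral edge, estimated as the interpolated half-maximum
crossing beyond the highest shoulder outside $1.3\times$ the horn. The
edge estimator is nearly unbiased (it locates a step midpoint), while the
horn of a finite-window spectrum is biased low because the underlying
lineshape diverges one-sidedly: about $-4\%$ with a 6-period window,
$-2\%$ at 12, and under $-1\%$ at 24 periods. Consequently the edge/horn
ratio of an ideal $\tfrac34$-scaled pattern measures 2.07/2.05/2.02 at
6/12/24 periods. Analyses that need the ratio or absolute horn position
accurately should use long windows; the distance error inherits one third
of the horn bias ($r \propto \nu_\perp^{-1/3}$), so even the 6-period
default stays within 1.5%. Distances come from
$r = (s\,d_{1\,\mathrm{nm}}/\nu_\perp)^{1/3}$ with the 1-nm constant
evaluated from fundamental constants and $s = 3/4$ by default ($s = 1$
for bare-spin data).

## Synthetic data

`gen_dressed_echo_trace()` produces
$V(t) = [(1-\lambda) + \lambda K(t)]\,e^{-(t/T)^{\xi/3}} + \varepsilon(t)$
on a $\tau_1$ grid, with $K$ either the closed-form powder kernel or a
Monte-Carlo ensemble trace (for artifact-bearing fixtures), and
$\varepsilon$ seeded i.i.d. Gaussian noise. Default modulation depth is
$\lambda = 0.5$: measured depths fall well below the ideal 1 (imperfect
dressed $\pi$ pulses leave an unmodulated fraction), no precise value is
established, and every fixture records $\lambda$ in its metadata. Default
background parameters ($T = 14.3$ µs, $\xi = 5.4$) and the relaxation
presets (2.9/5.9, 13.1/4.6, 930/2.4 and companions) mirror the measured
constants of the mono- and bis-trityl compounds. The generators emulate
the *statistical structure* of real traces — modulation at $\tfrac34 d$
with partial depth, stretched-exponential envelope, additive noise. They
do not model ESEEM, instantaneous diffusion, intermolecular backgrounds as
physical processes, correlated offset/orientation distributions, or
multiplicative noise; pipeline tests passing on these fixtures show the
processing is self-consistent at realistic SNR, not that real spectrometer
data contain no further surprises.

## Time-axis convention

Dipolar traces are indexed by the refocusing delay $\tau_1$, on which the
echo modulation $\cos(\tfrac34\omega_{dd}\tau_1)$ and hence the horn at
$\tfrac34 d$ are defined. Relaxation constants quoted for dressed-echo
decays conventionally refer to the total evolution time $t = 2\tau_1$;
the fitting functions operate on whatever axis they are given, so users
quoting $T_{2\rho}$ against $2\tau_1$ should pass that axis. Generator and
fitter share one axis in all round trips, making the package internally
consistent either way.

## Problem sizes used in the shipped tests

Unit and property tests run on 30–300 point grids and $\leq 6.4\times10^3$
Monte-Carlo draws. The end-to-end checks use: $10^4$ draws per ensemble for
the artifact study (400-point grid, four drive/offset configurations); a
1536-point, 24-period quadrature trace for the edge/horn ratio; 768-point,
12-period synthetic traces for the pipeline round trip; and a 17-point
$\tau_1$ scan for the full-sequence/simplified-simulator comparison. These
sizes were chosen so that discretization and Monte-Carlo error sit well
below the tolerances being asserted, as verified by the convergence
studies above.

## Known limitations

Resonator/amplifier distortions, drive noise (a plausible $T_{2\rho}$
contribution), stochastic relaxation superoperators, $g$-tensor
anisotropy, systems with more than two electron spins, and
distance-*distribution* recovery (Tikhonov-style $P(r)$ inversion) are all
out of scope. Decays enter only through the phenomenological
stretched-exponential envelope. The electron–nucleus module is a 4×4
demonstration of hyperfine decoupling, not a nuclear spin-bath model.
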