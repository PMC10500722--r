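#' Physical constants used throughout the package
#'
#' Returns the CODATA values needed to evaluate the electron-electron
#' dipole-dipole coupling: the magnetic constant factor \eqn{\mu_0/4\pi},
#' the Bohr magneton, the reduced Planck constant and the free-electron
#' g factor.
#'
#' @return A named list with elements `mu0_over_4pi` (T m/A), `muB` (J/T),
#'   `hbar` (J s) and `g_free` (dimensionless).
#' @export
#' @examples
#' epr_constants()$g_free
epr_constants <- function() {
  list(
    mu0_over_4pi = 1e-7,          # T m / A
    muB          = 9.2740100783e-24,  # J / T
    hbar         = 1.054571817e-34,   # J s
    g_free       = 2.00232
  )
}

#' Dipolar splitting constant d
#'
#' Evaluates the dipolar coupling prefactor
#' \deqn{d = \frac{1}{2\pi}\frac{\mu_0}{4\pi}\frac{\mu_B^2 g_1 g_2}{\hbar}
#'       \frac{1}{r^3}}
#' in ordinary frequency units. For two free electrons at 1 nm separation this
#' is 52.04 MHz; it falls off as \eqn{r^{-3}}.
#'
#' @param r Inter-spin distance in nm (strictly positive).
#' @param g1,g2 g factors of the two electrons; default free-electron value.
#' @return Dipolar constant in MHz.
#' @export
#' @examples
#' dipolar_constant_d(1)    # 52.04 MHz
#' dipolar_constant_d(4.1)  # 0.755 MHz
dipolar_constant_d <- function(r, g1 = epr_constants()$g_free, g2 = g1) {
  if (!all(is.finite(r)) || any(r <= 0))
    stop("`r` must be finite and > 0 (nm)")
  k <- epr_constants()
  r_m <- r * 1e-9
  d_hz <- k$mu0_over_4pi * k$muB^2 * g1 * g2 / k$hbar / r_m^3 / (2 * pi)
  d_hz / 1e6
}

#' Orientation-dependent dipolar coupling
#'
#' Angular dipolar coupling frequency
#' \eqn{\omega_{dd} = 2\pi d(r)\,(1 - 3\cos^2\theta)} for a spin pair whose
#' inter-spin vector makes angle `theta` with the static field. Vanishes at
#' the magic angle \eqn{\theta = \arccos(1/\sqrt{3})} and equals
#' \eqn{2\pi d} at \eqn{\theta = \pi/2}.
#'
#' @inheritParams dipolar_constant_d
#' @param theta Angle between field and inter-spin vector, rad.
#' @return Angular frequency in rad/us.
#' @export
omega_dd <- function(r, theta, g1 = epr_constants()$g_free, g2 = g1) {
  if (!all(is.finite(theta))) stop("`theta` must be finite")
  2 * pi * dipolar_constant_d(r, g1, g2) * (1 - 3 * cos(theta)^2)
}

# MHz (ordinary frequency) <-> rad/us (angular frequency)
mhz_to_ang <- function(nu) 2 * pi * nu
ang_to_mhz <- function(w) w / (2 * pi)
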