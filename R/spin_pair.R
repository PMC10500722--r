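#' Physical description of one electron-spin pair
#'
#' Bundles the parameters of a dipolar-coupled pair of spin-1/2 electrons:
#' distance, orientation, drive strength, bare resonance offsets, g factors
#' and exchange coupling. All frequencies are ordinary frequencies in MHz;
#' angles in rad.
#'
#' @param r Inter-spin distance, nm (> 0).
#' @param theta Angle between static field and inter-spin vector, rad, in
#'   `[0, pi/2]`.
#' @param nu1 Drive Rabi frequency \eqn{\nu_1}, MHz (>= 0).
#' @param offset1,offset2 Bare resonance offsets \eqn{\Omega_{S,1}/2\pi},
#'   \eqn{\Omega_{S,2}/2\pi}, MHz.
#' @param g1,g2 g factors.
#' @param J Exchange coupling \eqn{J/2\pi}, MHz.
#' @return Object of class `spin_pair`.
#' @export
#' @examples
#' spin_pair(r = 4.1, theta = pi / 2, nu1 = 100)
spin_pair <- function(r, theta = pi / 2, nu1 = 100,
                      offset1 = 0, offset2 = 0,
                      g1 = epr_constants()$g_free, g2 = g1, J = 0) {
  vals <- c(r = r, theta = theta, nu1 = nu1, offset1 = offset1,
            offset2 = offset2, g1 = g1, g2 = g2, J = J)
  if (!all(is.finite(vals))) stop("all spin-pair parameters must be finite")
  if (r <= 0) stop("`r` must be > 0 (nm)")
  if (theta < 0 || theta > pi / 2) stop("`theta` must lie in [0, pi/2]")
  if (nu1 < 0) stop("`nu1` must be >= 0 (MHz)")
  structure(as.list(vals), class = "spin_pair")
}

#' @export
print.spin_pair <- function(x, ...) {
  cat(sprintf(
    "<spin_pair> r = %.3g nm, theta = %.4g rad, nu1 = %.4g MHz\n", x$r,
    x$theta, x$nu1))
  cat(sprintf("  offsets = (%.4g, %.4g) MHz, g = (%.5f, %.5f), J = %.4g MHz\n",
              x$offset1, x$offset2, x$g1, x$g2, x$J))
  cat(sprintf("  d = %.4g MHz, 3/4 d = %.4g MHz\n",
              dipolar_constant_d(x$r, x$g1, x$g2),
              0.75 * dipolar_constant_d(x$r, x$g1, x$g2)))
  invisible(x)
}

# rotating-frame interaction Hamiltonian (offsets + dipolar + exchange),
# rad/us, without any drive term
interaction_hamiltonian <- function(pair) {
  ops <- spin_operators(2)
  wdd <- omega_dd(pair$r, pair$theta, pair$g1, pair$g2)
  H <- mhz_to_ang(pair$offset1) * ops$S1z +
    mhz_to_ang(pair$offset2) * ops$S2z +
    wdd * (ops$S1z %*% ops$S2z -
             0.5 * (ops$S1x %*% ops$S2x + ops$S1y %*% ops$S2y))
  if (pair$J != 0)
    H <- H + mhz_to_ang(pair$J) *
      (ops$S1x %*% ops$S2x + ops$S1y %*% ops$S2y + ops$S1z %*% ops$S2z)
  H
}

#' Rotating-frame Hamiltonian of a driven spin pair
#'
#' Assembles the full rotating-frame two-spin Hamiltonian
#' \deqn{H' = \Omega_1 S_{1z} + \Omega_2 S_{2z}
#'   + \omega_{dd}(S_{1z}S_{2z} - \tfrac12(S_{1x}S_{2x} + S_{1y}S_{2y}))
#'   + J\,\mathbf{S}_1\cdot\mathbf{S}_2
#'   + 2\pi\nu_1(\cos\phi\,(S_{1x}+S_{2x}) + \sin\phi\,(S_{1y}+S_{2y}))}
#' in angular frequency units (rad/us). The signed `drive_nu` supports the
#' mid-lock phase inversion of the simplified simulator.
#'
#' @param pair A [spin_pair()].
#' @param drive_nu Signed drive amplitude in MHz (defaults to `pair$nu1`).
#' @param drive_phase Drive phase \eqn{\phi}, rad.
#' @return Complex Hermitian 4x4 matrix, rad/us.
#' @export
two_spin_hamiltonian <- function(pair, drive_nu = pair$nu1, drive_phase = 0) {
  if (!inherits(pair, "spin_pair")) stop("`pair` must be a spin_pair")
  if (!is.finite(drive_nu) || !is.finite(drive_phase))
    stop("drive parameters must be finite")
  ops <- spin_operators(2)
  interaction_hamiltonian(pair) +
    mhz_to_ang(drive_nu) *
      (cos(drive_phase) * ops$Sx + sin(drive_phase) * ops$Sy)
}
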