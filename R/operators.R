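#' Pauli matrices
#'
#' The single Pauli kernel from which every spin operator in the package is
#' generated, so sign conventions cannot drift between modules.
#'
#' @return Named list of complex 2x2 matrices `x`, `y`, `z`, `id`.
#' @export
pauli_matrices <- function() {
  list(
    x  = matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    y  = matrix(c(0, 1i, -1i, 0), 2, 2),
    z  = diag(c(1, -1)) + 0i,
    id = diag(2) + 0i
  )
}

#' Product-basis spin operators for one or two spin-1/2 particles
#'
#' Builds Cartesian spin operators in the product basis
#' \eqn{|\alpha\alpha\rangle, |\alpha\beta\rangle, |\beta\alpha\rangle,
#' |\beta\beta\rangle} with spin 1 as the left Kronecker factor. The same
#' 4x4 layout serves the electron-electron pair and the electron-nucleus
#' demonstration system (spin 1 = electron, spin 2 = nucleus).
#'
#' @param nspins 1 or 2.
#' @return For `nspins = 1`, a list with `Sx`, `Sy`, `Sz` (2x2). For
#'   `nspins = 2`, a list with `S1x` ... `S2z`, totals `Sx`, `Sy`, `Sz`,
#'   and `id`.
#' @export
spin_operators <- function(nspins = 2) {
  p <- pauli_matrices()
  if (nspins == 1)
    return(list(Sx = p$x / 2, Sy = p$y / 2, Sz = p$z / 2, id = p$id))
  if (nspins != 2) stop("`nspins` must be 1 or 2")
  ops <- list(
    S1x = kronecker(p$x / 2, p$id), S1y = kronecker(p$y / 2, p$id),
    S1z = kronecker(p$z / 2, p$id),
    S2x = kronecker(p$id, p$x / 2), S2y = kronecker(p$id, p$y / 2),
    S2z = kronecker(p$id, p$z / 2)
  )
  ops$Sx <- ops$S1x + ops$S2x
  ops$Sy <- ops$S1y + ops$S2y
  ops$Sz <- ops$S1z + ops$S2z
  ops$id <- diag(4) + 0i
  ops
}

#' Labelled two-spin product-operator basis
#'
#' Orthonormal (Hilbert-Schmidt) basis of the 4x4 operator space built from
#' products of `{id, x, y, z}` on each spin, used to decompose averaged
#' Hamiltonians into named terms such as `"z1"`, `"x1x2"`.
#'
#' @return Named list of complex 4x4 matrices with unit Frobenius norm.
#' @export
two_spin_basis <- function() {
  p <- pauli_matrices()
  half <- list(id = p$id, x = p$x / 2, y = p$y / 2, z = p$z / 2)
  out <- list()
  for (n1 in names(half)) for (n2 in names(half)) {
    op <- kronecker(half[[n1]], half[[n2]])
    lab <- if (n1 == "id" && n2 == "id") "id"
    else if (n2 == "id") paste0(n1, "1")
    else if (n1 == "id") paste0(n2, "2")
    else paste0(n1, "1", n2, "2")
    out[[lab]] <- op / sqrt(sum(Mod(op)^2))
  }
  out
}

# Hermiticity check helper
is_hermitian <- function(M, tol = 1e-12) {
  max(Mod(M - Conj(t(M)))) < tol
}

# propagator for a constant Hermitian Hamiltonian (rad/us) over dt (us)
propagator <- function(H, dt) {
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values * dt) * Conj(t(e$vectors)))
}

# conjugation rho -> U rho U^H
evolve <- function(rho, U) U %*% rho %*% Conj(t(U))

expect_val <- function(rho, op) Re(sum(diag(rho %*% op)))
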