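// Monte-Carlo kernel for the phase-inversion spin-lock simulator.
//
// For each parameter draw the two-spin Hamiltonian (rotating frame,
// rad/us) is
//   H(+/-) = W1*S1z + W2*S2z + wdd*(S1z S2z - (S1x S2x + S1y S2y)/2)
//            +/- w1*(S1x + S2x)
// and the reported signal is <S1z + S2z> after evolving the initial
// state S1z + S2z for tau under H(+) and tau under H(-) (the mid-lock
// phase inversion that emulates the dressed refocusing pulse).
//
// Propagation uses one eigendecomposition of each constant Hamiltonian
// per draw, reused across the whole tau grid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cx_mat pair_hamiltonian(double W1, double W2, double wdd, double w1) {
  cx_mat H(4, 4, fill::zeros);
  // S1z, S2z diagonals and S1zS2z in |aa, ab, ba, bb> product order
  H(0, 0) = cx_double(0.5 * W1 + 0.5 * W2 + 0.25 * wdd, 0.0);
  H(1, 1) = cx_double(0.5 * W1 - 0.5 * W2 - 0.25 * wdd, 0.0);
  H(2, 2) = cx_double(-0.5 * W1 + 0.5 * W2 - 0.25 * wdd, 0.0);
  H(3, 3) = cx_double(-0.5 * W1 - 0.5 * W2 + 0.25 * wdd, 0.0);
  // -(wdd/2)(S1xS2x + S1yS2y): flip-flop between |ab> and |ba>
  H(1, 2) = cx_double(-0.25 * wdd, 0.0);
  H(2, 1) = cx_double(-0.25 * wdd, 0.0);
  // drive w1*(S1x + S2x)
  const cx_double hx(0.5 * w1, 0.0);
  H(0, 1) += hx; H(1, 0) += hx;
  H(0, 2) += hx; H(2, 0) += hx;
  H(1, 3) += hx; H(3, 1) += hx;
  H(2, 3) += hx; H(3, 2) += hx;
  return H;
}

// [[Rcpp::export(name = ".ens_echo_cpp")]]
arma::vec ens_echo_cpp(const arma::vec& W1, const arma::vec& W2,
                       const arma::vec& wdd, const arma::vec& w1,
                       const arma::vec& tau, const arma::vec& weights) {
  const uword ndraw = W1.n_elem, ntau = tau.n_elem;
  if (W2.n_elem != ndraw || wdd.n_elem != ndraw || w1.n_elem != ndraw ||
      weights.n_elem != ndraw)
    Rcpp::stop("draw parameter vectors must have equal length");

  vec acc(ntau, fill::zeros);
  const vec mdiag = {1.0, 0.0, 0.0, -1.0};  // S1z + S2z
  cx_mat M = conv_to<cx_mat>::from(diagmat(mdiag));

  for (uword i = 0; i < ndraw; ++i) {
    cx_mat Hp = pair_hamiltonian(W1(i), W2(i), wdd(i), w1(i));
    cx_mat Hm = pair_hamiltonian(W1(i), W2(i), wdd(i), -w1(i));
    vec Ep, Em;
    cx_mat Vp, Vm;
    eig_sym(Ep, Vp, Hp);
    eig_sym(Em, Vm, Hm);
    cx_mat W = Vm.t() * Vp;        // .t() is the conjugate transpose
    cx_mat Mt = Vm.t() * M * Vm;
    // initial density operator S1z+S2z = |aa><aa| - |bb><bb|
    cx_vec c_up = Vp.row(0).t();   // Vp^H e_1
    cx_vec c_dn = Vp.row(3).t();   // Vp^H e_4
    for (uword j = 0; j < ntau; ++j) {
      const double t = tau(j);
      cx_vec php = exp(cx_double(0.0, -1.0) * conv_to<cx_vec>::from(Ep) * t);
      cx_vec phm = exp(cx_double(0.0, -1.0) * conv_to<cx_vec>::from(Em) * t);
      cx_vec psi_up = phm % (W * (php % c_up));
      cx_vec psi_dn = phm % (W * (php % c_dn));
      double s = real(cdot(psi_up, Mt * psi_up)) -
                 real(cdot(psi_dn, Mt * psi_dn));
      acc(j) += weights(i) * s;
    }
  }
  return acc;
}
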