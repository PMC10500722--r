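# Shared fixtures and independent oracles for the test suite.

# relaxation constants (T in us, xi) of the three measured compounds
printed_decay_pairs <- list(
  mono_tm    = c(2.9, 5.9),  mono_t2rho = c(13.1, 4.6),
  mono_t1rho = c(930, 2.4),
  r41_tm     = c(3.3, 5.3),  r41_t1rho  = c(560, 2.9),
  r41_bg     = c(14.3, 5.4),
  r53_tm     = c(2.6, 4.9),  r53_t1rho  = c(730, 2.4),
  r53_bg     = c(14.5, 4.4)
)

# Monte-Carlo orientation average of the closed-form echo modulation:
# independent oracle for the quadrature-based powder kernel
mc_powder_oracle <- function(r, tau1, n = 20000, seed = 42) {
  set.seed(seed)
  th <- acos(stats::runif(n))
  w <- omega_dd(r, th)
  vapply(tau1, function(tt) mean(cos(0.75 * w * tt)), 0)
}

# frequency of the highest local maximum of a dipolar spectrum
peak_frequency <- function(spec) {
  a <- spec$amplitude
  lm <- which(diff(sign(diff(a))) == -2) + 1
  spec$frequency[lm[which.max(a[lm])]]
}

# operators shared by several files
test_ops <- spin_operators(2)
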