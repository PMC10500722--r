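test_that("phase profile follows the modulation only inside the pulse", {
  dr <- drive_params(nu1 = 100, phi0 = 0.2, a_pm = 0.3, nu_pm = 100)
  pulse <- pm_pulse(start = 0.1, duration = 0.05, phi_pm = 0)
  expect_equal(phase_profile(0.05, dr, pulse), 0.2)       # before the pulse
  expect_equal(phase_profile(0.3, dr, pulse), 0.2)        # after the pulse
  # at a time where the modulation clock is at phase 0: phi0 + a_pm
  t0 <- 0.11  # wpm * t = 2 pi * 100 * 0.11 = 22 pi = 0 mod 2 pi
  expect_equal(phase_profile(t0, dr, pulse), 0.2 + 0.3, tolerance = 1e-12)
  expect_equal(phase_profile(0.123, drive_params(a_pm = 0), NULL), 0)
  ts <- seq(0.1, 0.15, length.out = 101)
  expect_lt(max(abs(phase_profile(ts, dr, pulse) - 0.2)), 0.3 + 1e-12)
})

test_that("propagation core reproduces single-spin Rabi rotations", {
  one <- spin_operators(1)
  H <- 2 * pi * 100 * one$Sx
  U <- dressedEPR:::propagator(H, 1 / 400)  # quarter Rabi period = pi/2
  rho <- dressedEPR:::evolve(one$Sz + 0i, U)
  expect_equal(dressedEPR:::expect_val(rho, one$Sz), 0, tolerance = 1e-10)
  expect_equal(abs(dressedEPR:::expect_val(rho, one$Sy)), 0.5,
               tolerance = 1e-10)
  # lock along the magnetization holds it
  Ul <- dressedEPR:::propagator(2 * pi * 100 * one$Sy, 0.777)
  rho2 <- dressedEPR:::evolve(rho, Ul)
  expect_equal(dressedEPR:::expect_val(rho2, one$Sy),
               dressedEPR:::expect_val(rho, one$Sy), tolerance = 1e-9)
})

test_that("propagate refuses aliasing-coarse steps and conserves the norm", {
  p <- spin_pair(4.1, pi / 2, 100)
  dr <- drive_params(100, a_pm = 0.1)
  sq <- sequence_spec(tau1 = 0.3)
  expect_error(propagate(p, sq, dr, dt = 1), "too coarse")
  out <- propagate(p, sq, dr, readout = "lock")
  norm0 <- sqrt(sum(Mod(test_ops$Sz)^2))
  expect_equal(sqrt(sum(Mod(out$rho)^2)), norm0, tolerance = 1e-8)
  expect_equal(Re(sum(diag(out$rho))), 0, tolerance = 1e-10)
})

test_that("full sequence reproduces the closed-form dipolar modulation", {
  # zero offsets, single orientation: echo vs tau1 follows cos(3/4 wdd tau)
  p <- spin_pair(4.1, pi / 2, 100)
  dr <- drive_params(100, a_pm = 0.1)
  d <- dipolar_constant_d(4.1)
  tg <- seq(0, 1.5 / (0.75 * d), length.out = 9)
  tr <- dressed_echo_trace(p, dr, tg, readout = "lock")
  ref <- dressed_echo_closed_form(tg + tr$meta$tau_eff_offset,
                                  omega_dd(4.1, pi / 2))
  expect_lt(sqrt(mean((tr$y - ref)^2)), 0.02)
})

test_that("dipolar-free pair gives a flat full-sequence trace", {
  p <- spin_pair(3, acos(1 / sqrt(3)), 100)  # magic angle: no coupling
  dr <- drive_params(100, a_pm = 0.1)
  tg <- seq(0, 1.2, length.out = 5)
  tr <- dressed_echo_trace(p, dr, tg, readout = "lock")
  expect_lt(max(abs(tr$y - 1)), 5e-3)
})

test_that("refocused echo is least sensitive to the dressed offset at the rule point", {
  # tau2 = tau1 + t90_pm minimizes the spread over Omega_d = nu1 - nu_pm
  p <- spin_pair(4.1, pi / 2, 100)
  t90 <- 1 / (2 * 100 * 0.1)
  tau1 <- 0.4
  offs <- seq(-0.04, 0.04, by = 0.02)
  S <- sapply(c(97, 99, 101, 103), function(npm) {
    dr <- drive_params(100, a_pm = 0.1, nu_pm = npm)
    sapply(offs, function(o) {
      sq <- sequence_spec(tau1 = tau1, tau2 = tau1 + t90 + o)
      propagate(p, sq, dr, readout = "lock")$signal
    })
  })
  spread <- apply(S, 1, function(r) max(r) - min(r))
  expect_equal(offs[which.min(spread)], 0)
})

test_that("PM nutation runs at nu1*a_pm/2 and slows down at large amplitude", {
  p <- spin_pair(3, acos(1 / sqrt(3)), 100)  # uncoupled pair isolates the drive
  dr <- drive_params(100, a_pm = 0.1)
  tr <- dressed_nutation(p, dr, seq(0, 0.42, length.out = 57))
  expect_equal(dominant_frequency(tr), 5, tolerance = 0.05 * 5)
  # a_pm = 0: flat trace
  tr0 <- dressed_nutation(p, drive_params(100, a_pm = 0),
                          seq(0, 0.2, length.out = 9))
  expect_lt(max(tr0$y) - min(tr0$y), 1e-8)
  # a_pm = 0.3: pi time bracketed by the nominal 33.3 ns and 45 ns
  tr3 <- dressed_nutation(p, drive_params(100, a_pm = 0.3),
                          seq(0, 0.06, length.out = 61))
  t_pi <- tr3$t[which.min(tr3$y / tr3$y[1])]
  expect_gte(t_pi, 0.032)
  expect_lte(t_pi, 0.045)
})

test_that("single-step cycle reduces to plain propagation", {
  p <- spin_pair(4.1, pi / 2, 100, offset1 = 2, offset2 = -1)
  dr <- drive_params(100, a_pm = 0.1)
  sq <- sequence_spec(tau1 = 0.25)
  tab <- data.frame(phi1 = 0, phi2 = 0, phi3 = pi / 2, phi4 = 0,
                    receiver = complex(real = 1))
  expect_equal(run_phase_cycle(p, sq, dr, cycle = tab),
               propagate(p, sq, dr)$signal, tolerance = 1e-12)
  expect_error(run_phase_cycle(p, sq, dr, cycle = tab[0, ]), "empty")
})

test_that("phase cycling suppresses tau0-dependent crossing-echo signal", {
  p <- spin_pair(4.1, pi / 2, 100, offset1 = 4, offset2 = -2)
  dr <- drive_params(100, a_pm = 0.1, nu_pm = 97)
  tau0s <- seq(0.05, 0.11, by = 0.02)
  one <- function(t0, cyc) {
    sq <- sequence_spec(tau1 = 0.3, tau0 = t0, t_sl = 2.0, tau_sl = 0.05)
    if (is.null(cyc)) propagate(p, sq, dr, readout = "echo")$signal
    else run_phase_cycle(p, sq, dr, cycle = cyc, readout = "echo")
  }
  un <- sapply(tau0s, one, cyc = NULL)
  cy <- sapply(tau0s, one, cyc = default_phase_cycle())
  variation <- function(z) stats::sd(Re(z)) + stats::sd(Im(z))
  expect_gt(variation(un) / variation(cy), 3)
})

test_that("cycled magic-angle pair has no tau1 dependence", {
  p <- spin_pair(3, acos(1 / sqrt(3)), 100)
  dr <- drive_params(100, a_pm = 0.1)
  sig <- sapply(c(0.1, 0.5, 0.9), function(tt)
    run_phase_cycle(p, sequence_spec(tau1 = tt, t_sl = 2.3), dr,
                    cycle = default_phase_cycle(exorcycle = FALSE),
                    readout = "lock"))
  expect_lt(max(sig) - min(sig), 5e-3)
})

test_that("hyperfine decoupling strengthens with the drive", {
  expect_equal(hyperfine_decoupling_demo(A_nu = 0, nu1 = 100), 1)
  a100 <- hyperfine_decoupling_demo(A_nu = 5, nu1 = 100)
  a50 <- hyperfine_decoupling_demo(A_nu = 5, nu1 = 50)
  expect_lt(a100, 1)
  expect_lt(a100, a50)            # stronger drive decouples better
  expect_gte(a50, 2 * a100 * 0.8) # roughly (A/2 nu1)^2-like scaling
  expect_equal(hyperfine_decoupling_demo(A_nu = 5, nu1 = 0), 1,
               tolerance = 1e-9)
})

test_that("detuning the modulation acts as a dressed-spin offset", {
  # a dressed offset Omega_d = nu1 - nu_pm detunes the PM nutation the
  # same way a bare offset detunes a bare Rabi oscillation:
  # f_eff = sqrt(f_nut^2 + delta^2)
  p <- spin_pair(3, acos(1 / sqrt(3)), 100)
  for (delta in c(0, 3, 5)) {
    dr <- drive_params(100, a_pm = 0.1, nu_pm = 100 - delta)
    tr <- dressed_nutation(p, dr, seq(0, 0.5, length.out = 81))
    expect_equal(dominant_frequency(tr), sqrt(5^2 + delta^2),
                 tolerance = 0.05)
  }
})
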