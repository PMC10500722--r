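#' Microwave drive parameters
#'
#' Carrier and phase-modulation parameters of the spin-lock drive. During a
#' phase-modulation (PM) pulse the carrier phase follows
#' \eqn{\phi_{mw}(t) = \phi_0 + a_{PM}\cos(\omega_{PM} t + \phi_{PM})},
#' which acts as a resonant pulse on the dressed spins with nutation
#' frequency \eqn{\nu_1 a_{PM}/2} when \eqn{\omega_{PM} = \omega_1}. Large
#' `a_pm` deliberately leaves the rotating-wave regime (Bloch-Siegert
#' oscillations in nutation traces); no small-amplitude truncation is made
#' anywhere in the propagation.
#'
#' @param nu1 Rabi frequency \eqn{\nu_1}, MHz (>= 0).
#' @param phi0 Carrier phase, rad.
#' @param a_pm Modulation amplitude, rad (>= 0).
#' @param nu_pm Modulation frequency \eqn{\omega_{PM}/2\pi}, MHz; defaults
#'   to `nu1` (on-resonance dressed drive).
#' @return Object of class `drive_params`.
#' @export
drive_params <- function(nu1 = 100, phi0 = 0, a_pm = 0.1, nu_pm = nu1) {
  if (nu1 < 0 || a_pm < 0) stop("`nu1` and `a_pm` must be >= 0")
  structure(list(nu1 = nu1, phi0 = phi0, a_pm = a_pm, nu_pm = nu_pm),
            class = "drive_params")
}

#' Dressed-spin nutation frequency of a PM pulse
#'
#' First-order (rotating-wave) value \eqn{\nu_1 a_{PM}/2}.
#'
#' @param drive A [drive_params()].
#' @return Nutation frequency in MHz.
#' @export
pm_nutation_frequency <- function(drive) drive$nu1 * drive$a_pm / 2

# nominal PM pulse lengths (us) from the first-order nutation frequency
pm_pulse_lengths <- function(drive) {
  fn <- pm_nutation_frequency(drive)
  if (fn <= 0) stop("PM nutation frequency is zero; set nu1 and a_pm > 0")
  list(t90 = 1 / (4 * fn), t180 = 1 / (2 * fn))
}

#' A phase-modulation pulse within the spin lock
#'
#' @param start Start time within the lock, us (>= 0).
#' @param duration Pulse length, us (> 0).
#' @param phi_pm Dressed-pulse phase \eqn{\phi_{PM}}, rad.
#' @param a_pm Optional per-pulse amplitude override, rad.
#' @return Object of class `pm_pulse`.
#' @export
pm_pulse <- function(start, duration, phi_pm = 0, a_pm = NULL) {
  if (duration <= 0) stop("`duration` must be > 0")
  if (start < 0) stop("`start` must be >= 0")
  structure(list(start = start, duration = duration, phi_pm = phi_pm,
                 a_pm = a_pm), class = "pm_pulse")
}

#' Instantaneous carrier phase
#'
#' \eqn{\phi_0} outside PM pulses;
#' \eqn{\phi_0 + a_{PM}\cos(\omega_{PM} t + \phi_{PM})} inside. The
#' modulation clock `t` is global (time since lock start), so the relative
#' phases of successive PM pulses stay coherent.
#'
#' @param t Time since lock start, us. Vectorized.
#' @param drive A [drive_params()].
#' @param pulse A [pm_pulse()] or `NULL` (no modulation).
#' @return Phase in rad.
#' @export
phase_profile <- function(t, drive, pulse = NULL) {
  phi <- rep(drive$phi0, length(t))
  if (!is.null(pulse)) {
    a <- if (is.null(pulse$a_pm)) drive$a_pm else pulse$a_pm
    inside <- t >= pulse$start & t <= pulse$start + pulse$duration
    phi[inside] <- drive$phi0 +
      a * cos(mhz_to_ang(drive$nu_pm) * t[inside] + pulse$phi_pm)
  }
  phi
}

#' Timing skeleton of the dressed-echo sequence
#'
#' Bare pi/2 excitation (phase `phi1`), spin lock 90 degrees phase-shifted
#' (`phi_sl = phi1 + pi/2`) containing three PM pulses
#' (pi/2 - tau1 - pi - tau2 - pi/2 with phases `phi2`, `phi3`, `phi4`),
#' a constant total lock length `t_sl`, and a two-pulse read-out echo
#' (`tau_sl` - pi - `tau_sl`). By default `tau2` follows the echo-position
#' rule `tau2 = tau1 + t90_pm` and `t_sl` is chosen to cover the longest
#' `tau1` of a scan (`t_sl_margin` beyond the last PM pulse).
#'
#' @param tau1 Delay between the first PM pi/2 pulse and the PM pi pulse, us.
#' @param tau0 Delay from lock start to the first PM pulse, us.
#' @param tau2 Delay after the PM pi pulse; `NULL` applies the echo rule.
#' @param t_sl Total spin-lock length, us; `NULL` = cover pulses + margin.
#' @param t_sl_margin Lock tail after the last PM pulse when `t_sl` is
#'   automatic, us.
#' @param tau_sl Read-out echo delay, us.
#' @param t_pi2_bare Bare pi/2 pulse length, us; `NULL` = `1/(4 nu1)`
#'   (constant-amplitude rectangle at the lock Rabi frequency).
#' @param phi1 Bare-pulse phase, rad (lock phase is `phi1 + pi/2`).
#' @param phi2,phi3,phi4 PM pulse phases, rad.
#' @return Object of class `sequence_spec`.
#' @export
sequence_spec <- function(tau1, tau0 = 0.05, tau2 = NULL, t_sl = NULL,
                          t_sl_margin = 0.05, tau_sl = 0.2,
                          t_pi2_bare = NULL, phi1 = 0, phi2 = 0,
                          phi3 = pi / 2, phi4 = 0) {
  if (tau1 < 0 || tau0 < 0 || tau_sl < 0) stop("delays must be >= 0")
  structure(list(tau1 = tau1, tau0 = tau0, tau2 = tau2, t_sl = t_sl,
                 t_sl_margin = t_sl_margin, tau_sl = tau_sl,
                 t_pi2_bare = t_pi2_bare, phi1 = phi1, phi2 = phi2,
                 phi3 = phi3, phi4 = phi4), class = "sequence_spec")
}

# resolve derived timings for a given drive
resolve_sequence <- function(seq, drive) {
  pl <- pm_pulse_lengths(drive)
  tau2 <- if (is.null(seq$tau2)) seq$tau1 + pl$t90 else seq$tau2
  used <- seq$tau0 + pl$t90 + seq$tau1 + pl$t180 + tau2 + pl$t90
  t_sl <- if (is.null(seq$t_sl)) used + seq$t_sl_margin else seq$t_sl
  if (t_sl < used)
    stop(sprintf("t_sl = %.4g us is shorter than the PM pulse block (%.4g us)",
                 t_sl, used))
  t90b <- if (is.null(seq$t_pi2_bare)) 1 / (4 * drive$nu1) else seq$t_pi2_bare
  list(tau2 = tau2, t_sl = t_sl, tail = t_sl - used, t90_pm = pl$t90,
       t180_pm = pl$t180, t90_bare = t90b)
}

#' Propagate the dressed-echo sequence for one spin pair
#'
#' Exact piecewise propagation of the full phase-modulated sequence in the
#' rotating frame. Constant-phase segments use a single matrix exponential;
#' PM segments are sampled at `dt` with the full `cos/sin` of the modulated
#' phase (no small-amplitude truncation). The initial state is both spins
#' polarized along +z.
#'
#' @param pair A [spin_pair()].
#' @param seq A [sequence_spec()].
#' @param drive A [drive_params()].
#' @param dt Integration step for PM segments, us. Default
#'   `1/(40 max(nu1, nu_pm))`; values coarser than
#'   `1/(20 max(nu1, nu_pm))` are refused (silent aliasing of the
#'   modulation is never allowed).
#' @param readout `"echo"`: complex transverse amplitude
#'   \eqn{\langle S_x\rangle + i\langle S_y\rangle} at the read-out echo
#'   after the `tau_sl - pi - tau_sl` block; `"lock"`: signed magnetization
#'   component along the lock axis at the end of the lock (the direct
#'   analogue of the simplified simulator's observable).
#' @return List with `signal` (complex for `"echo"`, real for `"lock"`),
#'   `timing` (resolved sequence timings) and `rho` (final density
#'   operator).
#' @export
propagate <- function(pair, seq, drive, dt = NULL,
                      readout = c("echo", "lock")) {
  readout <- match.arg(readout)
  fmax <- max(drive$nu1, drive$nu_pm)
  if (is.null(dt)) dt <- 1 / (40 * fmax)
  if (dt > 1 / (20 * fmax))
    stop(sprintf(paste0("dt = %.3g us is too coarse for nu = %.4g MHz; ",
                        "need dt <= %.3g us"), dt, fmax, 1 / (20 * fmax)))
  tm <- resolve_sequence(seq, drive)
  ops <- spin_operators(2)
  Hint <- interaction_hamiltonian(pair)
  w1 <- mhz_to_ang(drive$nu1)
  drive_term <- function(phi) w1 * (cos(phi) * ops$Sx + sin(phi) * ops$Sy)
  phi_sl <- seq$phi1 + pi / 2
  H_lock <- Hint + drive_term(phi_sl)
  rho <- ops$Sz + 0i
  # bare pi/2 excitation
  rho <- evolve(rho, propagator(Hint + drive_term(seq$phi1), tm$t90_bare))
  # lock with PM pulses; modulation clock runs from lock start
  pm_block <- function(rho, t0, dur, phi_pm) {
    n <- max(1L, ceiling(dur / dt))
    h <- dur / n
    wpm <- mhz_to_ang(drive$nu_pm)
    for (k in seq_len(n)) {
      phi <- phi_sl + drive$a_pm * cos(wpm * (t0 + (k - 0.5) * h) + phi_pm)
      rho <- evolve(rho, propagator(Hint + drive_term(phi), h))
    }
    rho
  }
  lock_seg <- function(rho, dur)
    if (dur > 0) evolve(rho, propagator(H_lock, dur)) else rho
  t <- 0
  rho <- lock_seg(rho, seq$tau0);              t <- t + seq$tau0
  rho <- pm_block(rho, t, tm$t90_pm, seq$phi2);  t <- t + tm$t90_pm
  rho <- lock_seg(rho, seq$tau1);              t <- t + seq$tau1
  rho <- pm_block(rho, t, tm$t180_pm, seq$phi3); t <- t + tm$t180_pm
  rho <- lock_seg(rho, tm$tau2);               t <- t + tm$tau2
  rho <- pm_block(rho, t, tm$t90_pm, seq$phi4);  t <- t + tm$t90_pm
  rho <- lock_seg(rho, tm$tail)
  if (readout == "lock") {
    sig <- expect_val(rho, cos(phi_sl) * ops$Sx + sin(phi_sl) * ops$Sy)
    return(list(signal = sig, timing = tm, rho = rho))
  }
  Uf <- propagator(Hint, seq$tau_sl)
  rho <- evolve(rho, Uf)
  rho <- evolve(rho, propagator(Hint + drive_term(seq$phi1), 2 * tm$t90_bare))
  rho <- evolve(rho, Uf)
  sig <- sum(diag(rho %*% (ops$Sx + 1i * ops$Sy)))
  list(signal = sig, timing = tm, rho = rho)
}

#' Default phase cycle for the dressed-echo sequence
#'
#' Nested two-step inversions of the first and last PM pulse phases with
#' receiver sign alternation (selecting signal that passes through both
#' dressed-coherence conversions), by default combined with a four-step
#' EXORCYCLE-like rotation of the refocusing PM pulse phase with the
#' matching `exp(-2i phi3)` receiver rotation (selecting the p -> -p echo
#' pathway). Unwanted crossing echoes whose position depends on `tau0` are
#' suppressed by these PM-phase steps.
#'
#' @param exorcycle If `TRUE` (default), include the four-step rotation of
#'   `phi3`, giving 16 steps in total; otherwise the 4-step cycle.
#' @return Data frame with columns `phi1`, `phi2`, `phi3`, `phi4` (rad) and
#'   complex `receiver`.
#' @export
default_phase_cycle <- function(exorcycle = TRUE) {
  base <- expand.grid(p2 = c(0, pi), p4 = c(0, pi))
  tab <- data.frame(phi1 = 0, phi2 = base$p2, phi3 = pi / 2, phi4 = base$p4,
                    receiver = complex(real = cos(base$p2) * cos(base$p4),
                                       imaginary = 0))
  if (!exorcycle) return(tab)
  out <- do.call(rbind, lapply(0:3, function(k) {
    t2 <- tab
    t2$phi3 <- pi / 2 + k * pi / 2
    t2$receiver <- t2$receiver * exp(-2i * k * pi / 2)
    t2
  }))
  rownames(out) <- NULL
  out
}

#' Phase-cycled echo amplitude
#'
#' Receiver-weighted average of [propagate()] over a phase-cycle table.
#'
#' @inheritParams propagate
#' @param cycle Data frame as returned by [default_phase_cycle()]; a
#'   single-row table reduces to one call of [propagate()].
#' @return Complex (readout `"echo"`) or real (readout `"lock"`) amplitude.
#' @export
run_phase_cycle <- function(pair, seq, drive, cycle = default_phase_cycle(),
                            dt = NULL, readout = c("echo", "lock")) {
  readout <- match.arg(readout)
  if (nrow(cycle) < 1) stop("empty phase-cycle table")
  wsum <- sum(Mod(cycle$receiver))
  if (wsum == 0) stop("receiver weights sum to zero")
  acc <- 0
  for (i in seq_len(nrow(cycle))) {
    si <- seq
    si$phi1 <- cycle$phi1[i]
    si$phi2 <- cycle$phi2[i]
    si$phi3 <- cycle$phi3[i]
    si$phi4 <- cycle$phi4[i]
    out <- propagate(pair, si, drive, dt = dt, readout = readout)
    acc <- acc + cycle$receiver[i] * out$signal
  }
  acc <- acc / nrow(cycle)
  if (readout == "lock") Re(acc) else acc
}

#' Dressed-echo modulation trace from the full sequence
#'
#' Scans `tau1` at constant total lock length and returns the normalized
#' echo modulation. Keeping `t_sl` fixed is essential: a lock length that
#' grows with `tau1` lets unconverted dressed coherence (precessing at
#' \eqn{\omega_1}) beat against the scan grid. Because the PM pulses have
#' finite length, the trace equals the ideal phase-inversion result
#' evaluated at `tau1 + t90_pm` (one PM pi/2 length of extra dipolar
#' evolution); the offset is returned in the metadata.
#'
#' @inheritParams propagate
#' @param tau1_grid Ascending `tau1` grid starting at 0, us.
#' @param cycle Optional phase-cycle table; `NULL` = single shot.
#' @param tau0,t_sl_margin,tau_sl Passed to [sequence_spec()].
#' @return An [epr_trace()] (normalized to the first point) with
#'   `meta$tau_eff_offset = t90_pm`.
#' @export
dressed_echo_trace <- function(pair, drive, tau1_grid, cycle = NULL,
                               readout = c("lock", "echo"), dt = NULL,
                               tau0 = 0.05, t_sl_margin = 0.05,
                               tau_sl = 0.2) {
  readout <- match.arg(readout)
  pl <- pm_pulse_lengths(drive)
  tau1_max <- max(tau1_grid)
  t_sl <- tau0 + pl$t90 + tau1_max + pl$t180 + (tau1_max + pl$t90) + pl$t90 +
    t_sl_margin
  one <- function(tt) {
    sq <- sequence_spec(tau1 = tt, tau0 = tau0, t_sl = t_sl, tau_sl = tau_sl)
    if (is.null(cycle))
      propagate(pair, sq, drive, dt = dt, readout = readout)$signal
    else
      run_phase_cycle(pair, sq, drive, cycle = cycle, dt = dt,
                      readout = readout)
  }
  if (readout == "lock") {
    raw <- vapply(tau1_grid, one, 0)
  } else {  # echo readout: rotate onto the reference phase of the first point
    cx <- vapply(tau1_grid, one, 0i)
    raw <- Re(cx * exp(-1i * Arg(cx[1])))
  }
  epr_trace(tau1_grid, raw / raw[1], kind = "full_sequence_echo",
            r = pair$r, theta = pair$theta, nu1 = drive$nu1,
            a_pm = drive$a_pm, readout = readout,
            tau_eff_offset = pl$t90, t_sl = t_sl)
}

#' Dressed-spin nutation trace
#'
#' Echo (lock-axis) amplitude as a function of the length of a single PM
#' pulse applied during the lock: the dressed-spin Rabi oscillation. In the
#' rotating-wave regime the dominant frequency is \eqn{\nu_1 a_{PM}/2};
#' large modulation amplitudes show Bloch-Siegert-shift-related deviations
#' and a lengthened effective pi time.
#'
#' @inheritParams propagate
#' @param pm_length_grid PM pulse lengths to scan, us.
#' @param tau0 Delay from lock start to the pulse, us.
#' @param t_sl_margin Lock tail after the longest pulse, us.
#' @return An [epr_trace()] of the lock-axis amplitude vs pulse length
#'   (unnormalized; starts near 1).
#' @export
dressed_nutation <- function(pair, drive, pm_length_grid, tau0 = 0.05,
                             t_sl_margin = 0.05, dt = NULL) {
  fmax <- max(drive$nu1, drive$nu_pm)
  if (is.null(dt)) dt <- 1 / (40 * fmax)
  ops <- spin_operators(2)
  Hint <- interaction_hamiltonian(pair)
  w1 <- mhz_to_ang(drive$nu1)
  drive_term <- function(phi) w1 * (cos(phi) * ops$Sx + sin(phi) * ops$Sy)
  phi_sl <- pi / 2
  H_lock <- Hint + drive_term(phi_sl)
  t90b <- 1 / (4 * drive$nu1)
  t_sl <- tau0 + max(pm_length_grid) + t_sl_margin
  wpm <- mhz_to_ang(drive$nu_pm)
  y <- vapply(pm_length_grid, function(L) {
    rho <- evolve(ops$Sz + 0i, propagator(Hint + drive_term(0), t90b))
    rho <- evolve(rho, propagator(H_lock, tau0))
    if (L > 0 && drive$a_pm > 0) {
      n <- max(1L, ceiling(L / dt)); h <- L / n
      for (k in seq_len(n)) {
        phi <- phi_sl + drive$a_pm * cos(wpm * (tau0 + (k - 0.5) * h))
        rho <- evolve(rho, propagator(Hint + drive_term(phi), h))
      }
    } else if (L > 0) {
      rho <- evolve(rho, propagator(H_lock, L))
    }
    rho <- evolve(rho, propagator(H_lock, t_sl - tau0 - L))
    expect_val(rho, sin(phi_sl) * ops$Sy + cos(phi_sl) * ops$Sx)
  }, 0)
  epr_trace(pm_length_grid, y,
            kind = "pm_nutation", nu1 = drive$nu1, a_pm = drive$a_pm,
            nominal_nutation_mhz = pm_nutation_frequency(drive))
}

#' Fit the dominant oscillation frequency of a trace
#'
#' Damped-cosine least-squares fit seeded by the FFT peak; used for
#' nutation traces and single-orientation echo modulations.
#'
#' @param trace An [epr_trace()].
#' @return Frequency in MHz (cycles per us).
#' @export
dominant_frequency <- function(trace) {
  y <- trace$y - mean(trace$y)
  n <- length(y)
  dt <- trace$t[2] - trace$t[1]
  nz <- 8 * n
  sp <- Mod(stats::fft(c(y, rep(0, nz - n))))[seq_len(nz %/% 2)]
  f <- (seq_len(nz %/% 2) - 1) / (nz * dt)
  f0 <- f[which.max(sp)]
  df <- data.frame(t = trace$t - trace$t[1], y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ a * cos(2 * pi * fr * t + ph) * exp(-t / td),
    data = df,
    start = list(a = max(abs(y)), fr = f0, ph = 0, td = 100 * max(df$t)),
    lower = c(0, 0, -pi, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(f0)
  unname(stats::coef(fit)["fr"])
}

#' Hyperfine decoupling by a strong electron drive
#'
#' Electron-nucleus demonstration: an electron coupled to one nucleus by a
#' secular hyperfine term `A Sz Iz` (plus nuclear Zeeman `nuI Iz`) is
#' prepared transverse and either left free or spin-locked along its own
#' axis. The ratio of the hyperfine-induced modulation depth of the locked
#' vs free electron coherence quantifies the decoupling; it tends to 1 for
#' `A = 0` or vanishing drive and decreases with `nu1` roughly as
#' `(A/2 nu1)^2`.
#'
#' @param A_nu Secular hyperfine coupling, MHz.
#' @param nuI Nuclear Zeeman frequency, MHz.
#' @param nu1 Electron Rabi frequency, MHz.
#' @param duration Evolution window, us; default covers two hyperfine
#'   periods.
#' @param n_steps Number of sampled time points.
#' @return Attenuation factor in `[0, 1]` (1 = no decoupling).
#' @export
hyperfine_decoupling_demo <- function(A_nu, nuI = 14.8, nu1 = 100,
                                      duration = NULL, n_steps = 400) {
  if (is.null(duration))
    duration <- if (A_nu > 0) 2 / (A_nu / 2) else 1
  ops <- spin_operators(2)  # spin 1 = electron, spin 2 = nucleus
  H0 <- mhz_to_ang(A_nu) * ops$S1z %*% ops$S2z + mhz_to_ang(nuI) * ops$S2z
  Hl <- H0 + mhz_to_ang(nu1) * ops$S1x  # drive on the electron only
  rho0 <- ops$S1x + 0i
  ts <- seq(0, duration, length.out = n_steps)
  depth <- function(H) {
    e <- eigen(H, symmetric = TRUE)
    s <- vapply(ts, function(tt) {
      U <- e$vectors %*% (exp(-1i * e$values * tt) * Conj(t(e$vectors)))
      expect_val(evolve(rho0, U), ops$S1x)
    }, 0)
    max(s) - min(s)
  }
  d_free <- depth(H0)
  if (d_free < 1e-12) return(1)
  min(1, depth(Hl) / d_free)
}
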