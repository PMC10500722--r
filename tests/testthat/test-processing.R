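test_that("stretched-exponential fits recover noiseless parameters exactly", {
  for (p in printed_decay_pairs) {
    t <- seq(0, 3 * p[1], length.out = 120)
    fit <- fit_stretched_exponential(t, exp(-(t / p[1])^(p[2] / 3)))
    expect_true(fit$converged)
    expect_equal(fit$T, p[1], tolerance = 1e-4)
    expect_equal(fit$xi, p[2], tolerance = 1e-4)
    expect_equal(fit$A, 1, tolerance = 1e-4)
  }
})

test_that("fitted model passes through A/e at t = T for any xi", {
  for (xi in c(0.9, 3, 5.9)) {
    t <- seq(0, 30, length.out = 100)
    fit <- fit_stretched_exponential(t, 2 * exp(-(t / 8)^(xi / 3)))
    expect_equal(fit$model(fit$T), fit$A * exp(-1), tolerance = 1e-9)
  }
  expect_error(fit_stretched_exponential(1:5, 1:5), "8 points")
})

test_that("early truncation makes the slow-decay fit ill-conditioned", {
  # T = 930 us, xi = 2.4 decay observed only to 40 us with 1% noise:
  # T comes back with a very wide confidence interval
  set.seed(11)
  t <- seq(0, 40, length.out = 200)
  y <- exp(-(t / 930)^(2.4 / 3)) + stats::rnorm(200, 0, 0.01)
  fit <- fit_stretched_exponential(t, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$T - 930) / 930, 0.5)          # still in the ballpark
  se_T <- sqrt(fit$covariance[2, 2])
  expect_gt(se_T / fit$T, 0.1)                    # relative SE > 10 %
  # the same decay observed to 3 T is well-conditioned
  t2 <- seq(0, 2790, length.out = 200)
  set.seed(11)
  y2 <- exp(-(t2 / 930)^(2.4 / 3)) + stats::rnorm(200, 0, 0.01)
  fit2 <- fit_stretched_exponential(t2, y2)
  expect_lt(sqrt(fit2$covariance[2, 2]) / fit2$T, 0.02)
})

test_that("background division recovers the constructed modulation", {
  tg <- seq(0, 10, length.out = 256)
  fitref <- fit_stretched_exponential(tg, exp(-(tg / 14.3)^(5.4 / 3)))
  # trace == fit -> constant 1
  tr <- epr_trace(tg, fitref$model(tg))
  expect_lt(max(abs(background_divide(tr, fitref)$y - 1)), 1e-9)
  # modulation times background -> modulation back
  lam <- 0.4
  K <- cos(2 * pi * 0.566 * tg)
  tr2 <- epr_trace(tg, ((1 - lam) + lam * K) * fitref$model(tg))
  red <- background_divide(tr2, fitref)
  expect_equal(red$y, (1 - lam) + lam * K, tolerance = 1e-9)
  expect_equal(red$meta$background$T, fitref$T)
  bad <- fitref; bad$model <- function(tt) tt * 0
  expect_error(background_divide(tr2, bad), "zero")
})

test_that("background fit options remove the oscillation bias", {
  spec <- synth_trace_spec(r = 4.1, lambda = 0.5, T_bg = 14.3, xi_bg = 5.4,
                           noise = 0.01, seed = 2,
                           tau1_grid = default_tau1_grid(4.1, 768,
                                                         periods = 12))
  tr <- gen_dressed_echo_trace(spec)
  naive <- fit_background(tr)
  tuned <- fit_background(tr, exclude_periods = 1, boxcar_periods = 1)
  expect_gt(abs(naive$xi - 5.4) / 5.4, 0.1)   # the bias is real
  expect_lt(abs(tuned$T - 14.3) / 14.3, 0.03)
  expect_lt(abs(tuned$xi - 5.4) / 5.4, 0.05)
})

test_that("Fourier step resolves single tones and kills constants", {
  tg <- seq(0, 20, length.out = 512)
  sp <- to_dipolar_spectrum(epr_trace(tg, cos(2 * pi * 0.5 * tg)),
                            window = "none", zerofill_factor = 4)
  expect_equal(peak_frequency(sp), 0.5, tolerance = 0.01)
  spc <- to_dipolar_spectrum(epr_trace(tg, rep(2.5, 512)))
  expect_lt(max(abs(spc$amplitude)), 1e-9)
  # frequency axis spacing = 1 / zero-filled duration
  expect_equal(diff(sp$frequency[1:2]), 1 / (4 * 512 * diff(tg[1:2])),
               tolerance = 1e-12)
  expect_error(to_dipolar_spectrum(epr_trace(c(0, 1, 3), c(1, 1, 1))),
               "uniform")
})

test_that("singularity picking finds horn and edge and ignores scale", {
  sp <- pake_analytic(1, scale = 0.75, smoothing = 0.008)
  s1 <- find_singularities(sp)
  expect_equal(min(abs(s1 - 0.75)), 0, tolerance = 0.02)
  expect_equal(max(s1), 1.5, tolerance = 0.03)
  sp2 <- sp; sp2$amplitude <- sp$amplitude * 137
  expect_equal(find_singularities(sp2), s1)
  flat <- dipolar_spectrum(seq(0, 1, 0.01), rep(0, 101))
  expect_identical(find_singularities(flat), numeric(0))
})

test_that("distance inversion round-trips through the dipolar constant", {
  expect_equal(distance_from_perp_frequency(0.75 * 52.04105), 1,
               tolerance = 1e-4)
  expect_equal(distance_from_perp_frequency(0.566), 4.1, tolerance = 5e-3)
  expect_equal(distance_from_perp_frequency(52.04105, scale = 1), 1,
               tolerance = 1e-6)
  r <- c(2, 3.7, 5.3)
  nu <- 0.75 * dipolar_constant_d(r)
  expect_equal(distance_from_perp_frequency(nu), r, tolerance = 1e-9)
  expect_error(distance_from_perp_frequency(-1), "> 0")
})

test_that("full pipeline recovers the distance from a noisy synthetic trace", {
  spec <- synth_trace_spec(r = 4.1, lambda = 0.5, noise = 0.02, seed = 5,
                           tau1_grid = default_tau1_grid(4.1, 768,
                                                         periods = 12))
  res <- process_dipolar_trace(gen_dressed_echo_trace(spec))
  expect_lt(abs(res$distance_nm - 4.1) / 4.1, 0.02)
  expect_true(length(res$singularities) >= 2)
})
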