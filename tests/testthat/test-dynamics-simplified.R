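test_that("magic-angle pair with zero offsets gives a flat echo trace", {
  p <- spin_pair(3, acos(1 / sqrt(3)), nu1 = 100)
  tg <- seq(0, 2, length.out = 17)
  tr <- simulate_pair_echo(p, tg)
  expect_lt(max(abs(tr$y - 1)), 1e-6)
})

test_that("zero-offset pair oscillates at 3/4 of the bare dipolar frequency", {
  d <- dipolar_constant_d(4.1)
  p <- spin_pair(4.1, pi / 2, nu1 = 100)
  tg <- seq(0, 6 / (0.75 * d), length.out = 512)
  tr <- simulate_pair_echo(p, tg)
  expect_equal(dominant_frequency(tr) / d, 0.75, tolerance = 0.004)
  # and the trace matches the closed form closely in this regime
  ref <- dressed_echo_closed_form(tg, omega_dd(4.1, pi / 2))
  expect_lt(sqrt(mean((tr$y - ref)^2)), 0.01)
})

test_that("large symmetric offsets push the trace away from the closed form", {
  d <- dipolar_constant_d(4.1)
  tg <- seq(0, 4 / (0.75 * d), length.out = 257)
  ref <- dressed_echo_closed_form(tg, omega_dd(4.1, pi / 2))
  p0 <- spin_pair(4.1, pi / 2, nu1 = 100)
  poff <- spin_pair(4.1, pi / 2, nu1 = 100, offset1 = 8, offset2 = -8)
  dev0 <- sqrt(mean((simulate_pair_echo(p0, tg)$y - ref)^2))
  devo <- sqrt(mean((simulate_pair_echo(poff, tg)$y - ref)^2))
  expect_gt(devo, 0.02)       # artifact regime
  expect_gt(devo, 5 * dev0)   # clearly beyond the on-resonance deviation
})

test_that("compiled ensemble kernel agrees with the R reference simulator", {
  tg <- seq(0, 3, length.out = 33)
  for (cfg in list(c(4.1, pi / 2, 0, 0), c(5.3, 0.7, 5, -3),
                   c(3.0, 0.3, -8, 2))) {
    p <- spin_pair(cfg[1], cfg[2], nu1 = 100, offset1 = cfg[3],
                   offset2 = cfg[4])
    ref <- simulate_pair_echo(p, tg)$y
    raw <- as.numeric(dressedEPR:::.ens_echo_cpp(
      2 * pi * cfg[3], 2 * pi * cfg[4], omega_dd(cfg[1], cfg[2]),
      2 * pi * 100, tg, 1))
    expect_equal(raw / raw[1], ref, tolerance = 1e-10)
  }
})

test_that("ensemble trace is seeded, normalized and bounded", {
  spec <- ensemble_spec(nu1 = 100, offset_fwhm = 16, n_draws = 300, seed = 9)
  tg <- seq(0, 8, length.out = 65)
  tr1 <- ensemble_trace(spec, 5.3, tg)
  tr2 <- ensemble_trace(spec, 5.3, tg)
  expect_identical(tr1$y, tr2$y)          # bit-identical under one seed
  expect_equal(tr1$y[1], 1)
  expect_true(all(abs(tr1$y) <= 1 + 1e-9))  # unitary evolution bound
  tr3 <- ensemble_trace(ensemble_spec(nu1 = 100, offset_fwhm = 16,
                                      n_draws = 300, seed = 10), 5.3, tg)
  expect_false(identical(tr1$y, tr3$y))   # seed actually matters
})

test_that("single-draw zero-width ensemble equals the pair simulator", {
  spec <- ensemble_spec(nu1 = 100, offset_fwhm = 0, n_draws = 1, seed = 3)
  tg <- seq(0, 4, length.out = 33)
  tr <- ensemble_trace(spec, 4.1, tg)
  # reproduce the single seeded orientation draw exactly as the ensemble does
  set.seed(3)
  stats::rnorm(1, 0, fwhm_to_sigma(0))
  stats::rnorm(1, 0, fwhm_to_sigma(0))
  th <- acos(stats::runif(1))
  ref <- simulate_pair_echo(spin_pair(4.1, th, nu1 = 100), tg)
  expect_equal(tr$y, ref$y, tolerance = 1e-10)
})

test_that("Monte-Carlo convergence: quadrupling draws shrinks the change", {
  tg <- seq(0, 10, length.out = 65)
  t1 <- ensemble_trace(ensemble_spec(offset_fwhm = 16, n_draws = 400,
                                     seed = 1), 5.3, tg)
  t2 <- ensemble_trace(ensemble_spec(offset_fwhm = 16, n_draws = 1600,
                                     seed = 2), 5.3, tg)
  t3 <- ensemble_trace(ensemble_spec(offset_fwhm = 16, n_draws = 6400,
                                     seed = 3), 5.3, tg)
  d12 <- sqrt(mean((t1$y - t2$y)^2))
  d23 <- sqrt(mean((t2$y - t3$y)^2))
  expect_lt(d23, d12)            # ~1/sqrt(n) contraction
  expect_lt(d23, 0.05)
})

test_that("FWHM to sigma conversion matches the closed form", {
  expect_equal(fwhm_to_sigma(16), 16 / sqrt(8 * log(2)), tolerance = 1e-12)
  expect_equal(fwhm_to_sigma(16), 6.794, tolerance = 1e-3)
})

test_that("ensemble presets encode the artifact study conditions", {
  a <- ensemble_preset("a")
  expect_equal(a$specs[[1]]$offset_fwhm, 0)
  expect_equal(a$specs[[1]]$nu1, 100)
  b <- ensemble_preset("b")
  expect_equal(b$specs[[1]]$offset_fwhm, 16)
  c <- ensemble_preset("c")
  expect_equal(c$specs[[1]]$offset_fwhm, 8)
  d <- ensemble_preset("d")
  expect_equal(vapply(d$specs, function(s) s$nu1, 0), c(200, 400))
  expect_equal(d$specs[[1]]$offset_fwhm, 8)
  expect_equal(a$r, c(4.1, 5.3))
  expect_error(ensemble_preset("z"))
})

test_that("ideal-ensemble spectrum matches the 3/4-scaled Pake pattern", {
  d <- dipolar_constant_d(4.1)
  tr <- powder_average_trace(4.1, seq(0, 12 / (0.75 * d),
                                      length.out = 768), nu1 = 100,
                             nodes = 200)
  sp <- to_dipolar_spectrum(tr, zerofill_factor = 8)
  expect_equal(peak_frequency(sp), 0.75 * d, tolerance = 0.03)
  # closed-form kernel agrees with the quadrature simulation pointwise
  K <- powder_closed_form_trace(4.1, tr$t)
  expect_lt(sqrt(mean((tr$y - K$y)^2)), 0.01)
})
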