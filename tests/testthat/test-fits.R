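test_that("Boltzmann fit recovers exact parameters and the midpoint", {
  v <- seq(-100, 20, by = 10)
  y <- 1 / (1 + exp((-22 - v) / 7))
  fit <- fitBoltzmann(v, y)
  expect_equal(fit@v_half, -22, tolerance = 1e-4)
  expect_equal(fit@k, 7, tolerance = 1e-4)
  expect_equal(predictBoltzmann(fit, fit@v_half), 0.5)
  # descending form (availability)
  yd <- 1 / (1 + exp((v + 60) / 6))
  fd <- fitBoltzmann(v, yd)
  expect_equal(fd@direction, "descending")
  expect_equal(fd@v_half, -60, tolerance = 1e-4)
  expect_equal(fd@k, 6, tolerance = 1e-4)
  expect_error(fitBoltzmann(c(-10, 0, 10), c(0.2, 0.5, 0.9)),
               "fit-insufficiency")
})

test_that("Boltzmann fitting is accurate under Gaussian noise (Monte Carlo)", {
  v <- seq(-100, 70, by = 10)
  truth <- 1 / (1 + exp((-22 - v) / 7))
  set.seed(2024)
  err <- replicate(200, {
    fit <- fitBoltzmann(v, truth + rnorm(length(v), 0, 0.02))
    abs(fit@v_half + 22)
  })
  expect_lt(median(err), 1)
})

test_that("exponential decay fit is exact and flags degenerate traces", {
  t <- seq(0, 8, by = 0.02)
  fit <- fitExpDecay(t, -12 - 520 * exp(-t / 0.5))
  expect_equal(fit@tau, 0.5, tolerance = 1e-6)
  expect_equal(fit@offset, -12, tolerance = 1e-6)
  expect_error(fitExpDecay(t, rep(5, length(t))), "non-decaying")
  expect_error(fitExpDecay(t[1:3], t[1:3]), "fit-insufficiency")
})

test_that("double-exponential fit recovers constants and collapses cleanly", {
  t <- c(0, 0.5, 1, 2, 3, 5, 8, 12, 20, 30, 50, 100, 200)
  frac <- 1 - 0.9 * exp(-t / 2) - 0.1 * exp(-t / 50)
  expect_equal(frac[1], 0) # no recovery at zero time
  fit <- fitDoubleExp(t, frac)
  expect_false(fit@degenerate)
  expect_equal(fit@tau_fast, 2, tolerance = 1e-3)
  expect_equal(fit@tau_slow, 50, tolerance = 1e-3)
  expect_equal(fit@frac_fast, 0.9, tolerance = 1e-3)
  # equal time constants: model collapses, degeneracy flagged, tau recovered
  frac1 <- 1 - exp(-t / 10)
  d <- fitDoubleExp(t, frac1)
  expect_true(d@degenerate)
  expect_equal(d@tau_fast, 10, tolerance = 1e-3)
  expect_equal(d@tau_slow, d@tau_fast)
  expect_error(fitDoubleExp(t[1:5], frac[1:5]), "fit-insufficiency")
})

test_that("fits are deterministic", {
  v <- seq(-100, 20, by = 10)
  set.seed(7)
  y <- 1 / (1 + exp((-22 - v) / 7)) + rnorm(length(v), 0, 0.03)
  f1 <- fitBoltzmann(v, y)
  f2 <- fitBoltzmann(v, y)
  expect_identical(f1@v_half, f2@v_half)
  expect_identical(f1@k, f2@k)
})
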