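test_that("noise-free generation is bit-reproducible and noise is seeded", {
  ph <- defaultPhenotype("WT", 37)
  a <- simulateProtocol(ph, "activation")
  b <- simulateProtocol(ph, "activation")
  expect_identical(currentMatrix(a), currentMatrix(b))
  n1 <- simulateProtocol(ph, "activation", noise_sd = 5, seed = 11)
  n2 <- simulateProtocol(ph, "activation", noise_sd = 5, seed = 11)
  n3 <- simulateProtocol(ph, "activation", noise_sd = 5, seed = 12)
  expect_identical(currentMatrix(n1), currentMatrix(n2))
  expect_false(identical(currentMatrix(n1), currentMatrix(n3)))
})

test_that("pre-pulse current is zero and driving force vanishes at v_rev", {
  ph <- defaultPhenotype("WT", 37)
  ts <- simulateProtocol(ph, "activation")
  pre <- currentMatrix(ts)[traceTime(ts) < 1, ]
  expect_true(all(abs(pre) < 1e-12))
  # a sweep commanded exactly at the reversal potential carries no current
  ph2 <- defaultPhenotype("WT", 37, v_rev = 60)
  ts2 <- simulateProtocol(ph2, "activation")
  peaks <- measurePeaks(ts2)
  expect_equal(unname(peaks[["60"]]), 0)
})

test_that("persistent-protocol end/peak ratio equals f_persistent exactly", {
  for (g in c("WT", "L1624Q")) for (te in c(22, 37)) {
    ph <- defaultPhenotype(g, te)
    ts <- simulateProtocol(ph, "persistent")
    pf <- persistentFraction(ts)
    expect_equal(unname(pf["pct_end"]), 100 * ph@f_persistent,
                 tolerance = 1e-6)
  }
})

test_that("SSFI test-pulse peaks are monotone and recovery saturates", {
  ph <- defaultPhenotype("WT", 22)
  ssfi <- simulateProtocol(ph, "ssfi")
  time <- traceTime(ssfi)
  cur <- currentMatrix(ssfi)
  pk <- apply(abs(cur[time > 1.05, ]), 2, max)
  expect_true(all(diff(pk) <= 1e-9)) # non-increasing with prepulse voltage
  # recovered fraction approaches 1 analytically as t grows
  long <- vclampProtocol("recovery",
                         recovery_times = c(1, 2, 5, 10, 20, 50, 200, 2000))
  rec <- simulateProtocol(ph, long)
  fr <- attr(recoveryCurve(rec), "fraction")
  expect_equal(unname(fr[["2000"]]), 1, tolerance = 1e-6)
  expect_true(all(diff(fr) > 0))
})

test_that("cohort generation is seeded, unbiased and collapses at zero variance", {
  ph <- defaultPhenotype("WT", 37)
  same <- generateCohort(ph, n_cells = 28, cell_variability = 0,
                         protocols = "persistent", seed = 3)
  expect_length(same, 28L)
  m0 <- currentMatrix(same[[1]]$traces$persistent)
  for (cell in same)
    expect_identical(currentMatrix(cell$traces$persistent), m0)

  c1 <- generateCohort(ph, n_cells = 4, cell_variability = 0.2,
                       protocols = "persistent", seed = 9)
  c2 <- generateCohort(ph, n_cells = 4, cell_variability = 0.2,
                       protocols = "persistent", seed = 9)
  expect_identical(lapply(c1, function(x) currentMatrix(x$traces$persistent)),
                   lapply(c2, function(x) currentMatrix(x$traces$persistent)))

  # law of large numbers: 1000 cells at 30% variability, mean density
  # within 3% of the cohort ground truth
  big <- generateCohort(ph, n_cells = 1000, cell_variability = 0.3,
                        protocols = "persistent", seed = 5)
  dens <- vapply(big, function(x) x$phenotype@density_at_0mV, numeric(1))
  expect_lt(abs(mean(dens) / ph@density_at_0mV - 1), 0.03)
})

test_that("generator validates its inputs", {
  ph <- defaultPhenotype("WT", 37)
  expect_error(simulateProtocol(ph, "activation", capacitance = 0),
               "capacitance")
  expect_error(simulateProtocol(ph, "activation", noise_sd = -1), "noise_sd")
  expect_error(generateCohort(ph, n_cells = 0), "n_cells")
  expect_error(generateCohort(ph, n_cells = 2, cell_variability = -0.1),
               "cell_variability")
  p <- vclampProtocol("activation")
  p@step_voltages <- seq(-150, 20, by = 10)
  expect_error(simulateProtocol(ph, p), "-130")
})
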