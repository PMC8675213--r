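test_that("peak measurement matches density x capacitance at 0 mV", {
  ts <- simulateProtocol(defaultPhenotype("WT", 37), "activation",
                         capacitance = 20)
  peaks <- measurePeaks(ts)
  expect_equal(unname(peaks[["0"]]), -1456.4, tolerance = 1e-9) # 72.82 * 20
  expect_error(measurePeaks(simulateProtocol(defaultPhenotype("WT", 37),
                                             "ssfi")), "protocol-mismatch")
})

test_that("degenerate sweeps measure zero or error cleanly", {
  time <- seq(0, 11, by = 0.02)
  zero <- make_traceset(time, matrix(0, length(time), 4),
                        sweep_v = c(-20, -10, 0, 10),
                        protocol = vclampProtocol("activation"))
  expect_equal(unname(measurePeaks(zero)), rep(0, 4))
  expect_error(conductanceCurve(measurePeaks(zero)), "zero")
})

test_that("conductance curve inverts the activation Boltzmann", {
  ph <- defaultPhenotype("WT", 37)
  ts <- simulateProtocol(ph, "activation")
  g <- conductanceCurve(measurePeaks(ts))
  v <- as.numeric(names(g))
  a <- activationBoltzmann(ph, v)
  expect_equal(unname(g), unname(a / max(a)), tolerance = 1e-3)
  fit <- fitBoltzmann(g, direction = "ascending")
  expect_equal(fit@v_half, ph@v_half_act, tolerance = 1e-2)
  expect_equal(fit@k, ph@k_act, tolerance = 1e-2)
})

test_that("ohmic peaks give a flat normalized conductance", {
  v <- seq(-100, 40, by = 10)
  peaks <- setNames(0.5 * (v - 65), v)
  g <- conductanceCurve(peaks, v_rev = 65)
  expect_equal(unname(g), rep(1, length(g)))
  expect_error(conductanceCurve(peaks[1:3]), "4 voltages")
})

test_that("current density divides the 0 mV peak by capacitance", {
  ph <- defaultPhenotype("WT", 37)
  ts <- simulateProtocol(ph, "activation", capacitance = 20)
  expect_equal(currentDensity(ts), 72.82, tolerance = 1e-9)
  # homogeneity: same current trace attributed to twice the capacitance
  ts2 <- ts
  ts2@metadata$capacitance_pF <- 40
  expect_equal(currentDensity(ts2), 72.82 / 2, tolerance = 1e-9)
  # missing 0 mV sweep
  p <- vclampProtocol("activation")
  p@step_voltages <- seq(-95, 65, by = 10)
  expect_error(currentDensity(simulateProtocol(ph, p)), "0 mV")
})

test_that("onset time constants recover the generator table", {
  ph <- defaultPhenotype("L1624Q", 37)
  ts <- simulateProtocol(ph, "activation")
  taus <- onsetTauValues(fitOnsetTau(ts))
  expect_equal(unname(taus), unname(ph@tau_onset_table), tolerance = 1e-4)
  # the 37 C variant/WT tau ratio is 1/1.485 at every fitted voltage
  wt <- onsetTauValues(fitOnsetTau(
    simulateProtocol(defaultPhenotype("WT", 37), "activation")))
  expect_equal(unname(taus / wt), rep(1 / 1.485, 6), tolerance = 1e-4)
})

test_that("SSFI analysis recovers availability parameters and the shift", {
  ph22 <- defaultPhenotype("WT", 22)
  f22 <- ssfiCurve(simulateProtocol(ph22, "ssfi"))
  expect_equal(f22@v_half, ph22@v_half_inact, tolerance = 1e-2)
  expect_equal(f22@k, ph22@k_inact, tolerance = 1e-2)
  avail <- attr(f22, "availability")
  expect_equal(unname(avail[["-130"]]), 1, tolerance = 1e-3)
  f37 <- ssfiCurve(simulateProtocol(defaultPhenotype("WT", 37), "ssfi"))
  expect_gt(f37@v_half, f22@v_half) # right shift with temperature
})

test_that("recovery analysis recovers the double-exponential constants", {
  ph <- defaultPhenotype("WT", 22)
  fit <- recoveryCurve(simulateProtocol(ph, "recovery"))
  expect_false(fit@degenerate)
  expect_equal(fit@tau_fast, ph@rec_tau_fast, tolerance = 1e-3)
  expect_equal(fit@tau_slow, ph@rec_tau_slow, tolerance = 1e-3)
  expect_equal(fit@frac_fast, ph@rec_frac_fast, tolerance = 1e-3)
  short <- vclampProtocol("recovery", recovery_times = c(1, 2, 5, 10))
  expect_error(recoveryCurve(simulateProtocol(ph, short)), ">= 8")
})

test_that("persistent fraction handles square, decaying and zero traces", {
  # square non-inactivating pulse reads 100%
  time <- seq(0, 51, by = 0.02)
  sq <- matrix(ifelse(time >= 1 & time <= 51, -500, 0), ncol = 1)
  ts <- make_traceset(time, sq, sweep_v = 0,
                      protocol = vclampProtocol("persistent"))
  pf <- persistentFraction(ts)
  expect_equal(unname(pf["pct_end"]), 100)
  # fully decaying trace reads ~0%
  ph0 <- defaultPhenotype("WT", 22, f_persistent = 0)
  pf0 <- persistentFraction(simulateProtocol(ph0, "persistent"))
  expect_lt(unname(pf0["pct_end"]), 1e-6)
  # zero peak is an undefined fraction
  phz <- defaultPhenotype("WT", 22, density_at_0mV = 0)
  expect_error(persistentFraction(simulateProtocol(phz, "persistent")),
               "undefined-fraction")
  # a still-decaying current triggers the stability warning
  slowtab <- defaultTauTable(20)
  phs <- defaultPhenotype("WT", 22, tau_onset_table = slowtab,
                          f_persistent = 0.001)
  expect_warning(persistentFraction(simulateProtocol(phs, "persistent")),
                 "not stabilized")
})

test_that("full noise-free pipeline returns the phenotype exactly", {
  for (g in c("WT", "L1624Q")) for (te in c(22, 37)) {
    ph <- defaultPhenotype(g, te)
    m <- analyzeCell(make_cell(g, te))
    expect_equal(m@current_density_0mV, ph@density_at_0mV,
                 tolerance = 1e-3)
    expect_equal(m@persistent_pct_end, 100 * ph@f_persistent,
                 tolerance = 1e-3)
    expect_equal(m@gv_fit@v_half, ph@v_half_act, tolerance = 1e-3)
    expect_equal(m@ssfi_fit@v_half, ph@v_half_inact, tolerance = 1e-3)
    expect_equal(unname(m@tau_onset_by_v), unname(ph@tau_onset_table),
                 tolerance = 1e-3)
    expect_equal(m@recovery_fit@tau_fast, ph@rec_tau_fast,
                 tolerance = 1e-3)
    expect_equal(m@recovery_fit@tau_slow, ph@rec_tau_slow,
                 tolerance = 1e-3)
  }
})

test_that("cohort-mean persistent fraction is unbiased under recording noise", {
  ph <- defaultPhenotype("L1624Q", 37)
  noise <- 0.02 * ph@density_at_0mV * 20 # 2% of the 0 mV peak
  coh <- generateCohort(ph, n_cells = 20, cell_variability = 0,
                        protocols = "persistent", noise_sd = noise,
                        seed = 42)
  pf <- vapply(coh, function(cell)
    persistentFraction(cell$traces$persistent)[["pct_end"]], numeric(1))
  expect_lt(abs(mean(pf) - 100 * ph@f_persistent), 0.3)
})

test_that("metrics table has the tidy per-cell layout", {
  m <- metricsTable(list(analyzeCell(make_cell("WT", 37))))
  expect_equal(nrow(m), 1L)
  expect_true(all(c("genotype", "temperature_C", "density_pA_pF",
                    "v_half_act_mV", "k_act_mV", "v_half_inact_mV",
                    "k_inact_mV", "tau_ms_at_-30", "tau_ms_at_20",
                    "rec_tau_fast_ms", "rec_tau_slow_ms",
                    "persistent_pct") %in% names(m)))
})
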