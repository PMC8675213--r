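test_that("variant construction applies the sodium-current modifiers", {
  wt <- buildNeuron("WT")
  lq <- buildNeuron("L1624Q")
  expect_equal(wt@g_nap, 0.10 * wt@g_na * 0.018)
  expect_equal(lq@g_nap, 0.10 * lq@g_na * 0.046)
  expect_equal(wt@h_rate_multiplier, 1.0)
  expect_equal(lq@h_rate_multiplier, 1.485)
  # separate-effects models
  po <- buildNeuron("L1624Q_persistent_only")
  expect_equal(po@h_rate_multiplier, 1.0)
  expect_equal(po@g_nap, lq@g_nap)
  io <- buildNeuron("L1624Q_inactivation_only")
  expect_equal(io@h_rate_multiplier, 1.485)
  expect_equal(io@g_nap, wt@g_nap)
  # identity contract: both effects off reproduces WT exactly
  off <- buildNeuron(variantSpec("L1624Q",
                                 apply_inactivation_effect = FALSE,
                                 apply_persistent_effect = FALSE))
  for (sl in c("g_na", "g_nap", "g_kd", "g_km", "g_leak",
               "h_rate_multiplier"))
    expect_identical(slot(off, sl), slot(wt, sl))
  expect_error(variantSpec("T226M"), "unknown variant")
  expect_error(buildNeuron(variantSpec("WT", inact_rate_multiplier = -1)),
               "multiplier")
})

test_that("resting state is a stable fixed point for the WT neuron", {
  tr <- integrateNeuron(buildNeuron("WT"), stimStep(0, 1000),
                        duration = 1000, settle_ms = 500)
  expect_length(spikeTimes(tr), 0L)
  v_rest <- tr@v_m[length(tr@v_m)]
  expect_true(all(abs(tr@v_m - v_rest) < 1))
})

test_that("with all reversal potentials equal the membrane sits at that value", {
  p <- make_neuron(e_na = -65, e_k = -65, e_leak = -65)
  tr <- integrateNeuron(p, stimStep(0, 50), duration = 50)
  expect_true(all(abs(tr@v_m + 65) < 1e-9))
})

test_that("integration is deterministic and dt-convergent", {
  wt <- buildNeuron("WT")
  a <- integrateNeuron(wt, stimStep(10, 300), duration = 300)
  b <- integrateNeuron(wt, stimStep(10, 300), duration = 300)
  expect_identical(spikeTimes(a), spikeTimes(b))
  expect_identical(a@v_m, b@v_m)
  # halving dt: identical spike count, first-spike latency within 0.1 ms
  for (params in list(wt, buildNeuron("L1624Q"))) {
    c1 <- integrateNeuron(params, stimStep(10, 300), duration = 300,
                          dt = 0.005)
    c2 <- integrateNeuron(params, stimStep(10, 300), duration = 300,
                          dt = 0.0025)
    expect_equal(length(spikeTimes(c1)), length(spikeTimes(c2)))
    expect_lt(abs(spikeTimes(c1)[1] - spikeTimes(c2)[1]), 0.1)
  }
  expect_error(integrateNeuron(wt, stimStep(10, 100), duration = 100,
                               dt = 0.05), "dt")
})

test_that("gating variables stay in [0, 1] across regimes", {
  lq <- buildNeuron("L1624Q")
  for (stim in list(stimStep(40, 300), stimPulseOff(10, 50),
                    stimRamp(0.002, 400, 2000)))
    {
      tr <- integrateNeuron(lq, stim, duration = max(300,
        stim@pre_duration + stim@duration))
      expect_gte(tr@gating_range[1], 0)
      expect_lte(tr@gating_range[2], 1)
    }
})

test_that("persistent sodium current never decays under depolarization", {
  p <- make_neuron(g_na = 0, g_nap = 0.5)
  n_hold <- 50 / 0.005
  out <- testPulsePeakCurrent(p, hold_ms = 50, test_ms = 20)
  test_i <- out$trace[(n_hold + 200):length(out$trace)] # past activation
  expect_true(all(diff(abs(test_i)) >= -1e-12))
  expect_lt(max(abs(diff(test_i))), 1e-9) # steady, non-inactivating
})

test_that("voltage-clamp peak reflects the inactivation-rate multiplier", {
  wt <- buildNeuron("WT")
  same <- buildNeuron(variantSpec("custom", inact_rate_multiplier = 1,
                                  persistent_fraction = 0.018))
  expect_equal(testPulsePeakCurrent(same)$peak_pA,
               testPulsePeakCurrent(wt)$peak_pA)
  # near-instant inactivation abolishes the peak
  fast <- buildNeuron(variantSpec("custom", inact_rate_multiplier = 50,
                                  persistent_fraction = 0.018))
  expect_lt(abs(testPulsePeakCurrent(fast)$peak_pA),
            0.1 * abs(testPulsePeakCurrent(wt)$peak_pA))
})

test_that("rheobase responds to input resistance and vanishes without sodium", {
  leaky <- buildNeuron("WT", baseNeuronConfig(g_leak = 0.032))
  expect_gt(rheobase(leaky, resolution = 0.5, duration = 400),
            rheobase(buildNeuron("WT"), resolution = 0.5, duration = 400))
  passive <- make_neuron(g_na = 0, g_nap = 0)
  expect_true(is.na(rheobase(passive, resolution = 1, duration = 200)))
  expect_true(is.na(rampBlockTest(passive,
                                  stimRamp(duration = 1000))$block_onset_pA))
})

test_that("firing-rate curve is zero below rheobase and reports failures locally", {
  fi <- firingRateCurve(buildNeuron("WT"), c(0, 1), duration = 400)
  expect_equal(fi$rate_hz, c(0, 0))
  expect_equal(fi$n_spikes, c(0, 0))
})

test_that("stimulus waveforms realize the three regimes", {
  wf <- stimulusWaveform(stimStep(5, 100), 200, 0.01)
  expect_equal(wf[1], 5)
  expect_equal(wf[length(wf)], 0)
  wf2 <- stimulusWaveform(stimRamp(0.002, 400, 100), 100, 0.01)
  expect_equal(wf2[1], 0.002, tolerance = 1e-6)
  expect_lt(abs(wf2[length(wf2)] - 400), 1)
  expect_true(all(diff(wf2) > 0))
  wf3 <- stimulusWaveform(stimRamp(1, 10, 50, pre_amplitude = 10,
                                   pre_duration = 10), 60, 0.01)
  expect_equal(wf3[500], 10) # pre-stimulus
  expect_error(stimRamp(5, 2, 100), "ramp_from")
})
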