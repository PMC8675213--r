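test_that("packaged phenotypes carry the published condition values", {
  # persistent fractions at both temperatures
  expect_equal(defaultPhenotype("WT", 22)@f_persistent, 0.0095)
  expect_equal(defaultPhenotype("L1624Q", 22)@f_persistent, 0.0320)
  expect_equal(defaultPhenotype("WT", 37)@f_persistent, 0.0227)
  expect_equal(defaultPhenotype("L1624Q", 37)@f_persistent, 0.0458)
  # current densities at 37 C
  expect_equal(defaultPhenotype("WT", 37)@density_at_0mV, 72.82)
  expect_equal(defaultPhenotype("L1624Q", 37)@density_at_0mV, 45.42)
  # onset kinetics: variant is 1.485-fold faster at 37 C, identical at 22 C
  expect_equal(defaultPhenotype("L1624Q", 37)@tau_onset_table,
               defaultPhenotype("WT", 37)@tau_onset_table / 1.485)
  expect_identical(defaultPhenotype("L1624Q", 22)@tau_onset_table,
                   defaultPhenotype("WT", 22)@tau_onset_table)
  # 22 C densities are equal between genotypes (no published difference)
  expect_equal(defaultPhenotype("WT", 22)@density_at_0mV,
               defaultPhenotype("L1624Q", 22)@density_at_0mV)
  # SSFI midpoint right-shifted at 37 C for both genotypes
  expect_gt(defaultPhenotype("WT", 37)@v_half_inact,
            defaultPhenotype("WT", 22)@v_half_inact)
})

test_that("unsupported conditions raise explicit errors", {
  expect_error(defaultPhenotype("R1648H", 37), "should be one of")
  expect_error(defaultPhenotype("WT", 30), "unsupported condition")
})

test_that("defaults are overridable and validity is enforced", {
  ph <- defaultPhenotype("WT", 22, v_half_act = -30, density_at_0mV = 80)
  expect_equal(ph@v_half_act, -30)
  expect_equal(ph@density_at_0mV, 80)
  expect_error(channelPhenotype("x", 22, f_persistent = 1), "f_persistent")
  expect_error(channelPhenotype("x", 22, k_act = 0), "k_act")
  expect_error(channelPhenotype("x", 22, rec_tau_fast = -1), "recovery")
})

test_that("tau table lookups interpolate inside and extend outside", {
  ph <- defaultPhenotype("WT", 22)
  tab <- ph@tau_onset_table
  expect_equal(unname(tauOnsetAt(ph, 0)), unname(tab[["0"]]))
  # midpoint between grid entries
  expect_equal(unname(tauOnsetAt(ph, -5)),
               (tab[["-10"]] + tab[["0"]]) / 2, ignore_attr = TRUE)
  # nearest-endpoint extension outside the tabulated range
  expect_equal(unname(tauOnsetAt(ph, -100)), unname(tab[["-30"]]))
  bad <- ph
  bad@tau_onset_table[2] <- NA_real_
  expect_error(tauOnsetAt(bad, 0), "configuration error")
})
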