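test_that("protocol presets match the recording protocols", {
  act <- vclampProtocol("activation")
  expect_equal(act@step_voltages, seq(-100, 70, by = 10))
  expect_length(act@step_voltages, 18L)
  expect_equal(act@holding_v, -130)
  expect_equal(act@step_duration, 10)

  ssfi <- vclampProtocol("ssfi")
  expect_equal(ssfi@step_voltages, seq(-130, 10, by = 10))
  expect_equal(ssfi@step_duration, 200)
  expect_equal(ssfi@test_pulse_v, 0)
  expect_equal(ssfi@test_pulse_duration, 19)

  rec <- vclampProtocol("recovery")
  expect_equal(rec@step_voltages, 0)
  expect_equal(rec@step_duration, 200)
  expect_equal(rec@recovery_v, -90)
  expect_gte(length(rec@recovery_times), 8L)

  per <- vclampProtocol("persistent")
  expect_equal(per@step_duration, 50)
  expect_equal(per@holding_v, -130)
  expect_equal(per@step_voltages, 0)
})

test_that("protocol validity rejects malformed definitions", {
  p <- vclampProtocol("activation")
  p@sample_interval <- 1            # > step_duration / 50
  expect_error(validObject(p), "sample_interval")
  p <- vclampProtocol("activation")
  p@step_voltages <- c(0, 0, 10)
  expect_error(validObject(p), "strictly increasing")
  p <- vclampProtocol("recovery")
  p@recovery_times <- numeric()
  expect_error(validObject(p), "recovery")
})
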