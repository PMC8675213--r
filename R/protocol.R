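#' Voltage-clamp protocol presets
#'
#' The four whole-cell protocols, as used in the recordings the generator
#' emulates:
#' \describe{
#'   \item{activation}{10 ms steps to -100..+70 mV in 10 mV increments from a
#'     holding potential of -130 mV.}
#'   \item{ssfi}{200 ms prepulses to -130..+10 mV followed by a 19 ms test
#'     pulse at 0 mV.}
#'   \item{recovery}{200 ms conditioning pulse at 0 mV, a -90 mV recovery
#'     interval of increasing duration, then a 19 ms test pulse at 0 mV.}
#'   \item{persistent}{a single 50 ms pulse from -130 to 0 mV.}
#' }
#'
#' @param kind preset name.
#' @param sample_interval sampling interval (ms); default 0.02 ms (50 kHz).
#' @param recovery_times recovery intervals (ms) for the recovery preset,
#'   spanning both the fast (~2 ms) and slow (~50 ms) recovery regimes.
#' @return a \linkS4class{VClampProtocol}.
#' @export
#' @examples
#' vclampProtocol("activation")
vclampProtocol <- function(kind = c("activation", "ssfi", "recovery",
                                    "persistent"),
                           sample_interval = 0.02,
                           recovery_times = c(0.5, 1, 2, 3, 5, 8, 12, 20,
                                              30, 50, 100, 200)) {
  kind <- match.arg(kind)
  switch(kind,
    activation = new("VClampProtocol", kind = "activation",
      holding_v = -130, step_voltages = seq(-100, 70, by = 10),
      step_duration = 10, test_pulse_v = NA_real_,
      test_pulse_duration = NA_real_, recovery_v = NA_real_,
      recovery_times = numeric(), sample_interval = sample_interval),
    ssfi = new("VClampProtocol", kind = "ssfi",
      holding_v = -130, step_voltages = seq(-130, 10, by = 10),
      step_duration = 200, test_pulse_v = 0, test_pulse_duration = 19,
      recovery_v = NA_real_, recovery_times = numeric(),
      sample_interval = sample_interval),
    recovery = new("VClampProtocol", kind = "recovery",
      holding_v = -130, step_voltages = 0, step_duration = 200,
      test_pulse_v = 0, test_pulse_duration = 19, recovery_v = -90,
      recovery_times = recovery_times, sample_interval = sample_interval),
    persistent = new("VClampProtocol", kind = "persistent",
      holding_v = -130, step_voltages = 0, step_duration = 50,
      test_pulse_v = NA_real_, test_pulse_duration = NA_real_,
      recovery_v = NA_real_, recovery_times = numeric(),
      sample_interval = sample_interval)
  )
}

setMethod("show", "VClampProtocol", function(object) {
  cat("VClampProtocol:", object@kind, "\n")
  cat(sprintf("  holding %.0f mV; %d step voltage(s) %.0f..%.0f mV; step %.0f ms; fs = %.0f kHz\n",
              object@holding_v, length(object@step_voltages),
              min(object@step_voltages), max(object@step_voltages),
              object@step_duration, 1 / object@sample_interval))
  if (is.finite(object@test_pulse_v))
    cat(sprintf("  test pulse %.0f mV for %.0f ms\n", object@test_pulse_v,
                object@test_pulse_duration))
  if (length(object@recovery_times))
    cat("  recovery times (ms):", paste(object@recovery_times,
                                        collapse = ", "), "\n")
})
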