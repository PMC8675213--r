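# Single-compartment cortical pyramidal neuron with WT / L1624Q sodium
# currents. The base parameterization is a regular-spiking cortical model
# (Traub-type kinetics with a VT shift; transient Na, delayed-rectifier K,
# slow non-inactivating K, leak) extended with a persistent sodium current:
# a non-inactivating component of the fast sodium current with a single
# activation gate whose rates are 1000x the fast-Na activation rates.

#' Variant specification for the sodium currents
#'
#' Presets: \code{"WT"} (multiplier 1.0, persistent fraction 0.018),
#' \code{"L1624Q"} (multiplier 1.485, fraction 0.046),
#' \code{"L1624Q_persistent_only"} (WT kinetics with the L1624Q persistent
#' conductance) and \code{"L1624Q_inactivation_only"} (L1624Q kinetics with
#' the WT persistent conductance). The two effect switches allow any other
#' separate-effects combination.
#'
#' @param label preset name, or a custom label when the numeric arguments
#'   are given.
#' @param inact_rate_multiplier multiplier on the rate of fast-inactivation
#'   onset (the h-gate closing rate).
#' @param persistent_fraction fraction for the persistent-conductance
#'   formula g_NaP = 0.10 x g_Na x fraction.
#' @param apply_inactivation_effect,apply_persistent_effect logical switches;
#'   with both FALSE the neuron built from this spec is exactly the WT
#'   neuron.
#' @return a \linkS4class{VariantSpec}.
#' @export
#' @examples
#' variantSpec("L1624Q")
#' variantSpec("L1624Q", apply_inactivation_effect = FALSE) # persistent-only
variantSpec <- function(label = c("WT", "L1624Q", "L1624Q_persistent_only",
                                  "L1624Q_inactivation_only"),
                        inact_rate_multiplier = NULL,
                        persistent_fraction = NULL,
                        apply_inactivation_effect = NULL,
                        apply_persistent_effect = NULL) {
  if (is.null(inact_rate_multiplier) && length(label) == 1L &&
      !label %in% c("WT", "L1624Q", "L1624Q_persistent_only",
                    "L1624Q_inactivation_only") &&
      is.null(persistent_fraction))
    stop("unknown variant preset: ", label, call. = FALSE)
  preset <- if (length(label) > 1L || label %in%
                c("WT", "L1624Q", "L1624Q_persistent_only",
                  "L1624Q_inactivation_only")) match.arg(label) else label
  def <- switch(preset,
    WT = list(mult = 1.0, frac = 0.018, ai = TRUE, ap = TRUE),
    L1624Q = list(mult = 1.485, frac = 0.046, ai = TRUE, ap = TRUE),
    L1624Q_persistent_only = list(mult = 1.485, frac = 0.046, ai = FALSE,
                                  ap = TRUE),
    L1624Q_inactivation_only = list(mult = 1.485, frac = 0.046, ai = TRUE,
                                    ap = FALSE),
    list(mult = 1.0, frac = 0.018, ai = TRUE, ap = TRUE))
  new("VariantSpec", label = preset,
      inact_rate_multiplier = inact_rate_multiplier %||% def$mult,
      persistent_fraction = persistent_fraction %||% def$frac,
      apply_inactivation_effect = apply_inactivation_effect %||% def$ai,
      apply_persistent_effect = apply_persistent_effect %||% def$ap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Base constants of the cortical neuron model
#'
#' All base-model constants live here so they can be inspected or swapped as
#' one block. Defaults: specific capacitance 1 uF/cm2; compartment area
#' 2e-5 cm2 (a ~25 um-diameter soma, chosen so the WT rheobase for a 1 s
#' step falls in the 1-5 pA range); g_Na = 56, g_Kd = 3,
#' g_Ks (slow K) = 0.005, g_leak = 0.016 mS/cm2; E_Na = +50, E_K = -90,
#' E_leak = -70.3 mV; kinetic shift VT = -56.2 mV; slow-K time-constant
#' ceiling 608 ms; persistent-Na gate rates 1000x the fast-Na activation
#' rates. The potassium and leak conductances are calibrated so the model
#' expresses the variant phenomenology (bistable persistent firing in
#' L1624Q, silent rest in both genotypes) while keeping a regular-spiking
#' f-I curve. \code{nap_mode} selects how the persistent conductance is set:
#' \code{"formula"} (the literal reading, g_NaP = 0.10 x g_Na x fraction) or
#' \code{"matched"} (g_NaP chosen so the persistent current at a 0 mV test
#' pulse equals the stated fraction of the fast peak).
#'
#' @param ... overrides of any constant.
#' @return named list of base constants.
#' @export
baseNeuronConfig <- function(...) {
  base <- list(cm = 1, area = 2e-5,
               g_na = 56, g_kd = 3, g_km = 0.005, g_leak = 0.016,
               e_na = 50, e_k = -90, e_leak = -70.3,
               vt = -56.2, tau_max = 608,
               nap_rate_factor = 1000, nap_mode = "formula",
               wt_fraction = 0.018, temperature = 37)
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("unknown base constant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  modifyList(base, over)
}

#' Build a neuron parameterization from a variant specification
#'
#' Applies the variant's sodium-current modifiers to the base model: when
#' \code{apply_inactivation_effect} the fast-Na h-gate closing rate is
#' multiplied by \code{inact_rate_multiplier}; when
#' \code{apply_persistent_effect} the persistent conductance uses the
#' variant's fraction, otherwise the WT fraction. The persistent current has
#' no inactivation gate and its activation/deactivation rates are 1000x the
#' fast-Na activation rates.
#'
#' @param variant a \linkS4class{VariantSpec} or preset name.
#' @param base base constants from \code{\link{baseNeuronConfig}}.
#' @return a \linkS4class{NeuronParams}.
#' @export
#' @examples
#' buildNeuron("L1624Q")
buildNeuron <- function(variant = "WT", base = baseNeuronConfig()) {
  if (is.character(variant)) variant <- variantSpec(variant)
  stopifnot(is(variant, "VariantSpec"))
  validObject(variant)
  mult <- if (variant@apply_inactivation_effect)
    variant@inact_rate_multiplier else 1.0
  frac <- if (variant@apply_persistent_effect)
    variant@persistent_fraction else base$wt_fraction
  g_nap <- if (identical(base$nap_mode, "matched"))
    .matchedNapConductance(frac, mult, base)
  else 0.10 * base$g_na * frac
  new("NeuronParams", cm = base$cm, area = base$area,
      g_na = base$g_na, g_nap = g_nap, g_kd = base$g_kd, g_km = base$g_km,
      g_leak = base$g_leak, e_na = base$e_na, e_k = base$e_k,
      e_leak = base$e_leak, vt = base$vt, tau_max = base$tau_max,
      h_rate_multiplier = mult, nap_rate_factor = base$nap_rate_factor,
      temperature = base$temperature, label = variant@label)
}

# Alternative persistent-conductance reading: g_NaP such that, in a 0 mV
# voltage-clamp test pulse from -120 mV, the steady persistent current is
# the stated fraction of the fast-Na peak.
.matchedNapConductance <- function(frac, mult, base) {
  p0 <- .packParams2(base, g_nap = 0, h_mult = mult)
  n_hold <- round(50 / 0.005); n_test <- round(20 / 0.005)
  vc <- c(rep(-120, n_hold), rep(0, n_test))
  ina <- .hh_vclamp(p0, vc, 0.005)
  peak_fast <- abs(min(ina[(n_hold + 1):length(vc)]))
  # steady mp at 0 mV equals the fast-Na activation steady state at 0 mV
  u <- 0 - base$vt
  am <- 0.32 * (13 - u) / (exp((13 - u) / 4) - 1)
  bm <- 0.28 * (u - 40) / (exp((u - 40) / 5) - 1)
  mp_inf <- am / (am + bm)
  frac * peak_fast / (mp_inf * abs(0 - base$e_na))
}

.packParams <- function(params) {
  c(cm = params@cm, g_na = params@g_na, g_nap = params@g_nap,
    g_kd = params@g_kd, g_km = params@g_km, g_leak = params@g_leak,
    e_na = params@e_na, e_k = params@e_k, e_leak = params@e_leak,
    vt = params@vt, tau_max = params@tau_max,
    h_mult = params@h_rate_multiplier, nap_fac = params@nap_rate_factor)
}

.packParams2 <- function(base, g_nap, h_mult) {
  c(cm = base$cm, g_na = base$g_na, g_nap = g_nap, g_kd = base$g_kd,
    g_km = base$g_km, g_leak = base$g_leak, e_na = base$e_na,
    e_k = base$e_k, e_leak = base$e_leak, vt = base$vt,
    tau_max = base$tau_max, h_mult = h_mult, nap_fac = base$nap_rate_factor)
}

#' Current-injection stimulus programs
#'
#' Constructors for the three stimulation regimes: a sustained step
#' (\code{stimStep}), a brief pulse followed by zero stimulus
#' (\code{stimPulseOff}), and a slowly increasing ramp
#' (\code{stimRamp}; exponential in amplitude by default, since a fixed
#' fractional growth per unit time is what "slowly increasing" over five
#' decades of amplitude requires), optionally preceded by a pre-stimulus.
#'
#' @param amplitude step/pulse amplitude (pA).
#' @param duration stimulus duration (ms).
#' @param from,to ramp endpoints (pA).
#' @param shape \code{"exponential"} or \code{"linear"}.
#' @param pre_amplitude,pre_duration optional pre-stimulus (pA, ms).
#' @return a \linkS4class{StimulusProgram}.
#' @name stimulus
#' @export
#' @examples
#' stimRamp(0.002, 400, 10000, pre_amplitude = 10, pre_duration = 10)
stimStep <- function(amplitude, duration = 1000) {
  new("StimulusProgram", kind = "step", amplitude = amplitude,
      ramp_from = NA_real_, ramp_to = NA_real_, duration = duration,
      ramp_shape = "exponential", pre_amplitude = 0, pre_duration = 0)
}

#' @rdname stimulus
#' @export
stimPulseOff <- function(amplitude = 10, duration = 50) {
  new("StimulusProgram", kind = "pulse_then_off", amplitude = amplitude,
      ramp_from = NA_real_, ramp_to = NA_real_, duration = duration,
      ramp_shape = "exponential", pre_amplitude = 0, pre_duration = 0)
}

#' @rdname stimulus
#' @export
stimRamp <- function(from = 0.002, to = 400, duration = 10000,
                     shape = c("exponential", "linear"),
                     pre_amplitude = 0, pre_duration = 0) {
  new("StimulusProgram", kind = "ramp", amplitude = NA_real_,
      ramp_from = from, ramp_to = to, duration = duration,
      ramp_shape = match.arg(shape), pre_amplitude = pre_amplitude,
      pre_duration = pre_duration)
}

#' Stimulus waveform (pA) on the integration grid
#' @param stim a \linkS4class{StimulusProgram}.
#' @param total_ms total simulated time (ms).
#' @param dt integration step (ms).
#' @return numeric vector of injected current (pA) per step.
#' @export
stimulusWaveform <- function(stim, total_ms, dt) {
  validObject(stim)
  n <- round(total_ms / dt)
  t <- (seq_len(n) - 1L) * dt
  amp <- numeric(n)
  t0 <- stim@pre_duration
  if (t0 > 0) amp[t < t0] <- stim@pre_amplitude
  rel <- t - t0
  act <- rel >= 0 & rel < stim@duration
  if (stim@kind %in% c("step", "pulse_then_off")) {
    amp[act] <- stim@amplitude
  } else {
    amp[act] <- if (stim@ramp_shape == "exponential")
      stim@ramp_from * (stim@ramp_to / stim@ramp_from)^(rel[act] / stim@duration)
    else stim@ramp_from + (stim@ramp_to - stim@ramp_from) * rel[act] /
      stim@duration
  }
  amp
}

#' Integrate the neuron model
#'
#' Deterministic fixed-step integration of the current-balance equation with
#' all gating variables (forward Euler for the membrane potential,
#' exponential Euler for the gates, which keeps the 1000x-fast persistent-Na
#' gate stable). The model is first settled at zero stimulus for
#' \code{settle_ms} so the stimulus is applied from the resting state.
#' Spikes are upward 0 mV crossings with a 1 ms refractory. Numerical
#' blow-up (membrane potential outside [E_K - 40, E_Na + 40]) raises an
#' integration-failure error naming the time of failure.
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param stim a \linkS4class{StimulusProgram}.
#' @param duration total simulated time (ms); must cover the stimulus.
#' @param dt integration step (ms); <= 0.01 ms.
#' @param record_dt recording interval for the returned trace (ms).
#' @param settle_ms pre-stimulus settling time at zero input (ms).
#' @return a \linkS4class{SimTrace}.
#' @export
#' @examples
#' tr <- integrateNeuron(buildNeuron("WT"), stimStep(5, 200), duration = 250)
#' length(spikeTimes(tr))
integrateNeuron <- function(params, stim, duration = 1000, dt = 0.005,
                            record_dt = 0.05, settle_ms = 200) {
  stopifnot(is(params, "NeuronParams"), is(stim, "StimulusProgram"))
  validObject(params)
  if (dt > 0.01)
    stop("dt must be <= 0.01 ms (stiff persistent-Na gate rates)",
         call. = FALSE)
  if (duration < stim@pre_duration + stim@duration)
    stop("duration must cover the stimulus program", call. = FALSE)
  amp_pA <- stimulusWaveform(stim, duration, dt)
  stim_density <- amp_pA * 1e-6 / params@area  # pA -> uA/cm2
  record_every <- max(1L, round(record_dt / dt))
  res <- .hh_run(.packParams(params), stim_density, dt, record_every,
                 settle_ms)
  rec_idx <- pmin(length(amp_pA), floor(res$time / dt) + 1L)
  new("SimTrace", time = res$time, v_m = res$v,
      stimulus = amp_pA[rec_idx], spike_times = res$spike_times,
      fired_after_offset = NA, block_onset_current = NA_real_,
      dt = dt, gating_range = res$gating_range)
}

#' Peak sodium current under a voltage-clamp test pulse
#'
#' Drives the model's sodium currents (fast + persistent) with a commanded
#' voltage step (default 0 mV from a holding potential of -120 mV) and
#' returns the peak total sodium current during the pulse.
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param hold_v,test_v holding and test voltages (mV).
#' @param hold_ms,test_ms segment durations (ms).
#' @param dt integration step (ms).
#' @return list with \code{peak_pA} (signed, inward negative),
#'   \code{peak_density} (uA/cm2) and the current \code{trace} (pA) with its
#'   \code{time} (ms).
#' @export
#' @examples
#' wt <- testPulsePeakCurrent(buildNeuron("WT"))$peak_pA
#' lq <- testPulsePeakCurrent(buildNeuron("L1624Q"))$peak_pA
#' 100 * (1 - lq / wt)
testPulsePeakCurrent <- function(params, hold_v = -120, test_v = 0,
                                 hold_ms = 50, test_ms = 20, dt = 0.005) {
  stopifnot(is(params, "NeuronParams"))
  n_hold <- round(hold_ms / dt); n_test <- round(test_ms / dt)
  vc <- c(rep(hold_v, n_hold), rep(test_v, n_test))
  ina <- .hh_vclamp(.packParams(params), vc, dt)
  test_idx <- (n_hold + 1):length(vc)
  peak_density <- ina[test_idx][which.max(abs(ina[test_idx]))]
  pA <- ina * params@area * 1e6
  list(peak_pA = peak_density * params@area * 1e6,
       peak_density = peak_density,
       time = (seq_along(vc) - 1) * dt, trace = pA)
}

#' Firing-rate (f-I) curve
#'
#' Steady-state firing rate for 1 s current steps: twice the spike count in
#' the final 500 ms. Integration failures at single amplitudes are reported
#' as NA for that amplitude, not propagated globally.
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param amplitudes injected currents (pA), >= 0.
#' @param duration step duration (ms).
#' @param dt integration step (ms).
#' @return data.frame with columns \code{amplitude_pA}, \code{rate_hz},
#'   \code{n_spikes}.
#' @export
firingRateCurve <- function(params, amplitudes = seq(1, 100, by = 1),
                            duration = 1000, dt = 0.005) {
  stopifnot(all(amplitudes >= 0))
  rows <- lapply(amplitudes, function(a) {
    tr <- tryCatch(integrateNeuron(params, stimStep(a, duration),
                                   duration = duration, dt = dt),
                   error = function(e) {
                     warning("integration failed at ", a, " pA: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(tr))
      return(data.frame(amplitude_pA = a, rate_hz = NA_real_,
                        n_spikes = NA_integer_))
    ss <- spikeTimes(tr)
    n_ss <- sum(ss >= duration - 500 & ss <= duration)
    data.frame(amplitude_pA = a, rate_hz = 2 * n_ss,
               n_spikes = length(ss))
  })
  do.call(rbind, rows)
}

#' Persistent firing after stimulus offset
#'
#' Injects a brief pulse (default 10 pA for 50 ms) and asks whether action
#' potential firing continues to the end of the simulation after the
#' stimulus is removed: at least one post-offset spike and no terminal
#' silent period longer than max(3 median post-offset inter-spike intervals,
#' 50 ms).
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param amplitude,pulse_ms pulse amplitude (pA) and duration (ms).
#' @param total_ms total simulated time (ms).
#' @param dt integration step (ms).
#' @return list with \code{fired_after_offset} (logical),
#'   \code{n_spikes_after}, \code{duration_after_s} (time firing continued
#'   after offset, s) and the \linkS4class{SimTrace}.
#' @export
persistentFiringTest <- function(params, amplitude = 10, pulse_ms = 50,
                                 total_ms = 1000, dt = 0.005) {
  if (pulse_ms >= total_ms)
    stop("pulse must end before the total duration", call. = FALSE)
  tr <- integrateNeuron(params, stimPulseOff(amplitude, pulse_ms),
                        duration = total_ms, dt = dt)
  ss <- spikeTimes(tr)
  after <- ss[ss > pulse_ms]
  if (!length(after)) {
    flag <- FALSE; dur <- 0
  } else {
    gap_allow <- if (length(after) >= 3L)
      max(3 * median(diff(after)), 50) else 50
    flag <- (total_ms - after[length(after)]) <= gap_allow
    dur <- if (flag) (total_ms - pulse_ms) / 1000
           else (after[length(after)] - pulse_ms) / 1000
  }
  tr@fired_after_offset <- flag
  list(fired_after_offset = flag, n_spikes_after = length(after),
       duration_after_s = dur, trace = tr)
}

#' Depolarization-block onset under a current ramp
#'
#' Runs a slowly increasing current ramp (default exponential from 0.002 to
#' 400 pA over 10 s, optionally preceded by a 10 pA x 10 ms pre-stimulus)
#' and locates depolarization block: a spike-free terminal period of at
#' least 100 ms during which the membrane stays depolarized above -30 mV.
#' The block onset is the injected current at the last spike before that
#' period; NA when no block occurs before ramp end (or no spikes at all).
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param ramp a \linkS4class{StimulusProgram} of kind ramp.
#' @param dt integration step (ms).
#' @return list with \code{block_onset_pA} (NA if none),
#'   \code{last_spike_ms} and the \linkS4class{SimTrace}.
#' @export
#' @examples
#' \donttest{
#' rampBlockTest(buildNeuron("L1624Q"))$block_onset_pA
#' }
rampBlockTest <- function(params, ramp = stimRamp(), dt = 0.005) {
  stopifnot(is(ramp, "StimulusProgram"), identical(ramp@kind, "ramp"))
  total <- ramp@pre_duration + ramp@duration
  tr <- integrateNeuron(params, ramp, duration = total, dt = dt)
  ss <- spikeTimes(tr)
  block <- NA_real_; last_spike <- NA_real_
  if (length(ss)) {
    last_spike <- ss[length(ss)]
    t <- tr@time; v <- tr@v_m
    tail_idx <- which(t > last_spike)
    if (length(tail_idx)) {
      above <- v[tail_idx] > -30
      # first index after which the membrane stays above -30 mV to ramp end
      runs <- rev(cumprod(rev(above)))
      first_sustained <- which(runs == 1)[1L]
      if (!is.na(first_sustained)) {
        t_star <- t[tail_idx[first_sustained]]
        if (total - t_star >= 100) {
          wf <- stimulusWaveform(ramp, total, dt)
          block <- wf[min(length(wf), floor(last_spike / dt) + 1L)]
        }
      }
    }
  }
  tr@block_onset_current <- block
  list(block_onset_pA = block, last_spike_ms = last_spike, trace = tr)
}

#' Rheobase by bisection
#'
#' Smallest 1 s step amplitude evoking at least one spike, found by
#' bisection on [0, \code{max_amp}] down to \code{resolution}. NA when even
#' \code{max_amp} evokes no spike.
#'
#' @param params a \linkS4class{NeuronParams}.
#' @param resolution bisection resolution (pA), > 0.
#' @param max_amp search ceiling (pA).
#' @param duration step duration (ms).
#' @param dt integration step (ms).
#' @return rheobase (pA), or NA.
#' @export
rheobase <- function(params, resolution = 0.25, max_amp = 100,
                     duration = 1000, dt = 0.005) {
  if (resolution <= 0)
    stop("resolution must be > 0", call. = FALSE)
  fires <- function(a) {
    tr <- integrateNeuron(params, stimStep(a, duration),
                          duration = duration, dt = dt)
    length(spikeTimes(tr)) > 0L
  }
  if (!fires(max_amp)) return(NA_real_)
  lo <- 0; hi <- max_amp
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' @rdname accessors
setMethod("spikeTimes", "SimTrace", function(x) x@spike_times)

setMethod("show", "SimTrace", function(object) {
  cat(sprintf("SimTrace: %.0f ms recorded at %.3f ms (dt = %.3f ms), %d spikes\n",
              max(object@time), if (length(object@time) > 1)
                diff(object@time[1:2]) else NA_real_, object@dt,
              length(object@spike_times)))
  cat(sprintf("  v_m range %.1f..%.1f mV; gating range [%.3g, %.3g]\n",
              min(object@v_m), max(object@v_m), object@gating_range[1],
              object@gating_range[2]))
  if (!is.na(object@fired_after_offset))
    cat("  fired after stimulus offset:", object@fired_after_offset, "\n")
  if (is.finite(object@block_onset_current))
    cat(sprintf("  depolarization block onset at %.2f pA\n",
                object@block_onset_current))
})

setMethod("show", "NeuronParams", function(object) {
  cat("NeuronParams:", object@label, "\n")
  cat(sprintf("  g (mS/cm2): Na %.1f, NaP %.4f, Kd %.1f, Ks %.3f, leak %.4f\n",
              object@g_na, object@g_nap, object@g_kd, object@g_km,
              object@g_leak))
  cat(sprintf("  E (mV): Na %+.0f, K %+.0f, leak %+.1f; VT = %.1f mV\n",
              object@e_na, object@e_k, object@e_leak, object@vt))
  cat(sprintf("  h-rate multiplier %.3f; area %.2e cm2; Cm %.1f uF/cm2\n",
              object@h_rate_multiplier, object@area, object@cm))
})

setMethod("show", "VariantSpec", function(object) {
  cat("VariantSpec:", object@label, "\n")
  cat(sprintf("  inactivation-rate multiplier %.3f (%s), persistent fraction %.3f (%s)\n",
              object@inact_rate_multiplier,
              if (object@apply_inactivation_effect) "applied" else "off",
              object@persistent_fraction,
              if (object@apply_persistent_effect) "applied" else "off"))
})

setMethod("show", "StimulusProgram", function(object) {
  cat("StimulusProgram:", object@kind, "\n")
  if (object@kind == "ramp")
    cat(sprintf("  %s ramp %.3f -> %.1f pA over %.0f ms\n",
                object@ramp_shape, object@ramp_from, object@ramp_to,
                object@duration))
  else
    cat(sprintf("  %.2f pA for %.0f ms\n", object@amplitude,
                object@duration))
  if (object@pre_duration > 0)
    cat(sprintf("  pre-stimulus %.1f pA for %.0f ms\n",
                object@pre_amplitude, object@pre_duration))
})
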