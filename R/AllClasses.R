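#' @import methods
#' @importFrom stats approx coef lm median p.adjust pt qt rnorm rlnorm sd t.test
#'   setNames anova predict resid var aggregate
#' @importFrom utils read.table write.table packageVersion modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib navclamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ChannelPhenotype: generative ground truth for one genotype x temperature
#'
#' Holds every parameter the voltage-clamp generator needs to emit sweeps for
#' one condition: current density at 0 mV, activation and steady-state fast
#' inactivation (SSFI) Boltzmann parameters, a table of fast-inactivation
#' onset time constants over voltage, the persistent (non-inactivating)
#' current fraction, and double-exponential recovery constants.
#'
#' @slot genotype character label, e.g. \code{"WT"} or \code{"L1624Q"}.
#' @slot temperature numeric, degrees Celsius.
#' @slot density_at_0mV numeric, peak current density magnitude at 0 mV in
#'   pA/pF (currents themselves are inward-negative).
#' @slot v_half_act,k_act numeric, activation Boltzmann midpoint and slope
#'   factor (mV); \code{k_act > 0}.
#' @slot v_rev numeric, sodium reversal potential (mV).
#' @slot v_half_inact,k_inact numeric, SSFI Boltzmann midpoint and slope (mV).
#' @slot tau_onset_table named numeric, fast-inactivation onset time constant
#'   (ms) by voltage (names are mV); must cover the -30..+20 mV analysis grid.
#' @slot f_persistent numeric fraction in [0, 1): persistent current as a
#'   fraction of peak.
#' @slot rec_tau_fast,rec_tau_slow numeric, recovery time constants (ms).
#' @slot rec_frac_fast numeric in [0, 1], fast fraction of recovery.
#' @export
setClass("ChannelPhenotype",
  representation(
    genotype = "character",
    temperature = "numeric",
    density_at_0mV = "numeric",
    v_half_act = "numeric",
    k_act = "numeric",
    v_rev = "numeric",
    v_half_inact = "numeric",
    k_inact = "numeric",
    tau_onset_table = "numeric",
    f_persistent = "numeric",
    rec_tau_fast = "numeric",
    rec_tau_slow = "numeric",
    rec_frac_fast = "numeric"
  )
)

setValidity("ChannelPhenotype", function(object) {
  msg <- character()
  if (length(object@genotype) != 1L || !nzchar(object@genotype))
    msg <- c(msg, "genotype must be a single non-empty label")
  if (!(object@f_persistent >= 0 && object@f_persistent < 1))
    msg <- c(msg, "f_persistent must lie in [0, 1)")
  if (object@k_act <= 0)
    msg <- c(msg, "k_act must be > 0")
  if (object@k_inact <= 0)
    msg <- c(msg, "k_inact must be > 0")
  if (object@density_at_0mV < 0)
    msg <- c(msg, "density_at_0mV is a magnitude and must be >= 0")
  if (any(!is.finite(object@tau_onset_table)) ||
      any(object@tau_onset_table <= 0))
    msg <- c(msg, "tau_onset_table entries must be finite and > 0")
  if (length(object@tau_onset_table) < 2L ||
      is.null(names(object@tau_onset_table)))
    msg <- c(msg, "tau_onset_table must be a named vector with >= 2 voltages")
  if (object@rec_tau_fast <= 0 || object@rec_tau_slow <= 0)
    msg <- c(msg, "recovery time constants must be > 0")
  if (object@rec_frac_fast < 0 || object@rec_frac_fast > 1)
    msg <- c(msg, "rec_frac_fast must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' VClampProtocol: a voltage-clamp stimulation protocol
#'
#' Describes one of the four whole-cell protocols: \code{activation} (brief
#' depolarizing steps from a hyperpolarized holding potential), \code{ssfi}
#' (long prepulses followed by a fixed test pulse), \code{recovery}
#' (a conditioning pulse, a variable-duration recovery interval, then a test
#' pulse) and \code{persistent} (a single long depolarizing pulse).
#'
#' @slot kind one of \code{"activation"}, \code{"ssfi"}, \code{"recovery"},
#'   \code{"persistent"}.
#' @slot holding_v holding potential (mV).
#' @slot step_voltages step (or prepulse, or conditioning) voltages (mV),
#'   strictly increasing.
#' @slot step_duration duration of the step/prepulse/conditioning pulse (ms).
#' @slot test_pulse_v,test_pulse_duration test-pulse voltage (mV) and
#'   duration (ms); NA for protocols without a test pulse.
#' @slot recovery_v recovery-interval voltage (mV), recovery protocol only.
#' @slot recovery_times recovery intervals (ms), recovery protocol only.
#' @slot sample_interval sampling interval (ms).
#' @export
setClass("VClampProtocol",
  representation(
    kind = "character",
    holding_v = "numeric",
    step_voltages = "numeric",
    step_duration = "numeric",
    test_pulse_v = "numeric",
    test_pulse_duration = "numeric",
    recovery_v = "numeric",
    recovery_times = "numeric",
    sample_interval = "numeric"
  )
)

setValidity("VClampProtocol", function(object) {
  msg <- character()
  kinds <- c("activation", "ssfi", "recovery", "persistent")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (length(object@step_voltages) == 0L)
    msg <- c(msg, "step_voltages must be non-empty")
  if (length(object@step_voltages) > 1L &&
      any(diff(object@step_voltages) <= 0))
    msg <- c(msg, "step_voltages must be strictly increasing")
  if (object@step_duration <= 0)
    msg <- c(msg, "step_duration must be > 0")
  if (object@sample_interval <= 0)
    msg <- c(msg, "sample_interval must be > 0")
  if (object@sample_interval > object@step_duration / 50)
    msg <- c(msg, "sample_interval must be <= step_duration/50")
  if (identical(object@kind, "recovery")) {
    if (length(object@recovery_times) < 2L || any(object@recovery_times < 0))
      msg <- c(msg, "recovery protocol needs >= 2 non-negative recovery_times")
    if (!is.finite(object@test_pulse_v) ||
        !is.finite(object@test_pulse_duration))
      msg <- c(msg, "recovery protocol needs a test pulse")
  }
  if (identical(object@kind, "ssfi") &&
      (!is.finite(object@test_pulse_v) ||
       !is.finite(object@test_pulse_duration)))
    msg <- c(msg, "ssfi protocol needs a test pulse")
  if (length(msg)) msg else TRUE
})

#' TraceSet: a set of voltage-clamp current sweeps
#'
#' A \linkS4class{SummarizedExperiment} with one assay, \code{"current"}
#' (pA), rows = time points (with \code{rowData(x)$time_ms}) and columns =
#' sweeps. \code{colData} carries the per-sweep condition (\code{sweep_v} mV
#' for voltage-indexed protocols, \code{recovery_ms} for the recovery
#' protocol) plus \code{test_onset_ms}, the time at which the measured
#' pulse (step or test pulse) begins. \code{metadata} carries
#' \code{capacitance_pF}, \code{protocol} (a \linkS4class{VClampProtocol}),
#' \code{phenotype_id}, \code{genotype}, \code{temperature_C},
#' \code{noise_sd} and \code{seed}.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!"current" %in% assayNames(object))
    msg <- c(msg, "TraceSet must have a 'current' assay")
  rd <- rowData(object)
  if (!"time_ms" %in% colnames(rd))
    msg <- c(msg, "rowData must contain time_ms")
  else if (any(diff(rd$time_ms) <= 0))
    msg <- c(msg, "time_ms must be strictly increasing")
  md <- metadata(object)
  if (is.null(md$capacitance_pF) || md$capacitance_pF <= 0)
    msg <- c(msg, "metadata capacitance_pF must be > 0")
  if (!is(md$protocol, "VClampProtocol"))
    msg <- c(msg, "metadata protocol must be a VClampProtocol")
  if (!"test_onset_ms" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain test_onset_ms")
  if (length(msg)) msg else TRUE
})

#' BoltzmannFit: fitted Boltzmann curve
#'
#' Result of fitting \eqn{y = 1/(1 + \exp((V_{1/2} - V)/k))} (ascending,
#' conductance-voltage) or \eqn{y = 1/(1 + \exp((V - V_{1/2})/k))}
#' (descending, availability) to normalized data.
#'
#' @slot v_half midpoint (mV).
#' @slot k slope factor (mV), > 0.
#' @slot direction \code{"ascending"} or \code{"descending"}.
#' @slot residual_norm root-mean-square residual of the fit.
#' @export
setClass("BoltzmannFit",
  representation(v_half = "numeric", k = "numeric", direction = "character",
                 residual_norm = "numeric"))

setValidity("BoltzmannFit", function(object) {
  if (object@k <= 0) "slope factor k must be > 0" else TRUE
})

#' ExpFit: single-exponential decay fit
#'
#' Fit of \eqn{y(t) = \mathrm{offset} + \mathrm{amplitude}\,e^{-t/\tau}}.
#'
#' @slot tau time constant (ms), > 0.
#' @slot amplitude,offset pA.
#' @slot residual_norm root-mean-square residual.
#' @export
setClass("ExpFit",
  representation(tau = "numeric", amplitude = "numeric", offset = "numeric",
                 residual_norm = "numeric"))

setValidity("ExpFit", function(object) {
  if (object@tau <= 0) "tau must be > 0" else TRUE
})

#' DoubleExpFit: double-exponential recovery fit
#'
#' Fit of \eqn{y(t) = 1 - A_f e^{-t/\tau_f} - (1 - A_f) e^{-t/\tau_s}}.
#' When the two time constants are not separately identifiable the fit
#' collapses to a single exponential and \code{degenerate} is set.
#'
#' @slot tau_fast,tau_slow time constants (ms), \code{tau_fast <= tau_slow}.
#' @slot frac_fast fast fraction in [0, 1].
#' @slot residual_norm root-mean-square residual.
#' @slot degenerate logical degeneracy flag.
#' @export
setClass("DoubleExpFit",
  representation(tau_fast = "numeric", tau_slow = "numeric",
                 frac_fast = "numeric", residual_norm = "numeric",
                 degenerate = "logical"))

setValidity("DoubleExpFit", function(object) {
  msg <- character()
  if (object@tau_fast <= 0 || object@tau_slow < object@tau_fast)
    msg <- c(msg, "need 0 < tau_fast <= tau_slow")
  if (object@frac_fast < 0 || object@frac_fast > 1)
    msg <- c(msg, "frac_fast must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CellMetrics: all measured quantities for one cell
#'
#' @slot genotype,temperature condition labels.
#' @slot current_density_0mV pA/pF.
#' @slot gv_fit activation (conductance-voltage) \linkS4class{BoltzmannFit}.
#' @slot ssfi_fit steady-state fast inactivation \linkS4class{BoltzmannFit}.
#' @slot tau_onset_by_v named numeric, onset time constants (ms) by voltage.
#' @slot recovery_fit \linkS4class{DoubleExpFit}.
#' @slot persistent_pct_end,persistent_pct_25_30 persistent current as a
#'   percentage of peak (end-of-pulse window and 25-30 ms window).
#' @export
setClass("CellMetrics",
  representation(
    genotype = "character",
    temperature = "numeric",
    current_density_0mV = "numeric",
    gv_fit = "BoltzmannFit",
    ssfi_fit = "BoltzmannFit",
    tau_onset_by_v = "numeric",
    recovery_fit = "DoubleExpFit",
    persistent_pct_end = "numeric",
    persistent_pct_25_30 = "numeric"
  )
)

setValidity("CellMetrics", function(object) {
  p <- c(object@persistent_pct_end, object@persistent_pct_25_30)
  if (any(p < 0 | p > 100)) "persistent percentages must lie in [0, 100]"
  else TRUE
})

#' AnovaResult: genotype x temperature ANOVA summary
#'
#' @slot effects data.frame with columns \code{effect}, \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{significant}.
#' @slot alpha significance level (0.05).
#' @slot stepdown_applied TRUE when the interaction was not significant and
#'   main effects were re-evaluated under the additive model.
#' @slot response name of the analyzed response.
#' @export
setClass("AnovaResult",
  representation(effects = "data.frame", alpha = "numeric",
                 stepdown_applied = "logical", response = "character"))

setValidity("AnovaResult", function(object) {
  msg <- character()
  need <- c("effect", "F", "df1", "df2", "p", "significant")
  if (!all(need %in% names(object@effects)))
    msg <- c(msg, "effects table missing required columns")
  p <- object@effects$p
  if (any(is.finite(p) & (p < 0 | p > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' VariantSpec: sodium-current modifiers for a channel variant
#'
#' Captures how a variant perturbs the model sodium currents: a multiplier on
#' the rate of fast-inactivation onset and the persistent-current conductance
#' fraction, each independently switchable so that separate-effect models
#' (inactivation-only, persistent-only) can be built.
#'
#' @slot label variant label.
#' @slot inact_rate_multiplier multiplier on the h-gate closing rate
#'   (1.0 for WT, 1.485 for L1624Q).
#' @slot persistent_fraction fraction used in the persistent-conductance
#'   formula (0.018 WT, 0.046 L1624Q).
#' @slot apply_inactivation_effect,apply_persistent_effect logical switches;
#'   with both FALSE the variant neuron is exactly the WT neuron.
#' @export
setClass("VariantSpec",
  representation(label = "character",
                 inact_rate_multiplier = "numeric",
                 persistent_fraction = "numeric",
                 apply_inactivation_effect = "logical",
                 apply_persistent_effect = "logical"))

setValidity("VariantSpec", function(object) {
  msg <- character()
  if (!is.finite(object@inact_rate_multiplier) ||
      object@inact_rate_multiplier <= 0)
    msg <- c(msg, "inact_rate_multiplier must be > 0")
  if (object@persistent_fraction < 0 || object@persistent_fraction >= 1)
    msg <- c(msg, "persistent_fraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' NeuronParams: single-compartment conductance-based neuron
#'
#' Parameters of the regular-spiking cortical pyramidal model: specific
#' membrane capacitance and compartment area (fixing the pA to uA/cm2
#' conversion), maximal conductances for transient Na, persistent Na,
#' delayed-rectifier K, slow non-inactivating K and leak, reversal
#' potentials, the kinetic threshold shift VT, the slow-K time-constant
#' ceiling, and the variant's inactivation-rate multiplier.
#'
#' @slot cm uF/cm2. @slot area cm2.
#' @slot g_na,g_nap,g_kd,g_km,g_leak mS/cm2.
#' @slot e_na,e_k,e_leak mV.
#' @slot vt kinetic shift (mV) of the Traub-type rate functions.
#' @slot tau_max slow-K time-constant ceiling (ms).
#' @slot h_rate_multiplier multiplier applied to the h-gate closing rate.
#' @slot nap_rate_factor factor on persistent-Na gate rates (default 1000).
#' @slot temperature degrees Celsius (informational; 37 throughout).
#' @slot label description of the parameterization.
#' @export
setClass("NeuronParams",
  representation(cm = "numeric", area = "numeric",
                 g_na = "numeric", g_nap = "numeric", g_kd = "numeric",
                 g_km = "numeric", g_leak = "numeric",
                 e_na = "numeric", e_k = "numeric", e_leak = "numeric",
                 vt = "numeric", tau_max = "numeric",
                 h_rate_multiplier = "numeric", nap_rate_factor = "numeric",
                 temperature = "numeric", label = "character"))

setValidity("NeuronParams", function(object) {
  msg <- character()
  g <- c(object@g_na, object@g_nap, object@g_kd, object@g_km, object@g_leak)
  if (any(!is.finite(g)) || any(g < 0))
    msg <- c(msg, "conductances must be finite and >= 0")
  if (!is.finite(object@cm) || object@cm <= 0 ||
      !is.finite(object@area) || object@area <= 0)
    msg <- c(msg, "cm and area must be finite and > 0")
  if (!(object@e_k <= object@e_leak && object@e_leak <= object@e_na))
    msg <- c(msg, "need E_K <= E_leak <= E_Na")
  if (!is.finite(object@h_rate_multiplier) || object@h_rate_multiplier <= 0)
    msg <- c(msg, "h_rate_multiplier must be > 0")
  if (length(msg)) msg else TRUE
})

#' StimulusProgram: a current-injection program
#'
#' @slot kind \code{"step"}, \code{"pulse_then_off"} or \code{"ramp"}.
#' @slot amplitude step/pulse amplitude (pA).
#' @slot ramp_from,ramp_to ramp endpoints (pA), \code{ramp_from < ramp_to}.
#' @slot duration stimulus duration (ms).
#' @slot ramp_shape \code{"exponential"} or \code{"linear"}.
#' @slot pre_amplitude,pre_duration optional pre-stimulus (pA, ms); 0 for
#'   none.
#' @export
setClass("StimulusProgram",
  representation(kind = "character", amplitude = "numeric",
                 ramp_from = "numeric", ramp_to = "numeric",
                 duration = "numeric", ramp_shape = "character",
                 pre_amplitude = "numeric", pre_duration = "numeric"))

setValidity("StimulusProgram", function(object) {
  msg <- character()
  if (!object@kind %in% c("step", "pulse_then_off", "ramp"))
    msg <- c(msg, "kind must be step, pulse_then_off or ramp")
  if (object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (identical(object@kind, "ramp")) {
    if (!(object@ramp_from < object@ramp_to))
      msg <- c(msg, "ramp_from must be < ramp_to")
    if (!object@ramp_shape %in% c("exponential", "linear"))
      msg <- c(msg, "ramp_shape must be exponential or linear")
    if (identical(object@ramp_shape, "exponential") && object@ramp_from <= 0)
      msg <- c(msg, "exponential ramp needs ramp_from > 0")
  }
  if (object@pre_duration < 0)
    msg <- c(msg, "pre_duration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimTrace: simulated membrane-potential time course plus derived metrics
#'
#' @slot time ms (recorded grid). @slot v_m mV. @slot stimulus pA.
#' @slot spike_times ms, strictly increasing (upward 0 mV crossings with a
#'   1 ms refractory).
#' @slot fired_after_offset logical (NA when not applicable).
#' @slot block_onset_current pA (NA when no depolarization block occurred).
#' @slot dt integration step (ms). @slot gating_range min/max over all
#'   gating variables during integration (invariant check: within [0, 1]).
#' @export
setClass("SimTrace",
  representation(time = "numeric", v_m = "numeric", stimulus = "numeric",
                 spike_times = "numeric", fired_after_offset = "logical",
                 block_onset_current = "numeric", dt = "numeric",
                 gating_range = "numeric"))

setValidity("SimTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@v_m) ||
      length(object@time) != length(object@stimulus))
    msg <- c(msg, "time, v_m and stimulus must have equal length")
  if (length(object@spike_times) > 1L && any(diff(object@spike_times) <= 0))
    msg <- c(msg, "spike_times must be strictly increasing")
  if (length(msg)) msg else TRUE
})
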