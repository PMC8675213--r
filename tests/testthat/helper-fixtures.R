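# Shared fixture builders: everything is generated in code at test time.

all_protocols <- c("activation", "ssfi", "recovery", "persistent")

# One noise-free simulated cell (all four protocols) for a condition.
make_cell <- function(genotype = "WT", temperature = 37, noise_sd = 0,
                      seed = 1L, capacitance = 20, ...) {
  ph <- defaultPhenotype(genotype, temperature, ...)
  lapply(setNames(all_protocols, all_protocols), function(p)
    simulateProtocol(ph, p, capacitance = capacitance, noise_sd = noise_sd,
                     seed = seed))
}

# A custom TraceSet built from an explicit current matrix (for degenerate
# input tests).
make_traceset <- function(time, current, sweep_v, protocol,
                          capacitance = 20, test_onset = 1) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(current = current),
    rowData = S4Vectors::DataFrame(time_ms = time),
    colData = S4Vectors::DataFrame(
      sweep_v = sweep_v, test_onset_ms = rep(test_onset, length(sweep_v))),
    metadata = list(capacitance_pF = capacitance, protocol = protocol,
                    phenotype_id = "synthetic", genotype = "custom",
                    temperature_C = 22, noise_sd = 0, seed = 1L))
  new("TraceSet", se)
}

# A bare NeuronParams for degenerate-model tests.
make_neuron <- function(g_na = 56, g_nap = 0.1, g_kd = 3, g_km = 0.005,
                        g_leak = 0.016, e_na = 50, e_k = -90,
                        e_leak = -70.3, h_mult = 1) {
  new("NeuronParams", cm = 1, area = 2e-5, g_na = g_na, g_nap = g_nap,
      g_kd = g_kd, g_km = g_km, g_leak = g_leak, e_na = e_na, e_k = e_k,
      e_leak = e_leak, vt = -56.2, tau_max = 608, h_rate_multiplier = h_mult,
      nap_rate_factor = 1000, temperature = 37, label = "custom")
}
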