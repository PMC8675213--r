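# navclamp

Biophysics of mixed gain- and loss-of-function NaV1.1 (SCN1A) variants,
built around the familial epilepsy variant L1624Q: synthetic whole-cell
voltage-clamp data with known ground truth, the full per-cell
electrophysiology metric/fit suite, genotype x temperature statistics, and
a conductance-based cortical neuron model that shows how the variant's
opposing channel defects reshape excitability.

## The problem

L1624Q increases the persistent (non-inactivating) sodium current
(gain of function) while speeding fast-inactivation onset 1.485-fold and
reducing peak current density at 37 degC (loss of function). Raw
patch-clamp recordings for such studies are rarely archived, so the
package ships a *generator*: phenomenological voltage-clamp sweeps whose
peak follows

I_pk(V) = -rho · C_m · [a_inf(V)/a_inf(0)] · (V - V_rev)/(0 - V_rev),

decaying after the peak with the tabulated tau_onset(V) toward
f_persistent · I_pk. Every quantity the analysis measures is therefore
under exact, independent control, and the analysis stage (Boltzmann fits
of conductance-voltage and steady-state fast inactivation, exponential
onset fits, double-exponential recovery, persistent fraction, current
density) is tested as a round trip against that ground truth. The neuron
module implements a regular-spiking cortical pyramidal model (transient
Na m^3h, delayed-rectifier K n^4, slow K, leak) plus a persistent Na
current - no inactivation gate, gate rates 1000x the fast-Na activation
rates, g_NaP = 0.10 · g_Na · f with f = 1.8% (WT) / 4.6% (L1624Q) - and
the variant's h-gate closing rate scaled by 1.485.

For whom: ion-channel electrophysiologists who want a tested reference
implementation of the standard voltage-clamp analyses, and computational
neuroscientists studying how persistent current and inactivation kinetics
control persistent firing and depolarization block.

## Worked example

```r
library(navclamp)

ph <- defaultPhenotype("L1624Q", 37)   # packaged condition ground truth
cell <- list(
  activation = simulateProtocol(ph, "activation"),
  ssfi       = simulateProtocol(ph, "ssfi"),
  recovery   = simulateProtocol(ph, "recovery"),
  persistent = simulateProtocol(ph, "persistent"))
analyzeCell(cell)
#> CellMetrics: L1624Q at 37 degC
#>   density 0 mV   : 45.42 pA/pF
#>   G-V            : V1/2 = -22.00 mV, k = 7.00 mV
#>   SSFI           : V1/2 = -56.00 mV, k = 6.00 mV
#>   persistent     : 4.58 % (end), 4.58 % (25-30 ms)
#>   recovery       : tau_f = 2.00 ms, tau_s = 50.00 ms
#>   tau onset (ms) : -30 mV: 0.783; -20 mV: 0.525; -10 mV: 0.352;
#>                    0 mV: 0.236; 10 mV: 0.158; 20 mV: 0.106
```

The measured density (45.42 pA/pF) and persistent fraction (4.58 %) are
the variant's 37 degC condition values, recovered exactly from the
noise-free sweeps; the onset constants are the WT table divided by 1.485.
On the simulation side:

```r
wt <- buildNeuron("WT"); lq <- buildNeuron("L1624Q")
rheobase(wt); rheobase(lq)
#> [1] 2.148438
#> [1] 0.78125
persistentFiringTest(lq)$fired_after_offset
#> [1] TRUE
```

The variant neuron fires at roughly one third the injected current and,
after a 10 pA x 50 ms pulse, keeps firing to the end of a 1 s simulation
(WT falls silent) - the bistability that the enlarged persistent current
creates. `rampBlockTest()` shows the flip side: the variant enters
depolarization block at roughly half the WT ramp current.

End-to-end runs (generate -> analyze -> stats -> simulate, with a
manifest for bit-identical re-runs) go through `runPipeline()` /
`defaultRunConfig()`, or the thin CLI at
`inst/scripts/run-pipeline.R`. The methods vignette
(`vignettes/navclamp-methods.Rmd`) documents the model, defaults and
calibration choices.

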