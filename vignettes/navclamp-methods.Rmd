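---
title: "Methods: synthetic voltage clamp, channel metrics, and the variant neuron model"
author: "navclamp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic voltage clamp, channel metrics, and the variant neuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

# The scientific problem

The SCN1A gene encodes NaV1.1, the neuronal voltage-gated sodium channel
alpha subunit whose variants cause a broad spectrum of epilepsies. The
L1624Q substitution, on the DIV S3-S4 extracellular linker, is a familial
variant with a *mixed* functional phenotype: it increases the persistent
(non-inactivating) sodium current (gain of function) while speeding fast
inactivation onset and lowering peak current density at physiological
temperature (loss of function). `navclamp` packages the computational side
of characterizing such a variant:

1. a **synthetic voltage-clamp generator** that emits whole-cell sweep sets
   with known ground truth under the four standard protocols;
2. an **analysis suite** that measures everything a patch-clamp study
   reports per cell (peaks, conductance-voltage and availability Boltzmann
   fits, onset time constants, recovery kinetics, persistent fraction,
   current density);
3. the **statistical plan** (genotype x temperature interaction ANOVA with
   additive stepdown, per-voltage contrasts on log-transformed time
   constants);
4. a **single-compartment cortical neuron model** expressing WT or variant
   sodium currents, with excitability metrics (rheobase, firing-rate
   curves, persistent firing after stimulus offset, depolarization block
   under ramps).

# The synthetic-data generator

## Model

The generator is deliberately *phenomenological*, not mechanistic. Each
sweep is built as peak amplitude x stylized time course:

$$I_{pk}(V) = -\rho\, C_m\,\frac{a_\infty(V)}{a_\infty(0)}\cdot
  \frac{V - V_{rev}}{0 - V_{rev}},$$

where $\rho$ is the current density magnitude at 0 mV (pA/pF), $C_m$ the
cell capacitance and $a_\infty$ the activation Boltzmann
$1/(1+e^{(V_{1/2}-V)/k})$. The normalization makes the 0 mV peak equal
$-\rho C_m$ *exactly*, so current density is under direct control. After a
0.1 ms exponential rise that tops out exactly 0.3 ms after pulse onset
(the analysis never uses the rising phase; the 0.05 ms immediately after
pulse onset is additionally blanked during peak detection, standing in for
the capacitive transient), the current decays single-exponentially with the
tabulated onset constant $\tau(V)$ toward $f_{persistent} I_{pk}$. SSFI
sweeps scale the test-pulse peak by the availability Boltzmann of the
prepulse voltage; recovery sweeps scale it by
$1 - A_f e^{-t/\tau_f} - (1-A_f) e^{-t/\tau_s}$. Optional i.i.d. Gaussian
noise is added per sample; amplifier filtering and series-resistance or
leak-subtraction artifacts are out of scope.

This construction gives exact, independent control of every measured
quantity, which is the right contract for testing the analysis stage: a
noise-free round trip must return the generating parameters to numerical
precision, and it does (tested to 1e-3 relative, typically far better). A
mechanistic Hodgkin-Huxley model lives in the neuron module instead.

## Study conditions and defaults

The packaged phenotypes (`defaultPhenotype()`) install the published
condition values:

| quantity | WT 22C | L1624Q 22C | WT 37C | L1624Q 37C |
|---|---|---|---|---|
| persistent current (% of peak) | 0.95 | 3.20 | 2.27 | 4.58 |
| current density (pA/pF) | 60 | 60 | 72.82 | 45.42 |
| onset tau at 0 mV (ms) | 0.80 | 0.80 | 0.35 | 0.35/1.485 |

At 22 degC densities did not differ between genotypes and no value was
published, so a representative 60 pA/pF is used for both; likewise onset
kinetics differ only at 37 degC, where the variant is 1.485-fold faster at
every voltage. Quantities the study reports only as figures (Boltzmann
midpoints and slopes, absolute recovery constants) carry documented
representative NaV1.1 values: $V_{1/2,act} = -22$ mV, $k_{act} = 7$ mV,
$V_{rev} = +65$ mV, $V_{1/2,inact} = -60$ mV, $k_{inact} = 6$ mV,
recovery $\tau_f = 2$ ms, $\tau_s = 50$ ms, $A_f = 0.9$. These are
explicitly *not* study-anchored; tests only assert their recovery, never
their values. The steady-state fast inactivation midpoint is right-shifted
+4 mV at 37 degC for both genotypes, encoding the reported qualitative
temperature effect; the magnitude is a free choice since none was
published. The onset-tau table uses an e-fold/25 mV voltage dependence
(typical NaV1.1 shape), tabulated on the -30..+20 mV grid and extended by
its endpoints outside it.

The four protocol presets mirror the recordings: activation 10 ms steps to
-100..+70 mV from -130 mV; SSFI 200 ms prepulses to -130..+10 mV with a
19 ms, 0 mV test pulse; recovery via a 200 ms, 0 mV conditioning pulse and
a -90 mV interval of 0.5-200 ms; persistent current in a 50 ms pulse from
-130 to 0 mV. Sampling is 0.02 ms (50 kHz), typical for 10 ms activation
pulses.

Cohorts (`generateCohort()`) draw per-cell capacitance and multiplicative
density/tau/persistent-fraction factors from a log-normal law with mean
exactly 1 and the stated fractional SD (default 0.2, a typical
cell-to-cell scatter for transfected CHO cells; a single kinetic factor
scales a cell's whole tau table, so per-voltage values within a cell are
perfectly correlated). Everything is fixed by one seed.

## What passing tests do and do not show

The generator emulates the *structure* of the recordings, not their
artifacts: no seal or access resistance, no rundown, no filtering, no
capacitive transients beyond the stylized rise. Tests passing on synthetic
cohorts therefore demonstrate that the analysis is correct and calibrated
*given data of this form*; they cannot certify behavior on pathological
real recordings, which is why the published experimental p-values and
figure-only quantities are covered by recovery properties rather than
numeric targets.

# The analysis suite

Peaks are signed extrema after mean pre-pulse baseline subtraction.
Conductance is $G(V) = I_{pk}(V)/(V - V_{rev})$ normalized to its maximum,
with $V_{rev}$ estimated from the zero crossing of the peak I-V by linear
interpolation (the "observed" reversal potential) unless supplied.
"End of the 50 ms pulse" is operationalized as the mean over the final
2 ms, with the 25-30 ms window recomputed as a stability check that warns
at >20% relative disagreement. SSFI normalization uses the per-cell
maximum (the fitted-asymptote alternative is not used). Onset time
constants are reported per cell on the -30..+20 mV grid and averaged
across cells downstream, not pooled before fitting.

All fits are deterministic. Starting values follow fixed rules -
Boltzmann $V_{1/2,0}$ at the half-maximum crossing by linear
interpolation with $k_0 = 7$ mV; exponential $\tau_0$ from the log-linear
slope of the first decade of decay - and Levenberg-Marquardt runs
unconstrained on transformed parameters (log tau, logit fraction), which
enforces positivity and [0,1] constraints without bound projections. The
double-exponential recovery fit falls back to a flagged single
exponential when the two time constants collapse within 5% of each other
or the fast fraction reaches a boundary.

# The statistical plan

`interactionAnova()` fits `response ~ genotype * temperature` and tests
the interaction (differential temperature sensitivity). When the
interaction is not significant at alpha = 0.05 the model is refit
additively and main effects are evaluated independently; Type-II sums of
squares are used, which matters only for the unbalanced 37 degC cohorts.
A zero-residual-variance design (possible with synthetic data) reports
F = 0, p = 1 for zero-sum-of-squares effects rather than failing.
`perVoltageTests()` runs Welch two-sample t-tests on log10(tau) per
voltage - a conservative reading of the unstated per-voltage machinery -
with no multiplicity correction across voltages, mirroring the original
analysis. Time constants are log-transformed before analysis; calibration
of the interaction test (type-I error within [0.035, 0.065] over 1,000
null simulations at n = 8 per cell) and per-voltage power under the
packaged 1.485-fold effect are part of the acceptance suite.

# The neuron model

## Structure

A single-compartment, conductance-based regular-spiking cortical pyramidal
neuron in the Traub lineage with a threshold shift $V_T = -56.2$ mV:
transient Na ($m^3 h$), delayed-rectifier K ($n^4$), a slow
non-inactivating K current (M-type gate, $\tau_{max} = 608$ ms), and leak.
Because the base parameterization carries no persistent sodium current, a
non-inactivating component of the fast sodium current is added: no
inactivation gate, activation/deactivation rates 1,000x the fast-Na
activation rates (so the gate tracks voltage quasi-instantaneously), and
maximal conductance

$$g_{NaP} = 0.10 \times g_{Na} \times f,$$

with $f = 1.8\%$ for WT and $4.6\%$ for L1624Q. The persistent gate enters
with first power: the gate-exponent is not specified by the conductance
recipe, a single activation gate is the standard persistent-current
formulation, and it is what gives the persistent current its sub-threshold
presence (an $m^3$ gate renders it dynamically negligible below spike
threshold). An alternative reading of the recipe - conductance chosen so
the persistent current at a 0 mV test pulse equals the stated fraction of
the fast peak - is available via `baseNeuronConfig(nap_mode = "matched")`;
neither reading is asserted as the original intent.

The variant's kinetic effect multiplies the h-gate *closing* rate
$\beta_h$ by 1.485. Onset of fast inactivation at depolarized potentials
is governed by $\beta_h$, and leaving $\alpha_h$ untouched keeps recovery
from inactivation unchanged, matching the experimental finding that
recovery did not differ between genotypes. Both effects are independently
switchable (`variantSpec()`), so the separate-effects models
(persistent-only, inactivation-only) are first-class; with both switches
off the "variant" neuron is the WT neuron exactly.

## Calibration

Base constants that the lineage models do not fix were calibrated once,
against stated tuning targets, and live in `baseNeuronConfig()`:

* compartment area $2\times10^{-5}$ cm$^2$ (a ~25 um soma), placing the WT
  rheobase for a 1 s step at ~2.1 pA, inside the 1-5 pA target range;
* $g_{Na} = 56$, $g_{Kd} = 3$, $g_{Ks} = 0.005$, $g_{leak} = 0.016$
  mS/cm$^2$; $E_{Na} = +50$, $E_K = -90$, $E_{leak} = -70.3$ mV.

The potassium and leak conductances were chosen so the model expresses the
variant phenomenology: both genotypes rest silently at ~-70 mV, yet the
L1624Q persistent current sustains a stable spiking limit cycle that
coexists with rest (bistability), so a 10 pA x 50 ms pulse leaves the
variant firing for the remainder of a 1 s simulation while WT falls
silent. With the heavier delayed-rectifier AHP of the unmodified base
model the post-spike trajectory dives below the persistent current's
basin and persistent firing cannot occur for any genotype. The resulting
model reproduces, without further adjustment: a ~25% reduction of the
L1624Q test-pulse sodium peak (0 mV from -120 mV), lower L1624Q rheobase,
L1624Q firing at least as fast as WT at matched sub-block amplitudes,
earlier L1624Q depolarization block under ramps from rest and after a
pre-stimulus, persistent firing carried by the persistent-current effect
alone, and earlier block carried in part by the inactivation effect alone.

## Numerics

Integration is fixed-step: forward Euler for the membrane potential and
exponential Euler for every gate (exact for frozen voltage), which keeps
the 1,000x-fast persistent-Na gate stable at dt = 0.005 ms (the default;
dt <= 0.01 ms is enforced). The model settles for 200 ms at zero input
before the stimulus so every run starts from rest. Spikes are upward 0 mV
crossings with a 1 ms refractory; depolarization block is a spike-free
terminal period of at least 100 ms with the membrane sustained above
-30 mV, and the block onset is the injected current at the last spike
before it. The current ramp is exponential in amplitude (0.002 to 400 pA
over 10 s by default): a "slowly increasing" sweep over five decades of
amplitude implies constant fractional growth; a linear shape is available.
Halving dt leaves spike counts unchanged and moves first-spike latencies
by well under 0.1 ms; later spike times drift in phase by ~0.25 ms per
inter-spike interval, the expected first-order behavior of fixed-step
explicit integration, which is why convergence is asserted on counts and
latency rather than on late-spike phase. Numerical blow-up (membrane
outside $[E_K - 40, E_{Na} + 40]$ mV) raises an integration-failure error
naming the time of failure. Voltage-bound checks, gating-range tracking
(all gates in [0,1]) and bit-identical determinism are tested.

# Problem sizes

The shipped test and acceptance runs use the sizes at which the methods
are exercised end-to-end: cohorts of 2-28 cells (1,000 for the
law-of-large-numbers check on the cell-scatter law), 1,000 null
simulations for ANOVA calibration at n = 8 per cell, firing-rate grids of
~10-40 amplitudes, and 10 s ramps for block detection. These are the
package's chosen study sizes; all are configurable.

# Known limitations

* The generator's noise is white and Gaussian; real recordings have
  colored noise, capacitive transients and leak.
* The neuron model is single-compartment, synapse-free and 37 degC only;
  no Q10 machinery is included.
* The persistent-gate exponent and the exact base-model constants of the
  cited lineage are choices documented above, not published values;
  simulation claims are therefore qualitative orderings plus the ~25%
  peak-reduction anchor.
* Published experimental p-values are not reproducible (raw data
  unavailable) and are deliberately not targets.

# A minimal session

```{r example, eval = FALSE}
ph <- defaultPhenotype("L1624Q", 37)
cell <- list(
  activation = simulateProtocol(ph, "activation"),
  ssfi       = simulateProtocol(ph, "ssfi"),
  recovery   = simulateProtocol(ph, "recovery"),
  persistent = simulateProtocol(ph, "persistent"))
analyzeCell(cell)

lq <- buildNeuron("L1624Q")
persistentFiringTest(lq)$fired_after_offset
rampBlockTest(lq)$block_onset_pA
```
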