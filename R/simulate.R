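# Phenomenological sweep construction: every sweep is peak x (stylized rise,
# then single-exponential decay toward the persistent level), so each measured
# quantity is under exact, independent control of the phenotype. The rise is a
# 0.1 ms exponential ramp reaching the peak exactly 0.3 ms after pulse onset;
# the analysis never uses the rising phase.
.BASELINE_MS <- 1
.T_PEAK_MS <- 0.3
.TAU_RISE_MS <- 0.1

.pulseShape <- function(t_rel, tau_on, f) {
  s <- numeric(length(t_rel))
  rise <- t_rel >= 0 & t_rel <= .T_PEAK_MS
  dec <- t_rel > .T_PEAK_MS
  s[rise] <- (1 - exp(-t_rel[rise] / .TAU_RISE_MS)) /
    (1 - exp(-.T_PEAK_MS / .TAU_RISE_MS))
  s[dec] <- f + (1 - f) * exp(-(t_rel[dec] - .T_PEAK_MS) / tau_on)
  s
}

# Peak current (pA, inward negative) at step voltage v. Normalized so the
# 0 mV peak equals -density*C exactly: I(v) = -d*C * a(v)/a(0) * (v-Vr)/(0-Vr).
.peakCurrent <- function(phenotype, v, capacitance) {
  a <- activationBoltzmann(phenotype, v) / activationBoltzmann(phenotype, 0)
  -phenotype@density_at_0mV * capacitance * a *
    (v - phenotype@v_rev) / (0 - phenotype@v_rev)
}

.recoveryFraction <- function(phenotype, t) {
  1 - phenotype@rec_frac_fast * exp(-t / phenotype@rec_tau_fast) -
    (1 - phenotype@rec_frac_fast) * exp(-t / phenotype@rec_tau_slow)
}

#' Generate a voltage-clamp sweep set for one cell
#'
#' Produces a \linkS4class{TraceSet} of whole-cell sodium-current sweeps under
#' one of the four protocols, from a generative phenotype. The model is
#' phenomenological: each sweep's peak amplitude follows
#' \eqn{I_{pk}(V) = -\rho\,C_m\,[a_\infty(V)/a_\infty(0)]\,(V - V_{rev})/(0 - V_{rev})}
#' (so the 0 mV peak equals density x capacitance exactly, inward negative);
#' after the peak the current decays single-exponentially with the tabulated
#' \eqn{\tau_{onset}(V)} toward \eqn{f_{persistent} I_{pk}}. SSFI sweeps scale
#' the test-pulse peak by the availability Boltzmann of the prepulse voltage;
#' recovery sweeps scale the test pulse by the double-exponential recovered
#' fraction. With \code{noise_sd = 0} the output is bit-reproducible.
#'
#' @param phenotype a \linkS4class{ChannelPhenotype}.
#' @param protocol a \linkS4class{VClampProtocol} or preset name for
#'   \code{\link{vclampProtocol}}.
#' @param capacitance whole-cell capacitance (pF), > 0.
#' @param noise_sd per-sample i.i.d. Gaussian noise SD (pA), >= 0.
#' @param seed integer RNG seed used when \code{noise_sd > 0}.
#' @return a \linkS4class{TraceSet}.
#' @export
#' @examples
#' ts <- simulateProtocol(defaultPhenotype("WT", 37), "persistent")
#' persistentFraction(ts)
simulateProtocol <- function(phenotype, protocol = "activation",
                             capacitance = 20, noise_sd = 0, seed = 1L) {
  stopifnot(is(phenotype, "ChannelPhenotype"))
  if (is.character(protocol)) protocol <- vclampProtocol(protocol)
  validObject(protocol)
  if (!is.finite(capacitance) || capacitance <= 0)
    stop("validation error: capacitance must be > 0", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("validation error: noise_sd must be >= 0", call. = FALSE)
  volts <- c(protocol@step_voltages, protocol@test_pulse_v)
  volts <- volts[is.finite(volts)]
  if (any(volts < -130 | volts > 70))
    stop("validation error: protocol voltages must lie within [-130, 70] mV",
         call. = FALSE)

  dt <- protocol@sample_interval
  f <- phenotype@f_persistent
  kind <- protocol@kind

  if (kind %in% c("activation", "persistent")) {
    total <- .BASELINE_MS + protocol@step_duration
    time <- seq(0, total, by = dt)
    vs <- protocol@step_voltages
    cur <- vapply(vs, function(v) {
      .peakCurrent(phenotype, v, capacitance) *
        .pulseShape(time - .BASELINE_MS, tauOnsetAt(phenotype, v), f)
    }, numeric(length(time)))
    cd <- DataFrame(sweep_v = vs, test_onset_ms = rep(.BASELINE_MS,
                                                      length(vs)))
  } else if (kind == "ssfi") {
    total <- .BASELINE_MS + protocol@test_pulse_duration
    time <- seq(0, total, by = dt)
    vtest <- protocol@test_pulse_v
    ipk0 <- .peakCurrent(phenotype, vtest, capacitance)
    tau0 <- tauOnsetAt(phenotype, vtest)
    cur <- vapply(protocol@step_voltages, function(vpre) {
      ipk0 * inactivationBoltzmann(phenotype, vpre) *
        .pulseShape(time - .BASELINE_MS, tau0, f)
    }, numeric(length(time)))
    cd <- DataFrame(sweep_v = protocol@step_voltages,
                    test_onset_ms = rep(.BASELINE_MS,
                                        length(protocol@step_voltages)))
  } else { # recovery
    tr <- protocol@recovery_times
    total <- .BASELINE_MS + protocol@step_duration + max(tr) +
      protocol@test_pulse_duration
    time <- seq(0, total, by = dt)
    vcond <- protocol@step_voltages[1L]
    ipk <- .peakCurrent(phenotype, vcond, capacitance)
    tau0 <- tauOnsetAt(phenotype, vcond)
    cond_off <- .BASELINE_MS + protocol@step_duration
    cond <- ipk * .pulseShape(time - .BASELINE_MS, tau0, f)
    cond[time > cond_off] <- 0
    test_onset <- cond_off + tr
    cur <- vapply(seq_along(tr), function(i) {
      on <- test_onset[i]
      test <- ipk * .recoveryFraction(phenotype, tr[i]) *
        .pulseShape(time - on, tau0, f)
      test[time > on + protocol@test_pulse_duration] <- 0
      cond + test
    }, numeric(length(time)))
    cd <- DataFrame(recovery_ms = tr, test_onset_ms = test_onset,
                    cond_onset_ms = rep(.BASELINE_MS, length(tr)))
  }

  if (noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    cur <- cur + matrix(rnorm(length(cur), 0, noise_sd), nrow = nrow(cur))
  }

  colnames(cur) <- sprintf("sweep_%02d", seq_len(ncol(cur)))
  se <- SummarizedExperiment(
    assays = list(current = cur),
    rowData = DataFrame(time_ms = time),
    colData = cd,
    metadata = list(capacitance_pF = capacitance, protocol = protocol,
                    phenotype_id = paste0(phenotype@genotype, "_",
                                          phenotype@temperature, "C"),
                    genotype = phenotype@genotype,
                    temperature_C = phenotype@temperature,
                    noise_sd = noise_sd, seed = as.integer(seed))
  )
  new("TraceSet", se)
}

#' Generate a cohort of simulated cells
#'
#' Draws \code{n_cells} cells from a phenotype: each cell gets a capacitance
#' and multiplicative perturbations of density, onset time constants and
#' persistent fraction from a log-normal law with mean 1 and the stated
#' fractional SD, then its sweep sets are generated for the requested
#' protocols. The seed fixes the whole cohort (cell draws and per-cell noise).
#'
#' @param phenotype a \linkS4class{ChannelPhenotype} (cohort ground truth).
#' @param n_cells number of cells, >= 1.
#' @param cell_variability fractional SD of the log-normal cell perturbation,
#'   >= 0 (0 gives identical cells).
#' @param protocols character vector of protocol presets, or a named list of
#'   \linkS4class{VClampProtocol} objects.
#' @param capacitance mean whole-cell capacitance (pF).
#' @param noise_sd per-sample recording noise SD (pA).
#' @param seed integer seed for the full cohort.
#' @return a list of cells; each cell is a list with elements
#'   \code{phenotype} (the perturbed \linkS4class{ChannelPhenotype}),
#'   \code{capacitance} and \code{traces} (named list of
#'   \linkS4class{TraceSet}s).
#' @export
#' @examples
#' coh <- generateCohort(defaultPhenotype("WT", 37), n_cells = 3,
#'   cell_variability = 0.2, protocols = "persistent", seed = 7)
#' sapply(coh, function(cell) cell$phenotype@density_at_0mV)
generateCohort <- function(phenotype, n_cells, cell_variability = 0.2,
                           protocols = c("activation", "ssfi", "recovery",
                                         "persistent"),
                           capacitance = 20, noise_sd = 0, seed = 1L) {
  stopifnot(is(phenotype, "ChannelPhenotype"))
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("validation error: n_cells must be >= 1", call. = FALSE)
  if (!is.finite(cell_variability) || cell_variability < 0)
    stop("validation error: cell_variability must be >= 0", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (is.character(protocols))
    protocols <- setNames(lapply(protocols, vclampProtocol), protocols)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  fac <- .lnormFactors(n_cells * 4L, cell_variability)
  fac <- matrix(fac, ncol = 4L,
                dimnames = list(NULL, c("density", "tau", "f", "cap")))
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)

  lapply(seq_len(n_cells), function(i) {
    ph <- phenotype
    ph@density_at_0mV <- phenotype@density_at_0mV * fac[i, "density"]
    ph@tau_onset_table <- phenotype@tau_onset_table * fac[i, "tau"]
    ph@f_persistent <- min(phenotype@f_persistent * fac[i, "f"], 0.99)
    cap <- capacitance * fac[i, "cap"]
    traces <- lapply(protocols, function(p)
      simulateProtocol(ph, p, capacitance = cap, noise_sd = noise_sd,
                       seed = cell_seeds[i]))
    list(phenotype = ph, capacitance = cap, traces = traces)
  })
}

# Log-normal multiplicative factors with mean exactly 1 and fractional SD cv.
.lnormFactors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' @rdname accessors
setMethod("capacitance", "TraceSet",
          function(x) metadata(x)$capacitance_pF)

#' @rdname accessors
setMethod("protocolOf", "TraceSet", function(x) metadata(x)$protocol)

#' @rdname accessors
setMethod("traceTime", "TraceSet", function(x) rowData(x)$time_ms)

#' @rdname accessors
setMethod("sweepConditions", "TraceSet", function(x) {
  cd <- colData(x)
  if ("sweep_v" %in% colnames(cd)) cd$sweep_v else cd$recovery_ms
})

#' @rdname accessors
setMethod("currentMatrix", "TraceSet",
          function(x) assay(x, "current"))

#' @rdname accessors
setMethod("genotypeOf", "TraceSet", function(x) metadata(x)$genotype)

#' @rdname accessors
setMethod("temperatureOf", "TraceSet", function(x) metadata(x)$temperature_C)

setMethod("show", "TraceSet", function(object) {
  md <- metadata(object)
  cat(sprintf("TraceSet: %s protocol, %d sweeps x %d samples\n",
              md$protocol@kind, ncol(object), nrow(object)))
  cat(sprintf("  %s at %s degC; Cm = %.1f pF; noise SD = %g pA; seed = %d\n",
              md$genotype, md$temperature_C, md$capacitance_pF,
              md$noise_sd, md$seed))
})
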