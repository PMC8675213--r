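# Per-cell measurements: every quantity the voltage-clamp analysis reports
# is computed here from a TraceSet. Peak detection is the signed extremum
# after baseline subtraction, with the first 0.05 ms of each pulse excluded
# (the stylized capacitive-transient region).
.PEAK_BLANK_MS <- 0.05

.sweepPeak <- function(time, cur, onset, dur) {
  if (!length(cur) || all(!is.finite(cur)))
    stop("validation error: empty or non-finite sweep", call. = FALSE)
  base <- mean(cur[time < onset])
  if (!is.finite(base)) base <- 0
  win <- time >= onset + .PEAK_BLANK_MS & time <= onset + dur
  w <- cur[win] - base
  w[which.max(abs(w))]
}

#' Measure per-sweep peak currents of an activation protocol
#'
#' For every sweep, subtracts the mean pre-pulse baseline and returns the
#' signed extremum of the current within the depolarizing step (inward
#' currents are negative), excluding the first 0.05 ms of the step.
#'
#' @param traces an activation-protocol \linkS4class{TraceSet}.
#' @return named numeric vector, peak current (pA) by step voltage (mV).
#' @export
#' @examples
#' ts <- simulateProtocol(defaultPhenotype("WT", 37), "activation")
#' measurePeaks(ts)[["0"]]
measurePeaks <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  p <- protocolOf(traces)
  if (p@kind != "activation")
    stop("protocol-mismatch error: measurePeaks needs an activation TraceSet",
         call. = FALSE)
  time <- traceTime(traces)
  cur <- currentMatrix(traces)
  cd <- colData(traces)
  peaks <- vapply(seq_len(ncol(cur)), function(j)
    .sweepPeak(time, cur[, j], cd$test_onset_ms[j], p@step_duration),
    numeric(1))
  setNames(peaks, cd$sweep_v)
}

#' Normalized conductance-voltage curve from peak currents
#'
#' \eqn{G(V) = I_{pk}(V) / (V - V_{rev})}, normalized to its maximum. When
#' \code{v_rev} is not supplied it is estimated as the zero crossing of the
#' peak current-voltage relation by linear interpolation (the "observed"
#' reversal potential). Voltages within 1 mV of the reversal potential are
#' excluded from the curve.
#'
#' @param peaks named numeric vector from \code{\link{measurePeaks}}.
#' @param v_rev reversal potential (mV); estimated when NULL.
#' @return named numeric vector, normalized conductance by voltage.
#' @export
conductanceCurve <- function(peaks, v_rev = NULL) {
  v <- as.numeric(names(peaks))
  i <- as.numeric(peaks)
  if (length(v) < 4L)
    stop("fit-insufficiency error: need >= 4 voltages", call. = FALSE)
  if (all(abs(i) < 1e-12))
    stop("degenerate input: all peak currents are zero", call. = FALSE)
  if (is.null(v_rev)) {
    # zero crossing of the I-V by linear interpolation between the last
    # inward and first outward voltage
    s <- sign(i)
    idx <- which(s[-length(s)] < 0 & s[-1L] >= 0)
    if (!length(idx))
      stop("cannot estimate reversal potential: no zero crossing in the I-V",
           call. = FALSE)
    j <- idx[length(idx)]
    v_rev <- v[j] + (0 - i[j]) * (v[j + 1L] - v[j]) / (i[j + 1L] - i[j])
  }
  keep <- abs(v - v_rev) > 1
  g <- i[keep] / (v[keep] - v_rev)
  gmax <- max(g)
  if (gmax <= 0)
    stop("degenerate input: non-positive conductances", call. = FALSE)
  setNames(g / gmax, v[keep])
}

#' Current density at 0 mV
#'
#' Magnitude of the 0 mV peak current divided by the whole-cell capacitance.
#'
#' @param traces an activation-protocol \linkS4class{TraceSet} containing a
#'   0 mV sweep.
#' @return current density (pA/pF).
#' @export
#' @examples
#' currentDensity(simulateProtocol(defaultPhenotype("WT", 37), "activation"))
currentDensity <- function(traces) {
  peaks <- measurePeaks(traces)
  v <- as.numeric(names(peaks))
  at0 <- which(abs(v) < 1e-9)
  if (!length(at0))
    stop("protocol-mismatch error: activation protocol has no 0 mV sweep",
         call. = FALSE)
  unname(abs(peaks[at0[1L]])) / capacitance(traces)
}

#' Fast-inactivation onset time constants
#'
#' Fits a single exponential with offset to the decay of each activation
#' sweep on the reporting grid (-30..+20 mV by default), from the current
#' peak to the end of the step. Sweeps whose decay cannot be fit
#' (non-decaying traces) are flagged with NA and a warning, and are excluded
#' downstream. Downstream statistics consume these values log10-transformed.
#'
#' @param traces an activation-protocol \linkS4class{TraceSet}.
#' @param voltages voltages (mV) at which to fit; must be step voltages.
#' @return named list of \linkS4class{ExpFit} (NA where the fit failed).
#' @export
fitOnsetTau <- function(traces, voltages = seq(-30, 20, by = 10)) {
  stopifnot(is(traces, "TraceSet"))
  p <- protocolOf(traces)
  if (p@kind != "activation")
    stop("protocol-mismatch error: fitOnsetTau needs an activation TraceSet",
         call. = FALSE)
  time <- traceTime(traces)
  cur <- currentMatrix(traces)
  cd <- colData(traces)
  out <- lapply(voltages, function(v) {
    j <- which(abs(cd$sweep_v - v) < 1e-9)
    if (!length(j))
      stop("protocol-mismatch error: no sweep at ", v, " mV", call. = FALSE)
    j <- j[1L]
    onset <- cd$test_onset_ms[j]
    base <- mean(cur[time < onset, j])
    win <- time >= onset + .PEAK_BLANK_MS & time <= onset + p@step_duration
    y <- cur[win, j] - base
    tt <- time[win]
    pk <- which.max(abs(y))
    tryCatch(fitExpDecay(tt[pk:length(tt)], y[pk:length(y)]),
             fitError = function(e) {
               warning("onset fit failed at ", v, " mV: ",
                       conditionMessage(e), call. = FALSE)
               NA
             })
  })
  setNames(out, voltages)
}

#' @describeIn fitOnsetTau extract the tau values (ms) as a named vector,
#'   NA where the fit failed.
#' @param fits result of \code{fitOnsetTau}.
#' @export
onsetTauValues <- function(fits) {
  vapply(fits, function(f) if (is(f, "ExpFit")) f@tau else NA_real_,
         numeric(1))
}

#' Steady-state fast inactivation curve
#'
#' Measures the test-pulse peak of every SSFI sweep, normalizes to the
#' per-cell maximum, and fits a descending Boltzmann against prepulse
#' voltage.
#'
#' @param traces an ssfi-protocol \linkS4class{TraceSet}.
#' @return a \linkS4class{BoltzmannFit} with an \code{availability}
#'   attribute holding the normalized points.
#' @export
ssfiCurve <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  p <- protocolOf(traces)
  if (p@kind != "ssfi")
    stop("protocol-mismatch error: ssfiCurve needs an ssfi TraceSet",
         call. = FALSE)
  time <- traceTime(traces)
  cur <- currentMatrix(traces)
  cd <- colData(traces)
  peaks <- vapply(seq_len(ncol(cur)), function(j)
    .sweepPeak(time, cur[, j], cd$test_onset_ms[j], p@test_pulse_duration),
    numeric(1))
  avail <- abs(peaks) / max(abs(peaks))
  fit <- fitBoltzmann(cd$sweep_v, avail, direction = "descending")
  attr(fit, "availability") <- setNames(avail, cd$sweep_v)
  fit
}

#' Recovery from fast inactivation
#'
#' For each recovery sweep, measures the conditioning-pulse peak and the
#' test-pulse peak, forms the recovered fraction, and fits the
#' double-exponential recovery curve (\code{\link{fitDoubleExp}}; falls back
#' to a flagged single exponential on degeneracy).
#'
#' @param traces a recovery-protocol \linkS4class{TraceSet} with >= 8
#'   recovery times.
#' @return a \linkS4class{DoubleExpFit} with a \code{fraction} attribute
#'   holding the recovered fractions by recovery time.
#' @export
recoveryCurve <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  p <- protocolOf(traces)
  if (p@kind != "recovery")
    stop("protocol-mismatch error: recoveryCurve needs a recovery TraceSet",
         call. = FALSE)
  if (length(p@recovery_times) < 8L)
    stop("fit-insufficiency error: need >= 8 recovery times", call. = FALSE)
  time <- traceTime(traces)
  cur <- currentMatrix(traces)
  cd <- colData(traces)
  frac <- vapply(seq_len(ncol(cur)), function(j) {
    cond <- .sweepPeak(time, cur[, j], cd$cond_onset_ms[j], p@step_duration)
    y <- cur[, j]
    on <- cd$test_onset_ms[j]
    win <- time >= on + .PEAK_BLANK_MS & time <= on + p@test_pulse_duration
    w <- y[win]
    test <- w[which.max(abs(w))]
    test / cond
  }, numeric(1))
  fit <- fitDoubleExp(cd$recovery_ms, frac)
  attr(fit, "fraction") <- setNames(frac, cd$recovery_ms)
  fit
}

#' Persistent (non-inactivating) current fraction
#'
#' Divides the current amplitude at the end of the 50 ms depolarizing pulse
#' (operationalized as the mean over the final 2 ms) by the peak current, in
#' percent; also reports the same ratio over the 25-30 ms window as a
#' stability check, warning when the two differ by more than 20\% relatively.
#'
#' @param traces a persistent-protocol \linkS4class{TraceSet}.
#' @return named numeric vector \code{c(pct_end, pct_25_30)} (percent).
#' @export
#' @examples
#' persistentFraction(simulateProtocol(defaultPhenotype("L1624Q", 22),
#'   "persistent"))
persistentFraction <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  p <- protocolOf(traces)
  if (p@kind != "persistent")
    stop("protocol-mismatch error: persistentFraction needs a persistent TraceSet",
         call. = FALSE)
  time <- traceTime(traces)
  cur <- currentMatrix(traces)[, 1L]
  onset <- colData(traces)$test_onset_ms[1L]
  base <- mean(cur[time < onset])
  y <- cur - base
  win <- time >= onset + .PEAK_BLANK_MS & time <= onset + p@step_duration
  peak <- max(abs(y[win]))
  if (peak <= 0)
    stop("undefined-fraction error: peak current is zero", call. = FALSE)
  endw <- time >= onset + p@step_duration - 2 & time <= onset + p@step_duration
  midw <- time >= onset + 25 & time <= onset + 30
  pct_end <- 100 * mean(abs(y[endw])) / peak
  pct_mid <- 100 * mean(abs(y[midw])) / peak
  if (pct_mid > 1e-6 && abs(pct_end - pct_mid) / pct_mid > 0.2)
    warning("persistent current not stabilized: end (", round(pct_end, 3),
            "%) vs 25-30 ms (", round(pct_mid, 3), "%) windows differ by > 20%",
            call. = FALSE)
  c(pct_end = pct_end, pct_25_30 = pct_mid)
}

#' Analyze all four protocols of one cell
#'
#' Runs the full per-cell analysis (peaks, conductance-voltage Boltzmann,
#' SSFI Boltzmann, onset time constants, recovery kinetics, persistent
#' fraction, current density) and packages the result.
#'
#' @param traces named list of \linkS4class{TraceSet}s with elements
#'   \code{activation}, \code{ssfi}, \code{recovery}, \code{persistent}
#'   (as produced by \code{\link{generateCohort}}).
#' @param tau_voltages onset-tau reporting grid (mV).
#' @return a \linkS4class{CellMetrics}.
#' @export
analyzeCell <- function(traces, tau_voltages = seq(-30, 20, by = 10)) {
  need <- c("activation", "ssfi", "recovery", "persistent")
  if (!all(need %in% names(traces)))
    stop("traces must be a named list with elements: ",
         paste(need, collapse = ", "), call. = FALSE)
  act <- traces$activation
  peaks <- measurePeaks(act)
  gv <- fitBoltzmann(conductanceCurve(peaks), direction = "ascending")
  taus <- onsetTauValues(fitOnsetTau(act, tau_voltages))
  pers <- persistentFraction(traces$persistent)
  new("CellMetrics",
      genotype = genotypeOf(act), temperature = temperatureOf(act),
      current_density_0mV = currentDensity(act),
      gv_fit = gv, ssfi_fit = ssfiCurve(traces$ssfi),
      tau_onset_by_v = taus,
      recovery_fit = recoveryCurve(traces$recovery),
      persistent_pct_end = unname(pers["pct_end"]),
      persistent_pct_25_30 = unname(pers["pct_25_30"]))
}

#' Tidy table of per-cell metrics
#'
#' One row per cell, with the exact column layout consumed by the statistics
#' stage: \code{genotype}, \code{temperature_C}, \code{density_pA_pF},
#' \code{v_half_act_mV}, \code{k_act_mV}, \code{v_half_inact_mV},
#' \code{k_inact_mV}, one \code{tau_ms_at_<V>} column per reporting voltage,
#' \code{rec_tau_fast_ms}, \code{rec_tau_slow_ms}, \code{persistent_pct}.
#'
#' @param cells list of \linkS4class{CellMetrics}.
#' @return data.frame, one row per cell.
#' @export
metricsTable <- function(cells) {
  stopifnot(length(cells) > 0L,
            all(vapply(cells, is, logical(1), "CellMetrics")))
  rows <- lapply(seq_along(cells), function(i) {
    m <- cells[[i]]
    row <- data.frame(cell_id = i, genotype = m@genotype,
                      temperature_C = m@temperature,
                      density_pA_pF = m@current_density_0mV,
                      v_half_act_mV = m@gv_fit@v_half,
                      k_act_mV = m@gv_fit@k,
                      v_half_inact_mV = m@ssfi_fit@v_half,
                      k_inact_mV = m@ssfi_fit@k,
                      stringsAsFactors = FALSE)
    taus <- as.list(m@tau_onset_by_v)
    names(taus) <- paste0("tau_ms_at_", names(m@tau_onset_by_v))
    row <- cbind(row, as.data.frame(taus, check.names = FALSE))
    row$rec_tau_fast_ms <- m@recovery_fit@tau_fast
    row$rec_tau_slow_ms <- m@recovery_fit@tau_slow
    row$persistent_pct <- m@persistent_pct_end
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn analyzeCell analyze every cell of a cohort from
#'   \code{\link{generateCohort}} and return the tidy metrics table.
#' @param cohort list of cells from \code{\link{generateCohort}}.
#' @export
analyzeCohort <- function(cohort, tau_voltages = seq(-30, 20, by = 10)) {
  metricsTable(lapply(cohort, function(cell)
    analyzeCell(cell$traces, tau_voltages)))
}

setMethod("show", "CellMetrics", function(object) {
  cat(sprintf("CellMetrics: %s at %s degC\n", object@genotype,
              object@temperature))
  cat(sprintf("  density 0 mV   : %.2f pA/pF\n", object@current_density_0mV))
  cat(sprintf("  G-V            : V1/2 = %.2f mV, k = %.2f mV\n",
              object@gv_fit@v_half, object@gv_fit@k))
  cat(sprintf("  SSFI           : V1/2 = %.2f mV, k = %.2f mV\n",
              object@ssfi_fit@v_half, object@ssfi_fit@k))
  cat(sprintf("  persistent     : %.2f %% (end), %.2f %% (25-30 ms)\n",
              object@persistent_pct_end, object@persistent_pct_25_30))
  cat(sprintf("  recovery       : tau_f = %.2f ms, tau_s = %.2f ms\n",
              object@recovery_fit@tau_fast, object@recovery_fit@tau_slow))
  cat("  tau onset (ms) :",
      paste(sprintf("%s mV: %.3f", names(object@tau_onset_by_v),
                    object@tau_onset_by_v), collapse = "; "), "\n")
})
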