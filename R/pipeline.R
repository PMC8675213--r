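# End-to-end orchestration: one declarative config drives fixture
# generation, per-cell analysis, group statistics and neuron-simulation
# scenarios, with a machine-readable manifest for bit-identical re-runs.

.SCENARIOS <- c("fig5a", "fig5b", "fig5c", "fig6_rest", "fig6_prestim")
.PROTOCOL_PRESETS <- c(fig2 = "activation", fig3 = "ssfi", fig4 = "persistent",
                       activation = "activation", ssfi = "ssfi",
                       recovery = "recovery", persistent = "persistent")

#' Default run configuration
#'
#' The experiment grid the package emulates: the four genotype x temperature
#' cohorts under all four protocols, group statistics on density, persistent
#' fraction and per-voltage onset time constants, and the brief-pulse and
#' low-step neuron scenarios.
#'
#' @param seed integer seed for the full run.
#' @param outdir output directory.
#' @param n_cells cells per cohort.
#' @param cell_variability fractional cell-to-cell SD.
#' @param noise_sd per-sample recording noise (pA).
#' @param scenarios neuron scenarios to run (subset of fig5a, fig5b, fig5c,
#'   fig6_rest, fig6_prestim).
#' @return a named list (RunConfig).
#' @export
defaultRunConfig <- function(seed = 1L, outdir = tempfile("navclamp_run_"),
                             n_cells = 6, cell_variability = 0.1,
                             noise_sd = 0, scenarios = c("fig5a", "fig5c")) {
  grid <- expand.grid(genotype = c("WT", "L1624Q"), temperature = c(22, 37),
                      stringsAsFactors = FALSE)
  cohorts <- lapply(seq_len(nrow(grid)), function(i)
    list(genotype = grid$genotype[i], temperature = grid$temperature[i],
         n = n_cells, variability = cell_variability, noise_sd = noise_sd,
         capacitance = 20))
  list(seed = as.integer(seed), outdir = outdir, cohorts = cohorts,
       protocols = c("activation", "ssfi", "recovery", "persistent"),
       analyze = TRUE, stats = TRUE, scenarios = scenarios)
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of \code{\link{defaultRunConfig}}.
#' @return a RunConfig list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(defaultRunConfig(), cfg)
}

.validateConfig <- function(config) {
  if (is.null(config$seed))
    stop("config error [generate]: seed is required", call. = FALSE)
  bad <- setdiff(config$protocols, names(.PROTOCOL_PRESETS))
  if (length(bad))
    stop("config error [generate]: unknown protocol preset: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(config$scenarios, .SCENARIOS)
  if (length(bad))
    stop("config error [simulate]: unknown scenario preset: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(config)
}

#' Neuron scenario presets
#'
#' The named stimulation scenarios: \code{fig5a} (1 s steps at 1, 1.5, 2 and
#' 5 pA), \code{fig5b} (firing-rate curve, 1-100 pA), \code{fig5c} (10 pA x
#' 50 ms pulse then zero stimulus), \code{fig6_rest} (exponential ramp
#' 0.002-400 pA over 10 s from rest) and \code{fig6_prestim} (the same ramp
#' after a 10 pA x 10 ms pre-stimulus).
#'
#' @param name scenario name.
#' @return list describing the scenario.
#' @export
neuronScenario <- function(name = .SCENARIOS) {
  name <- match.arg(name)
  switch(name,
    fig5a = list(name = name, type = "steps",
                 amplitudes = c(1, 1.5, 2, 5), duration = 1000),
    fig5b = list(name = name, type = "fi_curve",
                 amplitudes = seq(1, 100, by = 1), duration = 1000),
    fig5c = list(name = name, type = "pulse_off", amplitude = 10,
                 pulse_ms = 50, total_ms = 1000),
    fig6_rest = list(name = name, type = "ramp", ramp = stimRamp()),
    fig6_prestim = list(name = name, type = "ramp",
                        ramp = stimRamp(pre_amplitude = 10,
                                        pre_duration = 10)))
}

.runScenario <- function(scn, variants = c("WT", "L1624Q"), dt = 0.005) {
  rows <- list()
  for (vn in variants) {
    params <- buildNeuron(vn)
    rows[[vn]] <- switch(scn$type,
      steps = do.call(rbind, lapply(scn$amplitudes, function(a) {
        tr <- integrateNeuron(params, stimStep(a, scn$duration),
                              duration = scn$duration, dt = dt)
        data.frame(scenario = scn$name, variant = vn,
                   measure = sprintf("n_spikes_at_%g_pA", a),
                   value = length(spikeTimes(tr)))
      })),
      fi_curve = {
        fi <- firingRateCurve(params, scn$amplitudes, scn$duration, dt)
        data.frame(scenario = scn$name, variant = vn,
                   measure = sprintf("rate_hz_at_%g_pA", fi$amplitude_pA),
                   value = fi$rate_hz)
      },
      pulse_off = {
        pf <- persistentFiringTest(params, scn$amplitude, scn$pulse_ms,
                                   scn$total_ms, dt)
        data.frame(scenario = scn$name, variant = vn,
                   measure = c("fired_after_offset", "n_spikes_after",
                               "duration_after_s"),
                   value = c(as.numeric(pf$fired_after_offset),
                             pf$n_spikes_after, pf$duration_after_s))
      },
      ramp = {
        rb <- rampBlockTest(params, scn$ramp, dt)
        data.frame(scenario = scn$name, variant = vn,
                   measure = c("block_onset_pA", "last_spike_ms"),
                   value = c(rb$block_onset_pA, rb$last_spike_ms))
      })
  }
  do.call(rbind, rows)
}

#' Run the full pipeline from a configuration
#'
#' Executes generate, analyze, stats and simulate as enabled by the config,
#' writing the per-cell metrics table (\code{cell_metrics.tsv}), the effects
#' table (\code{effects.tsv}), per-voltage contrasts
#' (\code{per_voltage_tests.tsv}), scenario summaries
#' (\code{sim_summary.tsv}) and a manifest (\code{manifest.json}: config,
#' seed, versions, file checksums). Identical config + seed give
#' byte-identical tables.
#'
#' @param config a RunConfig list (see \code{\link{defaultRunConfig}}), or a
#'   path to a YAML config file.
#' @return invisibly, a list with the metrics table, effects table,
#'   per-voltage tests, simulation summary and manifest path.
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(defaultRunConfig(seed = 7, n_cells = 2,
#'   scenarios = character()))
#' }
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .validateConfig(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("config error [generate]: cannot create output directory ", outdir,
         call. = FALSE)
  protocols <- unique(unname(.PROTOCOL_PRESETS[config$protocols]))

  # generate + analyze
  message("[generate] ", length(config$cohorts), " cohorts x ",
          length(protocols), " protocols")
  metrics <- NULL
  cohort_seeds <- config$seed + seq_along(config$cohorts) * 1000L
  for (i in seq_along(config$cohorts)) {
    cs <- config$cohorts[[i]]
    coh <- generateCohort(defaultPhenotype(cs$genotype, cs$temperature),
                          n_cells = cs$n, cell_variability = cs$variability,
                          protocols = protocols,
                          capacitance = cs$capacitance %||% 20,
                          noise_sd = cs$noise_sd, seed = cohort_seeds[i])
    analyzable <- all(c("activation", "ssfi", "recovery", "persistent") %in%
                        protocols)
    if (isTRUE(config$analyze) && !analyzable && i == 1L)
      message("[analyze] skipped: the full per-cell analysis needs all four ",
              "protocols (have: ", paste(protocols, collapse = ", "), ")")
    if (isTRUE(config$analyze) && analyzable) {
      message("[analyze] ", cs$genotype, " at ", cs$temperature, " degC (n = ",
              cs$n, ")")
      m <- analyzeCohort(coh)
      m$cell_id <- paste0(cs$genotype, "_", cs$temperature, "C_", m$cell_id)
      metrics <- rbind(metrics, m)
    }
  }
  if (!is.null(metrics))
    write.table(metrics, file.path(outdir, "cell_metrics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)

  # stats
  effects <- NULL; pvt <- NULL
  if (isTRUE(config$stats) && !is.null(metrics)) {
    message("[stats] genotype x temperature ANOVA + per-voltage contrasts")
    for (resp in c("density_pA_pF", "persistent_pct"))
      effects <- rbind(effects,
                       effectsTable(interactionAnova(metrics, resp)))
    write.table(effects, file.path(outdir, "effects.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    tl <- tauLongTable(metrics)
    tl37 <- tl[tl$temperature == 37 & is.finite(tl$tau), ]
    if (nrow(tl37))
      pvt <- perVoltageTests(tl37)
    if (!is.null(pvt))
      write.table(pvt, file.path(outdir, "per_voltage_tests.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # simulate
  sims <- NULL
  for (sn in config$scenarios) {
    message("[simulate] scenario ", sn)
    sims <- rbind(sims, .runScenario(neuronScenario(sn)))
  }
  if (!is.null(sims))
    write.table(sims, file.path(outdir, "sim_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)

  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    package_version = as.character(packageVersion("navclamp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, effects = effects,
                 per_voltage = pvt, sims = sims,
                 manifest = manifest_path, outdir = outdir))
}

#' Generate the fixture grid of TraceSet files
#'
#' Emits one noise-free TraceSet file per protocol x genotype x temperature
#' (16 files) plus noisy activation and persistent sets for each condition
#' (8 files), as plain-text TraceSet files.
#'
#' @param seed integer seed (noisy fixtures).
#' @param outdir writable output directory.
#' @param noise_sd noise SD (pA) for the noisy fixtures.
#' @return data.frame manifest (file, genotype, temperature, protocol,
#'   noisy), invisibly.
#' @export
generateFixtures <- function(seed = 1L, outdir, noise_sd = 10) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("I/O failure: cannot create ", outdir, call. = FALSE)
  grid <- expand.grid(protocol = c("activation", "ssfi", "recovery",
                                   "persistent"),
                      genotype = c("WT", "L1624Q"), temperature = c(22, 37),
                      stringsAsFactors = FALSE)
  grid$noisy <- FALSE
  noisy <- expand.grid(protocol = c("activation", "persistent"),
                       genotype = c("WT", "L1624Q"),
                       temperature = c(22, 37), stringsAsFactors = FALSE)
  noisy$noisy <- TRUE
  grid <- rbind(grid, noisy)
  grid$file <- file.path(outdir, sprintf(
    "traceset_%s_%sC_%s_%s.tsv", grid$genotype, grid$temperature,
    grid$protocol, ifelse(grid$noisy, "noisy", "noisefree")))
  for (i in seq_len(nrow(grid))) {
    ts <- simulateProtocol(defaultPhenotype(grid$genotype[i],
                                            grid$temperature[i]),
                           grid$protocol[i],
                           noise_sd = if (grid$noisy[i]) noise_sd else 0,
                           seed = seed + i)
    writeTraceSet(ts, grid$file[i])
  }
  invisible(grid)
}
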