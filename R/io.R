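# TraceSet files: a plain-text dialect (commented header block + delimited
# body, one column per sweep) and an equivalent binary container (R's native
# serialization). Both round-trip losslessly: text numbers are written with
# 17 significant digits.

.protocolToList <- function(p) {
  list(kind = p@kind, holding_v = p@holding_v,
       step_voltages = p@step_voltages, step_duration = p@step_duration,
       test_pulse_v = p@test_pulse_v,
       test_pulse_duration = p@test_pulse_duration,
       recovery_v = p@recovery_v, recovery_times = p@recovery_times,
       sample_interval = p@sample_interval)
}

.listToProtocol <- function(x) {
  num <- function(v) if (is.null(v) || !length(v)) NA_real_ else
    as.numeric(v)
  new("VClampProtocol", kind = x$kind, holding_v = num(x$holding_v),
      step_voltages = as.numeric(unlist(x$step_voltages)),
      step_duration = num(x$step_duration),
      test_pulse_v = num(x$test_pulse_v),
      test_pulse_duration = num(x$test_pulse_duration),
      recovery_v = num(x$recovery_v),
      recovery_times = as.numeric(unlist(x$recovery_times)),
      sample_interval = num(x$sample_interval))
}

#' Write a TraceSet to disk
#'
#' \code{format = "tsv"} writes a plain-text file: a commented header block
#' (capacitance, genotype, temperature, protocol descriptor, noise SD, seed,
#' per-sweep conditions) followed by a tab-delimited body whose first column
#' is time (ms) and remaining columns are sweep currents (pA), at full
#' double precision. \code{format = "rds"} writes the equivalent binary
#' container. Both round-trip losslessly through
#' \code{\link{readTraceSet}}.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"rds"} (default from the file
#'   extension, falling back to tsv).
#' @return \code{path}, invisibly.
#' @export
#' @examples
#' ts <- simulateProtocol(defaultPhenotype("WT", 22), "persistent")
#' f <- tempfile(fileext = ".tsv")
#' writeTraceSet(ts, f)
#' identical(currentMatrix(readTraceSet(f)), currentMatrix(ts))
writeTraceSet <- function(ts, path, format = NULL) {
  stopifnot(is(ts, "TraceSet"))
  if (is.null(format))
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tsv"
  format <- match.arg(format, c("tsv", "rds"))
  if (format == "rds") {
    saveRDS(ts, path)
    return(invisible(path))
  }
  md <- metadata(ts)
  cd <- as.data.frame(colData(ts))
  hdr <- c(
    "# navclamp TraceSet v1",
    paste0("# capacitance_pF: ", format(md$capacitance_pF, digits = 17)),
    paste0("# genotype: ", md$genotype),
    paste0("# temperature_C: ", md$temperature_C),
    paste0("# phenotype_id: ", md$phenotype_id),
    paste0("# noise_sd: ", format(md$noise_sd, digits = 17)),
    paste0("# seed: ", md$seed),
    paste0("# protocol: ",
           jsonlite::toJSON(.protocolToList(md$protocol), auto_unbox = TRUE,
                            digits = NA, na = "null")),
    paste0("# sweeps: ",
           jsonlite::toJSON(cd, digits = NA, na = "null"))
  )
  body <- cbind(time_ms = traceTime(ts), currentMatrix(ts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(body), collapse = "\t"), con)
  txt <- apply(body, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, con)
  invisible(path)
}

#' Read a TraceSet written by \code{\link{writeTraceSet}}
#'
#' The format (text or binary) is detected from the file contents.
#'
#' @param path file path.
#' @return a \linkS4class{TraceSet}.
#' @export
readTraceSet <- function(path) {
  if (!file.exists(path))
    stop("no such TraceSet file: ", path, call. = FALSE)
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE),
                    error = function(e) "")
  if (!length(first) || !startsWith(first, "# navclamp TraceSet")) {
    obj <- readRDS(path)
    if (!is(obj, "TraceSet"))
      stop("file does not contain a TraceSet: ", path, call. = FALSE)
    return(obj)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed TraceSet header: missing ", key,
                          call. = FALSE)
    sub(paste0("^# ", key, ": "), "", ln[1L])
  }
  protocol <- .listToProtocol(jsonlite::fromJSON(getval("protocol")))
  cd <- jsonlite::fromJSON(getval("sweeps"))
  # JSON carries no integer/double distinction; sweep annotations are doubles
  cd[] <- lapply(cd, function(x) if (is.numeric(x)) as.numeric(x) else x)
  nhdr <- length(hdr)
  body <- read.table(path, sep = "\t", skip = nhdr, header = TRUE,
                     check.names = FALSE)
  cur <- as.matrix(body[, -1L, drop = FALSE])
  se <- SummarizedExperiment(
    assays = list(current = cur),
    rowData = DataFrame(time_ms = body[[1L]]),
    colData = as(cd, "DataFrame"),
    metadata = list(capacitance_pF = as.numeric(getval("capacitance_pF")),
                    protocol = protocol,
                    phenotype_id = getval("phenotype_id"),
                    genotype = getval("genotype"),
                    temperature_C = as.numeric(getval("temperature_C")),
                    noise_sd = as.numeric(getval("noise_sd")),
                    seed = as.integer(getval("seed"))))
  new("TraceSet", se)
}

#' Write a simulated trace and its summary
#'
#' Writes the recorded time/voltage/stimulus table as tab-delimited text and
#' a structured-text (YAML) summary record carrying the spike times and
#' derived metrics.
#'
#' @param tr a \linkS4class{SimTrace}.
#' @param path output path for the trace table; the summary goes to
#'   \code{paste0(path, ".summary.yaml")}.
#' @return \code{path}, invisibly.
#' @export
writeSimTrace <- function(tr, path) {
  stopifnot(is(tr, "SimTrace"))
  df <- data.frame(time_ms = tr@time, v_m_mV = tr@v_m,
                   stimulus_pA = tr@stimulus)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- list(n_spikes = length(tr@spike_times),
               spike_times_ms = tr@spike_times,
               fired_after_offset = tr@fired_after_offset,
               block_onset_current_pA = tr@block_onset_current,
               dt_ms = tr@dt,
               gating_range = tr@gating_range)
  yaml::write_yaml(summ, paste0(path, ".summary.yaml"))
  invisible(path)
}
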