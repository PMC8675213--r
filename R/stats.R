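# Genotype x temperature statistics: two-way fixed-effects ANOVA with the
# interaction as the primary predictor, stepping down to an additive model
# when the interaction is absent (Type-II sums of squares), plus per-voltage
# genotype contrasts on log10-transformed onset time constants.

.checkDesign <- function(df, factors) {
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L)
      stop("design-deficiency error: factor '", f, "' has < 2 levels",
           call. = FALSE)
  }
  tab <- table(df[factors])
  if (any(tab == 0L))
    stop("design-deficiency error: empty cell in the ",
         paste(factors, collapse = " x "), " design", call. = FALSE)
  if (any(tab < 2L))
    stop("design-deficiency error: every design cell needs >= 2 cells (observations)",
         call. = FALSE)
  df
}

.effectRow <- function(name, F, df1, df2, p, alpha) {
  # guard the zero-variance corner: no effect and no residual variance
  # means "no evidence of an effect", F = 0, p = 1
  if (!is.finite(F)) { F <- 0; p <- 1 }
  data.frame(effect = name, F = F, df1 = df1, df2 = df2, p = p,
             significant = is.finite(p) && p < alpha,
             stringsAsFactors = FALSE)
}

#' Genotype x temperature interaction ANOVA with additive stepdown
#'
#' Fits a two-way fixed-effects ANOVA \code{response ~ genotype * temperature}
#' and tests the interaction (differential temperature sensitivity of the
#' variant). If the interaction is not significant at \code{alpha}, the model
#' is refit additively and the genotype and temperature main effects are
#' evaluated independently (Type-II sums of squares);
#' \code{stepdown_applied} records which path was taken.
#'
#' @param table data.frame with columns \code{genotype},
#'   \code{temperature} (or \code{temperature_C}) and the response.
#' @param response name of the response column.
#' @param alpha significance level (default 0.05).
#' @return an \linkS4class{AnovaResult}.
#' @export
#' @examples
#' df <- expand.grid(genotype = c("WT", "MUT"), temperature = c(22, 37),
#'                   rep = 1:6)
#' df$y <- rnorm(nrow(df)) + 2 * (df$genotype == "MUT") * (df$temperature == 37)
#' interactionAnova(df, "y")
interactionAnova <- function(table, response, alpha = 0.05) {
  stopifnot(is.data.frame(table))
  if (!"temperature" %in% names(table) && "temperature_C" %in% names(table))
    table$temperature <- table$temperature_C
  need <- c("genotype", "temperature", response)
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(table[[response]]))
    stop("missing responses in '", response, "'", call. = FALSE)
  df <- .checkDesign(table, c("genotype", "temperature"))
  df$.y <- df[[response]]

  fit <- lm(.y ~ genotype * temperature, data = df)
  if (sum(resid(fit)^2) < 1e-12 * max(1, sum(df$.y^2))) {
    # degenerate zero-residual fit: effects with zero SS carry no evidence
    a1 <- suppressWarnings(anova(fit))
    rows <- do.call(rbind, lapply(
      c("genotype:temperature", "genotype", "temperature"), function(eff) {
        F <- if (a1[eff, "Sum Sq"] < 1e-12) 0 else Inf
        .effectRow(eff, F, a1[eff, "Df"], a1["Residuals", "Df"],
                   if (F == 0) 1 else 0, alpha)
      }))
    return(new("AnovaResult", effects = rows, alpha = alpha,
               stepdown_applied = rows$p[1L] >= alpha, response = response))
  }
  a2 <- car::Anova(fit, type = 2)
  int <- "genotype:temperature"
  p_int <- a2[int, "Pr(>F)"]
  F_int <- a2[int, "F value"]
  df2 <- a2["Residuals", "Df"]
  rows <- .effectRow("genotype:temperature", F_int, a2[int, "Df"], df2,
                     p_int, alpha)
  stepdown <- !is.finite(p_int) || p_int >= alpha
  if (stepdown) {
    fit_add <- lm(.y ~ genotype + temperature, data = df)
    aa <- car::Anova(fit_add, type = 2)
    dfr <- aa["Residuals", "Df"]
    for (eff in c("genotype", "temperature"))
      rows <- rbind(rows, .effectRow(eff, aa[eff, "F value"], aa[eff, "Df"],
                                     dfr, aa[eff, "Pr(>F)"], alpha))
  } else {
    for (eff in c("genotype", "temperature"))
      rows <- rbind(rows, .effectRow(eff, a2[eff, "F value"], a2[eff, "Df"],
                                     df2, a2[eff, "Pr(>F)"], alpha))
  }
  new("AnovaResult", effects = rows, alpha = alpha,
      stepdown_applied = stepdown, response = response)
}

#' Per-voltage genotype contrasts on log-transformed time constants
#'
#' At each voltage of the reporting grid, compares log10(tau) between the two
#' genotypes at a fixed temperature with a Welch two-sample t-test. Time
#' constants are log-transformed before analysis; no multiplicity correction
#' is applied across voltages.
#'
#' @param table data.frame with columns \code{genotype}, \code{voltage} and
#'   the response (positive time constants, ms).
#' @param response name of the tau column (default \code{"tau"}).
#' @return data.frame with columns \code{voltage}, \code{t}, \code{df},
#'   \code{p}, \code{log10_ratio} (mean log10 difference, first genotype
#'   level minus second).
#' @export
perVoltageTests <- function(table, response = "tau") {
  stopifnot(is.data.frame(table))
  need <- c("genotype", "voltage", response)
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  y <- table[[response]]
  if (anyNA(y))
    stop("missing responses in '", response, "'", call. = FALSE)
  if (any(y <= 0)) {
    bad <- which(y <= 0)[1L]
    stop("transform error: non-positive tau at row ", bad,
         " (voltage ", table$voltage[bad], " mV, genotype ",
         table$genotype[bad], ")", call. = FALSE)
  }
  table$genotype <- factor(table$genotype)
  if (nlevels(table$genotype) != 2L)
    stop("design-deficiency error: exactly two genotypes required",
         call. = FALSE)
  out <- lapply(sort(unique(table$voltage)), function(v) {
    sub <- table[table$voltage == v, ]
    if (any(table(sub$genotype) < 2L))
      stop("design-deficiency error: < 2 cells per genotype at ", v, " mV",
           call. = FALSE)
    lt <- log10(sub[[response]])
    grp <- split(lt, sub$genotype)
    if (all(vapply(grp, var, numeric(1)) < 1e-20)) {
      # degenerate zero-variance groups: identical means carry no evidence
      d <- mean(grp[[1L]]) - mean(grp[[2L]])
      equal <- abs(d) < 1e-12
      return(data.frame(voltage = v, t = if (equal) 0 else Inf,
                        df = NA_real_, p = if (equal) 1 else 0,
                        log10_ratio = -d, stringsAsFactors = FALSE))
    }
    tt <- t.test(lt ~ sub$genotype, var.equal = FALSE)
    data.frame(voltage = v, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               log10_ratio = unname(diff(rev(tt$estimate))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Long-format tau table from a tidy metrics table
#'
#' Pivots the \code{tau_ms_at_<V>} columns of \code{\link{metricsTable}}
#' output into the long (cell, genotype, temperature, voltage, tau) layout
#' consumed by \code{\link{perVoltageTests}}.
#'
#' @param metrics data.frame from \code{\link{metricsTable}}.
#' @return long data.frame with columns \code{cell_id}, \code{genotype},
#'   \code{temperature}, \code{voltage}, \code{tau}.
#' @export
tauLongTable <- function(metrics) {
  taucols <- grep("^tau_ms_at_", names(metrics), value = TRUE)
  if (!length(taucols))
    stop("no tau_ms_at_<V> columns found", call. = FALSE)
  volts <- as.numeric(sub("^tau_ms_at_", "", taucols))
  out <- do.call(rbind, lapply(seq_along(taucols), function(i) {
    data.frame(cell_id = metrics$cell_id, genotype = metrics$genotype,
               temperature = metrics$temperature_C, voltage = volts[i],
               tau = metrics[[taucols[i]]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @describeIn interactionAnova flat effects table (one row per effect) for
#'   writing to disk.
#' @param result an \linkS4class{AnovaResult}.
#' @export
effectsTable <- function(result) {
  stopifnot(is(result, "AnovaResult"))
  cbind(response = result@response, result@effects,
        stepdown_applied = result@stepdown_applied)
}

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult for '%s' (alpha = %g, stepdown %s)\n",
              object@response, object@alpha,
              if (object@stepdown_applied) "applied" else "not applied"))
  print(object@effects, row.names = FALSE, digits = 4)
})
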