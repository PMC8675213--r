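# Nonlinear fits used throughout the analysis. All fits are deterministic:
# starting values follow fixed rules (Boltzmann v_half0 = voltage of
# half-maximum by linear interpolation, k0 = 7 mV; exponential tau0 from the
# log-linear slope of the first decade of decay) and Levenberg-Marquardt
# least squares (minpack.lm::nls.lm) runs unconstrained on transformed
# parameters (log tau, logit fraction), which enforces positivity and [0,1]
# constraints intrinsically.

.fitError <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("fitError", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

.lmFit <- function(par, fn, what) {
  r <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) .fitError(paste0(what, " fit failed: ",
                                         conditionMessage(e))))
  if (!r$info %in% 1:4 || !is.finite(r$deviance))
    .fitError(paste0(what, " fit failed to converge (info = ", r$info,
                     ": ", r$message, ")"),
              diagnostics = list(par = r$par, deviance = r$deviance))
  r
}

#' Fit a Boltzmann curve to normalized data
#'
#' Least-squares fit of \eqn{y = 1/(1 + \exp((V_{1/2} - V)/k))} (ascending;
#' conductance-voltage) or \eqn{y = 1/(1 + \exp((V - V_{1/2})/k))}
#' (descending; availability). The direction is inferred from the data unless
#' given. Requires at least 4 points.
#'
#' @param v voltages (mV); may also be a named numeric vector holding the
#'   values with voltages as names (then \code{y} is omitted).
#' @param y normalized responses in approximately [0, 1].
#' @param direction \code{"auto"}, \code{"ascending"} or \code{"descending"}.
#' @return a \linkS4class{BoltzmannFit}.
#' @export
#' @examples
#' v <- seq(-100, 20, 10)
#' fitBoltzmann(v, 1 / (1 + exp((-22 - v) / 7)))
fitBoltzmann <- function(v, y = NULL,
                         direction = c("auto", "ascending", "descending")) {
  direction <- match.arg(direction)
  if (is.null(y)) {
    y <- as.numeric(v)
    v <- as.numeric(names(v))
  }
  keep <- is.finite(v) & is.finite(y)
  v <- v[keep]; y <- y[keep]
  if (length(v) < 4L)
    .fitError("fit-insufficiency: need >= 4 finite points for a Boltzmann fit")
  o <- order(v); v <- v[o]; y <- y[o]
  if (direction == "auto")
    direction <- if (y[length(y)] >= y[1L]) "ascending" else "descending"
  sgn <- if (direction == "ascending") -1 else 1

  # v_half0: voltage where y crosses half-maximum, by linear interpolation
  yr <- (y - min(y)) / max(max(y) - min(y), .Machine$double.eps)
  cross <- approx(if (direction == "ascending") yr else rev(yr),
                  if (direction == "ascending") v else rev(v),
                  xout = 0.5, ties = "ordered")$y
  v_half0 <- if (is.finite(cross)) cross else median(v)

  fn <- function(p) y - 1 / (1 + exp(sgn * (v - p[1L]) / exp(p[2L])))
  r <- .lmFit(c(v_half = v_half0, lk = log(7)), fn, "Boltzmann")
  new("BoltzmannFit", v_half = unname(r$par[1L]), k = exp(unname(r$par[2L])),
      direction = direction, residual_norm = sqrt(mean(r$fvec^2)))
}

#' Evaluate a fitted Boltzmann curve
#' @param fit a \linkS4class{BoltzmannFit}.
#' @param v voltages (mV).
#' @return fitted values.
#' @export
predictBoltzmann <- function(fit, v) {
  sgn <- if (fit@direction == "ascending") -1 else 1
  1 / (1 + exp(sgn * (v - fit@v_half) / fit@k))
}

#' Fit a single-exponential decay with offset
#'
#' Fits \eqn{y(t) = \mathrm{offset} + \mathrm{amplitude}\; e^{-(t - t_0)/\tau}}
#' where \eqn{t_0 = t[1]}. Used for fast-inactivation onset: the fit window
#' runs from the current peak to the end of the depolarizing step. A trace
#' whose decaying amplitude is negligible against its range (a non-decaying,
#' persistent-dominated or constant trace) raises a fit failure.
#'
#' @param t time (ms). @param y current (pA).
#' @return an \linkS4class{ExpFit}.
#' @export
#' @examples
#' t <- seq(0, 8, 0.02)
#' fitExpDecay(t, 3 + 50 * exp(-t / 0.5))
fitExpDecay <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 5L)
    .fitError("fit-insufficiency: need >= 5 points for an exponential fit")
  tl <- t - t[1L]
  n <- length(y)
  offset0 <- mean(y[max(1L, n - max(5L, n %/% 10)):n])
  amp0 <- y[1L] - offset0
  if (abs(amp0) < 1e-9 || abs(amp0) < 1e-3 * max(abs(y), 1e-12))
    .fitError("non-decaying trace: no resolvable exponential amplitude",
              diagnostics = list(amplitude0 = amp0, offset0 = offset0))
  # tau0 from the log-linear slope of the first decade of decay
  z <- (y - offset0) / amp0
  first <- which(z > 0.1 & z <= 1)
  tau0 <- if (length(first) >= 3L) {
    sl <- unname(coef(lm(log(z[first]) ~ tl[first]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(tl)) / 3
  } else diff(range(tl)) / 3

  fn <- function(p) y - (p[1L] + p[2L] * exp(-tl / exp(p[3L])))
  r <- .lmFit(c(offset = offset0, amplitude = amp0, ltau = log(tau0)),
              fn, "exponential-decay")
  new("ExpFit", tau = exp(unname(r$par[3L])),
      amplitude = unname(r$par[2L]), offset = unname(r$par[1L]),
      residual_norm = sqrt(mean(r$fvec^2)))
}

#' Fit a double-exponential recovery curve
#'
#' Fits the recovered fraction
#' \eqn{R(t) = 1 - A_f e^{-t/\tau_f} - (1 - A_f) e^{-t/\tau_s}}.
#' If the two time constants are not separately identifiable (ratio within
#' 5\%, or the fast fraction collapses onto 0 or 1) the fit falls back to a
#' single exponential \eqn{R(t) = 1 - e^{-t/\tau}} and the \code{degenerate}
#' flag is raised.
#'
#' @param t recovery times (ms). @param frac recovered fraction in [0, 1].
#' @return a \linkS4class{DoubleExpFit}.
#' @export
#' @examples
#' t <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30, 50, 100, 200)
#' fitDoubleExp(t, 1 - 0.9 * exp(-t / 2) - 0.1 * exp(-t / 50))
fitDoubleExp <- function(t, frac) {
  keep <- is.finite(t) & is.finite(frac)
  t <- t[keep]; frac <- frac[keep]
  if (length(t) < 8L)
    .fitError("fit-insufficiency: need >= 8 recovery times")
  # slow tau0 from the tail of the log-linear residual-recovery decay
  z <- pmax(1 - frac, 1e-12)
  tail_idx <- t >= median(t)
  sl <- unname(coef(lm(log(z[tail_idx]) ~ t[tail_idx]))[2L])
  taus0 <- if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 3
  tauf0 <- max(taus0 / 10, min(t[t > 0], max(t) / 100) / 2)

  fn <- function(p) {
    af <- stats::plogis(p[1L])
    frac - (1 - af * exp(-t / exp(p[2L])) - (1 - af) * exp(-t / exp(p[3L])))
  }
  r <- tryCatch(.lmFit(c(qaf = 0, ltf = log(tauf0), lts = log(taus0)),
                       fn, "double-exponential"),
                fitError = function(e) NULL)

  degenerate <- FALSE
  if (!is.null(r)) {
    af <- stats::plogis(r$par[1L])
    tf <- exp(unname(r$par[2L])); ts <- exp(unname(r$par[3L]))
    if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp; af <- 1 - af }
    if (ts / tf < 1.05 || af < 1e-3 || af > 1 - 1e-3) degenerate <- TRUE
  }
  if (is.null(r) || degenerate) {
    fn1 <- function(p) frac - (1 - exp(-t / exp(p[1L])))
    r1 <- .lmFit(c(ltau = log(taus0)), fn1, "single-exponential recovery")
    tau <- exp(unname(r1$par[1L]))
    return(new("DoubleExpFit", tau_fast = tau, tau_slow = tau,
               frac_fast = 1, degenerate = TRUE,
               residual_norm = sqrt(mean(r1$fvec^2))))
  }
  new("DoubleExpFit", tau_fast = tf, tau_slow = ts,
      frac_fast = unname(af), degenerate = FALSE,
      residual_norm = sqrt(mean(r$fvec^2)))
}

setMethod("show", "BoltzmannFit", function(object) {
  cat(sprintf("BoltzmannFit (%s): V1/2 = %.3f mV, k = %.3f mV, rms = %.2e\n",
              object@direction, object@v_half, object@k,
              object@residual_norm))
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit: tau = %.4f ms, amplitude = %.2f pA, offset = %.2f pA, rms = %.2e\n",
              object@tau, object@amplitude, object@offset,
              object@residual_norm))
})

setMethod("show", "DoubleExpFit", function(object) {
  cat(sprintf("DoubleExpFit: tau_f = %.3f ms, tau_s = %.3f ms, A_f = %.3f%s, rms = %.2e\n",
              object@tau_fast, object@tau_slow, object@frac_fast,
              if (object@degenerate) " [degenerate: single exponential]"
              else "", object@residual_norm))
})
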