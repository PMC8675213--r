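#' Construct a ChannelPhenotype
#'
#' Low-level constructor; most users want \code{\link{defaultPhenotype}},
#' which packages the published WT / L1624Q values at 22 and 37 degrees C.
#'
#' @param genotype label, e.g. \code{"WT"}, \code{"L1624Q"} or a custom name.
#' @param temperature degrees Celsius.
#' @param density_at_0mV peak current density magnitude at 0 mV (pA/pF).
#' @param v_half_act,k_act activation Boltzmann midpoint and slope (mV).
#' @param v_rev reversal potential (mV).
#' @param v_half_inact,k_inact SSFI Boltzmann midpoint and slope (mV).
#' @param tau_onset_table named numeric vector of fast-inactivation onset
#'   time constants (ms) keyed by voltage (mV); must cover -30..+20 mV.
#' @param f_persistent persistent current fraction in [0, 1).
#' @param rec_tau_fast,rec_tau_slow,rec_frac_fast double-exponential recovery
#'   constants (ms, ms, fraction).
#' @return a \linkS4class{ChannelPhenotype}.
#' @export
#' @examples
#' ph <- channelPhenotype("custom", 22, density_at_0mV = 50,
#'   f_persistent = 0.01)
channelPhenotype <- function(genotype, temperature,
                             density_at_0mV = 60,
                             v_half_act = -22, k_act = 7, v_rev = 65,
                             v_half_inact = -60, k_inact = 6,
                             tau_onset_table = defaultTauTable(0.8),
                             f_persistent = 0.01,
                             rec_tau_fast = 2, rec_tau_slow = 50,
                             rec_frac_fast = 0.9) {
  new("ChannelPhenotype", genotype = as.character(genotype),
      temperature = as.numeric(temperature),
      density_at_0mV = density_at_0mV,
      v_half_act = v_half_act, k_act = k_act, v_rev = v_rev,
      v_half_inact = v_half_inact, k_inact = k_inact,
      tau_onset_table = tau_onset_table, f_persistent = f_persistent,
      rec_tau_fast = rec_tau_fast, rec_tau_slow = rec_tau_slow,
      rec_frac_fast = rec_frac_fast)
}

#' Default fast-inactivation onset time-constant table
#'
#' Builds a tau(V) table on the -30..+20 mV grid from the value at 0 mV,
#' using a mild exponential voltage dependence (e-fold per 25 mV of
#' hyperpolarization), the typical shape for NaV1.1 onset kinetics.
#'
#' @param tau_at_0 onset time constant at 0 mV (ms).
#' @param voltages voltage grid (mV).
#' @param v_efold e-fold voltage of the tau(V) dependence (mV).
#' @return named numeric vector of tau (ms) by voltage.
#' @export
defaultTauTable <- function(tau_at_0, voltages = seq(-30, 20, by = 10),
                            v_efold = 25) {
  setNames(tau_at_0 * exp(-voltages / v_efold), voltages)
}

#' Packaged WT / L1624Q phenotypes at 22 and 37 degrees C
#'
#' Returns the generative ground truth for one genotype x temperature
#' condition with all published values installed:
#' \itemize{
#'   \item persistent fractions: WT 0.95\% / L1624Q 3.20\% at 22 C and
#'     WT 2.27\% / L1624Q 4.58\% at 37 C;
#'   \item current densities at 37 C: WT 72.82 / L1624Q 45.42 pA/pF
#'     (at 22 C densities did not differ between genotypes and no value was
#'     published; a representative 60 pA/pF is used for both);
#'   \item fast-inactivation onset at 37 C is 1.485-fold faster in L1624Q
#'     (tau divided by 1.485 at every voltage); at 22 C onset does not
#'     differ between genotypes.
#' }
#' Quantities with no published value (Boltzmann midpoints/slopes, absolute
#' tau values, recovery constants) carry documented representative NaV1.1
#' defaults: V1/2,act = -22 mV, k_act = 7 mV, V_rev = +65 mV,
#' V1/2,inact = -60 mV (right-shifted +4 mV at 37 C for both genotypes,
#' encoding the observed temperature effect), k_inact = 6 mV, WT
#' tau_onset(0 mV) = 0.8 ms at 22 C and 0.35 ms at 37 C, recovery
#' tau_fast = 2 ms, tau_slow = 50 ms, frac_fast = 0.9. All are overridable
#' through \code{...}.
#'
#' @param genotype \code{"WT"} or \code{"L1624Q"}.
#' @param temperature 22 or 37 (degrees Celsius).
#' @param ... overrides passed to \code{\link{channelPhenotype}}.
#' @return a \linkS4class{ChannelPhenotype}.
#' @export
#' @examples
#' defaultPhenotype("L1624Q", 22)
defaultPhenotype <- function(genotype = c("WT", "L1624Q"),
                             temperature = c(22, 37), ...) {
  genotype <- match.arg(genotype)
  temperature <- as.numeric(temperature)[1L]
  if (!temperature %in% c(22, 37))
    stop("unsupported condition: temperature must be 22 or 37 (got ",
         temperature, ")", call. = FALSE)

  persistent <- list(`WT.22` = 0.0095, `L1624Q.22` = 0.0320,
                     `WT.37` = 0.0227, `L1624Q.37` = 0.0458)
  density <- list(`WT.22` = 60, `L1624Q.22` = 60,
                  `WT.37` = 72.82, `L1624Q.37` = 45.42)
  key <- paste(genotype, temperature, sep = ".")

  wt_tau0 <- if (temperature == 22) 0.8 else 0.35
  tau0 <- if (genotype == "L1624Q" && temperature == 37)
    wt_tau0 / 1.485 else wt_tau0
  v_half_inact <- if (temperature == 37) -56 else -60

  defaults <- list(genotype = genotype, temperature = temperature,
                   density_at_0mV = density[[key]],
                   f_persistent = persistent[[key]],
                   tau_onset_table = defaultTauTable(tau0),
                   v_half_inact = v_half_inact)
  args <- modifyList(defaults, list(...))
  do.call(channelPhenotype, args)
}

#' @describeIn defaultPhenotype activation Boltzmann of a phenotype,
#'   evaluated at voltages \code{v}.
#' @param phenotype a \linkS4class{ChannelPhenotype}.
#' @param v voltages (mV).
#' @export
activationBoltzmann <- function(phenotype, v) {
  1 / (1 + exp((phenotype@v_half_act - v) / phenotype@k_act))
}

#' @describeIn defaultPhenotype SSFI (availability) Boltzmann of a phenotype.
#' @export
inactivationBoltzmann <- function(phenotype, v) {
  1 / (1 + exp((v - phenotype@v_half_inact) / phenotype@k_inact))
}

#' Onset time constant at a voltage, by table interpolation
#'
#' Linear interpolation inside the tabulated range; nearest-endpoint
#' extension outside it (the analysis grid -30..+20 mV always lies inside
#' the default table). An empty, unnamed or non-finite table is a
#' configuration error.
#'
#' @param phenotype a \linkS4class{ChannelPhenotype}.
#' @param v voltages (mV).
#' @return tau (ms) at each voltage.
#' @export
tauOnsetAt <- function(phenotype, v) {
  tab <- phenotype@tau_onset_table
  vv <- as.numeric(names(tab))
  if (length(tab) < 2L || any(!is.finite(tab)) || any(!is.finite(vv)))
    stop("configuration error: tau_onset_table is undefined or non-finite",
         call. = FALSE)
  out <- approx(vv, tab, xout = v, rule = 2)$y
  if (any(!is.finite(out)))
    stop("configuration error: tau_onset undefined at voltage ",
         paste(v[!is.finite(out)], collapse = ", "), call. = FALSE)
  out
}

#' @rdname accessors
setMethod("genotypeOf", "ChannelPhenotype", function(x) x@genotype)

#' @rdname accessors
setMethod("temperatureOf", "ChannelPhenotype", function(x) x@temperature)

setMethod("show", "ChannelPhenotype", function(object) {
  cat("ChannelPhenotype:", object@genotype, "at", object@temperature,
      "degC\n")
  cat(sprintf("  density at 0 mV : %.2f pA/pF\n", object@density_at_0mV))
  cat(sprintf("  activation      : V1/2 = %.1f mV, k = %.1f mV, Vrev = %.1f mV\n",
              object@v_half_act, object@k_act, object@v_rev))
  cat(sprintf("  SSFI            : V1/2 = %.1f mV, k = %.1f mV\n",
              object@v_half_inact, object@k_inact))
  cat(sprintf("  persistent      : %.2f %% of peak\n",
              100 * object@f_persistent))
  cat(sprintf("  tau onset (0 mV): %.3f ms\n",
              unname(tauOnsetAt(object, 0))))
  cat(sprintf("  recovery        : tau_f = %.1f ms, tau_s = %.1f ms, A_f = %.2f\n",
              object@rec_tau_fast, object@rec_tau_slow, object@rec_frac_fast))
})
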