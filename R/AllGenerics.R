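#' Accessors for navclamp objects
#'
#' Small accessor generics so that slots are never reached into directly:
#' \code{capacitance} (pF), \code{protocolOf} (the
#' \linkS4class{VClampProtocol} behind a \linkS4class{TraceSet}),
#' \code{traceTime} (ms), \code{sweepConditions} (per-sweep condition values:
#' step voltage or recovery time), \code{currentMatrix} (pA, time x sweep),
#' \code{spikeTimes} and \code{genotypeOf}/\code{temperatureOf}.
#'
#' @param x a navclamp object.
#' @return the accessed component; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("capacitance", function(x) standardGeneric("capacitance"))

#' @rdname accessors
#' @export
setGeneric("protocolOf", function(x) standardGeneric("protocolOf"))

#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setGeneric("sweepConditions", function(x) standardGeneric("sweepConditions"))

#' @rdname accessors
#' @export
setGeneric("currentMatrix", function(x) standardGeneric("currentMatrix"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("genotypeOf", function(x) standardGeneric("genotypeOf"))

#' @rdname accessors
#' @export
setGeneric("temperatureOf", function(x) standardGeneric("temperatureOf"))
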