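#' @include AllClasses.R
NULL

#' Accessors for oscgrid objects
#'
#' Small accessor generics for the simulation containers; prefer these over
#' direct slot access.
#'
#' @param object an oscgrid S4 object.
#' @return the requested component.
#' @name oscgrid-accessors
NULL

#' @rdname oscgrid-accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("speed", function(object) standardGeneric("speed"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("heading", function(object) standardGeneric("heading"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("membranePotential",
           function(object) standardGeneric("membranePotential"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("inputCurrent", function(object) standardGeneric("inputCurrent"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("spikeSamples", function(object) standardGeneric("spikeSamples"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("dcShift", function(object) standardGeneric("dcShift"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("mpoEnvelope", function(object) standardGeneric("mpoEnvelope"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("fieldLabels", function(object) standardGeneric("fieldLabels"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @rdname oscgrid-accessors
#' @export
setGeneric("rateMatrix", function(object) standardGeneric("rateMatrix"))

setMethod("duration", "Trajectory",
          function(object) object@t[length(object@t)] - object@t[1])
setMethod("speed", "Trajectory", function(object) object@speed)
setMethod("heading", "Trajectory", function(object) object@heading)

setMethod("duration", "MembraneTrace",
          function(object) object@t[length(object@t)] - object@t[1])
setMethod("membranePotential", "MembraneTrace", function(object) object@Vm)
setMethod("inputCurrent", "MembraneTrace", function(object) object@I)
setMethod("spikeSamples", "MembraneTrace", function(object) object@spike)
setMethod("spikeTimes", "MembraneTrace",
          function(object) object@t[object@spike])

setMethod("dcShift", "AmplitudeSeries", function(object) object@dcShift)
setMethod("mpoEnvelope", "AmplitudeSeries",
          function(object) object@mpoEnvelope)

setMethod("fieldLabels", "FieldClassification", function(object) object@label)
setMethod("sampleLabels", "FieldClassification",
          function(object) object@sampleLabel)

setMethod("rateMatrix", "RateMap", function(object) object@rate)

#' @describeIn Trajectory-class coerce to a data.frame with columns
#'   `t, x, y, speed, heading`.
#' @param x a `Trajectory`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  data.frame(t = x@t, x = x@x, y = x@y, speed = x@speed,
             heading = x@heading)
})

#' @describeIn MembraneTrace-class coerce to a data.frame with columns
#'   `t, Vm, I, spike`.
#' @param x a `MembraneTrace`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "MembraneTrace", function(x, ...) {
  data.frame(t = x@t, Vm = x@Vm, I = x@I, spike = x@spike)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d samples, dt = %g s, duration = %.1f s\n",
    length(object@t), object@dt, duration(object)))
  cat(sprintf("  mean speed %.2f cm/s; arena half-width %s cm\n",
              mean(object@speed),
              ifelse(is.na(object@arenaHalfWidth), "unbounded",
                     format(object@arenaHalfWidth))))
})

setMethod("show", "BandParams", function(object) {
  cat(sprintf(
    "BandParams: %d populations, omega_b = %.3f rad/s, beta = %g, gain = %g\n",
    length(object@phiOffset), object@omegaB, object@beta, object@gain))
  cat(sprintf("  band wavelength 2*pi/(gain*beta) = %.1f cm\n",
              2 * pi / (object@gain * object@beta)))
})

setMethod("show", "CellParams", function(object) {
  cat(sprintf(
    "CellParams: tau_GL = %g s, E_L = %g mV, V_t = %g mV, dt = %g s\n",
    object@tauGL, object@EL, object@Vt, object@dt))
})

setMethod("show", "MembraneTrace", function(object) {
  cat(sprintf(
    "MembraneTrace: %d samples, duration %.1f s, %d spike samples\n",
    length(object@t), duration(object), sum(object@spike)))
  cat(sprintf("  Vm range [%.2f, %.2f] mV, threshold %g mV\n",
              min(object@Vm), max(object@Vm), object@cellParams@Vt))
})

setMethod("show", "RateMap", function(object) {
  cat(sprintf(
    "RateMap: %d x %d bins of %g cm; peak rate %.2f Hz, %d undefined bins\n",
    nrow(object@rate), ncol(object@rate), object@binSize,
    suppressWarnings(max(object@rate, na.rm = TRUE)),
    sum(is.na(object@rate))))
})

setMethod("show", "FieldClassification", function(object) {
  tab <- table(factor(object@label,
                      c("in_field", "out_of_field", "unassigned")))
  cat(sprintf(
    "FieldClassification: %d x %d bins of %g cm (%d shuffles)\n",
    nrow(object@label), ncol(object@label), object@binSize,
    object@nShuffles))
  cat(sprintf("  in-field %d, out-of-field %d, unassigned %d bins\n",
              tab[["in_field"]], tab[["out_of_field"]],
              tab[["unassigned"]]))
})

setMethod("show", "AmplitudeSeries", function(object) {
  cat(sprintf("AmplitudeSeries: %d samples, dt = %g s\n",
              length(object@dcShift), object@dt))
})

setMethod("show", "PrecessionResult", function(object) {
  cat(sprintf(
    "PrecessionResult (%s): %d spikes, rho = %s, p = %s\n",
    object@mode, length(object@phase),
    format(object@rho, digits = 4), format(object@p, digits = 3)))
})
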