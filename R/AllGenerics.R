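#' @rdname MID
#' @param object,x an object.
#' @export
setGeneric("nCarbons", function(x) standardGeneric("nCarbons"))

#' @rdname MID
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' Fractional 13C enrichment of a MID
#'
#' The average fraction of labeled carbons, \eqn{\sum_i i f_i / n}: 0 for a
#' pure M+0 distribution, 1 for a fully labeled one.
#'
#' @param x an \linkS4class{MID}.
#' @return numeric in [0, 1].
#' @examples
#' fractionalEnrichment(MID(c(0.5, 0, 0, 0, 0, 0.5), 5)) # 0.5
#' @export
setGeneric("fractionalEnrichment", function(x) standardGeneric("fractionalEnrichment"))

#' @rdname FluxSet
#' @param x a \linkS4class{FluxSet}.
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' Derived fluxes of a FluxSet
#'
#' \code{vGluOut} = VGLS - VGDH is the glutamate flux diverted to
#' non-oxidative fates (e.g. glutathione synthesis); \code{vOaaOut} = VGDH is
#' the balancing cataplerotic exit at oxaloacetate; \code{glsTcaRatio} =
#' VGLS/VTCA is the glutaminase-to-TCA-cycle flux ratio.
#'
#' @param x a \linkS4class{FluxSet}.
#' @return numeric scalar.
#' @export
setGeneric("vGluOut", function(x) standardGeneric("vGluOut"))

#' @rdname vGluOut
#' @export
setGeneric("vOaaOut", function(x) standardGeneric("vOaaOut"))

#' @rdname vGluOut
#' @export
setGeneric("glsTcaRatio", function(x) standardGeneric("glsTcaRatio"))

#' Evaluate a driving function at arbitrary times
#'
#' @param x a \linkS4class{DrivingFunction}.
#' @param t numeric vector of times (min).
#' @return matrix with one renormalized MID row per time.
#' @export
setGeneric("midAt", function(x, t) standardGeneric("midAt"))
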