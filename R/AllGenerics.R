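#' @title Generics for quatMS data objects
#' @description Accessor generics shared by the spectrum, peak-list and
#'   envelope classes. All containers are immutable value objects; accessors
#'   return plain vectors.
#' @name quatMS-generics
#' @keywords internal
NULL

#' @describeIn quatMS-generics m/z values (Th)
#' @param object a quatMS data object
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @describeIn quatMS-generics intensity values (arbitrary units)
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @describeIn quatMS-generics per-peak full width at half maximum (Th)
#' @export
setGeneric("fwhmMz", function(object) standardGeneric("fwhmMz"))

#' @describeIn quatMS-generics charge states of an envelope
#' @export
setGeneric("charges", function(object) standardGeneric("charges"))

#' @describeIn quatMS-generics number of peaks / members
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))

#' @describeIn quatMS-generics node subunit labels of a topology
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))

#' @describeIn quatMS-generics canonical string identifying an arrangement
#' @export
setGeneric("canonicalString", function(object) standardGeneric("canonicalString"))
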