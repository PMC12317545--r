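#' Accessor generics
#'
#' Small set of accessor generics for the package's S4 containers. Slot
#' access from user code is discouraged; these accessors are the supported
#' surface.
#'
#' @param x a [PhenotypeTable] or [GenotypeMatrix] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phenoRecords", function(x) standardGeneric("phenoRecords"))

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
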