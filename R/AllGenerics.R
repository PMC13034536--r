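#' @include geometry-utils.R
NULL

#' Accessor generics for mdslope classes
#'
#' Small accessor generics used across the package: `volData()` returns the
#' scalar array of a [ScalarVolume-class], `volSpacing()` and `volAffine()`
#' the grid geometry of any volume, `volUnits()` the unit tag,
#' `labelScheme()` the role-to-label map of a [SegmentationVolume-class],
#' `meanMDS()`, `perProfile()`, `nValidProfiles()` and `nTotalProfiles()`
#' the components of an [MDSResult-class].
#'
#' @param x An object of the corresponding mdslope class.
#' @return The slot value (see each class page for details).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' @rdname accessors
#' @export
setGeneric("volUnits", function(x) standardGeneric("volUnits"))

#' @rdname accessors
#' @export
setGeneric("labelScheme", function(x) standardGeneric("labelScheme"))

#' @rdname accessors
#' @export
setGeneric("meanMDS", function(x) standardGeneric("meanMDS"))

#' @rdname accessors
#' @export
setGeneric("perProfile", function(x) standardGeneric("perProfile"))

#' @rdname accessors
#' @export
setGeneric("nValidProfiles", function(x) standardGeneric("nValidProfiles"))

#' @rdname accessors
#' @export
setGeneric("nTotalProfiles", function(x) standardGeneric("nTotalProfiles"))
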