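#' @rdname MetaboSet-accessors
#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("featureMeta", function(x, ...) standardGeneric("featureMeta"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("injectionMeta", function(x, ...) standardGeneric("injectionMeta"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("sampleType", function(x, ...) standardGeneric("sampleType"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("runOrder", function(x, ...) standardGeneric("runOrder"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("subjectAge", function(x, ...) standardGeneric("subjectAge"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("subjectGender", function(x, ...) standardGeneric("subjectGender"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("injectionVolume", function(x, ...) standardGeneric("injectionVolume"))

#' @rdname BorutaResult-accessors
#' @export
setGeneric("decisions", function(x, ...) standardGeneric("decisions"))

#' @rdname BorutaResult-accessors
#' @export
setGeneric("confirmedFeatures", function(x, ...) standardGeneric("confirmedFeatures"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("constrainedFraction", function(x, ...) standardGeneric("constrainedFraction"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("siteScores", function(x, ...) standardGeneric("siteScores"))

#' @rdname OrdinationResult-accessors
#' @export
setGeneric("eigenvalues", function(x, ...) standardGeneric("eigenvalues"))

#' @rdname FilterReport-accessors
#' @export
setGeneric("removedFeatures", function(x, ...) standardGeneric("removedFeatures"))
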