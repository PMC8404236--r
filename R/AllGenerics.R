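#' @import methods
NULL

#' @rdname VariantPanel-class
#' @param x a \linkS4class{VariantPanel} or \linkS4class{AmpliconPanel}.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname VariantPanel-class
#' @export
setGeneric("variantType", function(x) standardGeneric("variantType"))

#' @rdname VariantPanel-class
#' @export
setGeneric("isGenotypable", function(x) standardGeneric("isGenotypable"))

#' @rdname AmpliconPanel-class
#' @export
setGeneric("ampliconSeqs", function(x) standardGeneric("ampliconSeqs"))

#' @rdname AmpliconPanel-class
#' @export
setGeneric("decoyReference", function(x) standardGeneric("decoyReference"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("truthGenotypes", function(x) standardGeneric("truthGenotypes"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("frdaAlleles", function(x) standardGeneric("frdaAlleles"))

#' @rdname RepeatReadStats-class
#' @param x a \linkS4class{RepeatReadStats} or \linkS4class{FrdaCall}.
#' @export
setGeneric("top3Rprf", function(x) standardGeneric("top3Rprf"))

#' @rdname RepeatReadStats-class
#' @export
setGeneric("repeatReadCount", function(x) standardGeneric("repeatReadCount"))

#' @rdname RepeatReadStats-class
#' @export
setGeneric("totalRepeats", function(x) standardGeneric("totalRepeats"))

#' @rdname RepeatReadStats-class
#' @export
setGeneric("perReadRepeats", function(x) standardGeneric("perReadRepeats"))

#' @rdname FrdaCall-class
#' @export
setGeneric("isCarrier", function(x) standardGeneric("isCarrier"))

#' @rdname CarrierScreenExperiment-class
#' @param x a \linkS4class{CarrierScreenExperiment}.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname CarrierScreenExperiment-class
#' @export
setGeneric("frdaCalls", function(x) standardGeneric("frdaCalls"))
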