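#' @rdname ExpressionCounts-class
#' @param x an object.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname ExpressionCounts-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname OrthologTable-class
#' @param x an object.
#' @export
setGeneric("orthologRecords", function(x) standardGeneric("orthologRecords"))

#' @rdname MappingCatalog-class
#' @param x an object.
#' @export
setGeneric("flyGenes", function(x) standardGeneric("flyGenes"))

#' @rdname MappingCatalog-class
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname CorrelationMatrix-class
#' @param x an object.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname ModuleSet-class
#' @param x an object.
#' @export
setGeneric("modules", function(x) standardGeneric("modules"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleTable", function(x) standardGeneric("moduleTable"))

#' @rdname TermCollection-class
#' @param x an object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname TermCollection-class
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))

#' @rdname SeizureTimeCourse-class
#' @param x an object.
#' @export
setGeneric("timeCourseData", function(x) standardGeneric("timeCourseData"))

#' @rdname SigmoidFit-class
#' @param x an object.
#' @export
setGeneric("t50", function(x) standardGeneric("t50"))
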