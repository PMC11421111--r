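#' @import methods
NULL

#' @rdname CompoundSet-class
#' @param x a `CompoundSet`, `PatternSet` or `OccurrenceMatrix` object.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname CompoundSet-class
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))

#' @rdname CompoundSet-class
#' @export
setGeneric("chemClasses", function(x) standardGeneric("chemClasses"))

#' @rdname CompoundSet-class
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @rdname CompoundSet-class
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))

#' @rdname PatternSet-class
#' @param x a `PatternSet` or `OccurrenceMatrix` object.
#' @export
setGeneric("patternIds", function(x) standardGeneric("patternIds"))

#' @rdname PatternSet-class
#' @export
setGeneric("patternSmarts", function(x) standardGeneric("patternSmarts"))

#' @rdname PatternSet-class
#' @export
setGeneric("flexibility", function(x) standardGeneric("flexibility"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname ScreeningResult-class
#' @param x a `ScreeningResult` object.
#' @export
setGeneric("scaffoldCounts", function(x) standardGeneric("scaffoldCounts"))

#' @rdname ScreeningResult-class
#' @export
setGeneric("rankedLists", function(x) standardGeneric("rankedLists"))

#' @rdname ScreeningResult-class
#' @export
setGeneric("screeningHits", function(x) standardGeneric("screeningHits"))
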