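#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics: `symptomValues()` and `positiveScore()` read the
#' observation matrix and the per-sample score of a [SymptomTable-class] (or
#' of the table inside a [SyndromeHierarchy-class]); `syndromeValues()`
#' returns the samples x groups syndrome matrix; `groupNames()` and
#' `groupSizes()` describe a [SyndromeGrouping-class]; `bestPosition()`,
#' `bestFitness()` and `fitnessTrace()` read a [SwarmFit-class].
#'
#' @param x an object of the documented class.
#' @return The accessed component (matrix, numeric vector or character
#'   vector as appropriate).
#' @name accessors
#' @aliases symptomValues positiveScore syndromeValues groupNames groupSizes
#'   bestPosition bestFitness fitnessTrace
NULL

#' @rdname accessors
#' @export
setGeneric("symptomValues", function(x) standardGeneric("symptomValues"))

#' @rdname accessors
#' @export
setGeneric("positiveScore", function(x) standardGeneric("positiveScore"))

#' @rdname accessors
#' @export
setGeneric("syndromeValues", function(x) standardGeneric("syndromeValues"))

#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname accessors
#' @export
setGeneric("bestPosition", function(x) standardGeneric("bestPosition"))

#' @rdname accessors
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @rdname accessors
#' @export
setGeneric("fitnessTrace", function(x) standardGeneric("fitnessTrace"))
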