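#' @name endemicity-generics
#' @title Accessor generics
#' @description Accessors for the S4 result and data classes.
#' @param x,object an object of the documented class.
#' @param ... passed to methods.
NULL

#' @rdname endemicity-generics
#' @export
setGeneric("speciesIDs", function(x) standardGeneric("speciesIDs"))

#' @rdname endemicity-generics
#' @export
setGeneric("areaIDs", function(x) standardGeneric("areaIDs"))

#' @rdname endemicity-generics
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' Per-area species richness
#'
#' Counts, for every area, the number of species scored as present: the
#' column sums of the incidence matrix.
#'
#' @param x an [IncidenceMatrix-class].
#' @return Named integer vector, one count per area.
#' @export
#' @examples
#' m <- IncidenceMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("sp1", "sp2"), c("A", "B"))))
#' richness(m)
setGeneric("richness", function(x) standardGeneric("richness"))

#' @rdname endemicity-generics
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname endemicity-generics
#' @export
setGeneric("searchTrees", function(x) standardGeneric("searchTrees"))

#' @rdname endemicity-generics
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' @rdname endemicity-generics
#' @export
setGeneric("consensusPhylo", function(x) standardGeneric("consensusPhylo"))

#' @rdname endemicity-generics
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname endemicity-generics
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' @rdname endemicity-generics
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname endemicity-generics
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))

#' @rdname endemicity-generics
#' @export
setGeneric("modelStats", function(x) standardGeneric("modelStats"))

#' @rdname endemicity-generics
#' @export
setGeneric("trueClades", function(x) standardGeneric("trueClades"))
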