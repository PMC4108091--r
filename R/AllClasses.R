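#' Binary species-by-area incidence matrix
#'
#' The character matrix of a Parsimony Analysis of Endemicity: rows are
#' species, columns are areas (e.g. freshwater ecoregions), and each cell
#' scores the species as present (1) or absent (0) in the area.
#'
#' @slot presence integer matrix of 0/1 with species as rownames and areas
#'   as colnames.
#'
#' @seealso [readIncidence()], [richness()], [writeNexus()],
#'   [dropUninformative()]
#' @export
setClass("IncidenceMatrix", representation(presence = "matrix"))

setValidity("IncidenceMatrix", function(object) {
  p <- object@presence
  msg <- character()
  if (!is.numeric(p)) msg <- c(msg, "presence must be a numeric 0/1 matrix")
  else if (!all(p %in% c(0, 1))) msg <- c(msg, "presence entries must be exactly 0 or 1")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "presence needs species rownames and area colnames")
  else {
    if (anyDuplicated(rownames(p)))
      msg <- c(msg, sprintf("duplicate species label: %s",
                            rownames(p)[duplicated(rownames(p))][1L]))
    if (anyDuplicated(colnames(p)))
      msg <- c(msg, sprintf("duplicate area label: %s",
                            colnames(p)[duplicated(colnames(p))][1L]))
  }
  if (nrow(p) < 1L) msg <- c(msg, "need at least 1 species")
  if (ncol(p) < 2L) msg <- c(msg, "need at least 2 areas")
  if (length(msg)) msg else TRUE
})

#' Result of a parsimony tree search over areas
#'
#' Holds the best tree length found, the retained distinct topologies
#' (each an [ape::phylo] over the areas plus the all-absent outgroup),
#' their lengths, and the search provenance.
#'
#' @slot bestScore integer, minimum Fitch length found.
#' @slot trees list of `phylo` objects, topologically distinct.
#' @slot scores numeric, Fitch length of each retained tree.
#' @slot keys character, canonical topology identifiers used for
#'   deduplication.
#' @slot replicatesRun integer, number of addition-sequence replicates.
#' @slot seed integer, run-level seed (`NA` when the caller managed the RNG).
#'
#' @seealso [heuristicSearch()], [exhaustiveSearch()], [tbrSearch()]
#' @export
setClass("SearchResult",
         representation(bestScore = "integer", trees = "list",
                        scores = "numeric", keys = "character",
                        replicatesRun = "integer", seed = "integer"))

setValidity("SearchResult", function(object) {
  msg <- character()
  if (length(object@trees) != length(object@scores) ||
      length(object@trees) != length(object@keys))
    msg <- c(msg, "trees, scores and keys must have equal length")
  if (anyDuplicated(object@keys))
    msg <- c(msg, "retained trees must be topologically distinct")
  if (length(object@scores) && any(object@scores < object@bestScore))
    msg <- c(msg, "no retained tree may score below bestScore")
  if (length(msg)) msg else TRUE
})

#' Majority-rule consensus area tree
#'
#' A possibly polytomous rooted tree over the ingroup areas (rooting given
#' by the all-absent outgroup), with each retained clade annotated by the
#' percentage of input trees containing it.
#'
#' @slot tree rooted `phylo` over the areas; internal node labels carry the
#'   support percentages.
#' @slot support numeric vector of clade support percentages in (50, 100],
#'   named by the sorted, comma-joined area labels of each clade.
#' @slot cutoff numeric, the frequency cutoff used (default 0.5).
#' @slot nTrees integer, number of input trees.
#'
#' @seealso [majorityRuleConsensus()]
#' @export
setClass("ConsensusTree",
         representation(tree = "ANY", support = "numeric",
                        cutoff = "numeric", nTrees = "integer"))

setValidity("ConsensusTree", function(object) {
  msg <- character()
  if (length(object@support) &&
      (any(object@support <= 100 * object@cutoff) || any(object@support > 100)))
    msg <- c(msg, "clade support must lie in (100*cutoff, 100]")
  if (length(msg)) msg else TRUE
})

#' Bivariate points for a constraint-envelope test
#'
#' Pairs of an environmental value `x` and a species richness `y` per area,
#' the input of the Boundary Sum of Squares test.
#'
#' @slot x numeric, environmental variable per area.
#' @slot y numeric, species richness per area.
#' @slot labels character, area identifiers.
#'
#' @seealso [bssTest()], [envelopePoints()]
#' @export
setClass("EnvelopePoints",
         representation(x = "numeric", y = "numeric", labels = "character"))

setValidity("EnvelopePoints", function(object) {
  msg <- character()
  n <- length(object@x)
  if (length(object@y) != n || length(object@labels) != n)
    msg <- c(msg, "x, y and labels must have equal length")
  if (n < 3L) msg <- c(msg, "need at least 3 points")
  if (anyNA(object@x) || anyNA(object@y)) msg <- c(msg, "x and y must be finite")
  else {
    if (diff(range(object@x)) <= 0) msg <- c(msg, "x has zero range")
    if (diff(range(object@y)) <= 0) msg <- c(msg, "y has zero range")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a Boundary Sum of Squares test
#'
#' @slot observedStat numeric, mean (power-transformed) distance of points
#'   outside the triangular envelope to its hypotenuse.
#' @slot nOutside integer, number of points strictly outside the triangle.
#' @slot nullStats numeric, the randomization null distribution.
#' @slot pValue numeric, one-sided add-one permutation p-value.
#' @slot triangle 3x2 matrix of triangle vertices (standardized scale when
#'   standardization is on).
#' @slot config list echoing the test configuration.
#'
#' @seealso [bssTest()]
#' @export
setClass("BssResult",
         representation(observedStat = "numeric", nOutside = "integer",
                        nullStats = "numeric", pValue = "numeric",
                        triangle = "matrix", config = "list"))

setValidity("BssResult", function(object) {
  msg <- character()
  N <- length(object@nullStats)
  expect <- (1 + sum(object@nullStats <= object@observedStat)) / (1 + N)
  if (N && abs(object@pValue - expect) > 1e-12)
    msg <- c(msg, "pValue must follow the add-one rule")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (object@observedStat < 0) msg <- c(msg, "observedStat must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multiple-regression fit of species richness on its candidate correlates
#'
#' @slot coefficients data.frame with columns term, estimate, std_error,
#'   t_value, p_value (intercept first, then predictors in standard order).
#' @slot fStatistic numeric, overall model F.
#' @slot modelP numeric, p-value of the overall F test.
#' @slot r2 numeric, coefficient of determination.
#' @slot adjR2 numeric, adjusted R-squared.
#' @slot residualDf integer.
#' @slot n integer, number of areas used.
#' @slot fit the underlying `lm` object.
#'
#' @seealso [fitOls()], [buildDesign()]
#' @export
setClass("RichnessFit",
         representation(coefficients = "data.frame", fStatistic = "numeric",
                        modelP = "numeric", r2 = "numeric", adjR2 = "numeric",
                        residualDf = "integer", n = "integer", fit = "ANY"))

setValidity("RichnessFit", function(object) {
  msg <- character()
  if (object@adjR2 > object@r2 + 1e-12) msg <- c(msg, "adjusted R2 must be <= R2")
  if (object@fStatistic < 0) msg <- c(msg, "F must be >= 0")
  k <- nrow(object@coefficients) - 1L
  if (object@n != object@residualDf + k + 1L)
    msg <- c(msg, "n must equal residual df + #predictors + 1")
  if (length(msg)) msg else TRUE
})

#' Planted truth of a synthetic biogeographical dataset
#'
#' Records everything a recovery test needs: the true area cladogram, its
#' nontrivial ingroup clades, the occurrence-noise parameters, and any
#' planted envelope or species-area parameters.
#'
#' @slot tree unrooted `phylo` over the areas plus the all-absent outgroup.
#' @slot clades list of character vectors: the nontrivial ingroup clades of
#'   the outgroup-rooted view.
#' @slot noise named numeric: `eps01` (false-presence rate), `eps10`
#'   (false-absence rate), `w` (widespread-species fraction).
#' @slot envelope list with slope, intercept, noiseSd, or empty.
#' @slot sar list with c, z, noiseSd, or empty.
#' @slot seed integer seed recorded at creation.
#'
#' @seealso [simulateAreaCladogram()], [simulateIncidence()]
#' @export
setClass("SyntheticTruth",
         representation(tree = "ANY", clades = "list", noise = "numeric",
                        envelope = "list", sar = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  nz <- object@noise
  if (!all(c("eps01", "eps10", "w") %in% names(nz)))
    msg <- c(msg, "noise must name eps01, eps10 and w")
  else if (any(nz < 0) || any(nz[c("eps01", "eps10")] >= 1) || nz["w"] > 1)
    msg <- c(msg, "noise rates must lie in [0, 1) (w in [0, 1])")
  if (length(msg)) msg else TRUE
})
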