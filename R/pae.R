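# Internal glue between the compiled search core (leaf 1 = outgroup,
# leaves 2..L = areas in matrix column order) and ape phylo objects.

# leaf labels in core order
.leafLabels <- function(x) c(paeOutgroupLabel(), areaIDs(x))

# character-state bitmask matrix: nchar x L, 1 = {0}, 2 = {1}
.stateMatrix <- function(x) {
  p <- presenceMatrix(x)
  cbind(rep(1L, nrow(p)), p + 1L)
}

# edge-list (node-pair matrix) -> phylo, via a placeholder newick string
.edgesToPhylo <- function(edges, labels) {
  nn <- max(edges)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  rec <- function(u, p) {
    kids <- setdiff(adj[[u]], p)
    if (!length(kids)) return(sprintf("t%d", u))
    paste0("(", paste(vapply(kids, rec, "", p = u), collapse = ","), ")")
  }
  hub <- adj[[1L]][1L]
  txt <- paste0("(t1,",
                paste(vapply(setdiff(adj[[hub]], 1L), rec, "", p = hub),
                      collapse = ","), ");")
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
  tr
}

# phylo -> edge list in core numbering; errors on label mismatch
.phyloToEdges <- function(tree, labels) {
  tr <- ape::unroot(ape::collapse.singles(tree))
  tips <- tr$tip.label
  extra <- setdiff(tips, labels)
  missing <- setdiff(labels, tips)
  if (length(extra) || length(missing))
    stop("tree/matrix leaf mismatch; only in tree: {",
         paste(extra, collapse = ", "), "}; only in matrix/outgroup: {",
         paste(missing, collapse = ", "), "}")
  L <- length(labels)
  ntip <- length(tips)
  map <- integer(max(tr$edge))
  map[seq_len(ntip)] <- match(tips, labels)
  inner <- sort(unique(as.vector(tr$edge)))
  inner <- inner[inner > ntip]
  map[inner] <- L + seq_along(inner)
  cbind(map[tr$edge[, 1L]], map[tr$edge[, 2L]])
}

.asSearchResult <- function(best, trees, scores, keys, labels, replicates,
                            seed) {
  new("SearchResult", bestScore = as.integer(best),
      trees = lapply(trees, .edgesToPhylo, labels = labels),
      scores = as.numeric(scores), keys = as.character(keys),
      replicatesRun = as.integer(replicates),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname endemicity-generics
#' @export
setMethod("bestScore", "SearchResult", function(x) x@bestScore)

#' @rdname endemicity-generics
#' @export
setMethod("searchTrees", "SearchResult", function(x) x@trees)

setMethod("show", "SearchResult", function(object) {
  cat(sprintf(
    "SearchResult: best length %d, %d distinct tree(s), %d replicate(s)\n",
    object@bestScore, length(object@trees), object@replicatesRun))
})

#' Fitch parsimony length of an area tree
#'
#' Sums, over species, the minimum number of presence/absence state changes
#' the tree requires (Fitch optimization for an unordered binary character).
#' The hypothetical all-absent outgroup is one of the leaves; the returned
#' length does not depend on where the tree is rooted.
#'
#' @param tree a `phylo` whose tip set is the areas of `x` plus
#'   [paeOutgroupLabel()].
#' @param x an [IncidenceMatrix-class].
#' @return Integer tree length.
#' @export
#' @examples
#' m <- IncidenceMatrix(matrix(c(1, 1, 0, 0), 1, 4,
#'   dimnames = list("sp1", LETTERS[1:4])))
#' tr <- ape::read.tree(text = "((A,B),(C,D),ROOT_ALL_ABSENT);")
#' fitchLength(tr, m)   # one gain on the (A,B) cherry
fitchLength <- function(tree, x) {
  labels <- .leafLabels(x)
  edges <- .phyloToEdges(tree, labels)
  cpp_fitch(edges, .stateMatrix(x), length(labels))
}

#' Stepwise-addition starting tree
#'
#' Builds a tree greedily: the outgroup and the first two areas of the
#' addition sequence form the initial star, and each subsequent area is
#' inserted on the attachment edge minimizing the Fitch length.  Ties are
#' broken uniformly at random, so a seed makes the tree reproducible.
#'
#' @param x an [IncidenceMatrix-class] with at least 3 areas.
#' @param order permutation of `areaIDs(x)` giving the addition sequence;
#'   `NULL` (default) draws a random sequence.
#' @param seed optional integer seed applied before any random draw.
#' @return A `phylo` over the areas plus the outgroup.
#' @export
stepwiseAddition <- function(x, order = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- areaIDs(x)
  if (length(ids) < 3L) stop("need at least 3 areas (no tree space below 4 leaves)")
  if (is.null(order)) order <- sample(ids)
  if (!identical(sort(order), sort(ids)))
    stop("order must be a permutation of the area ids")
  leafOrder <- c(1L, match(order, ids) + 1L)
  res <- cpp_stepwise(.stateMatrix(x), leafOrder, length(ids) + 1L)
  .edgesToPhylo(res$edges, .leafLabels(x))
}

#' TBR branch swapping from a starting tree
#'
#' Hill-climbs over tree-bisection-reconnection neighborhoods: every edge is
#' bisected and the two fragments reconnected across all pairs of their
#' edges.  Strict improvements are accepted (ties among equally best
#' neighbors broken at random) until no neighbor is shorter; up to `keep`
#' distinct topologies tied at the final best length are retained.
#'
#' @param start a `phylo` over the areas plus outgroup.
#' @param x an [IncidenceMatrix-class].
#' @param keep maximum number of retained topologies (default 100).
#' @param seed optional integer seed.
#' @return A [SearchResult-class].
#' @export
tbrSearch <- function(start, x, keep = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- .leafLabels(x)
  edges <- .phyloToEdges(start, labels)
  res <- cpp_tbr(edges, .stateMatrix(x), length(labels), as.integer(keep))
  .asSearchResult(res$best_score, res$trees,
                  rep(res$best_score, length(res$trees)), res$keys,
                  labels, 1L, seed)
}

#' Heuristic parsimony search over area trees
#'
#' The standard PAE search protocol: `replicates` random-addition-sequence
#' starts, each refined by TBR branch swapping; every replicate retains up
#' to `keep` distinct topologies tied at its best length, and the retained
#' trees are pooled across replicates with topological deduplication.
#'
#' @param x an [IncidenceMatrix-class].
#' @param replicates number of random addition sequences (default 1000, the
#'   conventional protocol; small analyses need far fewer).
#' @param keep per-replicate retained-tree cap (default 100).
#' @param seed run-level integer seed; all randomness (addition sequences
#'   and tie breaks) flows from it, making the result bit-reproducible.
#' @return A [SearchResult-class]; `bestScore` is the global minimum over
#'   replicates and `searchTrees` the pooled distinct topologies with their
#'   per-replicate scores.
#' @export
heuristicSearch <- function(x, replicates = 1000, keep = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- areaIDs(x)
  if (length(ids) < 3L) stop("need at least 3 areas")
  S <- .stateMatrix(x)
  L <- length(ids) + 1L
  labels <- .leafLabels(x)
  best <- Inf
  pooledKeys <- character()
  pooledTrees <- list()
  pooledScores <- numeric()
  for (r in seq_len(replicates)) {
    leafOrder <- c(1L, sample(2:L))
    st <- cpp_stepwise(S, leafOrder, L)
    tb <- cpp_tbr(st$edges, S, L, as.integer(keep))
    best <- min(best, tb$best_score)
    newKeys <- as.character(tb$keys)
    fresh <- !(newKeys %in% pooledKeys)
    if (any(fresh)) {
      pooledKeys <- c(pooledKeys, newKeys[fresh])
      pooledTrees <- c(pooledTrees, tb$trees[fresh])
      pooledScores <- c(pooledScores, rep(tb$best_score, sum(fresh)))
    }
  }
  .asSearchResult(best, pooledTrees, pooledScores, pooledKeys, labels,
                  replicates, seed)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted binary topology over the areas plus outgroup
#' ((2n-5)!! trees for n leaves) and returns the exact minimum Fitch length
#' with all optimal topologies.  Refuses more than 9 areas, where the tree
#' space (2,027,025 topologies at 10 leaves) makes enumeration the wrong
#' tool.
#'
#' @param x an [IncidenceMatrix-class] with 3 to 9 areas.
#' @param maxStore cap on stored optimal trees (default 10000).
#' @return A [SearchResult-class] whose `replicatesRun` is 0 and whose
#'   `seed` is `NA`; the attribute `nExamined` records the number of
#'   topologies enumerated.
#' @export
exhaustiveSearch <- function(x, maxStore = 10000) {
  ids <- areaIDs(x)
  if (length(ids) > 9L)
    stop("exhaustive search refused beyond 9 areas ",
         "(10 leaves already span 2,027,025 unrooted topologies)")
  if (length(ids) < 3L) stop("need at least 3 areas")
  res <- cpp_exhaustive(.stateMatrix(x), length(ids) + 1L,
                        as.integer(maxStore))
  out <- .asSearchResult(res$best_score, res$trees,
                         rep(res$best_score, length(res$trees)), res$keys,
                         .leafLabels(x), 0L, NULL)
  attr(out, "nExamined") <- res$n_examined
  out
}
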