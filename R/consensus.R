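# clade sets (area-label vectors) of the outgroup-rooted view of one tree
.ingroupClades <- function(tree, labels) {
  edges <- .phyloToEdges(tree, labels)
  L <- length(labels)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(nn)
  order <- integer(0)
  stk <- 1L
  parent[1L] <- -1L
  while (length(stk)) {
    u <- stk[length(stk)]
    stk <- stk[-length(stk)]
    order <- c(order, u)
    for (v in adj[[u]]) if (v != parent[u]) {
      parent[v] <- u
      stk <- c(stk, v)
    }
  }
  below <- vector("list", nn)
  for (i in rev(seq_along(order))) {
    u <- order[i]
    if (u <= L) below[[u]] <- u
    p <- parent[u]
    if (p > 0L) below[[p]] <- c(below[[p]], below[[u]])
  }
  out <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    if (a > L && b > L) {
      child <- if (parent[a] == b) a else b
      out[[length(out) + 1L]] <- sort(labels[below[[child]]])
    }
  }
  out
}

.treeList <- function(trees) {
  if (is(trees, "SearchResult")) return(trees@trees)
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (inherits(trees, "phylo")) return(list(trees))
  trees
}

#' Majority-rule consensus of area trees
#'
#' Counts, across the input trees, every clade of the outgroup-rooted view
#' and keeps exactly those occurring in more than `cutoff` of the trees;
#' for `cutoff >= 0.5` the retained clades are mutually compatible and
#' assemble into a unique (possibly polytomous) consensus tree over the
#' ingroup areas.  Each clade is annotated with its percentage frequency,
#' rounded to 1 decimal.
#'
#' @param trees a [SearchResult-class], a `multiPhylo`, or a list of
#'   `phylo` objects sharing one leaf set (areas plus outgroup).
#' @param cutoff frequency cutoff, default 0.5 (strict majority).
#' @return A [ConsensusTree-class].
#' @export
majorityRuleConsensus <- function(trees, cutoff = 0.5) {
  trees <- .treeList(trees)
  if (!length(trees)) stop("no trees supplied")
  if (cutoff < 0.5) stop("cutoff below 0.5 can select incompatible clades")
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees[-1L]) {
    if (!identical(sort(tr$tip.label), ref))
      stop("mismatched leaf sets among input trees; differing labels: ",
           paste(union(setdiff(sort(tr$tip.label), ref),
                       setdiff(ref, sort(tr$tip.label))), collapse = ", "))
  }
  og <- paeOutgroupLabel()
  if (!og %in% ref)
    stop("trees must include the outgroup leaf '", og, "'")
  areas <- setdiff(ref, og)
  labels <- c(og, areas)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (cl in .ingroupClades(tr, labels)) {
      key <- paste(cl, collapse = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  n <- length(trees)
  keys <- ls(counts, all.names = TRUE)
  freq <- vapply(keys, function(k) counts[[k]], 0L)
  keep <- freq / n > cutoff
  clades <- lapply(strsplit(keys[keep], "\r", fixed = TRUE), identity)
  support <- round(100 * freq[keep] / n, 1)
  names(support) <- vapply(clades, paste, "", collapse = ",")
  supLab <- function(s) sub("\\.0$", "", sprintf("%.1f", s))
  build <- function(set, pool, sup) {
    inside <- pool[vapply(pool, function(cl)
      length(cl) < length(set) && all(cl %in% set), TRUE)]
    isMax <- vapply(seq_along(inside), function(i)
      !any(vapply(seq_along(inside), function(j)
        j != i && all(inside[[i]] %in% inside[[j]]), TRUE)), TRUE)
    maxcl <- inside[isMax]
    singles <- setdiff(set, unlist(maxcl))
    parts <- c(
      vapply(maxcl, function(cl) {
        key <- paste(cl, collapse = ",")
        paste0(build(cl, inside, sup), supLab(sup[[key]]))
      }, ""),
      .quoteLabel(singles))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(areas, clades, support), ";")
  tree <- ape::read.tree(text = txt)
  new("ConsensusTree", tree = tree, support = support,
      cutoff = cutoff, nTrees = as.integer(n))
}

#' @rdname endemicity-generics
#' @export
setMethod("supportValues", "ConsensusTree", function(x) x@support)

#' @rdname endemicity-generics
#' @export
setMethod("consensusPhylo", "ConsensusTree", function(x) x@tree)

setMethod("show", "ConsensusTree", function(object) {
  cat(sprintf(
    "ConsensusTree over %d areas: %d clade(s) above %.0f%% in %d trees\n",
    length(object@tree$tip.label), length(object@support),
    100 * object@cutoff, object@nTrees))
})

#' Write a tree as Newick text
#'
#' Emits a single-line Newick string with clade supports (when present) as
#' internal node labels.  Labels containing spaces or other non-word
#' characters -- common among ecoregion names -- are single-quoted, with
#' embedded quotes doubled.
#'
#' @param tree a `phylo` or [ConsensusTree-class].
#' @param path optional output file; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
writeNewick <- function(tree, path = NULL) {
  if (is(tree, "ConsensusTree")) tree <- tree@tree
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    if (node <= nt) return(.quoteLabel(tree$tip.label[node]))
    lab <- ""
    if (!is.null(tree$node.label)) {
      nl <- tree$node.label[node - nt]
      if (!is.na(nl) && nzchar(nl)) lab <- nl
    }
    paste0("(", paste(vapply(kids[[as.character(node)]], rec, ""),
                      collapse = ","), ")", lab)
  }
  txt <- paste0(rec(nt + 1L), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
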