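# Independent oracles and fixture builders used across the test files.

# random binary incidence matrix
randomIncidence <- function(nSpecies, nAreas, p = 0.4,
                            areaIds = sprintf("A%02d", seq_len(nAreas))) {
  m <- matrix(as.integer(runif(nSpecies * nAreas) < p), nSpecies, nAreas,
              dimnames = list(sprintf("sp%03d", seq_len(nSpecies)), areaIds))
  IncidenceMatrix(m)
}

# Brute-force parsimony length: per species, enumerate every assignment of
# 0/1 to the internal nodes and count mismatched edges (Sankoff by
# exhaustion).  Independent of the Fitch implementation under test.
bruteForceLength <- function(tree, m) {
  p <- presenceMatrix(m)
  ed <- tree$edge
  nt <- length(tree$tip.label)
  ni <- max(ed) - nt
  grid <- as.matrix(expand.grid(rep(list(0:1), ni)))
  og <- paeOutgroupLabel()
  total <- 0L
  for (s in seq_len(nrow(p))) {
    tipState <- vapply(tree$tip.label, function(lab)
      if (lab == og) 0L else p[s, lab], 0L)
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      ns <- c(tipState, grid[g, ])
      best <- min(best, sum(ns[ed[, 1]] != ns[ed[, 2]]))
    }
    total <- total + as.integer(best)
  }
  total
}

# naive per-area recount by explicit loop
naiveRichness <- function(m) {
  p <- presenceMatrix(m)
  out <- integer(ncol(p))
  names(out) <- colnames(p)
  for (j in seq_len(ncol(p)))
    for (i in seq_len(nrow(p)))
      out[j] <- out[j] + p[i, j]
  out
}

# an arbitrary binary tree (with outgroup tip) over the areas of m
randomAreaTree <- function(m, seed = NULL) {
  simulateAreaCladogram(length(areaIDs(m)), seed = seed,
                        areaIds = areaIDs(m))
}

writeTempIncidence <- function(text) {
  tf <- tempfile(fileext = ".csv")
  writeLines(text, tf)
  tf
}
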