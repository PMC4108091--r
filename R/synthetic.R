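# Seeded generators that plant known structure -- an area cladogram with
# endemic species, a species-area relationship, a climatic constraint
# envelope -- so every analysis stage has a recovery-testable input.

#' Simulate a random area cladogram
#'
#' Draws a uniform random unrooted binary topology over `nAreas` labelled
#' areas plus the all-absent outgroup, by inserting each leaf on a
#' uniformly chosen edge of the growing tree.
#'
#' @param nAreas number of areas, at least 3.
#' @param seed optional integer seed.
#' @param areaIds optional area labels (default `A01`, `A02`, ...).
#' @return A `phylo` with `nAreas + 1` tips including
#'   [paeOutgroupLabel()].
#' @export
simulateAreaCladogram <- function(nAreas, seed = NULL, areaIds = NULL) {
  if (nAreas < 3L) stop("need at least 3 areas")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(areaIds)) areaIds <- sprintf("A%02d", seq_len(nAreas))
  if (length(areaIds) != nAreas || anyDuplicated(areaIds))
    stop("areaIds must be nAreas distinct labels")
  L <- nAreas + 1L
  edges <- rbind(c(1L, L + 1L), c(2L, L + 1L), c(3L, L + 1L))
  for (k in 4:L) {
    w <- L + k - 2L
    i <- sample.int(nrow(edges), 1L)
    old <- edges[i, ]
    edges[i, ] <- c(old[1L], w)
    edges <- rbind(edges, c(w, old[2L]), c(w, k))
  }
  .edgesToPhylo(edges, c(paeOutgroupLabel(), areaIds))
}

#' Create a synthetic-truth record
#'
#' Bundles a true area cladogram with occurrence-noise and optional
#' envelope / species-area parameters; [simulateIncidence()] consumes it
#' and recovery tests compare analysis output against it.
#'
#' @param tree a `phylo` over areas plus outgroup, e.g. from
#'   [simulateAreaCladogram()].
#' @param eps01 false-presence rate: probability a true absence is flipped
#'   to presence (default 0).
#' @param eps10 false-absence rate: probability a true presence is flipped
#'   to absence (default 0).
#' @param w fraction of species that are widespread-random instead of
#'   clade-endemic (default 0).
#' @param envelope optional list(slope, intercept, noiseSd).
#' @param sar optional list(c, z, noiseSd).
#' @param seed integer seed recorded with the truth (default 1).
#' @return A [SyntheticTruth-class]; its `clades` slot holds the
#'   nontrivial ingroup clades of the outgroup-rooted tree.
#' @export
syntheticTruth <- function(tree, eps01 = 0, eps10 = 0, w = 0,
                           envelope = list(), sar = list(), seed = 1L) {
  og <- paeOutgroupLabel()
  if (!og %in% tree$tip.label)
    stop("tree must include the outgroup leaf '", og, "'")
  areas <- setdiff(tree$tip.label, og)
  labels <- c(og, areas)
  new("SyntheticTruth", tree = tree,
      clades = .ingroupClades(tree, labels),
      noise = c(eps01 = eps01, eps10 = eps10, w = w),
      envelope = envelope, sar = sar, seed = as.integer(seed))
}

#' @rdname endemicity-generics
#' @export
setMethod("trueClades", "SyntheticTruth", function(x) x@clades)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d areas, %d nontrivial clades, eps01 = %g, eps10 = %g, w = %g\n",
    length(object@tree$tip.label) - 1L, length(object@clades),
    object@noise["eps01"], object@noise["eps10"], object@noise["w"]))
})

#' Simulate an incidence matrix from a known cladogram
#'
#' Each species is an endemic of one uniformly chosen nontrivial clade of
#' the true tree (present exactly in the clade's areas, a synapomorphy); a
#' fraction `w` of species is instead widespread-random (independent
#' Bernoulli(0.5) per area).  Cell-wise i.i.d. occurrence noise is then
#' applied: absences flip to presences with rate `eps01` and presences to
#' absences with rate `eps10`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nSpecies number of species to generate.
#' @param seed optional integer seed; defaults to the seed recorded in
#'   `truth`.
#' @return An [IncidenceMatrix-class] (species `sp001`, `sp002`, ...).
#' @export
simulateIncidence <- function(truth, nSpecies, seed = NULL) {
  set.seed(if (is.null(seed)) truth@seed else seed)
  areas <- setdiff(truth@tree$tip.label, paeOutgroupLabel())
  nA <- length(areas)
  eps01 <- truth@noise[["eps01"]]
  eps10 <- truth@noise[["eps10"]]
  w <- truth@noise[["w"]]
  p <- matrix(0L, nSpecies, nA,
              dimnames = list(sprintf("sp%03d", seq_len(nSpecies)), areas))
  widespread <- runif(nSpecies) < w
  cladeIdx <- sample.int(length(truth@clades), nSpecies, replace = TRUE)
  for (i in seq_len(nSpecies)) {
    if (widespread[i]) {
      p[i, ] <- as.integer(runif(nA) < 0.5)
    } else {
      p[i, truth@clades[[cladeIdx[i]]]] <- 1L
    }
  }
  if (eps01 > 0 || eps10 > 0) {
    flip <- matrix(runif(length(p)), nrow(p))
    p <- ifelse(p == 1L, ifelse(flip < eps10, 0L, 1L),
                ifelse(flip < eps01, 1L, 0L))
    dimnames(p) <- list(sprintf("sp%03d", seq_len(nSpecies)), areas)
  }
  IncidenceMatrix(p)
}

#' Simulate points under a (possibly planted) constraint envelope
#'
#' With `constrained = TRUE`, x is uniform on (0, 1) and y uniform between
#' 0 and the envelope line `slope * x + intercept`, plus Gaussian noise of
#' sd `noiseSd` (y clipped at 0) -- the upper-boundary pattern in which a
#' variable caps richness without predicting it.  With
#' `constrained = FALSE`, y is uniform on (0, 1) independent of x, the
#' null of no constraint.
#'
#' @param n number of points.
#' @param slope,intercept envelope line parameters (defaults 1 and 0).
#' @param noiseSd Gaussian jitter sd (default 0.05).
#' @param constrained plant the envelope (default `TRUE`)?
#' @param seed optional integer seed.
#' @return An [EnvelopePoints-class].
#' @export
simulateEnvelope <- function(n, slope = 1, intercept = 0, noiseSd = 0.05,
                             constrained = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n)
  y <- if (constrained) {
    cap <- pmax(0, slope * x + intercept)
    pmax(runif(n, 0, cap) + rnorm(n, 0, noiseSd), 0)
  } else {
    runif(n)
  }
  envelopePoints(x, y)
}

#' Simulate a species-area dataset with known slope
#'
#' Areas are log-uniform over four orders of magnitude (10 to 1e5 km^2);
#' richness follows `c + z * log(area)` plus Gaussian noise, floored at 0
#' and rounded to whole species on the raw scale.  The remaining seven
#' covariates are drawn independently of richness so that they carry no
#' signal, while respecting their physical constraints (max monthly
#' temperature above min, nonnegative precipitation).
#'
#' @param nAreas number of areas (default 72, a continental-scale ecoregion
#'   count).
#' @param c intercept of the species-area line (default 2).
#' @param z slope on log(area) (default 0.45).
#' @param noiseSd richness noise sd (default 1).
#' @param seed optional integer seed.
#' @param areaIds optional area labels.
#' @param responseScale `"raw"` (count response, default) or `"log"`
#'   (the line generates log-richness, exponentiated and rounded).
#' @return List with `covariates` (data.frame in [readCovariates()] layout),
#'   `richness` (named vector) and `truth` (list of c, z, noiseSd).
#' @export
simulateSpeciesArea <- function(nAreas = 72, c = 2, z = 0.45, noiseSd = 1,
                                seed = NULL, areaIds = NULL,
                                responseScale = c("raw", "log")) {
  responseScale <- match.arg(responseScale)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(areaIds)) areaIds <- sprintf("A%02d", seq_len(nAreas))
  area <- 10^runif(nAreas, 1, 5)
  lin <- c + z * log(area) + rnorm(nAreas, 0, noiseSd)
  richness <- if (responseScale == "raw") round(pmax(lin, 0)) else
    round(pmax(exp(lin), 0))
  amt <- runif(nAreas, -5, 28)
  covariates <- data.frame(
    area_id = areaIds,
    area = area,
    altitude = runif(nAreas, 0, 4000),
    annual_mean_temp = amt,
    max_temp_warmest_month = amt + runif(nAreas, 2, 12),
    min_temp_coldest_month = amt - runif(nAreas, 2, 15),
    annual_precip = runif(nAreas, 100, 3000),
    precip_driest_month = runif(nAreas, 0, 100),
    precip_wettest_month = runif(nAreas, 50, 500))
  list(covariates = covariates,
       richness = setNames(as.numeric(richness), areaIds),
       truth = list(c = c, z = z, noiseSd = noiseSd,
                    responseScale = responseScale))
}
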