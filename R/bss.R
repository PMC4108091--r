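#' Construct envelope points
#'
#' @param x numeric environmental values per area.
#' @param y numeric species richness per area.
#' @param labels optional area identifiers (defaults to `p1..pn`).
#' @return An [EnvelopePoints-class].
#' @export
envelopePoints <- function(x, y, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("p%d", seq_along(x))
  new("EnvelopePoints", x = as.numeric(x), y = as.numeric(y),
      labels = as.character(labels))
}

setMethod("show", "EnvelopePoints", function(object) {
  cat(sprintf("EnvelopePoints: %d areas, x range [%g, %g], y range [%g, %g]\n",
              length(object@x), min(object@x), max(object@x),
              min(object@y), max(object@y)))
})

#' Rescale envelope points to the unit square
#'
#' Affinely maps x and y, each by its own min/max, onto [0, 1].  Distances
#' to the envelope boundary are unit-free afterwards, which is what makes
#' the statistic comparable across variables measured in degrees C, mm or
#' km^2.  The mapping is recorded in the `"mapping"` attribute; the
#' operation is idempotent.
#'
#' @param points an [EnvelopePoints-class].
#' @return An [EnvelopePoints-class] on the unit square.
#' @export
standardizeEnvelope <- function(points) {
  rx <- range(points@x)
  ry <- range(points@y)
  if (diff(rx) <= 0) stop("x has zero range; envelope geometry undefined")
  if (diff(ry) <= 0) stop("y has zero range; envelope geometry undefined")
  out <- envelopePoints((points@x - rx[1L]) / diff(rx),
                        (points@y - ry[1L]) / diff(ry), points@labels)
  attr(out, "mapping") <- list(x = rx, y = ry)
  out
}

#' Triangular envelope vertices
#'
#' Builds the triangular constraint envelope inside the bounding rectangle
#' of the points.  `lower_right` (the upper-limit pattern: richness capped
#' by increasing x) has vertices (min x, min y), (max x, max y),
#' (max x, min y) and its hypotenuse runs from (min x, min y) to
#' (max x, max y).  `lower_left` (used when large x caps richness, e.g.
#' altitude) has vertices (min x, min y), (max x, min y), (min x, max y)
#' with hypotenuse from (min x, max y) to (max x, min y).
#'
#' @param points an [EnvelopePoints-class].
#' @param orientation `"lower_right"` or `"lower_left"`.
#' @return A 3x2 vertex matrix with a `"hypotenuse"` attribute (2x2 matrix
#'   of its endpoints).
#' @export
triangleVertices <- function(points,
                             orientation = c("lower_right", "lower_left")) {
  orientation <- match.arg(orientation)
  rx <- range(points@x)
  ry <- range(points@y)
  if (diff(rx) <= 0 || diff(ry) <= 0)
    stop("degenerate range: triangle undefined")
  v <- if (orientation == "lower_right") {
    rbind(c(rx[1L], ry[1L]), c(rx[2L], ry[2L]), c(rx[2L], ry[1L]))
  } else {
    rbind(c(rx[1L], ry[1L]), c(rx[2L], ry[1L]), c(rx[1L], ry[2L]))
  }
  dimnames(v) <- list(c("v1", "v2", "v3"), c("x", "y"))
  hyp <- if (orientation == "lower_right") v[c(1L, 2L), ] else
    rbind(v1 = c(rx[1L], ry[2L]), v2 = c(rx[2L], ry[1L]))
  attr(v, "hypotenuse") <- hyp
  attr(v, "orientation") <- orientation
  v
}

# distance from points to a segment a-b (vectorized over rows of p)
.segmentDistance <- function(px, py, a, b) {
  vx <- b[1L] - a[1L]
  vy <- b[2L] - a[2L]
  len2 <- vx * vx + vy * vy
  t <- pmin(1, pmax(0, ((px - a[1L]) * vx + (py - a[2L]) * vy) / len2))
  sqrt((px - (a[1L] + t * vx))^2 + (py - (a[2L] + t * vy))^2)
}

#' Distance from a point to the envelope boundary
#'
#' Zero for points inside or on the triangle; otherwise the Euclidean
#' distance to the nearest point of the hypotenuse segment.
#'
#' @param point numeric vector (x, y), or a 2-column matrix of points.
#' @param triangle vertex matrix from [triangleVertices()].
#' @return Nonnegative numeric, one value per point.
#' @export
#' @examples
#' pts <- envelopePoints(c(0, 0.5, 1), c(0, 0.5, 1))
#' tri <- triangleVertices(pts, "lower_right")
#' boundaryDistance(c(0, 1), tri)   # sqrt(2)/2
boundaryDistance <- function(point, triangle) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 2L)
  # inside test via half-plane signs against the three (CCW-ordered) edges
  v <- triangle[c(1L, 2L, 3L), , drop = FALSE]
  if (attr(triangle, "orientation") == "lower_right") v <- v[c(1L, 3L, 2L), ]
  sgn <- function(a, b) (b[1L] - a[1L]) * (p[, 2L] - a[2L]) -
    (b[2L] - a[2L]) * (p[, 1L] - a[1L])
  eps <- 1e-12
  inside <- sgn(v[1L, ], v[2L, ]) >= -eps &
    sgn(v[2L, ], v[3L, ]) >= -eps & sgn(v[3L, ], v[1L, ]) >= -eps
  hyp <- attr(triangle, "hypotenuse")
  d <- .segmentDistance(p[, 1L], p[, 2L], hyp[1L, ], hyp[2L, ])
  d[inside] <- 0
  unname(d)
}

#' Boundary Sum of Squares statistic
#'
#' Mean over the points strictly outside the triangular envelope of their
#' boundary distance raised to `distancePower` (1 = mean absolute distance,
#' the test's "average distance" reading; 2 = mean squared distance, the
#' sum-of-squares reading).  Zero when no point falls outside; points on
#' the hypotenuse count as inside.
#'
#' @param points an [EnvelopePoints-class].
#' @param orientation `"lower_right"` or `"lower_left"`.
#' @param distancePower 1 or 2.
#' @param standardize rescale to the unit square first (default `TRUE`).
#' @return List with `stat` and `nOutside`.
#' @export
bssStatistic <- function(points,
                         orientation = c("lower_right", "lower_left"),
                         distancePower = 1, standardize = TRUE) {
  orientation <- match.arg(orientation)
  stopifnot(distancePower %in% c(1, 2))
  if (standardize) points <- standardizeEnvelope(points)
  tri <- triangleVertices(points, orientation)
  d <- boundaryDistance(cbind(points@x, points@y), tri)
  out <- d > 0
  list(stat = if (any(out)) mean(d[out]^distancePower) else 0,
       nOutside = sum(out))
}

# signed "outside" distance to the hypotenuse line; valid for points within
# the bounding rectangle, where the projection always falls on the segment
.outsideDistance <- function(px, py, hyp) {
  a <- hyp[1L, ]
  b <- hyp[2L, ]
  len <- sqrt((b[1L] - a[1L])^2 + (b[2L] - a[2L])^2)
  cross <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
  pmax(cross, 0) / len
}

#' Boundary Sum of Squares constraint-envelope test
#'
#' Tests whether bivariate points concentrate below a triangular upper
#' boundary more than expected by chance.  The observed statistic (mean
#' boundary distance of points outside the triangle) is compared against a
#' randomization null; unusually small values mean the points hug the
#' envelope.  The default null permutes the y values over the points
#' (`"permute_y"`), which preserves both marginals; `"uniform_rectangle"`
#' draws points uniformly in the observed bounding rectangle, the classic
#' EcoSim-style null.  Significance uses the add-one rule
#' p = (1 + #\{null <= observed\}) / (1 + n_randomizations), one-sided.
#'
#' @inheritParams bssStatistic
#' @param nRandomizations number of resamples (default 1000).
#' @param nullModel `"permute_y"` or `"uniform_rectangle"`.
#' @param seed optional integer seed.
#' @return A [BssResult-class].
#' @export
#' @examples
#' set.seed(1)
#' pts <- envelopePoints(runif(40), runif(40))
#' bssTest(pts, nRandomizations = 99)
bssTest <- function(points, orientation = c("lower_right", "lower_left"),
                    distancePower = 1, nRandomizations = 1000,
                    nullModel = c("permute_y", "uniform_rectangle"),
                    standardize = TRUE, seed = NULL) {
  orientation <- match.arg(orientation)
  nullModel <- match.arg(nullModel)
  stopifnot(distancePower %in% c(1, 2), nRandomizations >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(points@x)
  if (n < 5L) warning("fewer than 5 points; the null distribution is coarse")
  if (standardize) points <- standardizeEnvelope(points)
  tri <- triangleVertices(points, orientation)
  hyp <- attr(tri, "hypotenuse")
  dObs <- .outsideDistance(points@x, points@y, hyp)
  obs <- if (any(dObs > 0)) mean(dObs[dObs > 0]^distancePower) else 0
  N <- as.integer(nRandomizations)
  if (nullModel == "permute_y") {
    # ranges are permutation-invariant: the triangle needs no recomputation
    P <- vapply(seq_len(N), function(i) sample(points@y), numeric(n))
    D <- .outsideDistance(points@x, P, hyp)
  } else {
    rx <- range(points@x)
    ry <- range(points@y)
    X <- matrix(runif(n * N, rx[1L], rx[2L]), n, N)
    Y <- matrix(runif(n * N, ry[1L], ry[2L]), n, N)
    D <- .outsideDistance(X, Y, hyp)
  }
  D <- matrix(D, n, N)
  nOut <- colSums(D > 0)
  nullStats <- ifelse(nOut > 0, colSums(D^distancePower * (D > 0)) /
                        pmax(nOut, 1L), 0)
  p <- (1 + sum(nullStats <= obs)) / (1 + N)
  new("BssResult", observedStat = obs, nOutside = sum(dObs > 0),
      nullStats = as.numeric(nullStats), pValue = p, triangle = tri[, ],
      config = list(orientation = orientation, distancePower = distancePower,
                    nRandomizations = N, nullModel = nullModel,
                    standardize = standardize,
                    seed = if (is.null(seed)) NA_integer_ else seed))
}

#' @rdname endemicity-generics
#' @export
setMethod("observedStat", "BssResult", function(x) x@observedStat)

#' @rdname endemicity-generics
#' @export
setMethod("nullStats", "BssResult", function(x) x@nullStats)

#' @rdname endemicity-generics
#' @export
setMethod("pValue", "BssResult", function(x) x@pValue)

setMethod("show", "BssResult", function(object) {
  cat(sprintf(
    "BSS test (%s, power %d, %s null): stat = %.5g, %d point(s) outside, p = %.4g\n",
    object@config$orientation, object@config$distancePower,
    object@config$nullModel, object@observedStat, object@nOutside,
    object@pValue))
})
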