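#' Construct an incidence matrix
#'
#' @param presence numeric or integer matrix of 0/1 with species as rows
#'   (rownames required) and areas as columns (colnames required).
#' @return An [IncidenceMatrix-class].
#' @export
#' @examples
#' IncidenceMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("sp1", "sp2"), c("A", "B"))))
IncidenceMatrix <- function(presence) {
  storage.mode(presence) <- "integer"
  new("IncidenceMatrix", presence = presence)
}

#' @rdname endemicity-generics
#' @export
setMethod("speciesIDs", "IncidenceMatrix", function(x) rownames(x@presence))

#' @rdname endemicity-generics
#' @export
setMethod("areaIDs", "IncidenceMatrix", function(x) colnames(x@presence))

#' @rdname endemicity-generics
#' @export
setMethod("presenceMatrix", "IncidenceMatrix", function(x) x@presence)

#' @rdname richness
#' @export
setMethod("richness", "IncidenceMatrix", function(x) colSums(x@presence))

setMethod("show", "IncidenceMatrix", function(object) {
  p <- object@presence
  cat(sprintf("IncidenceMatrix: %d species x %d areas, %d presences\n",
              nrow(p), ncol(p), sum(p)))
  cat("areas:", paste(head(colnames(p), 5), collapse = ", "),
      if (ncol(p) > 5) "..." else "", "\n")
})

#' Read a species-by-area incidence matrix from delimited text
#'
#' The first column holds species labels; remaining column headers are area
#' labels; cells must parse as 0 or 1.  The delimiter (comma or tab) is
#' auto-detected from the header line.  Row and column order is preserved.
#'
#' @param path path to a CSV/TSV file, UTF-8.
#' @return An [IncidenceMatrix-class].
#' @export
readIncidence <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need a species column plus at least 2 area columns")
  species <- df[[1L]]
  areas <- colnames(df)[-1L]
  if (anyDuplicated(species))
    stop(sprintf("duplicate species label: %s",
                 species[duplicated(species)][1L]))
  if (anyDuplicated(areas))
    stop(sprintf("duplicate area label: %s", areas[duplicated(areas)][1L]))
  cells <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(matrix(!(trimws(cells) %in% c("0", "1")), nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-binary cell '%s' at species '%s' (row %d), area '%s' (column %d)",
      cells[bad[1L, 1L], bad[1L, 2L]], species[bad[1L, 1L]], bad[1L, 1L],
      areas[bad[1L, 2L]], bad[1L, 2L]))
  }
  m <- matrix(as.integer(trimws(cells)), nrow = nrow(cells),
              dimnames = list(species, areas))
  IncidenceMatrix(m)
}

#' Write an incidence matrix as CSV
#'
#' Inverse of [readIncidence()]: species as rows, areas as columns.
#'
#' @param x an [IncidenceMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIncidence <- function(x, path) {
  df <- data.frame(species = speciesIDs(x), x@presence,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Remove parsimony-uninformative species
#'
#' With the all-absent hypothetical outgroup in place, a species present in
#' fewer than 2 areas is an autapomorphy of a single area (or constant) and
#' cannot affect the relative length of any topology.  Removing such species
#' changes every tree's length by the same constant.
#'
#' @param x an [IncidenceMatrix-class].
#' @return A list with elements `matrix` (the filtered
#'   [IncidenceMatrix-class]) and `removed` (character vector of dropped
#'   species labels, possibly empty).  Areas are never removed.
#' @export
dropUninformative <- function(x) {
  p <- presenceMatrix(x)
  keep <- rowSums(p) >= 2L
  if (!any(keep))
    stop("no parsimony-informative species remain")
  list(matrix = IncidenceMatrix(p[keep, , drop = FALSE]),
       removed = rownames(p)[!keep])
}

# quote a NEXUS/Newick token when it contains anything beyond word characters
.quoteLabel <- function(lab) {
  plain <- grepl("^[A-Za-z0-9_.-]+$", lab)
  ifelse(plain, lab, paste0("'", gsub("'", "''", lab), "'"))
}

#' Write the PAE character matrix as a NEXUS DATA block
#'
#' In PAE the areas play the role of taxa and the species of characters, so
#' the writer transposes the incidence matrix: `ntax` is the number of areas
#' (+1 when the all-absent outgroup row is included) and `nchar` the number
#' of species.  Labels containing spaces are single-quoted.
#'
#' @param x an [IncidenceMatrix-class].
#' @param path optional output file; when `NULL` the NEXUS text is returned.
#' @param includeOutgroup add a row of all 0s labelled
#'   [paeOutgroupLabel()] (default `TRUE`).
#' @return The NEXUS text as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
writeNexus <- function(x, path = NULL, includeOutgroup = TRUE) {
  p <- presenceMatrix(x)
  og <- paeOutgroupLabel()
  if (includeOutgroup && og %in% areaIDs(x))
    stop(sprintf("area label collides with reserved outgroup name '%s'", og))
  taxa <- t(p)   # areas x species
  if (includeOutgroup) {
    taxa <- rbind(matrix(0L, 1L, ncol(taxa), dimnames = list(og, NULL)), taxa)
  }
  labs <- .quoteLabel(rownames(taxa))
  pad <- formatC(labs, width = max(nchar(labs)), flag = "-")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(taxa), ncol(taxa)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE=NO;",
    "  MATRIX",
    sprintf("    %s  %s", pad, apply(taxa, 1L, paste, collapse = "")),
    "  ;",
    "END;")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read and validate a per-area covariate table
#'
#' Expects the eight standard predictors of richness analyses: surface
#' area (km^2), mean altitude (m), annual mean temperature, maximum
#' temperature of the warmest month, minimum temperature of the coldest
#' month (degrees C), annual precipitation, precipitation of the driest and
#' of the wettest month (mm).
#'
#' @param path CSV/TSV file with columns `area_id`, `area`, `altitude`,
#'   `annual_mean_temp`, `max_temp_warmest_month`, `min_temp_coldest_month`,
#'   `annual_precip`, `precip_driest_month`, `precip_wettest_month`.
#' @return A validated data.frame.
#' @export
readCovariates <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validateCovariates(df)
}

#' @rdname readCovariates
#' @param covariates a data.frame to validate in place.
#' @export
validateCovariates <- function(covariates) {
  needed <- c("area_id", "area", "altitude", "annual_mean_temp",
              "max_temp_warmest_month", "min_temp_coldest_month",
              "annual_precip", "precip_driest_month", "precip_wettest_month")
  missing <- setdiff(needed, colnames(covariates))
  if (length(missing))
    stop("covariate table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(covariates$area_id))
    stop("duplicate area_id in covariate table: ",
         covariates$area_id[duplicated(covariates$area_id)][1L])
  if (any(covariates$area <= 0))
    stop("area must be positive for every ecoregion")
  if (any(covariates$max_temp_warmest_month < covariates$min_temp_coldest_month))
    stop("max_temp_warmest_month below min_temp_coldest_month for area ",
         covariates$area_id[which(covariates$max_temp_warmest_month <
                                    covariates$min_temp_coldest_month)][1L])
  precip <- c("annual_precip", "precip_driest_month", "precip_wettest_month")
  if (any(as.matrix(covariates[, precip]) < 0))
    stop("precipitation fields must be nonnegative")
  covariates
}
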