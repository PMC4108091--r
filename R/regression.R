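# canonical predictor order of the richness regression
.predictorOrder <- c("log_area", "altitude", "annual_mean_temp",
                     "max_temp_warmest_month", "min_temp_coldest_month",
                     "annual_precip", "precip_driest_month",
                     "precip_wettest_month")

#' Assemble the richness-regression design table
#'
#' Joins per-area richness to the covariate table, logs the area predictor,
#' and applies the requested response transform.  Areas missing either a
#' richness value or a covariate row are dropped with a warning.
#'
#' @param covariates covariate data.frame as validated by
#'   [validateCovariates()].
#' @param richness named numeric vector of per-area species counts, a
#'   data.frame with columns `area_id` and `richness`, or an
#'   [IncidenceMatrix-class] (column sums are used).
#' @param responseTransform `"raw"` (default: the plain number of species),
#'   `"log"` or `"log1p"`.
#' @param logBase base of the area logarithm (and of the `"log"` response
#'   transform); natural log by default, `10` is the common alternative in
#'   species-area work.
#' @return A data.frame with columns `area_id`, `richness`, then the eight
#'   predictors in standard order; transform choices are recorded in the
#'   `"transforms"` attribute.
#' @export
buildDesign <- function(covariates, richness,
                        responseTransform = c("raw", "log", "log1p"),
                        logBase = exp(1)) {
  responseTransform <- match.arg(responseTransform)
  covariates <- validateCovariates(covariates)
  if (is(richness, "IncidenceMatrix")) richness <- richness(richness)
  if (is.data.frame(richness))
    richness <- setNames(richness$richness, richness$area_id)
  if (is.null(names(richness)))
    stop("richness must be named by area_id")
  common <- intersect(names(richness), covariates$area_id)
  droppedR <- setdiff(names(richness), common)
  droppedC <- setdiff(covariates$area_id, common)
  if (length(droppedR))
    warning("dropping area(s) with richness but no covariates: ",
            paste(droppedR, collapse = ", "))
  if (length(droppedC))
    warning("dropping area(s) with covariates but no richness: ",
            paste(droppedC, collapse = ", "))
  cv <- covariates[match(common, covariates$area_id), , drop = FALSE]
  if (any(cv$area <= 0))
    stop("cannot log nonpositive area for: ",
         paste(cv$area_id[cv$area <= 0], collapse = ", "))
  y <- as.numeric(richness[common])
  y <- switch(responseTransform,
              raw = y,
              log = {
                if (any(y <= 0))
                  stop("log response undefined for zero-richness area(s): ",
                       paste(common[y <= 0], collapse = ", "))
                log(y, base = logBase)
              },
              log1p = log1p(y) / log(logBase))
  out <- data.frame(area_id = common, richness = y,
                    log_area = log(cv$area, base = logBase),
                    altitude = cv$altitude,
                    annual_mean_temp = cv$annual_mean_temp,
                    max_temp_warmest_month = cv$max_temp_warmest_month,
                    min_temp_coldest_month = cv$min_temp_coldest_month,
                    annual_precip = cv$annual_precip,
                    precip_driest_month = cv$precip_driest_month,
                    precip_wettest_month = cv$precip_wettest_month,
                    row.names = NULL)
  attr(out, "transforms") <- list(responseTransform = responseTransform,
                                  logBase = logBase)
  out
}

#' Ordinary least squares fit of the richness regression
#'
#' Fits richness against every predictor column of the design table by OLS
#' and reports the coefficient table (estimate, standard error from the
#' unbiased residual variance, t, two-sided p) together with the overall
#' F statistic, its p-value, R-squared and adjusted R-squared.
#'
#' @param design a data.frame from [buildDesign()], or any data.frame whose
#'   first columns are `area_id` (optional) and `richness` followed by
#'   numeric predictors.
#' @return A [RichnessFit-class].
#' @export
fitOls <- function(design) {
  df <- design[, setdiff(colnames(design), "area_id"), drop = FALSE]
  if (!"richness" %in% colnames(df)) stop("design must contain 'richness'")
  k <- ncol(df) - 1L
  n <- nrow(df)
  if (n <= k + 1L)
    stop("need more areas than predictors + 1 (n = ", n, ", k = ", k, ")")
  X <- model.matrix(richness ~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm(richness ~ ., data = df)
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                      std_error = ct[, 2L], t_value = ct[, 3L],
                      p_value = ct[, 4L], row.names = NULL)
  f <- unname(sm$fstatistic)
  new("RichnessFit", coefficients = coefs,
      fStatistic = f[1L],
      modelP = pf(f[1L], f[2L], f[3L], lower.tail = FALSE),
      r2 = sm$r.squared, adjR2 = sm$adj.r.squared,
      residualDf = as.integer(fit$df.residual), n = as.integer(n),
      fit = fit)
}

#' @rdname endemicity-generics
#' @export
setMethod("coefficientTable", "RichnessFit", function(x) x@coefficients)

#' @rdname endemicity-generics
#' @export
setMethod("modelStats", "RichnessFit", function(x)
  c(F = x@fStatistic, p = x@modelP, r2 = x@r2, adjR2 = x@adjR2,
    residualDf = x@residualDf, n = x@n))

setMethod("show", "RichnessFit", function(object) {
  cat(sprintf("Richness regression: n = %d, F = %.2f, p = %.3g, adj R2 = %.2f\n",
              object@n, object@fStatistic, object@modelP, object@adjR2))
  print(object@coefficients, digits = 3)
})
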