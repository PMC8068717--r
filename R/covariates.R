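#' Rurality deciles from population density
#'
#' Ranks areas by descending population density and cuts them into
#' `nGroups` contiguous equal-count groups: label 1 = most urban (highest
#' density), label `nGroups` = most rural. When `n` is not divisible by
#' `nGroups` the remainder is distributed largest-remainder-first, i.e. the
#' first `n %% nGroups` groups take the extra unit, so group sizes differ
#' by at most one. Density ties are broken by a stable sort on area id, for
#' reproducibility.
#'
#' @param density named numeric vector of population densities
#'   (persons per km^2), strictly positive.
#' @param nGroups number of groups (default 10 deciles).
#' @return Integer vector of labels in `1..nGroups`, named like `density`,
#'   in the input order.
#' @export
assignDeciles <- function(density, nGroups = 10) {
  n <- length(density)
  if (any(!is.finite(density)) || any(density <= 0)) {
    stop("densities must be positive and finite")
  }
  if (nGroups > n) stop("nGroups exceeds number of areas")
  ids <- names(density)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-density, ids, method = "radix")   # stable tie-break on id
  base <- n %/% nGroups
  extra <- n %% nGroups
  sizes <- rep(base, nGroups) + c(rep(1L, extra), rep(0L, nGroups - extra))
  lab <- rep.int(seq_len(nGroups), sizes)
  out <- integer(n)
  out[ord] <- lab
  setNames(out, ids)
}

#' Log-transform and z-score covariate columns
#'
#' Right-skewed covariates (percent scales) are natural-log-transformed
#' first, then every column is standardized to a z-score using the sample
#' (n-1) standard deviation, each area weighted equally.
#'
#' @param raw numeric matrix or data.frame of per-area covariate values
#'   (columns named).
#' @param logColumns character vector of column names to log-transform
#'   before standardization.
#' @return Numeric matrix of z-scored columns (mean 0, unit sd), with
#'   attributes `center` and `scale` holding the post-log means and sds.
#' @export
transformCovariates <- function(raw, logColumns = character(0)) {
  m <- as.matrix(raw)
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  unknown <- setdiff(logColumns, colnames(m))
  if (length(unknown)) {
    stop("logColumns not present: ", paste(unknown, collapse = ", "))
  }
  for (cn in logColumns) {
    bad <- m[, cn] <= 0
    if (any(bad)) {
      who <- rownames(m)[bad]
      if (is.null(who)) who <- which(bad)
      stop("non-positive value(s) in log column '", cn, "' at area(s): ",
           paste(head(who, 5), collapse = ", "))
    }
    m[, cn] <- log(m[, cn])
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(scl == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[scl == 0], collapse = ", "))
  }
  z <- scale(m, center = ctr, scale = scl)
  out <- z[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Build the decile / covariate design matrix
#'
#' Indicator coding of the rurality deciles with decile 1 (most urban) as
#' the reference category, optionally followed by the standardized
#' socioeconomic covariates for the adjusted model.
#'
#' @param deciles integer labels in `1..10` per area.
#' @param covariates z-scored covariate matrix (areas x covariates), used
#'   only when `adjusted = TRUE`.
#' @param adjusted logical; append the covariate columns?
#' @param intercept logical; prepend an all-ones intercept column (default
#'   `TRUE`). The MCMC fitter carries the intercept itself and drops an
#'   `(Intercept)` column if present.
#' @return Numeric design matrix with columns
#'   `(Intercept), decile2 ... decile10[, <covariates>]`.
#' @export
buildDesign <- function(deciles, covariates = NULL, adjusted = FALSE,
                        intercept = TRUE) {
  if (any(!(deciles %in% 1:10))) {
    stop("decile labels must be integers in 1..10")
  }
  n <- length(deciles)
  present <- sort(unique(deciles[deciles > 1]))   # no column for empty levels
  ind <- matrix(0, n, length(present))
  if (length(present)) {
    dimnames(ind) <- list(names(deciles), paste0("decile", present))
  }
  for (j in seq_along(present)) ind[deciles == present[j], j] <- 1
  X <- ind
  if (adjusted) {
    if (is.null(covariates)) stop("adjusted design requires covariates")
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariate rows must match number of areas")
    X <- cbind(ind, cv)
  }
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  X
}
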