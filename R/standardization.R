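#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used
#' for the printed fold differences and percentage shares, as opposed to
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' National reference rates by gender and age band
#'
#' Reference rates for indirect standardization: pooled national event
#' counts divided by pooled person-years, per gender x 10-year age band.
#'
#' @param counts numeric matrix or vector of national event totals; when a
#'   matrix, rows are genders and columns age bands (any named layout works
#'   as long as `populations` matches it element-wise).
#' @param populations person-years at risk, same shape and names as
#'   `counts`.
#' @return Object of the same shape holding rates (events per person-year).
#' @export
nationalRates <- function(counts, populations) {
  if (!identical(dim(counts), dim(populations)) ||
      length(counts) != length(populations)) {
    stop("counts and populations must have identical shape")
  }
  if (any(counts < 0) || any(populations < 0)) {
    stop("counts and populations must be nonnegative")
  }
  bad <- counts > 0 & populations == 0
  if (any(bad)) {
    stop("positive count with zero person-years in band(s): ",
         paste(which(bad), collapse = ", "))
  }
  rates <- counts / populations
  rates[populations == 0] <- 0
  rates
}

#' Expected counts by indirect standardization
#'
#' Applies gender- and age-specific reference rates to each area's own
#' population structure: `E_i = sum_b pop[i, b] * rate[b]`. When the rates
#' come from the pooled areas themselves, `sum(E) == sum(O)` exactly
#' (self-standardization closure).
#'
#' @param pop numeric matrix of person-years, areas x strata (columns named
#'   by stratum).
#' @param rates numeric vector of reference rates named by the same strata.
#' @return Numeric vector `E` of expected counts named by area; areas with
#'   zero population get `E = 0` and an attribute `zeroExpected` listing
#'   them.
#' @export
expectedCounts <- function(pop, rates) {
  pop <- as.matrix(pop)
  if (is.null(colnames(pop)) || is.null(names(rates))) {
    if (ncol(pop) != length(rates)) stop("stratum mismatch: pop vs rates")
  } else {
    if (!setequal(colnames(pop), names(rates))) {
      stop("stratum labels of pop and rates do not match")
    }
    rates <- rates[colnames(pop)]
  }
  e <- as.numeric(pop %*% rates)
  names(e) <- rownames(pop)
  zero <- names(e)[e == 0]
  if (length(zero)) attr(e, "zeroExpected") <- zero
  e
}

#' Raw (unsmoothed) standardized mortality ratios
#'
#' `SMR_i = O_i / E_i`, the ratio of observed to expected events. Areas
#' with `E_i = 0` are flagged undefined rather than producing `Inf`/`NaN`.
#'
#' @param observed nonnegative integer vector of observed counts.
#' @param expected nonnegative numeric vector of expected counts.
#' @return data.frame with columns `area_id` (from names, else index),
#'   `observed`, `expected`, `smr`, `undefined` (logical).
#' @export
rawSMR <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(observed < 0) || any(expected < 0)) {
    stop("observed and expected counts must be nonnegative")
  }
  ids <- names(observed)
  if (is.null(ids)) ids <- names(expected)
  if (is.null(ids)) ids <- as.character(seq_along(observed))
  undef <- expected == 0
  smr <- ifelse(undef, NA_real_, observed / expected)
  data.frame(
    area_id = ids, observed = as.numeric(observed),
    expected = as.numeric(expected), smr = smr, undefined = undef,
    stringsAsFactors = FALSE
  )
}

#' Fold difference between two quantiles
#'
#' @param lowerValue value at the lower quantile (must be > 0).
#' @param upperValue value at the upper quantile.
#' @return list with `raw` (the ratio) and `rounded` (half-up, 1 decimal).
#' @export
foldDifference <- function(lowerValue, upperValue) {
  if (lowerValue <= 0) stop("lower quantile value must be positive")
  r <- upperValue / lowerValue
  list(raw = r, rounded = roundHalfUp(r, 1))
}

#' 90%-range fold difference of SMRs
#'
#' Dispersion of area SMRs summarized as the ratio between the values at the
#' 95th and 5th percentiles — robust to the unstable extremes of small-area
#' estimates. Quantiles use linear interpolation between order statistics
#' (type 7); the published convention rounds the ratio half-up to one
#' decimal.
#'
#' @param values numeric vector of SMRs; `NA` (undefined) entries dropped.
#' @param lower,upper probabilities of the bracketing quantiles.
#' @return list with `qLower`, `qUpper`, `raw` ratio and `rounded` value.
#' @export
rangeRatio <- function(values, lower = 0.05, upper = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 defined values")
  q <- quantile(values, probs = c(lower, upper), names = FALSE, type = 7)
  if (q[1] <= 0) stop("lower quantile is not positive; ratio undefined")
  fd <- foldDifference(q[1], q[2])
  list(qLower = q[1], qUpper = q[2], raw = fd$raw, rounded = fd$rounded)
}

## category bins, symmetric on the log scale around 1
.smrBreaks <- c(0, 0.50, 0.67, 0.90, 1.10, 1.50, 2.00, Inf)

#' SMR map category labels
#'
#' @return Character vector of the 7 ordered category labels.
#' @export
smrCategoryLabels <- function() {
  c("<0.50", "0.50-<0.67", "0.67-<0.90", "0.90-<1.10",
    "1.10-<1.50", "1.50-<2.00", ">=2.00")
}

#' Categorize SMRs into the 7 map bins
#'
#' Bins are left-closed/right-open and symmetric on the logarithmic scale
#' (log 0.50 = -log 2.00, log 0.67 ~ -log 1.50): <0.50, 0.50-<0.67,
#' 0.67-<0.90, 0.90-<1.10, 1.10-<1.50, 1.50-<2.00, >=2.00. Categories 1-3
#' map to blues (below-average risk), 4 to pale yellow, 5-7 to browns.
#'
#' @param values nonnegative numeric vector of SMRs (`NA` passed through).
#' @return data.frame with `smr`, `category_index` (1-7) and
#'   `category_label` (ordered factor).
#' @export
categorizeSMR <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("SMR values must be nonnegative")
  idx <- findInterval(values, .smrBreaks[-1] , left.open = FALSE) + 1L
  idx[is.na(values)] <- NA_integer_
  labs <- smrCategoryLabels()
  data.frame(
    smr = values,
    category_index = idx,
    category_label = factor(labs[idx], levels = labs, ordered = TRUE),
    stringsAsFactors = FALSE
  )
}
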