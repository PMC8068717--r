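#' AreaExperiment: area-level counts and populations by gender x age band
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' area-level inputs of the mapping pipeline: one row per area, one column
#' per gender x 10-year-age-band stratum, with assays `events` (observed
#' event counts) and `personYears` (population at risk). Area covariates
#' (population density, socioeconomic variables, rurality decile) live in
#' `rowData`; the adjacency [AreaGraph-class] travels in
#' `metadata(x)$graph`.
#'
#' @seealso [AreaExperiment()], [stratumData()], [simulateAreaData()]
#' @export
setClass("AreaExperiment", contains = "SummarizedExperiment")

setValidity("AreaExperiment", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("events", "personYears") %in% a)) {
    return("assays 'events' and 'personYears' are required")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    return("rownames (area ids) must be present and unique")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("gender", "ageBand") %in% names(cd))) {
    return("colData must carry 'gender' and 'ageBand'")
  }
  if (any(SummarizedExperiment::assay(object, "events") < 0, na.rm = TRUE) ||
      any(SummarizedExperiment::assay(object, "personYears") < 0,
          na.rm = TRUE)) {
    return("events and personYears must be nonnegative")
  }
  g <- S4Vectors::metadata(object)$graph
  if (!is.null(g)) {
    if (!is(g, "AreaGraph")) return("metadata$graph must be an AreaGraph")
    if (!identical(areaIds(g), rownames(object))) {
      return("graph area ids must equal rownames, in order")
    }
  }
  TRUE
})

#' Default 10-year age bands
#'
#' @return Character vector `"0-9"` ... `"70-79"`, `"80+"`.
#' @export
ageBands <- function() {
  c(paste(seq(0, 70, 10), seq(9, 79, 10), sep = "-"), "80+")
}

#' Age bands making up an age-group stratum
#'
#' Strata are unions of 10-year bands: `all`, `0-39` (bands up to 30-39),
#' `40-59`, and `60+`.
#'
#' @param group one of `"all"`, `"0-39"`, `"40-59"`, `"60+"`.
#' @param bands the full band vector (default [ageBands()]).
#' @return Character vector of band labels in the group.
#' @export
bandsForGroup <- function(group, bands = ageBands()) {
  lowEdge <- suppressWarnings(as.integer(sub("[-+].*$", "", bands)))
  switch(group,
    "all" = bands,
    "0-39" = bands[lowEdge <= 30],
    "40-59" = bands[lowEdge >= 40 & lowEdge <= 50],
    "60+" = bands[lowEdge >= 60],
    stop("unknown age group: ", group)
  )
}

#' Construct an AreaExperiment
#'
#' @param events integer matrix of observed counts, areas x strata; column
#'   names `"<gender>:<band>"` (e.g. `"male:40-49"`).
#' @param personYears numeric matrix of person-years, same shape/dimnames.
#' @param rowData optional data.frame of area covariates.
#' @param graph optional [AreaGraph-class] over the same areas (same
#'   order).
#' @return An [AreaExperiment-class].
#' @export
AreaExperiment <- function(events, personYears, rowData = NULL,
                           graph = NULL) {
  events <- as.matrix(events)
  personYears <- as.matrix(personYears)
  if (!identical(dimnames(events), dimnames(personYears))) {
    stop("events and personYears must share dimnames")
  }
  parts <- strsplit(colnames(events), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("column names must be '<gender>:<ageBand>'")
  }
  cd <- S4Vectors::DataFrame(
    gender = vapply(parts, `[`, "", 1L),
    ageBand = vapply(parts, `[`, "", 2L),
    row.names = colnames(events)
  )
  md <- if (is.null(graph)) list() else list(graph = graph)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(events = events, personYears = personYears),
    colData = cd, metadata = md
  )
  if (!is.null(rowData)) {
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  }
  new("AreaExperiment", se)
}

#' @rdname events
#' @export
setMethod("events", "AreaExperiment", function(x) {
  SummarizedExperiment::assay(x, "events")
})

#' @rdname personYears
#' @export
setMethod("personYears", "AreaExperiment", function(x) {
  SummarizedExperiment::assay(x, "personYears")
})

#' @rdname areaIds
#' @export
setMethod("areaIds", "AreaExperiment", function(x) rownames(x))

#' @rdname areaGraph
#' @export
setMethod("areaGraph", "AreaExperiment", function(x) {
  S4Vectors::metadata(x)$graph
})

#' @rdname areaGraph
#' @export
setMethod("areaGraph<-", "AreaExperiment", function(x, value) {
  S4Vectors::metadata(x)$graph <- value
  validObject(x)
  x
})

setMethod("show", "AreaExperiment", function(object) {
  callNextMethod()
  g <- areaGraph(object)
  if (!is.null(g)) {
    cat(sprintf("graph: %d edges, %d component(s)\n",
                sum(lengths(adjacencyList(g))) / 2, nComponents(g)))
  }
})

## long CSV (area_id,gender,age_band,<value>) -> areas x strata matrix
.longToMatrix <- function(df, valueCol, areaOrder = NULL) {
  need <- c("area_id", "gender", "age_band", valueCol)
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)),
                                      collapse = ", "))
  }
  strata <- unique(paste(df$gender, df$age_band, sep = ":"))
  areas <- if (is.null(areaOrder)) unique(df$area_id) else areaOrder
  m <- matrix(0, length(areas), length(strata),
              dimnames = list(areas, strata))
  key <- cbind(match(df$area_id, areas),
               match(paste(df$gender, df$age_band, sep = ":"), strata))
  if (anyNA(key[, 1])) {
    stop("area id(s) outside declared order: ",
         paste(unique(df$area_id[is.na(key[, 1])]), collapse = ", "))
  }
  m[key] <- m[key] + df[[valueCol]]
  m
}

#' Read area-level counts and populations into an AreaExperiment
#'
#' @param countsPath CSV with columns `area_id,gender,age_band,count`
#'   (or an equivalent data.frame).
#' @param populationPath CSV with columns
#'   `area_id,gender,age_band,person_years`.
#' @param covariatesPath optional CSV with columns
#'   `area_id,density,single_person_hh_pct,unmarried_pct,unemployment_pct,college_pct`.
#' @param graph optional [AreaGraph-class]; defines the area order, and
#'   rows are aligned to it.
#' @return An [AreaExperiment-class].
#' @export
readAreaExperiment <- function(countsPath, populationPath,
                               covariatesPath = NULL, graph = NULL) {
  cnt <- if (is.data.frame(countsPath)) countsPath else {
    read.csv(countsPath, colClasses = c(area_id = "character"))
  }
  pop <- if (is.data.frame(populationPath)) populationPath else {
    read.csv(populationPath, colClasses = c(area_id = "character"))
  }
  areaOrder <- if (is.null(graph)) unique(pop$area_id) else areaIds(graph)
  pm <- .longToMatrix(pop, "person_years", areaOrder)
  cm <- .longToMatrix(cnt, "count", areaOrder)
  # population defines the stratum universe; counts aligned (absent = 0)
  full <- matrix(0, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  shared <- intersect(colnames(cm), colnames(pm))
  full[, shared] <- cm[, shared]
  rd <- NULL
  if (!is.null(covariatesPath)) {
    cv <- read.csv(covariatesPath, colClasses = c(area_id = "character"))
    rd <- cv[match(areaOrder, cv$area_id), , drop = FALSE]
    rownames(rd) <- areaOrder
    rd$area_id <- NULL
  }
  AreaExperiment(full, pm, rowData = rd, graph = graph)
}

#' Observed and expected counts for one gender x age-group stratum
#'
#' Pools the experiment's own counts and person-years into national
#' gender- and band-specific reference rates, then applies them to each
#' area's population (indirect standardization), restricted to the
#' requested stratum. Self-standardization guarantees
#' `sum(expected) == sum(observed)` within the stratum.
#'
#' @param x an [AreaExperiment-class].
#' @param gender `"male"`, `"female"`, or `"both"` (genders pooled but
#'   rates still gender-specific).
#' @param ageGroup one of `"all"`, `"0-39"`, `"40-59"`, `"60+"`.
#' @return data.frame with columns `area_id`, `observed`, `expected`, plus
#'   attribute `rates` (the reference rates used).
#' @export
stratumData <- function(x, gender = "male", ageGroup = "all") {
  stopifnot(is(x, "AreaExperiment"))
  cd <- SummarizedExperiment::colData(x)
  genders <- if (gender == "both") unique(cd$gender) else gender
  if (!all(genders %in% cd$gender)) {
    stop("gender '", gender, "' not present in the experiment")
  }
  keep <- cd$gender %in% genders &
    cd$ageBand %in% bandsForGroup(ageGroup, unique(cd$ageBand))
  if (!any(keep)) stop("no strata match gender/ageGroup selection")
  ev <- events(x)[, keep, drop = FALSE]
  py <- personYears(x)[, keep, drop = FALSE]
  rates <- nationalRates(colSums(ev), colSums(py))
  e <- expectedCounts(py, rates)
  out <- data.frame(
    area_id = rownames(x),
    observed = as.numeric(rowSums(ev)),
    expected = as.numeric(e),
    stringsAsFactors = FALSE
  )
  attr(out, "rates") <- rates
  out
}
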