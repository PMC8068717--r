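#' Decile display labels, most urban to most rural
#'
#' @return Character vector of the 10 rural-urban continuum labels.
#' @export
decileLabels <- function() {
  c("Most urban", "2nd most urban", "3rd most urban", "4th most urban",
    "5th most urban", "5th most rural", "4th most rural", "3rd most rural",
    "2nd most rural", "Most rural")
}

#' Run configuration for the end-to-end pipeline
#'
#' @param counts,population,covariates,neighbors input paths (CSV, CSV,
#'   CSV, GAL neighbor list).
#' @param extraEdges optional CSV (`area_a,area_b`) of extra neighbor
#'   edges, e.g. sea routes.
#' @param mergeMap optional CSV (`area_id,group_id`) of municipality
#'   aggregations.
#' @param polygons optional GeoJSON of area polygons for map export.
#' @param strata character vector of `"<gender>:<ageGroup>"` strata
#'   (default both genders x all/0-39/40-59/60+).
#' @param modes model modes to fit: subset of
#'   `c("unadjusted", "adjusted")`; the covariate-free smoothing model is
#'   always fitted.
#' @param mcmc an [mcmcConfig()] list.
#' @param outputDir directory for tables and the manifest.
#' @param seed integer seed (overrides `mcmc$seed` as the run's base
#'   seed).
#' @return Named list (class `smrmapRunConfig`).
#' @export
runConfig <- function(counts, population, covariates, neighbors,
                      extraEdges = NULL, mergeMap = NULL, polygons = NULL,
                      strata = as.vector(outer(c("male", "female"),
                        c("all", "0-39", "40-59", "60+"), paste, sep = ":")),
                      modes = c("unadjusted", "adjusted"),
                      mcmc = mcmcConfig(seed = 1),
                      outputDir = "smrmap-output", seed = mcmc$seed) {
  cfg <- list(
    counts = counts, population = population, covariates = covariates,
    neighbors = neighbors, extraEdges = extraEdges, mergeMap = mergeMap,
    polygons = polygons, strata = strata, modes = modes, mcmc = mcmc,
    outputDir = outputDir, seed = as.integer(seed)
  )
  class(cfg) <- "smrmapRunConfig"
  cfg
}

#' Read a YAML run-configuration file
#'
#' Top-level keys mirror the [runConfig()] arguments; an `mcmc` block maps
#' onto [mcmcConfig()]. Relative input paths are resolved against the
#' file's directory.
#'
#' @param path YAML file.
#' @return A [runConfig()] list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  mc <- do.call(mcmcConfig, y$mcmc)
  args <- list(
    counts = resolve(y$counts), population = resolve(y$population),
    covariates = resolve(y$covariates), neighbors = resolve(y$neighbors),
    extraEdges = resolve(y$extraEdges), mergeMap = resolve(y$mergeMap),
    polygons = resolve(y$polygons), mcmc = mc,
    outputDir = if (is.null(y$outputDir)) "smrmap-output" else y$outputDir
  )
  if (!is.null(y$strata)) args$strata <- y$strata
  if (!is.null(y$modes)) args$modes <- y$modes
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(runConfig, args)
}

## one structured log line per pipeline stage
.logStage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste(..., collapse = " ")))
}

#' Long-format rate-ratio table across strata and modes
#'
#' One row per stratum x mode x decile in the published table layout: the
#' reference (most urban) row carries RR = 1 with empty interval fields,
#' and the significance flag marks 95% intervals excluding 1.
#'
#' @param summaries named list: `summaries[[stratum]][[mode]]` is a
#'   [bymSummary()] result whose rate-ratio terms include
#'   `decile2 ... decile10`.
#' @param path optional CSV output path.
#' @return data.frame with columns `stratum`, `mode`, `decile`,
#'   `decile_label`, `rr`, `ci_low`, `ci_high`, `significant`.
#' @export
writeRRTable <- function(summaries, path = NULL) {
  labs <- decileLabels()
  rows <- list()
  for (stratum in names(summaries)) {
    for (mode in names(summaries[[stratum]])) {
      rr <- summaries[[stratum]][[mode]]$rateRatios
      ref <- data.frame(
        stratum = stratum, mode = mode, decile = 1L,
        decile_label = labs[1], rr = 1, ci_low = NA_real_,
        ci_high = NA_real_, significant = NA, stringsAsFactors = FALSE
      )
      dec <- rr[grepl("^decile[0-9]+$", rr$term), , drop = FALSE]
      k <- as.integer(sub("^decile", "", dec$term))
      body <- data.frame(
        stratum = stratum, mode = mode, decile = k,
        decile_label = labs[k], rr = dec$rr, ci_low = dec$ci_low,
        ci_high = dec$ci_high, significant = dec$significant,
        stringsAsFactors = FALSE
      )
      rows[[paste(stratum, mode)]] <- rbind(ref, body[order(k), ])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Export categorized SMRs onto GeoJSON polygons
#'
#' Joins an SMR table onto a polygon FeatureCollection by the feature
#' property `area_id` and writes a FeatureCollection whose properties
#' carry `smr`, `category_index` (1-7), `category_label` and a suggested
#' fill color (three blues below, pale yellow around 1, three browns
#' above). Features whose id has no SMR value, and areas without a
#' polygon, are dropped with a logged message.
#'
#' @param polygons path to a GeoJSON FeatureCollection (features must
#'   carry `properties.area_id`).
#' @param smrTable data.frame with `area_id` and `smr` columns.
#' @param path output GeoJSON path.
#' @return `path` invisibly; attribute `nWritten`/`nDropped` on the
#'   return value report the join.
#' @export
writeMapGeoJSON <- function(polygons, smrTable, path) {
  gj <- jsonlite::fromJSON(polygons, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("polygons file is not a GeoJSON FeatureCollection")
  }
  pal <- c("#2166ac", "#67a9cf", "#d1e5f0", "#ffffcc",
           "#d8b365", "#bf812d", "#8c510a")
  cat7 <- categorizeSMR(smrTable$smr)
  vals <- data.frame(area_id = smrTable$area_id, smr = smrTable$smr,
                     category_index = cat7$category_index,
                     category_label = as.character(cat7$category_label),
                     stringsAsFactors = FALSE)
  featIds <- vapply(gj$features, function(f) {
    id <- f$properties$area_id
    if (is.null(id)) NA_character_ else as.character(id)
  }, "")
  keep <- list()
  for (i in seq_along(gj$features)) {
    j <- match(featIds[i], vals$area_id)
    if (is.na(j)) next
    f <- gj$features[[i]]
    f$properties$smr <- vals$smr[j]
    f$properties$category_index <- vals$category_index[j]
    f$properties$category_label <- vals$category_label[j]
    f$properties$fill <- pal[vals$category_index[j]]
    keep[[length(keep) + 1L]] <- f
  }
  dropped <- sum(!featIds %in% vals$area_id)
  if (dropped) {
    .logStage("map", sprintf("%d polygon(s) without SMR value dropped",
                             dropped))
  }
  missingPoly <- setdiff(vals$area_id, featIds)
  if (length(missingPoly)) {
    .logStage("map", sprintf("%d area(s) without polygon omitted",
                             length(missingPoly)))
  }
  out <- list(type = "FeatureCollection", features = keep)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  res <- invisible(path)
  attr(res, "nWritten") <- length(keep)
  attr(res, "nDropped") <- dropped
  invisible(res)
}

## md5 of the serialized configuration, via a temp file (provenance only)
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "mcmc")],
                              auto_unbox = TRUE, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full mapping pipeline
#'
#' For each requested gender x age-group stratum: computes raw SMRs and
#' their 90%-range fold difference; fits the covariate-free BYM model for
#' smoothed SMRs (with map categories); fits the decile model
#' (`unadjusted`) and the decile + socioeconomic model (`adjusted`) for
#' rate-ratio tables; the adjusted fit also yields residual SMRs. Writes
#' per-stratum CSVs, a combined rate-ratio table, optional GeoJSON maps,
#' and a JSON manifest recording the seed, a configuration hash,
#' record-exclusion accounting and convergence flags.
#'
#' @param config a [runConfig()] (or [readRunConfig()]) list.
#' @return Invisibly, a list with `manifest`, `paths`, `summaries` and
#'   `exitStatus` (0 = clean, 2 = completed with warnings such as
#'   non-convergence or dropped records).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "smrmapRunConfig"))
  t0 <- Sys.time()
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  warnings_ <- character()

  ## ---- graph ----
  graph <- readNeighborList(config$neighbors)
  if (!is.null(config$extraEdges)) graph <- addEdges(graph, config$extraEdges)
  .logStage("graph", sprintf("%d areas, %d component(s)", length(graph),
                             nComponents(graph)))

  ## ---- counts with exclusion accounting ----
  cnt <- read.csv(config$counts, colClasses = c(area_id = "character"))
  bad <- is.na(cnt$area_id) | cnt$area_id == "" |
    is.na(cnt$age_band) | cnt$age_band == "" |
    is.na(cnt$gender) | cnt$gender == ""
  totalEvents <- sum(cnt$count)
  excludedEvents <- sum(cnt$count[bad])
  if (excludedEvents > 0) {
    warnings_ <- c(warnings_, sprintf(
      "%d event(s) (%.1f%%) excluded: missing area or age assignment",
      excludedEvents, 100 * excludedEvents / totalEvents))
    .logStage("counts", warnings_[length(warnings_)])
  }
  cnt <- cnt[!bad, , drop = FALSE]

  ## ---- assemble experiment (aggregating municipalities if asked) ----
  ae <- readAreaExperiment(cnt, config$population, config$covariates,
                           graph = graph)
  if (!is.null(config$mergeMap)) {
    mm <- readMergeMap(config$mergeMap)
    agg <- aggregateAreas(graph, mm,
                          additiveTables = list(events = events(ae),
                                                personYears = personYears(ae)))
    rd <- as.data.frame(SummarizedExperiment::rowData(ae))
    w <- rowSums(personYears(ae))
    grp <- setNames(areaIds(graph), areaIds(graph))
    grp[names(mm)] <- mm
    rd2 <- do.call(rbind, lapply(split(seq_len(nrow(rd)), grp[rownames(rd)]),
      function(ix) {
        as.data.frame(lapply(rd[ix, , drop = FALSE], function(col) {
          if (is.numeric(col)) sum(col * w[ix]) / sum(w[ix]) else col[1]
        }))
      }))
    rd2 <- rd2[areaIds(agg$graph), , drop = FALSE]
    ae <- AreaExperiment(agg$tables$events, agg$tables$personYears,
                         rowData = rd2, graph = agg$graph)
    graph <- agg$graph
    .logStage("aggregate", sprintf("%d -> %d areas", length(grp),
                                   length(graph)))
  }

  ## ---- covariate design ----
  rd <- as.data.frame(SummarizedExperiment::rowData(ae))
  deciles <- assignDeciles(setNames(rd$density, rownames(ae)))
  covZ <- transformCovariates(
    rd[, c("single_person_hh_pct", "unmarried_pct", "unemployment_pct",
           "college_pct")],
    logColumns = c("single_person_hh_pct", "college_pct")
  )
  designs <- list(
    unadjusted = buildDesign(deciles, intercept = FALSE),
    adjusted = buildDesign(deciles, covZ, adjusted = TRUE, intercept = FALSE)
  )

  ## ---- per-stratum fits ----
  paths <- list()
  summaries <- list()
  rangeRows <- list()
  convergence <- list()
  for (stratum in config$strata) {
    parts <- strsplit(stratum, ":", fixed = TRUE)[[1]]
    sd <- stratumData(ae, gender = parts[1], ageGroup = parts[2])
    tag <- gsub("[^a-z0-9]+", "_", tolower(stratum))
    raw <- rawSMR(setNames(sd$observed, sd$area_id),
                  setNames(sd$expected, sd$area_id))
    p <- file.path(config$outputDir, sprintf("raw_smr_%s.csv", tag))
    write.csv(cbind(stratum = stratum, raw), p, row.names = FALSE)
    paths[[paste0("raw_", tag)]] <- p
    ## sparse strata can have a zero 5th percentile; report NA, don't stop
    safeRange <- function(x) tryCatch(rangeRatio(x), error = function(e) {
      warnings_ <<- c(warnings_, paste0(stratum, ": ", conditionMessage(e)))
      list(qLower = NA_real_, qUpper = NA_real_, raw = NA_real_,
           rounded = NA_real_)
    })
    rawRange <- safeRange(raw$smr)

    mc <- config$mcmc
    mc$seed <- config$seed + 13L * match(stratum, config$strata)
    .logStage("fit", stratum, "smoothing model")
    fit0 <- bymFit(sd$observed, sd$expected, design = NULL, graph = graph,
                   config = mc)
    sm0 <- suppressWarnings(bymSummary(fit0, mode = "smoothed"))
    convergence[[paste0(stratum, ":smoothing")]] <-
      attr(bymDiagnostics(fit0), "converged")
    cats <- categorizeSMR(sm0$areas$smr)
    smoothTab <- cbind(stratum = stratum, sm0$areas,
                       category_index = cats$category_index,
                       category_label = as.character(cats$category_label))
    p <- file.path(config$outputDir, sprintf("smoothed_smr_%s.csv", tag))
    write.csv(smoothTab, p, row.names = FALSE)
    paths[[paste0("smoothed_", tag)]] <- p
    smRange <- safeRange(sm0$areas$smr)
    rangeRows[[stratum]] <- data.frame(
      stratum = stratum,
      raw_q5 = rawRange$qLower, raw_q95 = rawRange$qUpper,
      raw_fold = rawRange$rounded,
      smoothed_q5 = smRange$qLower, smoothed_q95 = smRange$qUpper,
      smoothed_fold = smRange$rounded, stringsAsFactors = FALSE
    )
    if (!is.null(config$polygons)) {
      p <- file.path(config$outputDir, sprintf("map_smoothed_%s.geojson", tag))
      writeMapGeoJSON(config$polygons,
                      data.frame(area_id = sm0$areas$area_id,
                                 smr = sm0$areas$smr), p)
      paths[[paste0("map_", tag)]] <- p
    }

    summaries[[stratum]] <- list()
    for (mode in config$modes) {
      .logStage("fit", stratum, mode, "model")
      mc2 <- mc
      mc2$seed <- mc$seed + if (mode == "adjusted") 1L else 2L
      fit <- bymFit(sd$observed, sd$expected, design = designs[[mode]],
                    graph = graph, config = mc2)
      convergence[[paste0(stratum, ":", mode)]] <-
        attr(bymDiagnostics(fit), "converged")
      sm <- suppressWarnings(
        bymSummary(fit, mode = if (mode == "adjusted") "adjusted"
                   else "smoothed"))
      summaries[[stratum]][[mode]] <- sm
      if (mode == "adjusted") {
        cats <- categorizeSMR(sm$areas$smr)
        resTab <- cbind(stratum = stratum, sm$areas,
                        category_index = cats$category_index,
                        category_label = as.character(cats$category_label))
        p <- file.path(config$outputDir,
                       sprintf("residual_smr_%s.csv", tag))
        write.csv(resTab, p, row.names = FALSE)
        paths[[paste0("residual_", tag)]] <- p
        resRange <- safeRange(sm$areas$smr)
        rangeRows[[stratum]]$residual_q5 <- resRange$qLower
        rangeRows[[stratum]]$residual_q95 <- resRange$qUpper
        rangeRows[[stratum]]$residual_fold <- resRange$rounded
      }
    }
  }

  rrPath <- file.path(config$outputDir, "rr_table.csv")
  writeRRTable(summaries, rrPath)
  paths$rr_table <- rrPath
  rngPath <- file.path(config$outputDir, "range_report.csv")
  rangeTab <- do.call(rbind, lapply(rangeRows, function(d) {
    for (cl in c("residual_q5", "residual_q95", "residual_fold")) {
      if (is.null(d[[cl]])) d[[cl]] <- NA_real_
    }
    d
  }))
  rownames(rangeTab) <- NULL
  write.csv(rangeTab, rngPath, row.names = FALSE)
  paths$range_report <- rngPath

  nonConverged <- vapply(convergence, isFALSE, TRUE)
  if (any(nonConverged)) {
    warnings_ <- c(warnings_, paste("NON-CONVERGED:",
      paste(names(convergence)[nonConverged], collapse = ", ")))
  }
  manifest <- list(
    seed = config$seed,
    configHash = .configHash(config),
    package = as.character(utils::packageVersion("smrmap")),
    rVersion = R.version.string,
    nAreas = length(graph),
    nComponents = nComponents(graph),
    totalEvents = totalEvents,
    excludedEvents = excludedEvents,
    excludedPercent = roundHalfUp(100 * excludedEvents /
                                    max(totalEvents, 1), 1),
    strata = config$strata,
    modes = config$modes,
    mcmc = config$mcmc,
    convergence = convergence,
    nonConverged = any(nonConverged),
    warnings = warnings_,
    elapsedSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manPath <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths$manifest <- manPath
  .logStage("done", sprintf("%.1fs, %d output file(s)",
                            manifest$elapsedSeconds, length(paths)))
  invisible(list(
    manifest = manifest, paths = paths, summaries = summaries,
    rangeReport = rangeTab,
    exitStatus = if (length(warnings_)) 2L else 0L
  ))
}
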