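#' Regular lattice area graph, optionally with island blocks
#'
#' Builds a 4-neighbor grid graph — the standard stand-in for an
#' administrative adjacency structure — and optionally appends detached
#' island blocks that are connected back to the mainland by single
#' "sea-route" edges via [addEdges()].
#'
#' @param nrows,ncols lattice dimensions (`nrows * ncols >= 4`).
#' @param islands number of detached island blocks to append.
#' @param islandSize `c(rows, cols)` of each island block.
#' @param bridge connect each island to the mainland with one extra edge?
#'   With `bridge = FALSE` the islands stay separate components.
#' @return An [AreaGraph-class]; mainland ids `m<row>x<col>`, island ids
#'   `i<k>n<j>`.
#' @export
makeLattice <- function(nrows, ncols, islands = 0, islandSize = c(2, 2),
                        bridge = TRUE) {
  if (nrows * ncols < 4) stop("lattice must have at least 4 areas")
  gridEdges <- function(nr, nc, ids) {
    idx <- function(r, c) (r - 1L) * nc + c
    e <- NULL
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        if (c < nc) e <- rbind(e, c(idx(r, c), idx(r, c + 1L)))
        if (r < nr) e <- rbind(e, c(idx(r, c), idx(r + 1L, c)))
      }
    }
    cbind(ids[e[, 1]], ids[e[, 2]])
  }
  mainIds <- as.vector(outer(seq_len(ncols), seq_len(nrows),
                             function(c, r) sprintf("m%02dx%02d", r, c)))
  edges <- gridEdges(nrows, ncols, mainIds)
  ids <- mainIds
  bridges <- NULL
  if (islands > 0) {
    for (k in seq_len(islands)) {
      isIds <- as.vector(outer(
        seq_len(islandSize[2]), seq_len(islandSize[1]),
        function(c, r) sprintf("i%dn%02d", k, (r - 1L) * islandSize[2] + c)
      ))
      if (prod(islandSize) > 1) {
        edges <- rbind(edges, gridEdges(islandSize[1], islandSize[2], isIds))
      }
      ids <- c(ids, isIds)
      # deterministic sea route: island corner to a mainland border cell
      bridges <- rbind(bridges,
                       c(isIds[1], mainIds[min(k * 3 - 2, length(mainIds))]))
    }
  }
  g <- AreaGraph(ids, edges)
  if (islands > 0 && bridge) g <- addEdges(g, bridges)
  g
}

#' Sample the constrained ICAR field
#'
#' Draws from the intrinsic CAR distribution with precision
#' `tau_u * (D - W)`, restricted to the sum-to-zero subspace of each
#' connected component, by spectral decomposition of the precision on its
#' row space: `u = V diag(1/sqrt(tau_u * lambda)) z` over the positive
#' eigenpairs. Exact at the scales used here (the eigendecomposition is
#' cached nowhere; for very large graphs a sparse-Cholesky sampler would
#' be the natural replacement).
#'
#' @param graph an [AreaGraph-class].
#' @param tauU positive precision parameter.
#' @return Numeric vector `u`, named by area id, summing to zero per
#'   component (draws from the current RNG stream).
#' @export
simulateICARField <- function(graph, tauU) {
  if (tauU <= 0) stop("tauU must be positive")
  Q <- as.matrix(icarPrecision(graph))
  eg <- eigen(Q, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  pos <- eg$values > tol
  if (!any(pos)) return(setNames(rep(0, length(graph)), areaIds(graph)))
  z <- rnorm(sum(pos))
  u <- eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(tauU * eg$values[pos]))
  setNames(as.numeric(u), areaIds(graph))
}

#' Configuration of the synthetic municipality system
#'
#' Defaults emulate the statistical shape of a national municipality
#' system observed over a multi-year period: ~400 areas, population
#' densities log-spread over four orders of magnitude (1.6 to ~22,000
#' persons per km^2) with spatial autocorrelation, person-years spanning
#' several orders of magnitude (median area ~2.7e5 person-years, i.e. a
#' median population of ~30,000 followed for 9 years), an age profile of
#' event rates rising steeply from childhood to adulthood, and four
#' spatially correlated socioeconomic covariates of which two
#' (single-person households, college education) are right-skewed on the
#' raw percent scale.
#'
#' @param nrows,ncols lattice dimensions.
#' @param islands,bridge island blocks passed to [makeLattice()].
#' @param seed integer seed (mandatory).
#' @param bands age-band labels.
#' @param densityRange range of population density (persons per km^2).
#' @param medianPersonYears person-years of the median area (pooled over
#'   the study period).
#' @param densityExponent person-years scale as `density^densityExponent`:
#'   population grows sublinearly with density because dense municipalities
#'   occupy little land (0.5 keeps the smallest areas' expected counts away
#'   from zero while person-years still span >2 orders of magnitude).
#' @param tauU,tauV true precisions of the structured and unstructured
#'   fields.
#' @param alpha true log baseline relative risk (0 = rates correctly
#'   calibrated).
#' @param betaDecile length-9 vector of true log rate ratios for deciles
#'   2..10 versus the most-urban reference (default all zero).
#' @param betaCovariates length-4 vector of true log rate ratios per unit
#'   z-score of the four covariates (default all zero).
#' @param ruralRR optional single rate ratio attached to a rural-half
#'   indicator (deciles 6-10); when set it replaces the decile/covariate
#'   effects as the true fixed-effect structure.
#' @return Named list of generator settings.
#' @export
syntheticConfig <- function(nrows = 20, ncols = 20, islands = 0,
                            bridge = TRUE, seed,
                            bands = ageBands(),
                            densityRange = c(1.6, 21898),
                            medianPersonYears = 2.7e5,
                            densityExponent = 0.5,
                            tauU = 25, tauV = 400,
                            alpha = 0,
                            betaDecile = rep(0, 9),
                            betaCovariates = rep(0, 4),
                            ruralRR = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(betaDecile) == 9, length(betaCovariates) == 4,
            densityRange[1] > 0, densityRange[2] > densityRange[1],
            medianPersonYears > 0, tauU > 0, tauV > 0)
  list(
    nrows = nrows, ncols = ncols, islands = islands, bridge = bridge,
    seed = as.integer(seed), bands = bands, densityRange = densityRange,
    medianPersonYears = medianPersonYears,
    densityExponent = densityExponent, tauU = tauU, tauV = tauV,
    alpha = alpha, betaDecile = betaDecile,
    betaCovariates = betaCovariates, ruralRR = ruralRR
  )
}

## baseline event rates per person-year by gender and 10-year band:
## an age gradient rising steeply out of childhood, higher for males
.baselineRates <- function(bands) {
  male <- c(0.5, 8, 22, 24, 28, 32, 30, 28, 32) * 1e-5
  female <- c(0.3, 4, 9, 10, 12, 13, 13, 15, 18) * 1e-5
  k <- length(bands)
  c(setNames(male[seq_len(k)], paste0("male:", bands)),
    setNames(female[seq_len(k)], paste0("female:", bands)))
}

## spatially autocorrelated standard-normal-ish latent score
.spatialScore <- function(graph, weightSpatial = 0.7) {
  f <- simulateICARField(graph, tauU = 1)
  f <- if (sd(f) > 0) f / sd(f) else f
  z <- weightSpatial * f + sqrt(1 - weightSpatial^2) * rnorm(length(graph))
  as.numeric(z)
}

#' Simulate populations and population density over an area graph
#'
#' Density is log-uniform over the configured range with spatial
#' autocorrelation (ranks of a spatially smooth score mapped onto the
#' log-density grid). Person-years scale as `density^densityExponent` with a
#' lognormal land-area-like jitter, and are split ~50/50 by gender across
#' an aging-population band profile.
#'
#' @param graph an [AreaGraph-class].
#' @param config a [syntheticConfig()] list (RNG from the current stream).
#' @return list with `personYears` (areas x `gender:band` matrix) and
#'   `density` (named vector).
#' @export
simulatePopulation <- function(graph, config) {
  n <- length(graph)
  score <- .spatialScore(graph)
  r <- rank(score, ties.method = "first")
  lo <- log10(config$densityRange[1]); hi <- log10(config$densityRange[2])
  density <- 10^(lo + (hi - lo) * (r - 1) / (n - 1))
  names(density) <- areaIds(graph)
  # person-years ~ density^exponent x lognormal jitter, target median scale
  py <- density^config$densityExponent * exp(rnorm(n, 0, 0.3))
  py <- py * config$medianPersonYears / median(py)
  bandShare <- c(0.08, 0.09, 0.10, 0.12, 0.13, 0.13, 0.14, 0.12, 0.09)
  bandShare <- bandShare[seq_along(config$bands)]
  bandShare <- bandShare / sum(bandShare)
  strata <- c(paste0("male:", config$bands), paste0("female:", config$bands))
  share <- c(0.5 * bandShare, 0.5 * bandShare)
  pm <- outer(py, share) * exp(matrix(rnorm(n * length(share), 0, 0.05),
                                      n, length(share)))
  dimnames(pm) <- list(areaIds(graph), strata)
  list(personYears = pm, density = density)
}

#' Simulate spatially correlated socioeconomic covariates
#'
#' Four area-level percent-scale covariates, each mixing a density
#' gradient, a smooth spatial field and idiosyncratic noise.
#' Single-person households and college education are generated lognormal
#' (right-skewed raw distributions); unmarried share and unemployment are
#' roughly symmetric.
#'
#' @param graph an [AreaGraph-class].
#' @param density named density vector (persons per km^2).
#' @return data.frame with columns `single_person_hh_pct`,
#'   `unmarried_pct`, `unemployment_pct`, `college_pct`.
#' @export
simulateCovariates <- function(graph, density) {
  n <- length(graph)
  dz <- as.numeric(scale(log(density)))
  lat <- function(wd) {           # wd = weight on the density gradient
    z <- wd * dz + sqrt(max(0, 1 - wd^2)) * .spatialScore(graph)
    as.numeric(scale(z))
  }
  data.frame(
    single_person_hh_pct = exp(3.20 + 0.35 * lat(0.6)),   # median ~24.5%
    unmarried_pct = pmax(28 + 5 * lat(0.4), 1),
    unemployment_pct = pmax(6 + 1.5 * lat(0.2), 0.3),
    college_pct = exp(2.60 + 0.50 * lat(0.7)),             # median ~13.5%
    row.names = areaIds(graph)
  )
}

#' Simulate observed counts from the BYM log-linear model
#'
#' `O_i ~ Poisson(E_i * exp(alpha + x_i' beta + u_i + v_i))`.
#'
#' @param expected baseline expected counts `E_i` (>= 0).
#' @param design fixed-effect design matrix or `NULL`.
#' @param truth list with `alpha`, `beta`, `u`, `v`.
#' @return Integer vector of counts; `E_i = 0` always yields 0.
#' @export
simulateCounts <- function(expected, design = NULL, truth) {
  eta <- truth$alpha + truth$u + truth$v
  if (!is.null(design) && length(truth$beta)) {
    eta <- eta + as.numeric(as.matrix(design) %*% truth$beta)
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  mu <- expected * exp(eta)
  rpois(length(mu), mu)
}

## true fixed-effect design + coefficient vector implied by a config
.truthDesign <- function(config, deciles, covZ) {
  if (!is.null(config$ruralRR)) {
    X <- cbind(rural = as.numeric(deciles >= 6))
    list(design = X, beta = c(rural = log(config$ruralRR)))
  } else {
    adj <- any(config$betaCovariates != 0)
    X <- buildDesign(deciles, covZ, adjusted = adj, intercept = FALSE)
    beta <- config$betaDecile
    names(beta) <- paste0("decile", 2:10)
    if (adj) {
      bc <- setNames(config$betaCovariates, colnames(covZ))
      beta <- c(beta, bc)
    }
    list(design = X[, seq_along(beta), drop = FALSE], beta = beta)
  }
}

#' Simulate a complete synthetic area dataset with ground truth
#'
#' End-to-end generator: lattice graph (plus optional bridged islands),
#' spatially autocorrelated log-uniform density, populations by gender x
#' age band, four socioeconomic covariates, rurality deciles, ICAR and iid
#' latent fields, and Poisson counts per gender x band stratum from the
#' BYM log-linear model with stratum-specific baseline rates.
#'
#' @param config a [syntheticConfig()] list; the seed makes the dataset
#'   fully reproducible.
#' @return list with `experiment` (an [AreaExperiment-class] carrying the
#'   graph, density, covariates and decile in `rowData`), `truth`
#'   (`alpha`, `beta`, `u`, `v`, `tauU`, `tauV`, `design`, `seed`) and
#'   `rates` (the true baseline `gender:band` rates).
#' @export
simulateAreaData <- function(config) {
  set.seed(config$seed)
  g <- makeLattice(config$nrows, config$ncols, islands = config$islands,
                   bridge = config$bridge)
  pop <- simulatePopulation(g, config)
  cov <- simulateCovariates(g, pop$density)
  deciles <- assignDeciles(pop$density)
  covZ <- transformCovariates(cov, logColumns = c("single_person_hh_pct",
                                                  "college_pct"))
  td <- .truthDesign(config, deciles, covZ)
  u <- simulateICARField(g, config$tauU)
  v <- rnorm(length(g), 0, 1 / sqrt(config$tauV))
  truth <- list(
    alpha = config$alpha, beta = td$beta, u = u, v = v,
    tauU = config$tauU, tauV = config$tauV, design = td$design,
    seed = config$seed
  )
  rates <- .baselineRates(config$bands)
  strata <- colnames(pop$personYears)
  ev <- matrix(0L, nrow(pop$personYears), length(strata),
               dimnames = dimnames(pop$personYears))
  thetaEta <- truth$alpha + u + v +
    as.numeric(as.matrix(td$design) %*% td$beta)
  for (s in strata) {
    eBase <- pop$personYears[, s] * rates[[s]]
    ev[, s] <- rpois(length(eBase), eBase * exp(thetaEta))
  }
  rd <- cbind(data.frame(density = pop$density, decile = deciles,
                         row.names = areaIds(g)), cov)
  ae <- AreaExperiment(ev, pop$personYears, rowData = rd, graph = g)
  list(experiment = ae, truth = truth, rates = rates)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits the same CSV/GAL files [runPipeline()] reads — counts,
#' population, covariates, neighbor list — plus a JSON sidecar holding the
#' generator's ground truth, so synthetic runs exercise the real I/O path.
#'
#' @param sim result of [simulateAreaData()].
#' @param dir output directory (created if needed).
#' @return Named list of the file paths written.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ae <- sim$experiment
  cd <- SummarizedExperiment::colData(ae)
  long <- function(m, valueName) {
    df <- data.frame(
      area_id = rep(rownames(m), times = ncol(m)),
      gender = rep(cd$gender, each = nrow(m)),
      age_band = rep(cd$ageBand, each = nrow(m)),
      value = as.vector(m), stringsAsFactors = FALSE
    )
    names(df)[4] <- valueName
    df
  }
  paths <- list(
    counts = file.path(dir, "counts.csv"),
    population = file.path(dir, "population.csv"),
    covariates = file.path(dir, "covariates.csv"),
    neighbors = file.path(dir, "neighbors.gal"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(long(events(ae), "count"), paths$counts, row.names = FALSE)
  write.csv(long(personYears(ae), "person_years"), paths$population,
            row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(ae))
  cvs <- cbind(area_id = rownames(ae),
               rd[, c("density", "single_person_hh_pct", "unmarried_pct",
                      "unemployment_pct", "college_pct")])
  write.csv(cvs, paths$covariates, row.names = FALSE)
  writeNeighborList(areaGraph(ae), paths$neighbors)
  tr <- sim$truth
  jsonlite::write_json(
    list(alpha = tr$alpha, beta = as.list(tr$beta), tauU = tr$tauU,
         tauV = tr$tauV, seed = tr$seed, u = unname(tr$u), v = unname(tr$v)),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  paths
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates a dataset with known truth, fits the BYM model to
#' the pooled counts, and scores recovery of the fixed-effect rate
#' ratios: bias and RMSE of the posterior-median RRs, empirical coverage
#' of the 95% credible intervals, and the significance-star false-positive
#' rate when the truth is null. Non-finite or non-converged fits are
#' counted, never silently dropped.
#'
#' @param config a [syntheticConfig()] list; replicate `r` reuses it with
#'   seed `config$seed + r`.
#' @param replicates number of simulate-fit cycles.
#' @param mcmc an [mcmcConfig()] list used for every fit (its seed is
#'   offset per replicate).
#' @return list with `perReplicate` (data.frame: replicate, term, trueRR,
#'   estimate, ci_low, ci_high, covered, significant), `summary`
#'   (per-term bias, rmse, coverage, starRate) and `nonConverged` count.
#' @export
recoveryExperiment <- function(config, replicates, mcmc) {
  rows <- list()
  nonConv <- 0L
  for (r in seq_len(replicates)) {
    cfgR <- config
    cfgR$seed <- config$seed + r
    sim <- simulateAreaData(cfgR)
    ae <- sim$experiment
    sd <- stratumData(ae, gender = "both", ageGroup = "all")
    mc <- mcmc
    mc$seed <- mcmc$seed + 7919L * r
    fit <- bymFit(sd$observed, sd$expected, design = sim$truth$design,
                  graph = areaGraph(ae), config = mc)
    dg <- bymDiagnostics(fit)
    if (isFALSE(attr(dg, "converged"))) nonConv <- nonConv + 1L
    sm <- suppressWarnings(bymSummary(fit, mode = "adjusted"))
    rr <- sm$rateRatios
    trueRR <- exp(sim$truth$beta)[rr$term]
    rows[[r]] <- data.frame(
      replicate = r, term = rr$term, trueRR = unname(trueRR),
      estimate = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
      covered = rr$ci_low <= trueRR & trueRR <= rr$ci_high,
      significant = rr$significant,
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$term), function(d) {
    data.frame(
      term = d$term[1], trueRR = d$trueRR[1],
      meanEstimate = mean(d$estimate),
      bias = mean(d$estimate - d$trueRR),
      rmse = sqrt(mean((d$estimate - d$trueRR)^2)),
      coverage = mean(d$covered),
      starRate = mean(d$significant),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  list(perReplicate = per, summary = agg, nonConverged = nonConv)
}
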