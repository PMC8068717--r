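test_that("lattice generator has the closed-form edge count", {
  g22 <- makeLattice(2, 2)
  expect_identical(length(g22), 4L)
  expect_equal(sum(lengths(adjacencyList(g22))) / 2, 4)

  g <- makeLattice(20, 20)
  expect_identical(length(g), 400L)
  expect_equal(sum(lengths(adjacencyList(g))) / 2, 760)  # 2nm - n - m

  gi <- makeLattice(4, 4, islands = 1)
  expect_identical(nComponents(gi), 1L)
  gisep <- makeLattice(4, 4, islands = 2, bridge = FALSE)
  expect_identical(nComponents(gisep), 3L)
  expect_error(makeLattice(1, 2), "at least 4")
})

test_that("constrained ICAR field: sum-to-zero, covariance, precision limit", {
  g <- makeLattice(3, 4, islands = 1, bridge = FALSE)
  set.seed(51)
  u <- simulateICARField(g, tauU = 2)
  lab <- unname(componentLabels(g))
  for (k in unique(lab)) expect_lt(abs(sum(u[lab == k])), 1e-10)

  # empirical covariance vs pseudo-inverse of tau * Q on a 3x3 lattice
  g9 <- makeLattice(3, 3)
  Q <- as.matrix(icarPrecision(g9))
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-9
  pinv <- eg$vectors[, pos] %*% diag(1 / eg$values[pos]) %*%
    t(eg$vectors[, pos])
  tau <- 3
  set.seed(52)
  draws <- t(replicate(10000, simulateICARField(g9, tau)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - pinv / tau)), 0.1 * max(pinv / tau))

  set.seed(53)
  tiny <- simulateICARField(g9, tauU = 1e9)
  expect_lt(sqrt(sum(tiny^2)), 1e-3)
  expect_error(simulateICARField(g9, tauU = -1), "positive")
})

test_that("simulated densities and populations match the configured scales", {
  cfg <- syntheticConfig(seed = 60)
  g <- makeLattice(cfg$nrows, cfg$ncols)
  set.seed(60)
  pop <- simulatePopulation(g, cfg)
  expect_gte(log10(max(pop$density) / min(pop$density)), 3)
  expect_equal(median(rowSums(pop$personYears)), cfg$medianPersonYears,
               tolerance = 0.02)
  expect_identical(as.integer(max(table(assignDeciles(pop$density))) -
                     min(table(assignDeciles(pop$density)))), 0L)

  # total person-years scales linearly with the scale parameter
  cfg2 <- cfg; cfg2$medianPersonYears <- 2 * cfg$medianPersonYears
  set.seed(60)
  pop2 <- simulatePopulation(g, cfg2)
  expect_equal(sum(pop2$personYears), 2 * sum(pop$personYears),
               tolerance = 1e-9)
})

test_that("counts follow the BYM log-linear model", {
  set.seed(61)
  n <- 4000
  E <- runif(n, 10, 30)
  truthNull <- list(alpha = 0, beta = numeric(0), u = rep(0, n),
                    v = rep(0, n))
  O <- simulateCounts(E, NULL, truthNull)
  expect_equal(mean(O / E), 1, tolerance = 0.02)

  X <- cbind(rural = rbinom(n, 1, 0.5))
  truth <- list(alpha = 0, beta = log(2), u = rep(0, n), v = rep(0, n))
  O2 <- simulateCounts(E, X, truth)
  ratio <- (sum(O2[X == 1]) / sum(E[X == 1])) /
    (sum(O2[X == 0]) / sum(E[X == 0]))
  expect_equal(ratio, 2, tolerance = 0.05)

  expect_identical(simulateCounts(c(0, 0), NULL,
                                  list(alpha = 0, beta = numeric(0),
                                       u = c(0, 0), v = c(0, 0))),
                   c(0L, 0L))
  expect_error(simulateCounts(c(1, 1), NULL,
                              list(alpha = Inf, beta = numeric(0),
                                   u = c(0, 0), v = c(0, 0))),
               "non-finite")
})

test_that("generator is deterministic and round-trips through the I/O path", {
  cfg <- syntheticConfig(nrows = 6, ncols = 6, seed = 62)
  s1 <- simulateAreaData(cfg)
  s2 <- simulateAreaData(cfg)
  expect_identical(events(s1$experiment), events(s2$experiment))
  expect_identical(s1$truth$u, s2$truth$u)

  dir <- file.path(tempdir(), "synth-roundtrip")
  paths <- writeSyntheticData(s1, dir)
  g <- readNeighborList(paths$neighbors)
  ae <- readAreaExperiment(paths$counts, paths$population,
                           paths$covariates, graph = g)
  expect_identical(areaIds(ae), areaIds(s1$experiment))
  expect_equal(unname(events(ae)[, colnames(events(s1$experiment))]),
               unname(events(s1$experiment)))
  expect_equal(sum(personYears(ae)), sum(personYears(s1$experiment)),
               tolerance = 1e-9)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$tauU, cfg$tauU)
})

test_that("skewed covariates become symmetric after the log transform", {
  cfg <- syntheticConfig(nrows = 32, ncols = 32, seed = 63)
  sim <- simulateAreaData(cfg)
  rd <- as.data.frame(SummarizedExperiment::rowData(sim$experiment))
  expect_gt(sampleSkewness(rd$single_person_hh_pct), 0.5)
  expect_gt(sampleSkewness(rd$college_pct), 0.5)
  z <- transformCovariates(
    rd[, c("single_person_hh_pct", "unmarried_pct", "unemployment_pct",
           "college_pct")],
    logColumns = c("single_person_hh_pct", "college_pct")
  )
  for (j in seq_len(ncol(z))) {
    expect_lt(abs(sampleSkewness(z[, j])), 0.5)
  }
})

test_that("stratum tables from synthetic data close and stay consistent", {
  sim <- simulateAreaData(syntheticConfig(nrows = 8, ncols = 8, seed = 64))
  for (gdr in c("male", "female", "both")) {
    for (grp in c("all", "0-39", "40-59", "60+")) {
      sd1 <- stratumData(sim$experiment, gdr, grp)
      expect_equal(sum(sd1$expected), sum(sd1$observed), tolerance = 1e-12)
    }
  }
  allT <- stratumData(sim$experiment, "both", "all")
  expect_equal(sum(allT$observed), sum(events(sim$experiment)))
})
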