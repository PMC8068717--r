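pathGraph3 <- function() AreaGraph(c("a", "b", "c"),
                                   cbind(c("a", "b"), c("b", "c")))

test_that("ICAR quadratic form matches direct pairwise enumeration", {
  g <- pathGraph3()
  expect_equal(icarQuadratic(c(0, 1, 3), g), 5)          # 1 + 4
  expect_equal(icarQuadratic(c(2, 2, 2), g), 0)          # null space
  g0 <- AreaGraph(c("x", "y"))                           # no edges
  expect_equal(icarQuadratic(c(10, -4), g0), 0)
  expect_error(icarQuadratic(1:2, g), "length")

  set.seed(31)
  for (rep in 1:6) {
    n <- sample(5:50, 1)
    ids <- sprintf("n%02d", seq_len(n))
    g <- AreaGraph(ids, randomEdges(n, 0.15, ids))
    u <- rnorm(n)
    expect_equal(icarQuadratic(u, g),
                 bruteIcarQuadratic(u, adjacencyList(g)), tolerance = 1e-12)
  }
})

test_that("ICAR precision is D - W with one null dimension per component", {
  g <- pathGraph3()
  Q <- as.matrix(icarPrecision(g))
  expect_equal(unname(Q),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  set.seed(32)
  ids <- sprintf("n%02d", 1:9)
  g2 <- AreaGraph(ids, rbind(randomEdges(5, 0.6, ids[1:5]),
                             randomEdges(4, 0.6, ids[6:9])))
  Q2 <- as.matrix(icarPrecision(g2))
  expect_equal(as.numeric(Q2 %*% rep(1, 9)), rep(0, 9), tolerance = 1e-12)
  ev <- eigen(Q2, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-9), as.integer(nComponents(g2)))
})

test_that("precision Gibbs draw follows the conjugate Gamma", {
  # u = (0,1,3,3) on a path: S = 1 + 4 + 0 = 5; shape 1 + 3/2, rate b + 5/2
  g4 <- AreaGraph(letters[1:4], cbind(letters[1:3], letters[2:4]))
  u <- c(0, 1, 3, 3)
  expect_equal(icarQuadratic(u, g4), 5)
  shape <- 1 + (4 - 1) / 2
  rate <- 5e-5 + 5 / 2
  set.seed(33)
  draws <- replicate(1e5, sampleTau(u, g4))
  analyticMean <- shape / rate
  analyticSd <- sqrt(shape) / rate
  expect_lt(abs(mean(draws) - analyticMean),
            3 * analyticSd / sqrt(length(draws)))
  ks <- ks.test(draws, pgamma, shape = shape, rate = rate)
  expect_gt(ks$p.value, 0.001)

  # zero field: posterior reduces to Gamma(a + (n-c)/2, b)
  set.seed(34)
  z <- replicate(2e4, sampleTau(rep(0, 4), g4))
  expect_equal(mean(z), shape / 5e-5, tolerance = 0.05)

  # unstructured field: Gamma(a + n/2, b + sum(v^2)/2)
  v <- c(1, -1, 2, 0)
  set.seed(35)
  dv <- replicate(1e5, sampleTau(v, graph = NULL))
  shapeV <- 1 + 2; rateV <- 5e-5 + 3
  expect_lt(abs(mean(dv) - shapeV / rateV),
            3 * sqrt(shapeV) / rateV / sqrt(length(dv)))
})

test_that("log-posterior agrees with a naive second implementation", {
  set.seed(36)
  n <- 12
  ids <- sprintf("n%02d", seq_len(n))
  g <- AreaGraph(ids, rbind(randomEdges(n, 0.25, ids), cbind(ids[1], ids[n])))
  E <- runif(n, 2, 40)
  O <- rpois(n, E)
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  mkState <- function() list(
    alpha = rnorm(1, 0, 0.3), beta = rnorm(2, 0, 0.2),
    u = rnorm(n, 0, 0.5), v = rnorm(n, 0, 0.2),
    tauU = rgamma(1, 2, 0.5), tauV = rgamma(1, 2, 0.5)
  )
  for (rep in 1:4) {
    s1 <- mkState(); s2 <- mkState()
    d1 <- bymLogPosterior(s1, O, E, X, g) - bymLogPosterior(s2, O, E, X, g)
    d2 <- bruteLogPosterior(s1, O, E, X, adjacencyList(g),
                            componentLabels(g)) -
      bruteLogPosterior(s2, O, E, X, adjacencyList(g), componentLabels(g))
    expect_equal(d1, d2, tolerance = 1e-9)
  }
  bad <- mkState(); bad$u[1] <- NaN
  expect_error(bymLogPosterior(bad, O, E, X, g), "non-finite")
})

test_that("log-posterior is increasing in O_i where theta_i > 1", {
  g <- pathGraph3()
  st <- list(alpha = 0.5, beta = numeric(0), u = c(0.1, -0.2, 0.1),
             v = c(0, 0, 0), tauU = 2, tauV = 2)
  E <- c(5, 5, 5)
  vals <- sapply(3:8, function(o) {
    bymLogPosterior(st, c(o, 4, 4), E, NULL, g)
  })
  expect_true(all(diff(vals) > 0))
})

test_that("ICAR term is shift-invariant within a connected graph when the
           intercept compensates", {
  set.seed(37)
  g <- makeLattice(4, 4)
  n <- length(g)
  E <- runif(n, 5, 30); O <- rpois(n, E)
  st <- list(alpha = 0.2, beta = numeric(0), u = rnorm(n, 0, 0.4),
             v = rnorm(n, 0, 0.2), tauU = 3, tauV = 5)
  for (shift in c(-0.7, 0.31)) {
    st2 <- st
    st2$u <- st$u + shift
    st2$alpha <- st$alpha - shift
    expect_equal(bymLogPosterior(st2, O, E, NULL, g),
                 bymLogPosterior(st, O, E, NULL, g), tolerance = 1e-8)
  }
})

test_that("MCMC is bit-reproducible and honors the sum-to-zero constraint", {
  set.seed(38)
  g <- makeLattice(4, 4, islands = 1, bridge = FALSE)  # two components
  n <- length(g)
  E <- runif(n, 5, 50)
  O <- rpois(n, E * exp(rnorm(n, 0, 0.15)))
  cfg <- mcmcConfig(iterations = 400, burnin = 200, seed = 99)
  f1 <- bymFit(O, E, graph = g, config = cfg)
  f2 <- bymFit(O, E, graph = g, config = cfg)
  expect_identical(f1@draws, f2@draws)

  u <- posteriorDraws(f1, "u")
  lab <- unname(componentLabels(g))
  for (k in unique(lab)) {
    expect_lt(max(abs(rowSums(u[, lab == k, drop = FALSE]))), 1e-10)
  }
})

test_that("zero-expected areas are dropped from the likelihood with a
           warning", {
  set.seed(39)
  g <- makeLattice(3, 3)
  E <- c(0, runif(8, 5, 20))
  O <- c(3, rpois(8, E[-1]))
  expect_warning(
    fit <- bymFit(O, E, graph = g,
                  config = mcmcConfig(iterations = 300, burnin = 150,
                                      seed = 7)),
    "zero expected"
  )
  expect_s4_class(fit, "BymFit")
})

test_that("single-area Poisson-lognormal posterior matches quadrature", {
  # O = 5, E = 10, theta = exp(v), v ~ N(0, 1): an exactly integrable toy
  g1 <- AreaGraph("only")
  O <- 5; E <- 10
  fit <- bymFit(O, E, graph = g1,
                config = mcmcConfig(iterations = 22000, burnin = 2000,
                                    seed = 11),
                alpha = FALSE, spatial = FALSE, fixedTauV = 1)
  th <- exp(posteriorDraws(fit, "v")[, 1])
  target <- quadraturePoissonLognormalMean(O, E, tauV = 1)
  mcse <- sd(th) / sqrt(effectiveSize(matrix(th, ncol = 1)))
  expect_lt(abs(mean(th) - target), 3 * mcse)
})

test_that("summaries flag credible intervals excluding one", {
  set.seed(40)
  g <- makeLattice(5, 5)
  n <- length(g)
  X <- cbind(grp = rep(c(0, 1), length.out = n))
  E <- rep(400, n)
  O <- rpois(n, E * exp(0.15 * X[, 1]))
  fit <- bymFit(O, E, design = X, graph = g,
                config = mcmcConfig(iterations = 1200, burnin = 600,
                                    seed = 12))
  sm <- suppressWarnings(bymSummary(fit, mode = "adjusted"))
  rr <- sm$rateRatios
  expect_identical(rr$significant, rr$ci_low > 1 | rr$ci_high < 1)
  expect_true(rr$ci_low <= rr$rr && rr$rr <= rr$ci_high)
  # residual SMRs exclude the intercept; smoothed include it
  smo <- suppressWarnings(bymSummary(fit, mode = "smoothed"))
  expect_equal(
    median(exp(posteriorDraws(fit, "u")[, 1] + posteriorDraws(fit, "v")[, 1])),
    sm$areas$smr[1]
  )
  expect_false(isTRUE(all.equal(smo$areas$smr, sm$areas$smr)))
})

test_that("split R-hat separates mixed from stuck chains", {
  set.seed(41)
  ok <- cbind(rnorm(3000), rnorm(3000))
  expect_lt(abs(splitRhat(ok) - 1), 0.01)
  stuck <- cbind(rnorm(500, 0), rnorm(500, 8))
  expect_gt(splitRhat(stuck), 1.5)
})

test_that("effective sample size recovers the AR(1) closed form", {
  set.seed(42)
  n <- 40000; rho <- 0.5
  x <- as.numeric(arima.sim(list(ar = rho), n))
  ess <- effectiveSize(matrix(x, ncol = 1))
  expect_equal(ess, n * (1 - rho) / (1 + rho), tolerance = 0.2)
})

test_that("diagnostics table covers intercept, coefficients, precisions", {
  set.seed(43)
  g <- makeLattice(3, 3)
  E <- runif(9, 20, 60); O <- rpois(9, E)
  X <- cbind(z = rnorm(9))
  fit <- bymFit(O, E, design = X, graph = g,
                config = mcmcConfig(iterations = 500, burnin = 250,
                                    seed = 3, chains = 2))
  d <- bymDiagnostics(fit)
  expect_setequal(d$parameter, c("alpha", "z", "tau_u", "tau_v"))
  expect_true(all(is.finite(d$ess)))
  expect_true(all(is.finite(d$rhat)))
  expect_true(attr(d, "converged") %in% c(TRUE, FALSE))
})
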