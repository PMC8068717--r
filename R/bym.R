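#' ICAR pairwise quadratic form
#'
#' The kernel of the intrinsic conditional autoregressive prior:
#' `S = sum over neighbor pairs {i~j} of (u_i - u_j)^2 = u' (D - W) u`,
#' each unordered pair counted once.
#'
#' @param u numeric vector indexed by the graph's areas (names checked when
#'   present).
#' @param graph an [AreaGraph-class].
#' @return Nonnegative scalar.
#' @export
icarQuadratic <- function(u, graph) {
  stopifnot(is(graph, "AreaGraph"))
  if (length(u) != length(graph)) stop("length(u) must equal number of areas")
  if (!is.null(names(u)) && !identical(names(u), areaIds(graph))) {
    stop("names(u) do not match graph area ids")
  }
  e <- .edgeMatrix(graph@adj)
  if (!nrow(e)) return(0)
  sum((u[e[, 1]] - u[e[, 2]])^2)
}

#' ICAR precision matrix
#'
#' `Q = D - W` where `D` is the diagonal of vertex degrees and `W` the 0/1
#' adjacency matrix. `Q` is symmetric, its rows sum to zero, and its rank
#' deficiency equals the number of connected components (the ICAR prior is
#' improper: constant shifts within a component cost nothing).
#'
#' @param graph an [AreaGraph-class].
#' @return Sparse symmetric [Matrix::Matrix] of dimension n x n.
#' @export
icarPrecision <- function(graph) {
  stopifnot(is(graph, "AreaGraph"))
  W <- adjacencyMatrix(graph)
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Hyperpriors and fixed-effect prior for the BYM model
#'
#' Both random-effect precisions get Gamma(shape, rate) priors,
#' Gamma(1, 5e-5) by default — the conventional vague default for
#' disease-mapping precisions. Regression coefficients get independent
#' Normal(0, betaVar); the intercept is flat (identified through the
#' sum-to-zero constraint on the structured field).
#'
#' @param aU,bU Gamma shape and rate for the structured precision `tau_u`.
#' @param aV,bV Gamma shape and rate for the unstructured precision
#'   `tau_v`.
#' @param betaVar prior variance of each regression coefficient.
#' @return Named list of prior settings.
#' @export
bymPriors <- function(aU = 1, bU = 5e-5, aV = 1, bV = 5e-5,
                      betaVar = 1000) {
  stopifnot(aU > 0, bU > 0, aV > 0, bV > 0, betaVar > 0)
  list(aU = aU, bU = bU, aV = aV, bV = bV, betaVar = betaVar)
}

#' MCMC run configuration
#'
#' @param iterations total sweeps per chain (including burn-in).
#' @param burnin sweeps discarded; adaptation of proposal scales happens
#'   only here, so the retained chain is Markovian.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param chains number of independent chains.
#' @param seed integer random seed (mandatory; chain `k` uses
#'   `seed + 1000 * (k - 1)`).
#' @param adaptBatch adaptation batch length in sweeps.
#' @param targetSingle target acceptance rate for single-site updates.
#' @param targetJoint nominal acceptance target for a random-walk block
#'   update; retained for configuration completeness (the fitter's
#'   least-squares block proposal needs no scale tuning).
#' @return Named list of configuration values.
#' @export
mcmcConfig <- function(iterations = 4000, burnin = 2000, thin = 1,
                       chains = 1, seed, adaptBatch = 50,
                       targetSingle = 0.44, targetJoint = 0.234) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(burnin < iterations, thin >= 1, chains >= 1)
  list(
    iterations = as.integer(iterations), burnin = as.integer(burnin),
    thin = as.integer(thin), chains = as.integer(chains),
    seed = as.integer(seed), adaptBatch = as.integer(adaptBatch),
    targetSingle = targetSingle, targetJoint = targetJoint
  )
}

#' BymFit: posterior draws from the BYM hierarchical Poisson model
#'
#' @slot draws list, one element per chain; each chain is a list of
#'   matrices/vectors `alpha`, `beta`, `u`, `v`, `tauU`, `tauV` over
#'   retained iterations.
#' @slot config the [mcmcConfig()] list used.
#' @slot priors the [bymPriors()] list used.
#' @slot graph the [AreaGraph-class] the structured effect lives on.
#' @slot data list with `observed`, `expected`, `design`, `included`.
#' @slot acceptance list of mean acceptance rates per update type.
#' @export
setClass("BymFit",
  representation(
    draws = "list", config = "list", priors = "list",
    graph = "AreaGraph", data = "list", acceptance = "list"
  )
)

setMethod("show", "BymFit", function(object) {
  ch <- object@draws
  p <- ncol(ch[[1]]$beta)
  cat(sprintf(
    "BymFit: %d chain(s) x %d retained draws; %d areas, %d coefficient(s)\n",
    length(ch), length(ch[[1]]$alpha), length(object@graph), p
  ))
  cat(sprintf("  acceptance: u %.2f, v %.2f, block %.2f\n",
              object@acceptance$u, object@acceptance$v,
              object@acceptance$block))
})

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "BymFit", function(x, parameter) {
  key <- switch(parameter,
    alpha = "alpha", beta = "beta", u = "u", v = "v",
    tau_u = "tauU", tauU = "tauU", tau_v = "tauV", tauV = "tauV",
    stop("unknown parameter: ", parameter)
  )
  do.call(rbind, lapply(x@draws, function(ch) {
    d <- ch[[key]]
    if (is.matrix(d)) d else matrix(d, ncol = 1)
  }))
})

#' Gibbs draw of a random-effect precision
#'
#' Conjugate full conditional of a Gamma(a, b) prior: for the ICAR field
#' `u` on a graph with `c` connected components the conditional is
#' Gamma(a + (n - c)/2, b + S/2) with `S` the pairwise quadratic form; for
#' the iid field `v` it is Gamma(a + n/2, b + sum(v^2)/2).
#'
#' @param values the current field (`u` or `v`).
#' @param graph the [AreaGraph-class] for a structured field, or `NULL`
#'   for the unstructured one.
#' @param a,b Gamma prior shape and rate.
#' @return One precision draw (uses the current RNG stream).
#' @export
sampleTau <- function(values, graph = NULL, a = 1, b = 5e-5) {
  n <- length(values)
  if (is.null(graph)) {
    S <- sum(values^2)
    shape <- a + n / 2
  } else {
    S <- icarQuadratic(values, graph)
    shape <- a + (n - nComponents(graph)) / 2
  }
  if (S < 0) stop("negative quadratic form")
  rgamma(1, shape = shape, rate = b + S / 2)
}

#' Unnormalized log-posterior of the BYM model
#'
#' `O_i ~ Poisson(E_i * theta_i)`, `log theta_i = alpha + x_i' beta + u_i
#' + v_i`; ICAR prior on `u` with precision `tau_u`, iid Normal on `v`
#' with precision `tau_v`, Gamma hyperpriors, Normal(0, betaVar) on
#' `beta`, flat on `alpha`. Returned up to an additive constant; areas
#' with `E_i = 0` contribute nothing to the likelihood.
#'
#' @param state list with `alpha`, `beta`, `u`, `v`, `tauU`, `tauV`.
#' @param observed,expected numeric vectors over the graph's areas.
#' @param design numeric matrix (n x p) or `NULL`.
#' @param graph an [AreaGraph-class].
#' @param priors a [bymPriors()] list.
#' @return Scalar log-density (up to a constant).
#' @export
bymLogPosterior <- function(state, observed, expected, design = NULL,
                            graph, priors = bymPriors()) {
  n <- length(graph)
  u <- state$u; v <- state$v
  beta <- state$beta
  if (length(u) != n || length(v) != n) stop("u/v length mismatch")
  ok <- vapply(state, function(z) all(is.finite(z)), TRUE)
  if (!all(ok)) stop("non-finite state component(s): ",
                     paste(names(state)[!ok], collapse = ", "))
  eta <- state$alpha + u + v
  if (!is.null(design) && length(beta)) {
    eta <- eta + as.numeric(as.matrix(design) %*% beta)
  }
  use <- expected > 0
  ll <- sum(observed[use] * (log(expected[use]) + eta[use]) -
              expected[use] * exp(eta[use]))
  cN <- nComponents(graph)
  Su <- icarQuadratic(u, graph)
  lpU <- (n - cN) / 2 * log(state$tauU) - state$tauU * Su / 2
  lpV <- n / 2 * log(state$tauV) - state$tauV * sum(v^2) / 2
  lpTau <- (priors$aU - 1) * log(state$tauU) - priors$bU * state$tauU +
    (priors$aV - 1) * log(state$tauV) - priors$bV * state$tauV
  lpBeta <- if (length(beta)) -sum(beta^2) / (2 * priors$betaVar) else 0
  ll + lpU + lpV + lpTau + lpBeta
}

## greedy vertex coloring -> list of site-index classes whose members are
## mutually non-adjacent (single-site u updates can run vectorized per class)
.colorClasses <- function(graph) {
  n <- length(graph)
  if (n == 0L) return(list())
  e <- .edgeMatrix(graph@adj)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  col <- as.integer(igraph::greedy_vertex_coloring(g))
  split(seq_len(n), col)
}

#' Fit the BYM model by MCMC
#'
#' Sampler: conjugate Gibbs for the two precisions; adaptive single-site
#' random-walk Metropolis for each structured effect `u_i` (sites are
#' processed in graph-coloring classes, which is equivalent to one-at-a-time
#' updates because sites of one class are mutually non-adjacent) and each
#' unstructured effect `v_i` (conditionally independent, updated in one
#' vectorized pass); and a joint Metropolis-Hastings update of the
#' intercept/coefficient block using a one-step iteratively-reweighted
#' least-squares (Gaussian full-conditional approximation) proposal, which
#' gives near-independent block draws where a random walk would crawl.
#' After every sweep the structured field is re-centered to sum to zero
#' per connected component, the intercept absorbing the (size-weighted)
#' shift. Single-site proposal scales adapt toward 0.44 acceptance during
#' burn-in only, so retained draws come from a fixed transition kernel.
#'
#' @param observed nonnegative integer counts per area, aligned with
#'   `graph` (names checked when present).
#' @param expected expected counts per area; areas with `E_i = 0` are
#'   dropped from the likelihood with a warning.
#' @param design optional fixed-effect design matrix (n x p), without an
#'   intercept column; an `(Intercept)` column is dropped automatically.
#' @param graph an [AreaGraph-class].
#' @param config an [mcmcConfig()] list (`seed` mandatory).
#' @param priors a [bymPriors()] list.
#' @param alpha include a (flat-prior) intercept?
#' @param spatial include the ICAR field `u`?
#' @param iid include the unstructured field `v`?
#' @param fixedTauU,fixedTauV optional fixed precision values (no Gibbs
#'   update), used in oracle checks and degenerate limits.
#' @return A [BymFit-class].
#' @export
bymFit <- function(observed, expected, design = NULL, graph,
                   config, priors = bymPriors(),
                   alpha = TRUE, spatial = TRUE, iid = TRUE,
                   fixedTauU = NULL, fixedTauV = NULL) {
  stopifnot(is(graph, "AreaGraph"))
  n <- length(graph)
  O <- as.numeric(observed); E <- as.numeric(expected)
  if (length(O) != n || length(E) != n) stop("data length mismatch with graph")
  if (!is.null(names(observed)) &&
      !identical(names(observed), areaIds(graph))) {
    stop("names(observed) do not match graph area ids")
  }
  if (any(O < 0) || any(E < 0)) stop("counts must be nonnegative")
  dropIdx <- which(E == 0)
  if (length(dropIdx)) {
    warning(length(dropIdx),
            " area(s) with zero expected count dropped from the likelihood")
    O[dropIdx] <- 0  # with E=0 these areas contribute nothing
  }
  X <- NULL
  if (!is.null(design)) {
    X <- as.matrix(design)
    const <- apply(X, 2, function(cl) all(cl == cl[1]))
    if (alpha && any(const)) X <- X[, !const, drop = FALSE]
    if (ncol(X) == 0L) X <- NULL
    if (!is.null(X) && nrow(X) != n) stop("design rows must match areas")
  }
  p <- if (is.null(X)) 0L else ncol(X)

  e <- .edgeMatrix(graph@adj)
  W <- adjacencyMatrix(graph)
  deg <- as.numeric(Matrix::rowSums(W))
  comp <- graph@componentLabels
  cN <- nComponents(graph)
  compSize <- tabulate(comp, cN)
  classes <- if (spatial) .colorClasses(graph) else list()

  cfg <- config
  nKeep <- (cfg$iterations - cfg$burnin) %/% cfg$thin
  if (nKeep < 1) stop("no retained iterations under this configuration")

  runChain <- function(chainSeed) {
    set.seed(chainSeed)
    a <- if (alpha) log(max(sum(O), 0.5) / sum(E[E > 0])) else 0
    beta <- rep(0, p)
    ## small random fields: a zero start would make the first Gibbs
    ## precision draw explode (S = 0) and stall the site-level adaptation
    u <- if (spatial) rnorm(n, 0, 0.1) else rep(0, n)
    if (spatial && alpha) {
      for (kk in seq_len(cN)) u[comp == kk] <- u[comp == kk] -
          mean(u[comp == kk])
    }
    v <- if (iid) rnorm(n, 0, 0.05) else rep(0, n)
    tauU <- if (is.null(fixedTauU)) 50 else fixedTauU
    tauV <- if (is.null(fixedTauV)) 100 else fixedTauV
    xb <- if (p) as.numeric(X %*% beta) else rep(0, n)

    lsV <- rep(log(0.5), n)
    lsU <- rep(log(0.5), n)
    accV <- rep(0, n); accU <- rep(0, n)
    totV <- 0; totU <- 0; totAccV <- 0; totAccU <- 0
    totB <- 0; totAccB <- 0
    blockDim <- as.integer(alpha) + p
    ## Gaussian independence proposal for the GLM block, centered at the
    ## conditional mode (found by IWLS; the Poisson log-link conditional
    ## is strictly concave, so the mode is unique) with the curvature
    ## there, corrected by Metropolis-Hastings
    usePos <- which(E > 0)
    Xt <- cbind(if (alpha) rep(1, length(usePos)),
                if (p) X[usePos, , drop = FALSE])
    Ou <- O[usePos]; Eu <- E[usePos]
    priorPrec <- c(if (alpha) 0, rep(1 / priors$betaVar, p))
    Pm <- diag(priorPrec, nrow = blockDim)
    blockLogLik <- function(theta, off) {
      eta <- as.numeric(Xt %*% theta) + off
      sum(Ou * eta - Eu * exp(pmin(eta, 40))) -
        0.5 * sum(priorPrec * theta^2)
    }
    blockMode <- function(theta, off) {
      R <- NULL
      for (stepIt in 1:25) {
        eta <- as.numeric(Xt %*% theta) + off
        lam <- pmax(Eu * exp(pmin(eta, 40)), 1e-12)
        z <- eta - off + (Ou - lam) / lam   # offset-adjusted working response
        Cinv <- crossprod(Xt * sqrt(lam)) + Pm
        R <- chol(Cinv)
        m <- as.numeric(backsolve(R, forwardsolve(t(R),
                                                  crossprod(Xt, lam * z))))
        if (max(abs(m - theta)) < 1e-9) { theta <- m; break }
        theta <- m
      }
      list(m = theta, R = R)
    }
    logqBlock <- function(st, theta) {
      sum(log(diag(st$R))) - 0.5 * sum((st$R %*% (theta - st$m))^2)
    }
    batch <- 0

    keep <- list(
      alpha = numeric(nKeep), beta = matrix(0, nKeep, p),
      u = matrix(0, nKeep, n), v = matrix(0, nKeep, n),
      tauU = numeric(nKeep), tauV = numeric(nKeep)
    )
    colnames(keep$u) <- areaIds(graph)
    colnames(keep$v) <- areaIds(graph)
    if (p) colnames(keep$beta) <- colnames(X)
    k <- 0L

    for (it in seq_len(cfg$iterations)) {
      ## -- Gibbs: precisions ------------------------------------------
      if (spatial && is.null(fixedTauU)) {
        Su <- if (nrow(e)) sum((u[e[, 1]] - u[e[, 2]])^2) else 0
        tauU <- rgamma(1, priors$aU + (n - cN) / 2, rate = priors$bU + Su / 2)
      }
      if (iid && is.null(fixedTauV)) {
        tauV <- rgamma(1, priors$aV + n / 2, rate = priors$bV + sum(v^2) / 2)
      }
      ## -- v: all sites conditionally independent ---------------------
      if (iid) {
        eta0 <- a + xb + u
        pv <- v + exp(lsV) * rnorm(n)
        logr <- O * (pv - v) - E * (exp(eta0 + pv) - exp(eta0 + v)) -
          tauV / 2 * (pv^2 - v^2)
        accvec <- log(runif(n)) < logr
        v[accvec] <- pv[accvec]
        accV <- accV + accvec
        totAccV <- totAccV + sum(accvec); totV <- totV + n
      }
      ## -- u: single-site Metropolis by color class -------------------
      if (spatial) {
        eta0 <- a + xb + v
        for (cls in classes) {
          m <- as.numeric(W %*% u)[cls]
          ucl <- u[cls]
          pu <- ucl + exp(lsU[cls]) * rnorm(length(cls))
          logr <- O[cls] * (pu - ucl) -
            E[cls] * (exp(eta0[cls] + pu) - exp(eta0[cls] + ucl)) -
            tauU / 2 * (deg[cls] * (pu^2 - ucl^2) - 2 * m * (pu - ucl))
          accvec <- log(runif(length(cls))) < logr
          u[cls[accvec]] <- pu[accvec]
          accU[cls] <- accU[cls] + accvec
          totAccU <- totAccU + sum(accvec); totU <- totU + length(cls)
        }
        ## re-center per component; intercept absorbs the weighted shift
        if (alpha) {
          sh <- vapply(seq_len(cN), function(kk) mean(u[comp == kk]), 0)
          u <- u - sh[comp]
          a <- a + sum(sh * compSize) / n
        }
      }
      ## -- joint block: (alpha, beta) via mode-centered MH --------------
      if (blockDim) {
        theta <- c(if (alpha) a, beta)
        off <- (u + v)[usePos]
        st <- blockMode(theta, off)
        thetaP <- st$m + backsolve(st$R, rnorm(blockDim))
        logr <- (blockLogLik(thetaP, off) - blockLogLik(theta, off)) +
          logqBlock(st, theta) - logqBlock(st, thetaP)
        if (is.finite(logr) && log(runif(1)) < logr) {
          if (alpha) { a <- thetaP[1]; beta <- thetaP[-1] } else {
            beta <- thetaP
          }
          xb <- if (p) as.numeric(X %*% beta) else xb
          totAccB <- totAccB + 1
        }
        totB <- totB + 1
      }
      ## -- adaptation (burn-in only) ----------------------------------
      if (it <= cfg$burnin && it %% cfg$adaptBatch == 0L) {
        batch <- batch + 1
        delta <- min(0.25, 2 / sqrt(batch))
        rateV <- accV / cfg$adaptBatch
        lsV <- pmin(pmax(lsV + ifelse(rateV > cfg$targetSingle,
                                      delta, -delta), -8), 3)
        accV[] <- 0
        rateU <- accU / cfg$adaptBatch
        lsU <- pmin(pmax(lsU + ifelse(rateU > cfg$targetSingle,
                                      delta, -delta), -8), 3)
        accU[] <- 0
      }
      ## -- retention ---------------------------------------------------
      if (it > cfg$burnin && (it - cfg$burnin) %% cfg$thin == 0L) {
        eta <- a + xb + u + v
        if (any(!is.finite(eta)) || !is.finite(tauU) || !is.finite(tauV)) {
          stop("sampler diverged to a non-finite state at iteration ", it,
               "; state: alpha=", a, " tauU=", tauU, " tauV=", tauV)
        }
        k <- k + 1L
        keep$alpha[k] <- a
        if (p) keep$beta[k, ] <- beta
        keep$u[k, ] <- u
        keep$v[k, ] <- v
        keep$tauU[k] <- tauU
        keep$tauV[k] <- tauV
      }
    }
    attr(keep, "acc") <- c(
      u = if (totU) totAccU / totU else NA_real_,
      v = if (totV) totAccV / totV else NA_real_,
      block = if (totB) totAccB / totB else NA_real_
    )
    keep
  }

  chains <- lapply(seq_len(cfg$chains), function(ci) {
    runChain(cfg$seed + 1000L * (ci - 1L))
  })
  accs <- do.call(rbind, lapply(chains, attr, "acc"))
  new("BymFit",
    draws = chains, config = cfg, priors = priors, graph = graph,
    data = list(observed = O, expected = E, design = X,
                included = E > 0, dropped = dropIdx),
    acceptance = list(u = mean(accs[, "u"]), v = mean(accs[, "v"]),
                      block = mean(accs[, "block"]))
  )
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classic between/within variance
#' ratio computed over the resulting 2m sequences.
#'
#' @param x numeric matrix, iterations x chains (or a vector for one
#'   chain, which yields `NA`: at least two chains are required).
#' @return Scalar R-hat estimate.
#' @export
splitRhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])
  }))
  m <- ncol(halves)
  if (m < 2) return(NA_real_)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive
#' sequence on the chain-averaged autocorrelations.
#'
#' @param x numeric matrix, iterations x chains, or a vector.
#' @return Scalar ESS estimate.
#' @export
effectiveSize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  maxLag <- min(n - 2L, 1000L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    v <- var(x[, j])
    if (v == 0) return(rep(0, maxLag + 1))
    stats::acf(x[, j], lag.max = maxLag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(maxLag + 1)))
  ## Geyer: sum pair sums Gamma_k = rho_{2k} + rho_{2k+1} while positive
  s <- 0
  k <- 1L
  while (k + 1 <= maxLag) {
    g <- rho[k + 1] + rho[k + 2]
    if (g <= 0) break
    s <- s + g
    k <- k + 2L
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}

#' Convergence diagnostics for a BYM fit
#'
#' @param fit a [BymFit-class].
#' @param rhatLimit flag the run non-converged when any monitored R-hat
#'   exceeds this (default 1.05).
#' @return data.frame with one row per monitored scalar (`alpha`, each
#'   coefficient, `tau_u`, `tau_v`): `rhat`, `ess`; attribute
#'   `converged` (logical, `NA` with a single chain for R-hat purposes).
#' @export
bymDiagnostics <- function(fit, rhatLimit = 1.05) {
  stopifnot(is(fit, "BymFit"))
  perChain <- function(key) {
    lapply(fit@draws, function(ch) {
      d <- ch[[key]]
      if (is.matrix(d)) d else matrix(d, ncol = 1)
    })
  }
  mats <- list(alpha = perChain("alpha"))
  p <- ncol(fit@draws[[1]]$beta)
  if (p) {
    bn <- colnames(fit@draws[[1]]$beta)
    if (is.null(bn)) bn <- paste0("beta", seq_len(p))
    for (j in seq_len(p)) {
      mats[[bn[j]]] <- lapply(perChain("beta"), function(m) {
        m[, j, drop = FALSE]
      })
    }
  }
  mats$tau_u <- perChain("tauU")
  mats$tau_v <- perChain("tauV")
  rows <- lapply(names(mats), function(nm) {
    m <- do.call(cbind, mats[[nm]])
    data.frame(
      parameter = nm,
      rhat = if (length(fit@draws) >= 2) splitRhat(m) else NA_real_,
      ess = effectiveSize(m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  conv <- if (length(fit@draws) >= 2) {
    all(out$rhat <= rhatLimit, na.rm = TRUE)
  } else {
    NA
  }
  attr(out, "converged") <- conv
  out
}

#' Posterior summaries: rate ratios, smoothed and residual SMRs
#'
#' Rate ratios are `exp(beta)` posterior medians with equal-tailed 95%
#' credible intervals; the significance star marks intervals excluding 1.
#' In `"smoothed"` mode (covariate-free fit) the per-area smoothed SMR is
#' the posterior median of `exp(alpha + u_i + v_i)`; in `"adjusted"` mode
#' the per-area residual SMR is the posterior median of `exp(u_i + v_i)` —
#' spatial variation the covariates do not explain.
#'
#' @param fit a [BymFit-class].
#' @param mode `"smoothed"` or `"adjusted"`.
#' @param level credible level (default 0.95).
#' @param minEss warn when any reported quantity has fewer effective
#'   samples than this (default 200).
#' @return list with data.frames `rateRatios` (`term`, `rr`, `ci_low`,
#'   `ci_high`, `significant`, `ess`) and `areas` (`area_id`, `smr`,
#'   `ci_low`, `ci_high`), plus `mode`.
#' @export
bymSummary <- function(fit, mode = c("smoothed", "adjusted"),
                       level = 0.95, minEss = 200) {
  stopifnot(is(fit, "BymFit"))
  mode <- match.arg(mode)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  beta <- posteriorDraws(fit, "beta")
  rr <- NULL
  if (ncol(beta)) {
    rrDraws <- exp(beta)
    med <- apply(rrDraws, 2, median)
    ci <- apply(rrDraws, 2, quantile, probs = qs)
    ess <- apply(beta, 2, function(cl) {
      effectiveSize(matrix(cl, ncol = length(fit@draws)))
    })
    rr <- data.frame(
      term = colnames(beta),
      rr = unname(med), ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
      significant = unname(ci[1, ] > 1 | ci[2, ] < 1),
      ess = unname(ess),
      stringsAsFactors = FALSE
    )
    if (any(rr$ess < minEss)) {
      warning("effective sample size below ", minEss,
              " for coefficient(s): ",
              paste(rr$term[rr$ess < minEss], collapse = ", "))
    }
  }
  u <- posteriorDraws(fit, "u")
  v <- posteriorDraws(fit, "v")
  lin <- u + v
  if (mode == "smoothed") {
    lin <- lin + as.numeric(posteriorDraws(fit, "alpha"))
  }
  smrDraws <- exp(lin)
  med <- apply(smrDraws, 2, median)
  ci <- apply(smrDraws, 2, quantile, probs = qs)
  areas <- data.frame(
    area_id = areaIds(fit@graph),
    smr = unname(med), ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
    stringsAsFactors = FALSE
  )
  list(rateRatios = rr, areas = areas, mode = mode, level = level)
}
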