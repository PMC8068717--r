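# Independent oracles, deliberately naive: these re-derive quantities the
# package computes, by direct enumeration, and must not call package internals.

# breadth-first-search connected components over a neighbor list
bfsComponents <- function(adj) {
  n <- length(adj)
  lab <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      node <- queue[[1]]
      queue <- queue[-1]
      for (nb in adj[[node]]) {
        if (is.na(lab[nb])) {
          lab[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# pairwise-difference ICAR quadratic by direct double loop
bruteIcarQuadratic <- function(u, adj) {
  s <- 0
  for (i in seq_along(adj)) {
    for (j in adj[[i]]) {
      if (j > i) s <- s + (u[i] - u[j])^2
    }
  }
  s
}

# Erdos-Renyi-style random undirected graph as an edge matrix
randomEdges <- function(nAreas, pEdge, ids) {
  e <- NULL
  for (i in seq_len(nAreas - 1)) {
    for (j in seq((i + 1), nAreas)) {
      if (runif(1) < pEdge) e <- rbind(e, c(ids[i], ids[j]))
    }
  }
  e
}

# naive re-implementation of the full BYM log-posterior (second opinion)
bruteLogPosterior <- function(state, observed, expected, design, adj,
                              compLab, aU = 1, bU = 5e-5, aV = 1,
                              bV = 5e-5, betaVar = 1000) {
  n <- length(adj)
  eta <- numeric(n)
  for (i in seq_len(n)) {
    eta[i] <- state$alpha + state$u[i] + state$v[i]
    if (!is.null(design)) {
      eta[i] <- eta[i] + sum(design[i, ] * state$beta)
    }
  }
  ll <- 0
  for (i in seq_len(n)) {
    if (expected[i] > 0) {
      ll <- ll + observed[i] * (log(expected[i]) + eta[i]) -
        expected[i] * exp(eta[i])
    }
  }
  S <- bruteIcarQuadratic(state$u, adj)
  cN <- length(unique(compLab))
  lp <- (n - cN) / 2 * log(state$tauU) - state$tauU * S / 2
  lp <- lp + n / 2 * log(state$tauV) - state$tauV * sum(state$v^2) / 2
  lp <- lp + (aU - 1) * log(state$tauU) - bU * state$tauU
  lp <- lp + (aV - 1) * log(state$tauV) - bV * state$tauV
  if (!is.null(design)) lp <- lp - sum(state$beta^2) / (2 * betaVar)
  ll + lp
}

# posterior mean of theta = exp(v) for a single-area Poisson-lognormal
# model, v ~ N(0, 1/tauV), by adaptive quadrature
quadraturePoissonLognormalMean <- function(O, E, tauV) {
  post <- function(v) exp(O * v - E * exp(v)) * dnorm(v, 0, 1 / sqrt(tauV))
  Z <- integrate(post, -10, 10, rel.tol = 1e-10)$value
  integrate(function(v) exp(v) * post(v), -10, 10,
            rel.tol = 1e-10)$value / Z
}

# writes a GAL-dialect file from an id -> neighbor-ids list
writeGalFixture <- function(nbrs, path, header = length(nbrs)) {
  lines <- as.character(header)
  for (id in names(nbrs)) {
    lines <- c(lines, paste(id, length(nbrs[[id]])))
    if (length(nbrs[[id]])) lines <- c(lines, paste(nbrs[[id]],
                                                    collapse = " "))
  }
  writeLines(lines, path)
  path
}

# sample skewness (g1)
sampleSkewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
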