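# Independent oracles used across the suite. These deliberately avoid the
# package's C++ code paths (except the Polya-Gamma primitive, which is
# verified separately against its analytic moments).

# random-walk Metropolis on the exact negative binomial log-likelihood with
# independent Gaussian priors on beta; returns post-burn-in draws
rwMetropolisNB <- function(y, X, r, priorSd, steps = 2e5, proposalSd = 0.25,
                           burnFraction = 0.1) {
  p <- ncol(X)
  logpost <- function(b) {
    eta <- drop(X %*% b)
    sum(dnbinom(y, size = r, prob = plogis(-eta), log = TRUE)) +
      sum(dnorm(b, 0, priorSd, log = TRUE))
  }
  draws <- matrix(NA_real_, steps, p)
  cur <- rep(0, p)
  lp <- logpost(cur)
  for (s in seq_len(steps)) {
    prop <- cur + rnorm(p, 0, proposalSd)
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      cur <- prop
      lp <- lpp
    }
    draws[s, ] <- cur
  }
  draws[-seq_len(floor(burnFraction * steps)), , drop = FALSE]
}

# Monte-Carlo standard error of a chain mean, via the package's spectral
# variance estimate
mcse <- function(x) sqrt(spanbvs:::.spectralVar0(x) / length(x))

essOf <- function(x) spanbvs:::.essSpectral(x)

# Rao-Blackwellized exhaustive-enumeration oracle for spike-and-slab PIPs.
# A blocked Gibbs chain over (PG latents, model, beta[, w_g]): given the
# latents, the posterior over all 2^m models is computed by direct Gaussian
# integration of the PG-conditional likelihood and averaged across sweeps.
# `slabVar` is the per-feature slab variance; `inclProb` a fixed per-feature
# prior inclusion probability, or NULL to sample per-group w_g ~ Beta(1, 1)
# using `groupIndex` (1-based per feature).
enumeratePips <- function(y, X, r, slabVar, inclProb = NULL, groupIndex = NULL,
                          vIntercept = 100, sweeps = 30000, burn = sweeps / 2) {
  n <- length(y)
  m <- ncol(X) - 1L
  models <- as.matrix(expand.grid(rep(list(0:1), m)))
  kap <- (y - r) / 2
  priorv <- c(vIntercept, slabVar)
  logEv <- function(idx, om) {
    Xs <- X[, idx, drop = FALSE]
    P <- crossprod(Xs * om, Xs) + diag(1 / priorv[idx], length(idx))
    b <- crossprod(Xs, kap)
    ch <- chol(P)
    mu <- backsolve(ch, forwardsolve(t(ch), b))
    -0.5 * sum(log(priorv[idx])) - sum(log(diag(ch))) + 0.5 * sum(b * mu)
  }
  betac <- rep(0, m + 1)
  w <- if (is.null(inclProb)) rep(0.5, max(groupIndex)) else NULL
  acc <- rep(0, m)
  kept <- 0L
  for (s in seq_len(sweeps)) {
    om <- rPolyaGamma(n, y + r, drop(X %*% betac))
    pj <- if (is.null(inclProb)) w[groupIndex] else inclProb
    lw <- apply(models, 1, function(g) {
      idx <- c(1L, which(g == 1) + 1L)
      logEv(idx, om) + sum(g * log(pj) + (1 - g) * log(1 - pj))
    })
    pr <- exp(lw - max(lw))
    pr <- pr / sum(pr)
    if (s > burn) {
      acc <- acc + colSums(models * pr)
      kept <- kept + 1L
    }
    g <- models[sample.int(nrow(models), 1L, prob = pr), ]
    idx <- c(1L, which(g == 1) + 1L)
    Xs <- X[, idx, drop = FALSE]
    P <- crossprod(Xs * om, Xs) + diag(1 / priorv[idx], length(idx))
    ch <- chol(P)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, kap)))
    betac <- rep(0, m + 1)
    betac[idx] <- mu + backsolve(ch, rnorm(length(idx)))
    if (is.null(inclProb)) {
      sg <- tapply(g, groupIndex, sum)
      Mg <- tabulate(groupIndex)
      w <- rbeta(length(Mg), 1 + sg, 1 + Mg - sg)
    }
  }
  acc / kept
}

# brute-force AUC: fraction of concordant (positive, negative) score pairs,
# ties counted half
pairwiseAuc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small simulated dataset for engine smoke tests
toyStudy <- function(seed = 1, n = 50, p = 20, design = "sim1", ...) {
  simulateScenario(design, n = n, p = p, seed = seed, ...)
}
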