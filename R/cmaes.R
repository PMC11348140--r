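# Covariance matrix adaptation evolution strategy (mu/mu_w, lambda)
# with box constraints by projection. Minimal implementation of the
# standard update rules; deterministic given the seed.

#' Minimize a function by CMA-ES under box constraints
#'
#' @param fn Objective returning a scalar (may return Inf for invalid
#'   candidates).
#' @param lower,upper Box constraints (define the search dimension).
#' @param x0 Initial mean (default: box center).
#' @param sigma0 Initial step size (default: 0.3 of the box range).
#' @param generations Number of generations (0 returns the initial
#'   candidate and its cost).
#' @param popsize Candidates per generation (default 4 + floor(3 ln n)).
#' @param seed Integer seed.
#' @return List with `par`, `value`, `trace` (best cost per
#'   generation), `evaluations`.
#' @export
cmaes_minimize <- function(fn, lower, upper, x0 = NULL, sigma0 = NULL,
                           generations = 64, popsize = NULL, seed = 1) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(upper > lower))
  scale <- upper - lower
  if (is.null(x0)) x0 <- (lower + upper) / 2
  if (is.null(sigma0)) sigma0 <- 0.3
  if (is.null(popsize)) popsize <- 4L + floor(3 * log(n))
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  # work in box-normalized coordinates z in [0, 1]^n
  tobox <- function(z) lower + pmin(pmax(z, 0), 1) * scale
  .with_seed(seed, {
    xmean <- (x0 - lower) / scale
    sigma <- sigma0
    pc <- ps <- numeric(n)
    C <- diag(n); invsqrtC <- diag(n)
    best <- list(par = tobox(xmean), value = fn(tobox(xmean)))
    trace <- numeric(0)
    evals <- 1L
    if (generations > 0) {
      for (g in seq_len(generations)) {
        Z <- matrix(stats::rnorm(n * lambda), n, lambda)
        eigC <- eigen(C, symmetric = TRUE)
        D <- sqrt(pmax(eigC$values, 1e-20))
        BD <- eigC$vectors %*% diag(D, n)
        Y <- BD %*% Z
        X <- xmean + sigma * Y
        costs <- apply(X, 2, function(z) fn(tobox(z)))
        evals <- evals + lambda
        ord <- order(costs)
        if (costs[ord[1]] < best$value)
          best <- list(par = tobox(X[, ord[1]]), value = costs[ord[1]])
        trace <- c(trace, best$value)
        sel <- ord[seq_len(mu)]
        yw <- drop(Y[, sel, drop = FALSE] %*% wts)
        xmean <- xmean + sigma * yw
        xmean <- pmin(pmax(xmean, 0), 1)
        invsqrtC <- eigC$vectors %*% diag(1 / D, n) %*% t(eigC$vectors)
        ps <- (1 - cs) * ps +
          sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% yw)
        hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * g)) / n < 2 + 4 / (n + 1)
        pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
        artmp <- Y[, sel, drop = FALSE]
        C <- (1 - c1 - cmu) * C +
          c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
          cmu * artmp %*% (wts * t(artmp))
        C <- (C + t(C)) / 2
        sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
        sigma <- min(sigma, 1)
      }
    }
    list(par = best$par, value = best$value, trace = trace,
         evaluations = evals)
  })
}
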