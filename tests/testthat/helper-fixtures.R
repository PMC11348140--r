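# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env()

# small parcellation + distance matrix
mini_parc <- function(n_cortical = 24, n_subcortical = 6, seed = 1) {
  key <- paste("parc", n_cortical, n_subcortical, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_parcellation(n_cortical, n_subcortical, seed)
  .fixture_env[[key]]
}

# small simulated cohort used by several modules
mini_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- simulate_cohort(mini_parc(), n_nc = 12, n_scz = 12,
                                           T = 160, K = 2, effect = 0.6,
                                           seed = 7)
  .fixture_env$cohort
}

# analytic lagged covariance of two identical AR(1) channels
identical_ar1_cov <- function(phi) {
  S <- matrix(0, 4, 4)
  S[1:2, 1:2] <- 1
  S[3:4, 3:4] <- 1
  S[1:2, 3:4] <- phi
  S[3:4, 1:2] <- phi
  S
}

# random valid 4x4 covariance (Wishart draw)
random_cov4 <- function() {
  Z <- matrix(stats::rnorm(40), 10, 4)
  crossprod(Z) / 10
}

# random stable VAR(1) system of 2 channels
random_var2 <- function() {
  repeat {
    A <- matrix(stats::runif(4, -0.6, 0.6), 2, 2)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < 0.9) break
  }
  q <- stats::runif(1, -0.6, 0.6)
  Q <- matrix(c(1, q, q, 1), 2, 2)
  list(A = A, Q = Q)
}
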