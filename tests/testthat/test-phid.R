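# Gaussian PhiID: lagged covariance estimation, mutual information,
# redundancy, and the 16-atom decomposition.

test_that("lagged covariance matches AR(1) closed form and z-scores inputs", {
  set.seed(1)
  phi <- 0.5
  T <- 10000
  x <- as.vector(stats::arima.sim(list(ar = phi), T))
  lc <- lagged_covariance(x, rnorm(T), tau = 1)
  expect_s3_class(lc, "lagged_cov")
  # z-scored: unit variances on the diagonal (up to estimation error)
  expect_equal(unname(diag(lc$cov)), rep(1, 4), tolerance = 0.02)
  # lag-1 autocovariance of channel 1 ~ phi
  expect_equal(lc$cov[1, 3], phi, tolerance = 4 / sqrt(T) + 0.02)
  # independent channels: cross entries near zero
  expect_lt(abs(lc$cov[1, 2]), 4 / sqrt(T))
  expect_lt(abs(lc$cov[1, 4]), 4 / sqrt(T))
})

test_that("lagged covariance rejects degenerate input", {
  expect_error(lagged_covariance(rep(1, 100), rnorm(100)), "degenerate")
  expect_error(lagged_covariance(rnorm(25), rnorm(25), tau = 10), "20")
})

test_that("gaussian_mi reproduces the bivariate closed form", {
  S <- diag(4)
  expect_equal(gaussian_mi(S, 1, 2), 0)
  S[1, 2] <- S[2, 1] <- 0.5
  expect_equal(gaussian_mi(S, 1, 2), 0.5 * log(1 / (1 - 0.25)),
               tolerance = 1e-10)
  S[1, 2] <- S[2, 1] <- 1
  expect_error(gaussian_mi(S, 1, 2), "singular")
})

test_that("double redundancy is the minimum lagged channel MI", {
  phi <- 0.6
  expect_equal(double_redundancy_mmi(identical_ar1_cov(phi)),
               0.5 * log(1 / (1 - phi^2)), tolerance = 1e-10)
  # independent channels: all cross MIs vanish
  J <- var1_lagged_cov(diag(c(0.5, 0.7)), diag(2), 1)
  expect_equal(double_redundancy_mmi(J), 0, tolerance = 1e-12)
  # min property against the four channel MIs
  set.seed(4)
  for (i in 1:10) {
    S <- random_cov4()
    mis <- c(gaussian_mi(S, 1, 3), gaussian_mi(S, 1, 4),
             gaussian_mi(S, 2, 3), gaussian_mi(S, 2, 4))
    expect_lte(double_redundancy_mmi(S), min(mis) + 1e-12)
  }
})

test_that("atoms sum to the time-delayed mutual information", {
  set.seed(11)
  for (i in 1:20) {
    S <- random_cov4()
    at <- phid_decompose(S)
    tdmi <- gaussian_mi(S, 1:2, 3:4)
    expect_equal(sum(at$atoms), tdmi, tolerance = 1e-8)
    expect_equal(at$tdmi, tdmi, tolerance = 1e-10)
    expect_length(at$atoms, 16)
  }
})

test_that("analytic limits: independent and identical AR(1) channels", {
  J <- var1_lagged_cov(diag(c(0.5, 0.7)), diag(2), 1)
  at <- phid_decompose(J)
  expect_equal(unname(at$synergy), 0, tolerance = 1e-8)
  expect_equal(unname(at$redundancy), 0, tolerance = 1e-8)
  # channel 1's information shows up as its unique-persistent atom
  expect_equal(unname(at$atoms[["Un1->Un1"]]), 0.5 * log(1 / (1 - 0.25)),
               tolerance = 1e-8)
  phi <- 0.6
  at2 <- phid_decompose(identical_ar1_cov(phi))
  expect_equal(unname(at2$redundancy), 0.5 * log(1 / (1 - phi^2)),
               tolerance = 1e-8)
  expect_equal(unname(at2$synergy), 0, tolerance = 1e-8)
})

test_that("linear-system solution equals Moebius inversion", {
  set.seed(21)
  for (i in 1:25) {
    S <- random_cov4()
    expect_equal(max(abs(phid_decompose(S)$atoms - phid_mobius(S))), 0,
                 tolerance = 1e-10)
  }
})

test_that("solved atoms reproduce every measured constraint", {
  set.seed(31)
  downsets <- list(Red = "Red", Un1 = c("Red", "Un1"), Un2 = c("Red", "Un2"),
                   Syn = c("Red", "Un1", "Un2", "Syn"))
  cols <- list(Un1 = 1L, Un2 = 2L, Syn = c(1L, 2L))
  for (rep in 1:5) {
    S <- random_cov4()
    at <- phid_decompose(S)$atoms
    for (a in c("Un1", "Un2", "Syn")) for (b in c("Un1", "Un2", "Syn")) {
      mi <- gaussian_mi(S, cols[[a]], cols[[b]] + 2L)
      atoms_in <- as.vector(outer(downsets[[a]], downsets[[b]],
                                  function(x, y) paste0(x, "->", y)))
      expect_equal(sum(at[atoms_in]), mi, tolerance = 1e-8)
    }
  }
})

test_that("sample-covariance atoms converge to analytic VAR(1) atoms", {
  sys <- list(A = matrix(c(0.5, 0.3, 0.3, 0.5), 2, 2), Q = diag(2))
  target <- phid_decompose(var1_lagged_cov(sys$A, sys$Q, 1))
  set.seed(5)
  x <- synfactor:::.simulate_var1(sys$A, 50000, sys$Q)
  est <- phid_decompose(lagged_covariance(x[, 1], x[, 2], 1))
  expect_lt(max(abs(est$atoms - target$atoms)), 0.01)
})

test_that("collection-level redundancy variant leaves a synergy floor", {
  J <- var1_lagged_cov(diag(c(0.5, 0.7)), diag(2), 1)
  at <- phid_decompose(J, redundancy = "collection")
  i1 <- gaussian_mi(J, 1, 3); i2 <- gaussian_mi(J, 2, 4)
  expect_equal(unname(at$synergy), 2 * min(i1, i2), tolerance = 1e-8)
})
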