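# Mean-field dynamics: transfer function, regional parameterization,
# integration, hemodynamics, FCD, cost and CMA-ES.

test_that("regional parameters are elementwise linear maps", {
  mye <- c(1, 0, -1); grad <- c(0, 1, 0)
  rp <- regional_params(mye, grad, c(0.2, 0.1, 0.5, 0, 0, 0.3,
                                     0, 0, 0.005))
  expect_equal(rp$W, c(0.7, 0.6, 0.3))
  expect_equal(rp$I, rep(0.3, 3))
  expect_equal(rp$sigma, rep(0.005, 3))
  expect_false(rp$clipped)
  # zero a/b coefficients: constant vectors at the c-terms
  rp0 <- regional_params(mye, grad, c(0, 0, 1.1, 0, 0, 0.3, 0, 0, 0.004))
  expect_equal(rp0$W, rep(1.1, 3))
  # one-hot myelin perturbs exactly one region by a_w
  oh <- regional_params(c(1, 0, 0), c(0, 0, 0),
                        c(0.25, 0, 1, 0, 0, 0.3, 0, 0, 0.004))
  expect_equal(oh$W, c(1.25, 1, 1))
  # floor binds and is flagged
  neg <- regional_params(mye, grad, c(1, 0, 0.5, 0, 0, 0.3, 0, 0, 0.005))
  expect_true(neg$clipped)
  expect_true(all(neg$W >= 1e-4))
})

test_that("the transfer function evaluates its removable singularity", {
  cst <- mfm_constants()
  expect_identical(h_rate(cst$b / cst$a), 1 / cst$d)
  # smooth through the singularity
  eps <- 1e-7
  expect_equal(h_rate(cst$b / cst$a + eps), 1 / cst$d, tolerance = 1e-4)
  expect_equal(h_rate(cst$b / cst$a - eps), 1 / cst$d, tolerance = 1e-4)
  expect_gt(h_rate(0.5), h_rate(0.3))
})

test_that("noise-free dynamics stay on the fixed point", {
  parc <- mini_parc(12, 0, seed = 2)
  sc <- simulate_structural(parc, 0.5, seed = 2)$sc
  fp <- mfm_fixed_point(0.5, 0.32)
  pr <- list(W = rep(0.5, 12), I = rep(0.32, 12), sigma = rep(0, 12), G = 0)
  sim <- simulate_mfm(sc, pr, duration = 100, seed = 1, store_every = 100,
                      S0 = rep(fp, 12))
  expect_lt(max(abs(sim$S_trace - fp)), 1e-6)
  # isolated-region terminal state solves the scalar balance equation
  sim2 <- simulate_mfm(sc, pr, duration = 60, seed = 1, store_every = 100,
                       S0 = rep(0.5, 12))
  expect_lt(max(abs(sim2$S_trace[nrow(sim2$S_trace), ] - fp)), 1e-6)
  # halving dt barely moves the terminal deterministic state
  sim3 <- simulate_mfm(sc, pr, dt = 0.005, duration = 60, seed = 1,
                       store_every = 200, S0 = rep(0.5, 12))
  expect_lt(max(abs(sim3$S_trace[nrow(sim3$S_trace), ] -
                    sim2$S_trace[nrow(sim2$S_trace), ])), 1e-4)
})

test_that("stochastic gating stays in [0, 1] and responds to noise", {
  parc <- mini_parc(12, 0, seed = 2)
  sc <- simulate_structural(parc, 0.5, seed = 2)$sc
  pr <- list(W = rep(0.45, 12), I = rep(0.32, 12), sigma = rep(0.006, 12),
             G = 0.2)
  sim <- simulate_mfm(sc, pr, duration = 60, seed = 3, store_every = 5)
  expect_true(all(sim$S_trace >= 0 & sim$S_trace <= 1))
  # fluctuation variance scales with sigma^2 in the linear regime
  vs <- sapply(c(0.002, 0.004, 0.008), function(s) {
    pr$sigma <- rep(s, 12)
    sm <- simulate_mfm(sc, pr, duration = 120, seed = 4, store_every = 5)
    mean(apply(sm$S_trace[200:2400, ], 2, var))
  })
  slope <- coef(lm(log(vs) ~ log(c(0.002, 0.004, 0.008))))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)
})

test_that("hemodynamics produce one row per repetition time", {
  parc <- mini_parc(12, 0, seed = 2)
  sc <- simulate_structural(parc, 0.5, seed = 2)$sc
  pr <- list(W = rep(0.45, 12), I = rep(0.32, 12), sigma = rep(0.005, 12),
             G = 0.2)
  sim <- simulate_mfm(sc, pr, duration = 120, seed = 5)
  bold <- hemodynamics(sim, TR = 2, burn_in = 40)
  expect_equal(nrow(bold), (120 - 40) / 2)
  expect_equal(ncol(bold), 12)
  expect_true(all(is.finite(bold)))
  # constant drive settles to a constant signal
  cstS <- matrix(0.2, 6000, 3)
  b2 <- hemodynamics(cstS, dt = 0.01, TR = 2, burn_in = 40)
  expect_lt(max(apply(b2, 2, sd)), 1e-6)
  expect_error(hemodynamics(sim, TR = 0.013), "multiple")
})

test_that("FCD is a correlation of window FC patterns", {
  set.seed(6)
  bold <- matrix(rnorm(120 * 8), 120, 8)
  m <- fcd(bold, window = 30, stride = 10)
  expect_identical(unname(m), unname(t(m)))
  expect_equal(diag(m), rep(1, nrow(m)))
  expect_lt(mean(abs(m[upper.tri(m)])), 0.4)
  # a signal periodic at the stride duplicates windows: high FCD bands
  base <- matrix(rnorm(10 * 8), 10, 8)
  per <- base[rep(1:10, 12), ] + matrix(rnorm(120 * 8, 0, 0.01), 120, 8)
  mp <- fcd(per, window = 30, stride = 10)
  expect_gt(min(mp[upper.tri(mp)]), 0.9)
  expect_error(fcd(bold, window = 200), "invalid")
})

test_that("the fitting cost separates its FC and KS terms", {
  set.seed(7)
  A <- cor(matrix(rnorm(600), 100, 6))
  expect_equal(fit_cost(A, A, A, A)$total, 0)
  expect_equal(fit_cost(-A, A)$fc_term, 2)
  # KS term equals the brute-force maximum CDF gap
  x <- rnorm(20); y <- rnorm(20, 0.5)
  gap <- max(sapply(c(x, y), function(t)
    abs(mean(x <= t) - mean(y <= t))))
  expect_equal(fit_cost(A, A, x, y)$ks_term, gap, tolerance = 1e-12)
})

test_that("CMA-ES contracts: budget zero, determinism, convergence", {
  f <- function(x) sum((x - 0.25)^2)
  r0 <- cmaes_minimize(f, rep(-1, 4), rep(1, 4), generations = 0, seed = 1)
  expect_equal(r0$par, rep(0, 4))       # box center, untouched
  expect_equal(r0$value, f(rep(0, 4)))
  r1 <- cmaes_minimize(f, rep(-1, 4), rep(1, 4), generations = 40, seed = 2)
  r2 <- cmaes_minimize(f, rep(-1, 4), rep(1, 4), generations = 40, seed = 2)
  expect_identical(r1$par, r2$par)
  expect_lt(r1$value, 1e-4)
  expect_true(all(diff(r1$trace) <= 0))
  expect_true(all(r1$par >= -1 & r1$par <= 1))
})

test_that("parameter-difference maps correlate with their planted factor", {
  parc <- mini_parc(20, 0, seed = 3)
  D <- parcellation_dist(parc)
  set.seed(8)
  fmaps <- rbind(as.vector(synfactor:::.smooth_field(D, 30)),
                 as.vector(synfactor:::.smooth_field(D, 30)))
  base <- list(W = rep(0.5, 20), I = rep(0.3, 20))
  scz <- list(W = base$W + fmaps[2, ] * 0.05, I = base$I)
  out <- param_diff_factor_corr(scz, base, fmaps, D, n_surrogates = 49,
                                seed = 9)
  expect_equal(out$r[out$parameter == "W" & out$factor == 2], 1,
               tolerance = 1e-10)
  expect_true(all(out$constant[out$parameter == "I"]))
  expect_true(all(is.na(out$r[out$parameter == "I"])))
})
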