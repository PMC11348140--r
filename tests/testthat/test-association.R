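# RDMs, Kendall tau, RSA comparison, clinical correlations and GLM
# contrasts.

test_that("RDMs implement the stated dissimilarities", {
  r <- rdm(c(20, 25, 30), "numeric", "age")
  expect_equal(r$d[1, 3], 10)
  expect_equal(diag(r$d), rep(0, 3))
  expect_identical(r$d, t(r$d))
  L <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(rdm(L, "numeric")$d[1, 2], sqrt(2))
  g <- rdm(c("M", "F", "M"), "categorical")
  expect_equal(g$d[1, 3], 0)
  expect_equal(g$d[1, 2], 1)
  expect_equal(rdm(rep(5, 4))$d, matrix(0, 4, 4))
  expect_error(rdm(c(1, NA, 3)), "missing")
})

test_that("Kendall tau matches the brute-force concordance count", {
  brute_tau <- function(a, b) {
    n <- length(a); num <- 0; t1 <- 0; t2 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- sign(a[i] - a[j]); sb <- sign(b[i] - b[j])
      num <- num + sa * sb
      t1 <- t1 + (sa != 0); t2 <- t2 + (sb != 0)
    }
    num / sqrt(t1 * t2)
  }
  set.seed(1)
  for (rep in 1:10) {
    S <- sample(4:8, 1)
    a <- as.matrix(dist(rnorm(S)))
    b <- as.matrix(dist(sample(0:2, S, replace = TRUE)))
    if (sd(b[lower.tri(b)]) == 0) next
    expect_equal(kendall_tau_lower(a, b),
                 brute_tau(a[lower.tri(a)], b[lower.tri(b)]),
                 tolerance = 1e-12)
  }
  a <- as.matrix(dist(c(1, 2, 4, 7)))
  expect_equal(kendall_tau_lower(a, a), 1)
  expect_equal(kendall_tau_lower(a, max(a) - a + 1), -1)
  expect_error(kendall_tau_lower(matrix(0, 3, 3), a[1:3, 1:3]), "undefined")
})

test_that("RSA separates loading-driven from map-driven characteristics", {
  set.seed(2)
  S <- 40
  L <- synfactor:::.rdirichlet(S, c(0.5, 0.5, 0.5))
  runs <- lapply(1:6, function(i) L + matrix(runif(S * 3, 0, 0.02), S, 3))
  raw <- matrix(rnorm(S * 50), S, 50)
  chars <- data.frame(
    driven = drop(L %*% c(2, -1, 0)) + rnorm(S, 0, 0.1),
    noise = rnorm(S))
  out <- rsa_compare(runs, raw, chars)
  expect_gt(out$tau_factor_mean[out$characteristic == "driven"],
            out$tau_raw[out$characteristic == "driven"])
  expect_lt(abs(out$tau_factor_mean[out$characteristic == "noise"]), 0.15)
  expect_equal(out$tau_factor_final[1],
               kendall_tau_lower(rdm(runs[[6]], "numeric"),
                                 rdm(chars$driven, "numeric")))
})

test_that("clinical correlations recover a planted loading-symptom link", {
  set.seed(3)
  S <- 120
  L <- synfactor:::.rdirichlet(S, c(0.5, 0.5, 0.5))
  site <- rep(c("s1", "s2", "s3"), length.out = S)
  clin <- data.frame(
    pos = drop(scale(L[, 1])) * 0.3 + rnorm(S) * sqrt(1 - 0.09),
    neg = rnorm(S))
  cc <- clinical_correlations(L, clin, data.frame(site = site))
  ov <- cc[cc$site == "overall", ]
  r11 <- ov$r[ov$factor == 1 & ov$scale == "pos"]
  expect_gt(r11, 0.1)
  expect_true(ov$p_fdr[ov$factor == 1 & ov$scale == "pos"] < 0.05)
  expect_true(all(ov$ci_lo <= ov$r & ov$r <= ov$ci_hi))
  expect_setequal(unique(cc$site), c("overall", "s1", "s2", "s3"))
  # exact linear dependence gives r = 1
  cc2 <- clinical_correlations(L[, 1:2], data.frame(y = L[, 1]))
  expect_equal(cc2$r[cc2$factor == 1], 1, tolerance = 1e-10)
  expect_warning(
    clinical_correlations(L, clin, data.frame(site = c("tiny",
                                                       site[-1]))),
    "skipped")
})

test_that("GLM contrasts are exact on deterministic input and calibrated", {
  set.seed(4)
  S <- 80
  L <- synfactor:::.rdirichlet(S, c(1, 1, 1))
  # y exactly equal to p1: the factor-1 coefficient test diverges
  g <- glm_contrast(L[, 1], L, H = c(0, 1, 0))
  expect_lt(g$p, 1e-10)
  # agreement with the reference linear-hypothesis implementation
  y <- rnorm(S)
  fit <- lm(y ~ L[, 1] + L[, 2])
  ref <- car::linearHypothesis(fit, "L[, 1] - L[, 2] = 0")
  ours <- glm_contrast(y, L, H = c(0, -1, 1))
  expect_equal(ours$statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(ours$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
  # null calibration of the contrast test: p values uniform
  ps <- replicate(400, glm_contrast(rnorm(30),
                                    synfactor:::.rdirichlet(30, c(1, 1, 1)),
                                    H = c(0, -1, 1))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 1e-3)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("residualized correlation equals the partial correlation", {
  set.seed(5)
  n <- 60
  z <- data.frame(a = rnorm(n), b = rnorm(n))
  x <- rnorm(n) + z$a; y <- rnorm(n) - 2 * z$b + 0.5 * x
  rx <- residualize(x, z); ry <- residualize(y, z)
  r1 <- cor(rx, ry)
  # partial correlation via the inverse correlation matrix
  Rm <- cor(cbind(x, y, z$a, z$b))
  P <- solve(Rm)
  r2 <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(r1, r2, tolerance = 1e-10)
})
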