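# Normalization against controls, document construction, LDA fitting,
# factor matching, model-order selection, maps and subtypes.

test_that("z-normalization uses the control mean and n-1 sd per entry", {
  m <- function(v) { M <- matrix(0, 2, 2); M[2, 1] <- M[1, 2] <- v; M }
  z <- znormalize_to_controls(list(m(0)), list(m(1), m(2), m(3)))
  expect_equal(z[[1]][2, 1], -2)          # (0 - 2) / sd({1,2,3}) = -2
  z2 <- znormalize_to_controls(list(m(2)), list(m(1), m(2), m(3)))
  expect_equal(z2[[1]][2, 1], 0)
  z3 <- znormalize_to_controls(list(m(1)), list(m(1), m(2), m(3)))
  expect_equal(z3[[1]][2, 1], -1)
  expect_error(znormalize_to_controls(list(m(0)), list(m(1), m(1), m(1))),
               "degenerate")
  expect_error(znormalize_to_controls(list(m(0)), list(m(1), m(2))), "3")
})

test_that("documents keep only scaled synergy reductions", {
  m <- function(v) { M <- matrix(0, 2, 2); M[2, 1] <- M[1, 2] <- v; M }
  d <- suppressWarnings(prepare_documents(list(m(2.3), m(-1.7)), scale = 10))
  expect_equal(d$counts[1, 1], 0)         # positive z reset to zero
  expect_equal(d$counts[2, 1], 17)        # |-1.7| * 10
  expect_warning(prepare_documents(list(m(1))), "empty")
  expect_error(prepare_documents(list(m(1)), scale = 0), "invalid")
  # document length equals the pair count
  zz <- replicate(3, matrix(-1, 115, 115), simplify = FALSE)
  expect_equal(ncol(prepare_documents(zz)$counts), 6555)
})

test_that("LDA recovers planted topics and keeps its ELBO monotone", {
  set.seed(10)
  K <- 3; S <- 120; P <- 300
  beta <- matrix(rgamma(K * P, 0.1), K, P); beta <- beta / rowSums(beta)
  theta <- synfactor:::.rdirichlet(S, rep(0.5, K))
  docs <- t(sapply(seq_len(S), function(d)
    rmultinom(1, 300, colSums(theta[d, ] * beta))))
  m <- fit_lda(docs, 3, seed = 5)
  expect_s3_class(m, "factor_model")
  expect_equal(rowSums(m$patterns), rep(1, 3))
  expect_equal(rowSums(m$loadings), rep(1, S))
  ll <- m$log_likelihood
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
  mt <- match_factors(m$patterns, beta)
  expect_true(all(mt$correlations > 0.9))
  # determinism
  m2 <- fit_lda(docs, 3, seed = 5)
  expect_identical(m$patterns, m2$patterns)
  expect_error(fit_lda(docs, 1), "K")
  expect_error(fit_lda(docs[1:2, ], 5), "K")
})

test_that("a single-topic corpus concentrates every loading row", {
  set.seed(11)
  beta <- rgamma(200, 0.2); beta <- beta / sum(beta)
  docs <- t(sapply(1:40, function(d) rmultinom(1, 250, beta)))
  # a sparse loading prior resolves the split-a-topic-in-two degeneracy
  m <- fit_lda(docs, 2, alpha = 0.1, seed = 3)
  expect_gt(mean(apply(m$loadings, 1, max)), 0.9)
  # and the expressed pattern is the single generating topic (the
  # unused factor may stay at its flat prior)
  expect_gt(max(suppressWarnings(cor(t(m$patterns), beta)), na.rm = TRUE),
            0.95)
})

test_that("factor matching finds permutations and rejects mismatched K", {
  set.seed(12)
  A <- matrix(rgamma(4 * 100, 0.3), 4, 100); A <- A / rowSums(A)
  mt <- match_factors(A, A)
  expect_equal(mt$permutation, 1:4)
  expect_equal(mt$correlations, rep(1, 4))
  perm <- c(3, 1, 4, 2)
  mt2 <- match_factors(A, A[perm, ])
  expect_equal(mt2$permutation[perm], 1:4)
  expect_equal(mt2$correlations, rep(1, 4))
  B <- matrix(rgamma(3 * 500, 0.3), 3, 500); B <- B / rowSums(B)
  C <- matrix(rgamma(3 * 500, 0.3), 3, 500); C <- C / rowSums(C)
  expect_lt(match_factors(B, C)$mean_correlation, 0.3)
  expect_error(match_factors(A, B), "K")
})

test_that("split-half stability selects the planted factor count", {
  set.seed(13)
  K <- 3; S <- 160; P <- 250
  beta <- matrix(rgamma(K * P, 0.08), K, P); beta <- beta / rowSums(beta)
  theta <- synfactor:::.rdirichlet(S, rep(0.4, K))
  docs <- t(sapply(seq_len(S), function(d)
    rmultinom(1, 250, colSums(theta[d, ] * beta))))
  sel <- select_k(docs, 2:4, n_splits = 3, seed = 2)
  expect_equal(sel$K, 3)
  sel2 <- select_k(docs, 2:4, n_splits = 3, seed = 2)
  expect_identical(sel$stability, sel2$stability)
})

test_that("refits across seeds give essentially the same factors", {
  set.seed(14)
  K <- 3; S <- 80; P <- 200
  beta <- matrix(rgamma(K * P, 0.1), K, P); beta <- beta / rowSums(beta)
  theta <- synfactor:::.rdirichlet(S, rep(0.5, K))
  docs <- t(sapply(seq_len(S), function(d)
    rmultinom(1, 300, colSums(theta[d, ] * beta))))
  ref <- fit_lda(docs, 3, seed = 1)
  r <- vapply(2:11, function(sd)
    match_factors(ref, fit_lda(docs, 3, seed = sd))$mean_correlation,
    numeric(1))
  expect_gte(mean(r), 0.9)
})

test_that("factor maps aggregate pair weights onto regions", {
  # N = 4 toy with hand-computed sums; pair order (2,1),(3,1),(4,1),(3,2),(4,2),(4,3)
  pat <- rbind(c(0.1, 0.2, 0.3, 0.15, 0.15, 0.1))
  fm <- factor_map(pat, 1)
  expect_equal(fm, c(0.1 + 0.2 + 0.3, 0.1 + 0.15 + 0.15,
                     0.2 + 0.15 + 0.1, 0.3 + 0.15 + 0.1))
  # uniform pattern: constant map
  P <- 6; u <- rbind(rep(1 / P, P))
  expect_equal(factor_map(u, 1), rep(3 / P, 4))
  # mass on a single pair: only its two regions, equally
  one <- rbind(c(1, 0, 0, 0, 0, 0))
  expect_equal(factor_map(one, 1), c(1, 1, 0, 0))
  expect_error(factor_map(pat, 2), "invalid")
})

test_that("subtyping takes the dominant factor with flagged index ties", {
  L <- rbind(c(0.7, 0.2, 0.1), c(1, 1, 1) / 3, c(0.2, 0.5, 0.3))
  st <- assign_subtype(L)
  expect_equal(st$subtype, c(1, 1, 2))
  expect_equal(st$tie, c(FALSE, TRUE, FALSE))
})

test_that("top-section masks partition ranked regions", {
  m <- seq(100, 1)
  ts <- top_sections_mask(m, n_sections = 20, top_fraction = 0.2)
  expect_length(ts$masks, 4)
  expect_true(all(vapply(ts$masks, sum, 0L) == 5))
  expect_true(ts$masks[[1]][which.max(m)])
  expect_false(ts$tie)
  expect_false(any(ts$masks[[1]] & ts$masks[[2]]))
  cst <- top_sections_mask(rep(1, 40))
  expect_true(cst$tie)
  expect_identical(cst$masks, top_sections_mask(rep(1, 40))$masks)
})
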