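# Latent Dirichlet allocation by batch variational EM, adapted to
# continuous brain-dysfunction features discretized into counts.
# Subjects play the role of documents, region pairs the role of words,
# and latent dysfunction factors the role of topics.

.dir_explog <- function(M) {
  # E[log x] rows of independent Dirichlets given their parameter rows
  digamma(M) - digamma(rowSums(M))
}

.lda_elbo <- function(n, gamma, lambda, alpha, eta) {
  S <- nrow(gamma); K <- ncol(gamma); P <- ncol(lambda)
  Elogtheta <- .dir_explog(gamma)
  Elogbeta <- .dir_explog(lambda)
  phinorm <- exp(Elogtheta) %*% exp(Elogbeta) + 1e-100
  score <- sum(n * log(phinorm))
  score <- score + sum((alpha - gamma) * Elogtheta) + sum(lgamma(gamma)) -
    sum(lgamma(rowSums(gamma))) + S * (lgamma(K * alpha) - K * lgamma(alpha))
  score + sum((eta - lambda) * Elogbeta) + sum(lgamma(lambda)) -
    sum(lgamma(rowSums(lambda))) + K * (lgamma(P * eta) - P * lgamma(eta))
}

#' Fit an LDA factor model by variational EM
#'
#' Smoothed LDA with symmetric Dirichlet priors: loading rows
#' (subject-level factor expressions) have prior Dirichlet(alpha), and
#' factor-specific pattern rows Dirichlet(eta). Inference is batch
#' variational EM; the evidence lower bound (ELBO) is tracked and is
#' nondecreasing across iterations. Deterministic given `seed`.
#'
#' @param docs S x P nonnegative count matrix (see
#'   [prepare_documents()]), or a `document_matrix`.
#' @param K Number of factors (>= 2, <= S).
#' @param alpha Loading-prior concentration (default 100 / K).
#' @param eta Pattern-prior concentration.
#' @param seed Integer seed for the random pattern initialization.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative ELBO change for convergence.
#' @return Object of class `factor_model`: `patterns` (K x P rows
#'   summing to 1), `loadings` (S x K rows on the simplex), `K`,
#'   `alpha`, `eta`, `seed`, `log_likelihood` (ELBO trace).
#' @export
fit_lda <- function(docs, K, alpha = 100 / K, eta = 0.01, seed = 1,
                    max_iter = 150, tol = 1e-6) {
  n <- if (inherits(docs, "document_matrix")) docs$counts else as.matrix(docs)
  S <- nrow(n); P <- ncol(n)
  if (K < 2) stop("invalid argument: K must be >= 2")
  if (K > S) stop("invalid argument: K exceeds the number of subjects")
  if (sum(n) <= 0) stop("invalid argument: documents are empty")
  .with_seed(seed, {
    lambda <- matrix(stats::rgamma(K * P, 100, 1) / 100, K, P)
    gamma <- matrix(alpha + rowSums(n) / K, S, K)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      expElogbeta <- exp(.dir_explog(lambda))
      for (inner in 1:100) {
        expElogtheta <- exp(.dir_explog(gamma))
        phinorm <- expElogtheta %*% expElogbeta + 1e-100
        gamma_new <- alpha + expElogtheta * ((n / phinorm) %*% t(expElogbeta))
        delta <- mean(abs(gamma_new - gamma))
        gamma <- gamma_new
        if (delta < 1e-3) break
      }
      expElogtheta <- exp(.dir_explog(gamma))
      phinorm <- expElogtheta %*% expElogbeta + 1e-100
      lambda <- eta + (t(expElogtheta) %*% (n / phinorm)) * expElogbeta
      trace <- c(trace, .lda_elbo(n, gamma, lambda, alpha, eta))
      if (it > 1 &&
          abs(trace[it] - trace[it - 1]) < tol * abs(trace[it - 1])) break
    }
    structure(list(
      K = K,
      patterns = lambda / rowSums(lambda),
      loadings = gamma / rowSums(gamma),
      alpha = alpha, eta = eta, seed = seed,
      log_likelihood = trace
    ), class = "factor_model")
  })
}
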