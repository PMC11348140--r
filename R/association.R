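# Representational similarity analysis between factor expressions and
# subject characteristics, per-site and pooled clinical correlations,
# and general-linear-model contrasts across factor expressions.

#' Representational dissimilarity matrix of one subject characteristic
#'
#' Numeric variables: absolute difference (scalars) or Euclidean
#' distance (row vectors, e.g. factor loadings or vectorized
#' z-matrices). Categorical variables: 0 when equal, 1 otherwise.
#'
#' @param values Vector (one value per subject), or matrix with one row
#'   per subject.
#' @param kind "numeric" or "categorical".
#' @param label Characteristic name carried in the result.
#' @return Object of class `rdm`: list with `label`, `d` (S x S
#'   symmetric, zero diagonal).
#' @export
rdm <- function(values, kind = c("numeric", "categorical"), label = "") {
  kind <- match.arg(kind)
  if (kind == "numeric") {
    values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
    if (any(is.na(values)))
      stop("missing-data: subjects ",
           paste(which(rowSums(is.na(values)) > 0), collapse = ", "))
    d <- as.matrix(stats::dist(values))
  } else {
    values <- as.character(values)
    if (any(is.na(values)))
      stop("missing-data: subjects ", paste(which(is.na(values)), collapse = ", "))
    d <- outer(values, values, FUN = "!=") * 1
  }
  dimnames(d) <- NULL
  structure(list(label = label, d = d), class = "rdm")
}

.rdm_vec <- function(x) {
  d <- if (inherits(x, "rdm")) x$d else as.matrix(x)
  d[lower.tri(d)]
}

#' Kendall rank correlation between two RDMs
#'
#' Kendall tau-b (tie-corrected) over the strict lower triangles.
#'
#' @param rdmA,rdmB `rdm` objects or symmetric matrices on the same
#'   subjects.
#' @return Kendall tau.
#' @export
kendall_tau_lower <- function(rdmA, rdmB) {
  a <- .rdm_vec(rdmA); b <- .rdm_vec(rdmB)
  if (length(a) != length(b)) stop("RDMs differ in size")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined-correlation: constant dissimilarities")
  stats::cor(a, b, method = "kendall")
}

#' RSA: do latent factors explain subject similarity better than raw maps?
#'
#' For each characteristic, compares the Kendall tau between its RDM
#' and (a) factor-expression RDMs across LDA runs with (b) the single
#' tau of the raw vectorized z-matrix RDM, via an unpaired t test of
#' the run distribution against the raw-map value.
#'
#' @param loading_runs List of loading matrices (one per LDA run) or of
#'   `factor_model`s.
#' @param raw_z S x P matrix of vectorized z-scores (subjects in rows).
#' @param characteristics Data frame of subject characteristics; factor
#'   columns are treated as categorical, numeric columns as numeric.
#' @param final Index of the run reported as the final estimate
#'   (default: the last; callers may pass the highest-likelihood run).
#' @return Data frame: characteristic, tau_raw, tau_factor_mean,
#'   tau_factor_sd, tau_factor_final, t, p.
#' @export
rsa_compare <- function(loading_runs, raw_z, characteristics, final = NULL) {
  if (length(loading_runs) < 2) stop("need at least 2 LDA runs")
  L <- lapply(loading_runs, function(m)
    if (inherits(m, "factor_model")) m$loadings else as.matrix(m))
  if (is.null(final)) final <- length(L)
  rdm_raw <- rdm(as.matrix(raw_z), "numeric", "raw_z")
  rdm_runs <- lapply(L, rdm, kind = "numeric", label = "loadings")
  out <- lapply(names(characteristics), function(ch) {
    v <- characteristics[[ch]]
    kind <- if (is.numeric(v)) "numeric" else "categorical"
    rc <- rdm(v, kind, ch)
    tau_raw <- kendall_tau_lower(rdm_raw, rc)
    taus <- vapply(rdm_runs, kendall_tau_lower, numeric(1), rdmB = rc)
    ht <- stats::t.test(taus, mu = tau_raw)
    data.frame(characteristic = ch, tau_raw = tau_raw,
               tau_factor_mean = mean(taus), tau_factor_sd = stats::sd(taus),
               tau_factor_final = taus[final],
               t = unname(ht$statistic), p = ht$p.value)
  })
  do.call(rbind, out)
}

.fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Factor-loading vs clinical-score correlations, per site and pooled
#'
#' Residualizes both the loadings and the clinical scores against the
#' covariates (within each site for per-site records), computes Pearson
#' correlations per (factor, scale) with Fisher-z 95% confidence
#' intervals, and applies FDR-BH across the factor x scale family
#' within each grouping.
#'
#' @param loadings S x K loading matrix (patients only).
#' @param clinical Data frame of symptom scores (one column per scale).
#' @param covariates Data frame of non-clinical covariates; a `site`
#'   column (if present) defines the per-site records.
#' @param min_site Minimum subjects for a per-site record.
#' @return Data frame of class `correlation_record`: site, factor,
#'   scale, n, r, ci_lo, ci_hi, p, p_fdr.
#' @export
clinical_correlations <- function(loadings, clinical, covariates = NULL,
                                  min_site = 4) {
  loadings <- as.matrix(loadings)
  K <- ncol(loadings)
  site <- if (!is.null(covariates) && "site" %in% names(covariates))
    as.character(covariates$site) else rep("overall", nrow(loadings))
  other <- if (is.null(covariates)) NULL
           else covariates[, setdiff(names(covariates), "site"), drop = FALSE]
  one_group <- function(ix, label) {
    cov_ix <- if (!is.null(other) && ncol(other) > 0 && length(ix) > ncol(other) + 2)
      other[ix, , drop = FALSE] else NULL
    ld <- residualize(loadings[ix, , drop = FALSE], cov_ix)
    cl <- residualize(as.matrix(clinical[ix, , drop = FALSE]), cov_ix)
    ld <- as.matrix(ld); cl <- as.matrix(cl)
    recs <- expand.grid(factor = seq_len(K), scale = names(clinical),
                        stringsAsFactors = FALSE)
    recs$site <- label
    recs$n <- length(ix)
    stat <- t(mapply(function(k, sc) {
      ct <- stats::cor.test(ld[, k], cl[, match(sc, names(clinical))])
      c(r = unname(ct$estimate), p = ct$p.value)
    }, recs$factor, recs$scale))
    recs$r <- stat[, "r"]; recs$p <- stat[, "p"]
    ci <- t(vapply(recs$r, .fisher_ci, numeric(2), n = length(ix)))
    recs$ci_lo <- ci[, 1]; recs$ci_hi <- ci[, 2]
    recs$p_fdr <- stats::p.adjust(recs$p, "BH")
    recs[, c("site", "factor", "scale", "n", "r", "ci_lo", "ci_hi", "p", "p_fdr")]
  }
  out <- one_group(seq_len(nrow(loadings)), "overall")
  if (length(unique(site)) > 1) {
    for (s in unique(site)) {
      ix <- which(site == s)
      if (length(ix) < min_site) {
        warning("site ", s, " skipped: fewer than ", min_site, " subjects")
        next
      }
      out <- rbind(out, one_group(ix, s))
    }
  }
  class(out) <- c("correlation_record", "data.frame")
  out
}

#' General-linear-hypothesis contrast of a characteristic on loadings
#'
#' Fits Y = b0 + b1 p1 + b2 p2 + e (the last factor is implicit through
#' the loading simplex) and tests the null H b = 0 by a Wald F test.
#'
#' @param y Characteristic (one value per subject).
#' @param loadings S x K simplex rows; the first K-1 columns enter the
#'   model.
#' @param H Contrast row vector of length K (e.g. c(0, -1, 1) compares
#'   factors 1 and 2 through their coefficients).
#' @param covariates Optional covariates (e.g. site) residualized out of
#'   both sides first.
#' @return List with `estimate` (H %*% beta), `statistic` (F),
#'   `p`, `beta`.
#' @export
glm_contrast <- function(y, loadings, H, covariates = NULL) {
  loadings <- as.matrix(loadings)
  K <- ncol(loadings)
  if (length(H) != K) stop("invalid argument: H must have length K")
  if (!is.null(covariates)) {
    y <- residualize(y, covariates)
    loadings <- as.matrix(residualize(loadings, covariates))
  }
  X <- cbind(1, loadings[, seq_len(K - 1), drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinearity in loading regressors")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  H <- matrix(H, nrow = 1)
  est <- drop(H %*% beta)
  Fstat <- drop(est^2 / (sigma2 * H %*% XtXinv %*% t(H)))
  list(estimate = est, statistic = Fstat,
       p = stats::pf(Fstat, 1, df, lower.tail = FALSE), beta = beta)
}
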