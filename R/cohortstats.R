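# Group-difference mapping with covariate control, regional and network
# summaries, and multiple-testing control.

# dummy-coded full-rank design from a covariate data frame (no response)
.design_matrix <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(matrix(1, 1, 1))
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity in covariates: ", paste(bad, collapse = ", "))
  }
  X
}

#' Residualize values against covariates
#'
#' Ordinary least-squares residuals of `y` on a dummy-coded covariate
#' design (with intercept). `y` may be a vector or a matrix whose
#' columns are residualized jointly against the same design.
#'
#' @param y Numeric vector or matrix (subjects in rows).
#' @param covariates Data frame of covariates (numeric and/or
#'   categorical); NULL means intercept only.
#' @return Residuals with the same shape as `y` (column means 0).
#' @export
residualize <- function(y, covariates = NULL) {
  y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (is.null(covariates)) return(scale(y, scale = FALSE)[, , drop = TRUE])
  X <- .design_matrix(covariates)
  if (nrow(X) == 1) return(scale(y, scale = FALSE)[, , drop = TRUE])
  stopifnot(nrow(X) == nrow(y))
  drop(stats::lm.fit(X, y)$residuals)
}

.pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Region-pair group-difference t map
#'
#' For every region pair, residualizes the per-subject interaction
#' values against the covariates and applies a pooled-variance
#' two-sample t test with contrast NC - SCZ (positive t = reduction in
#' patients).
#'
#' @param matrices List of per-subject symmetric interaction matrices.
#' @param groups Character/factor vector ("NC"/"SCZ") per subject.
#' @param covariates Optional covariate data frame (e.g. age, gender,
#'   site).
#' @return Object of class `group_diff_map`: list with `t_values`,
#'   `p_values` (N x N symmetric), `df`, `contrast`, `kind`.
#' @export
group_t_map <- function(matrices, groups, covariates = NULL) {
  groups <- as.character(groups)
  if (length(matrices) != length(groups))
    stop("one group label per subject matrix required")
  if (min(table(groups)) < 3) stop("insufficient sample: need >= 3 per group")
  N <- nrow(matrices[[1]])
  V <- do.call(rbind, lapply(matrices, lower_tri_vec))  # subjects x pairs
  R <- if (is.null(covariates)) V else residualize(V, covariates)
  nc <- groups == "NC"; sz <- groups == "SCZ"
  tv <- pv <- numeric(ncol(R))
  for (p in seq_len(ncol(R))) {
    r <- .pooled_t(R[nc, p], R[sz, p])
    tv[p] <- r$t; pv[p] <- r$p
  }
  structure(list(t_values = unvec_lower_tri(tv, N),
                 p_values = unvec_lower_tri(pv, N) + diag(1, N),
                 df = sum(nc) + sum(sz) - 2,
                 contrast = "NC-SCZ",
                 kind = attr(matrices[[1]], "kind")),
            class = "group_diff_map")
}

#' Regional profile of a group-difference map
#'
#' Mean of each region's row of the t matrix, excluding the diagonal.
#'
#' @param diff A `group_diff_map` or symmetric matrix.
#' @return N-vector of regional mean t statistics.
#' @export
regional_profile <- function(diff) {
  M <- if (inherits(diff, "group_diff_map")) diff$t_values else as.matrix(diff)
  N <- nrow(M)
  (rowSums(M) - diag(M)) / (N - 1)
}

#' Per-network summary of a regional vector or interaction matrix
#'
#' For vectors: mean and sd of the values of the regions in each
#' network. For matrices: within- and between-network block means.
#'
#' @param x N-vector or N x N symmetric matrix.
#' @param parc A `parcellation` covering the same regions.
#' @return Data frame (vector input: network, n, mean, sd) or matrix of
#'   network-block means (matrix input).
#' @export
network_summary <- function(x, parc) {
  nets <- parc$network
  known <- unique(c(.cortical_networks, "SUB"))
  if (!all(nets %in% known))
    stop("schema error: unknown network label(s): ",
         paste(setdiff(nets, known), collapse = ", "))
  if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) == length(nets)) {
    labs <- intersect(known, unique(nets))
    B <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      ri <- nets == labs[i]; rj <- nets == labs[j]
      blk <- x[ri, rj, drop = FALSE]
      if (i == j) {
        if (sum(ri) < 2) next
        B[i, j] <- mean(blk[lower.tri(blk)])
      } else B[i, j] <- mean(blk)
    }
    return(B)
  }
  x <- as.numeric(x)
  if (length(x) != length(nets)) stop("length of x must match parcellation")
  out <- do.call(rbind, lapply(intersect(known, unique(nets)), function(nw) {
    v <- x[nets == nw]
    data.frame(network = nw, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' @param p Vector of p values in \[0, 1\].
#' @param q FDR level.
#' @return List with `rejected` (logical), `p_adjusted` (BH-adjusted).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("invalid argument: p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Paired t test between two regional profiles
#'
#' @param profileA,profileB Equal-length regional vectors paired by
#'   region.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_profile_test <- function(profileA, profileB) {
  if (length(profileA) != length(profileB))
    stop("schema error: profiles differ in length")
  d <- profileA - profileB
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
    stop("degenerate-variance: constant nonzero profile difference")
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

#' Compare the dispersion of two score samples
#'
#' Two-sided unpaired t test on per-subject squared deviations from the
#' respective group mean, a t-based analogue of a variance comparison.
#'
#' @param scoresA,scoresB Numeric samples (>= 3 each).
#' @return List with `statistic`, `p`.
#' @export
variance_comparison <- function(scoresA, scoresB) {
  if (length(scoresA) < 3 || length(scoresB) < 3)
    stop("insufficient sample: need >= 3 per group")
  da <- (scoresA - mean(scoresA))^2
  db <- (scoresB - mean(scoresB))^2
  if (stats::sd(da) == 0 && stats::sd(db) == 0)
    return(list(statistic = 0, p = 1))
  ht <- stats::t.test(da, db)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
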