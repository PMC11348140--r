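# Per-subject region x region interaction matrices: persistent synergy,
# double redundancy, and plain Pearson functional connectivity.

#' Regional time-series container
#'
#' @param data T x N numeric matrix (rows = time points, cols = regions).
#' @param subject_id Subject identifier.
#' @param dt Sampling interval in seconds (one repetition time).
#' @return Object of class `regional_ts`.
#' @export
regional_ts <- function(data, subject_id = "sub-01", dt = 2) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("time series contains missing values")
  structure(list(subject_id = subject_id, data = data, dt = dt),
            class = "regional_ts")
}

.ts_matrix <- function(ts) {
  if (inherits(ts, "regional_ts")) ts$data else as.matrix(ts)
}

#' Interaction matrix constructor
#'
#' A symmetric region x region matrix of one interaction kind with the
#' diagonal fixed at 0 by convention.
#'
#' @param values N x N symmetric numeric matrix.
#' @param kind One of "synergy", "redundancy", "fc".
#' @param subject_id Subject identifier.
#' @export
interaction_matrix <- function(values, kind = c("synergy", "redundancy", "fc"),
                               subject_id = NA_character_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("interaction matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("interaction matrix must be symmetric")
  diag(values) <- 0
  structure(values, kind = kind, subject_id = subject_id,
            class = c("interaction_matrix", "matrix", "array"))
}

#' Synergy and redundancy matrices for every region pair
#'
#' Runs the Gaussian PhiID on each unordered region pair of one subject:
#' entry (i, j) of the synergy matrix is the persistent-synergy atom
#' `Syn->Syn`, and of the redundancy matrix the double-redundancy atom
#' `Red->Red`, both in nats. The decomposition is invariant to channel
#' relabeling, so both matrices are symmetric by construction.
#'
#' @param ts A `regional_ts` or T x N matrix.
#' @param tau Lag in samples (default 1 TR).
#' @param redundancy Redundancy-constraint convention passed to the
#'   decomposition; see [phid_decompose()].
#' @return List with elements `synergy` and `redundancy`
#'   (`interaction_matrix` objects).
#' @export
pairwise_interaction_matrices <- function(ts, tau = 1L,
                                          redundancy = c("channelwise",
                                                         "collection")) {
  redundancy <- match.arg(redundancy)
  X <- .ts_matrix(ts)
  sid <- if (inherits(ts, "regional_ts")) ts$subject_id else NA_character_
  N <- ncol(X); T <- nrow(X)
  if (N < 2L) stop("need at least two regions")
  if (T - tau < 20L) stop("need at least 20 overlapping samples after lagging")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate series in region(s): ",
         paste(which(sds == 0), collapse = ", "))
  Z <- scale(X)
  past <- Z[seq_len(T - tau), , drop = FALSE]
  fut  <- Z[(1L + tau):T, , drop = FALSE]
  C <- stats::cov(cbind(past, fut))
  Minv <- .phid_solver()
  w_syn <- Minv["Syn->Syn", ]
  w_red <- Minv["Red->Red", ]
  syn <- matrix(0, N, N); red <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      ix <- c(i, j, N + i, N + j)
      fr <- tryCatch(.phid_f(C[ix, ix], redundancy),
                     error = function(e)
                       stop("PhiID failed for region pair (", i, ", ", j, "): ",
                            conditionMessage(e), call. = FALSE))
      syn[i, j] <- syn[j, i] <- sum(w_syn * fr$f)
      red[i, j] <- red[j, i] <- sum(w_red * fr$f)
    }
  }
  list(synergy = interaction_matrix(syn, "synergy", sid),
       redundancy = interaction_matrix(red, "redundancy", sid))
}

#' Functional connectivity matrix
#'
#' Pearson correlation between all pairs of regional time series; the
#' unit diagonal is replaced by 0 per the interaction-matrix convention.
#'
#' @inheritParams pairwise_interaction_matrices
#' @return An `interaction_matrix` of kind "fc".
#' @export
functional_connectivity <- function(ts) {
  X <- .ts_matrix(ts)
  sid <- if (inherits(ts, "regional_ts")) ts$subject_id else NA_character_
  if (ncol(X) < 2L) stop("need at least two regions")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate series in region(s): ",
         paste(which(sds == 0), collapse = ", "))
  interaction_matrix(stats::cor(X), "fc", sid)
}

#' Whole-brain mean interaction score of one subject
#'
#' Mean over the strict lower triangle of a symmetric interaction
#' matrix (N(N-1)/2 region pairs; 6555 for a 115-region parcellation).
#'
#' @param mat Symmetric matrix.
#' @return Scalar mean.
#' @export
subject_mean_score <- function(mat) {
  mat <- as.matrix(mat)
  mean(mat[lower.tri(mat)])
}

#' Vectorize the strict lower triangle in a fixed pair order
#'
#' Pair order is column-major over (row > col): (2,1), (3,1), ...,
#' (N,1), (3,2), ... This order is used consistently for LDA documents
#' and factor patterns.
#'
#' @param mat Symmetric N x N matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @export
lower_tri_vec <- function(mat) {
  mat <- as.matrix(mat)
  mat[lower.tri(mat)]
}

#' Pair index table for a parcellation of N regions
#'
#' @param N Region count.
#' @return Data frame with columns `row`, `col` (row > col) matching the
#'   vectorization order of [lower_tri_vec()].
#' @export
pair_index <- function(N) {
  ix <- which(lower.tri(matrix(0, N, N)), arr.ind = TRUE)
  data.frame(row = ix[, 1], col = ix[, 2])
}

# rebuild a symmetric matrix from its lower-triangle vector
unvec_lower_tri <- function(v, N) {
  M <- matrix(0, N, N)
  M[lower.tri(M)] <- v
  M + t(M)
}
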