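# Gaussian integrated information decomposition (PhiID) for pairs of
# time series, using the minimum-mutual-information (MMI) redundancy
# function. All information quantities are in nats.

.phid_nodes <- c("Red", "Un1", "Un2", "Syn")

# down-sets of the four-node redundancy lattice Red <= Un1, Un2 <= Syn
.phid_downsets <- list(
  Red = "Red",
  Un1 = c("Red", "Un1"),
  Un2 = c("Red", "Un2"),
  Syn = c("Red", "Un1", "Un2", "Syn")
)

.phid_atom_names <- as.vector(outer(.phid_nodes, .phid_nodes,
                                    function(a, b) paste0(a, "->", b)))

# 16 x 16 cumulative-constraint matrix: row (a,b), column (alpha,beta),
# entry 1 iff alpha <= a and beta <= b in the product lattice order.
.phid_constraint_matrix <- function() {
  M <- matrix(0L, 16L, 16L, dimnames = list(.phid_atom_names, .phid_atom_names))
  for (a in .phid_nodes) for (b in .phid_nodes) {
    row <- paste0(a, "->", b)
    cols <- as.vector(outer(.phid_downsets[[a]], .phid_downsets[[b]],
                            function(x, y) paste0(x, "->", y)))
    M[row, cols] <- 1L
  }
  M
}

.phid_env <- new.env(parent = emptyenv())

.phid_solver <- function() {
  if (is.null(.phid_env$Minv)) {
    M <- .phid_constraint_matrix()
    .phid_env$M <- M
    .phid_env$Minv <- solve(M)
  }
  .phid_env$Minv
}

#' Lagged joint covariance of a pair of series
#'
#' Z-scores both series and returns the 4 x 4 sample covariance of the
#' stacked vector (X1_t, X2_t, X1_{t+tau}, X2_{t+tau}) over the common
#' window t = 1..T-tau.
#'
#' @param x,y Numeric vectors of equal length (one region each).
#' @param tau Lag in samples (non-negative integer).
#' @return An object of class `lagged_cov`: list with elements `tau` and
#'   `cov` (4 x 4 matrix, variables ordered past-1, past-2, future-1,
#'   future-2).
#' @export
lagged_covariance <- function(x, y, tau = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  T <- length(x)
  if (T - tau < 20L) stop("need at least 20 overlapping samples after lagging")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate series: zero variance input")
  x <- as.vector(scale(x)); y <- as.vector(scale(y))
  past <- cbind(x[seq_len(T - tau)], y[seq_len(T - tau)])
  fut  <- cbind(x[(1L + tau):T],     y[(1L + tau):T])
  S <- stats::cov(cbind(past, fut))
  dimnames(S) <- list(NULL, NULL)
  structure(list(tau = as.integer(tau), cov = S), class = "lagged_cov")
}

.as_cov4 <- function(cov) {
  if (inherits(cov, "lagged_cov")) cov <- cov$cov
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(4L, 4L))) stop("expected a 4 x 4 lagged covariance")
  if (any(!is.finite(cov))) stop("covariance contains non-finite values")
  (cov + t(cov)) / 2
}

# orthonormal basis spanning the full-rank directions of a covariance block
.full_rank_basis <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values[1], 1)
  if (!any(keep)) stop("degenerate series: zero-variance block")
  e$vectors[, keep, drop = FALSE]
}

.logdet_pd <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= tol * max(max(e), 1))
    stop("singular-covariance: joint block is rank deficient")
  sum(log(e))
}

#' Gaussian mutual information between two coordinate groups
#'
#' Computes I(A; B) = 1/2 log( det S_AA det S_BB / det S_{A u B} ) from a
#' lagged covariance, in nats. Linearly dependent coordinates *within* a
#' group are projected out (duplicated channels carry no extra
#' information); rank deficiency *across* the groups signals genuinely
#' infinite information and raises a singular-covariance error. The
#' result is clamped at zero.
#'
#' @param cov A `lagged_cov` or plain 4 x 4 covariance matrix.
#' @param A,B Disjoint, nonempty index sets into the 4 coordinates.
#' @return Mutual information in nats (non-negative scalar).
#' @export
gaussian_mi <- function(cov, A, B) {
  S <- .as_cov4(cov)
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  if (length(intersect(A, B))) stop("A and B must be disjoint")
  TA <- .full_rank_basis(S[A, A, drop = FALSE])
  TB <- .full_rank_basis(S[B, B, drop = FALSE])
  SAA <- crossprod(TA, S[A, A, drop = FALSE] %*% TA)
  SBB <- crossprod(TB, S[B, B, drop = FALSE] %*% TB)
  SAB <- crossprod(TA, S[A, B, drop = FALSE] %*% TB)
  J <- rbind(cbind(SAA, SAB), cbind(t(SAB), SBB))
  mi <- 0.5 * (.logdet_pd(SAA) + .logdet_pd(SBB) - .logdet_pd(J))
  max(mi, 0)
}

# The nine lagged MIs between past collections {1},{2},{1,2} and future
# collections, as a 3 x 3 matrix (rows past, cols future). Fast closed-form
# determinants with a fallback to the rank-aware path near degeneracy.
.phid_mi9 <- function(S, tol = 1e-12) {
  d2 <- function(i, j) S[i, i] * S[j, j] - S[i, j]^2
  det3 <- function(ix) {
    a <- S[ix[1], ix[1]]; b <- S[ix[1], ix[2]]; c <- S[ix[1], ix[3]]
    d <- S[ix[2], ix[2]]; e <- S[ix[2], ix[3]]; f <- S[ix[3], ix[3]]
    a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d)
  }
  grp <- list(1L, 2L, c(1L, 2L))
  fgrp <- list(3L, 4L, c(3L, 4L))
  ldp <- c(log(S[1, 1]), log(S[2, 2]), log(d2(1, 2)))
  ldf <- c(log(S[3, 3]), log(S[4, 4]), log(d2(3, 4)))
  out <- matrix(NA_real_, 3, 3)
  ok <- all(is.finite(c(ldp, ldf)))
  if (ok) {
    for (i in 1:3) for (j in 1:3) {
      ix <- c(grp[[i]], fgrp[[j]])
      dj <- if (length(ix) == 2L) d2(ix[1], ix[2])
            else if (length(ix) == 3L) det3(ix)
            else det(S)
      if (dj <= tol) { ok <- FALSE; break }
      out[i, j] <- max(0, 0.5 * (ldp[i] + ldf[j] - log(dj)))
    }
  }
  if (!ok) {
    for (i in 1:3) for (j in 1:3)
      out[i, j] <- gaussian_mi(S, grp[[i]], fgrp[[j]])
  }
  out
}

# Cumulative constraint values f(alpha -> beta) for all 16 lattice node
# pairs. Under the default "channelwise" convention every redundancy
# constraint is a minimum over *single-channel* lagged MIs (the double-
# redundancy rule applied uniformly); "collection" evaluates one-sided
# redundancies against the joint collection (min_i I(X^i; X^b)), which
# leaves a positive persistent-synergy floor for independent
# autocorrelated channels.
.phid_f <- function(S, redundancy = c("channelwise", "collection")) {
  redundancy <- match.arg(redundancy)
  mi <- .phid_mi9(S)
  cols <- list(Red = 1:2, Un1 = 1L, Un2 = 2L, Syn = 3L)
  f <- numeric(16); names(f) <- .phid_atom_names
  for (a in .phid_nodes) for (b in .phid_nodes) {
    ia <- cols[[a]]; ib <- cols[[b]]
    if (redundancy == "channelwise") {
      # inside a redundancy constraint (either side at the Red node),
      # joint collections contribute their individual channels
      if (a == "Red" && b == "Syn") ib <- 1:2
      if (b == "Red" && a == "Syn") ia <- 1:2
    }
    f[paste0(a, "->", b)] <- min(mi[ia, ib])
  }
  list(f = f, tdmi = mi[3, 3])
}

#' Double redundancy under minimum mutual information
#'
#' The information about the future that is redundant across both past
#' channels and remains redundant across both future channels: the
#' minimum of the four single-channel lagged mutual informations
#' I(X^i_t; X^j_{t+tau}).
#'
#' @param cov A `lagged_cov` or 4 x 4 covariance matrix.
#' @return Double redundancy in nats.
#' @export
double_redundancy_mmi <- function(cov) {
  S <- .as_cov4(cov)
  min(.phid_mi9(S)[1:2, 1:2])
}

#' Decompose a lagged covariance into the 16 PhiID atoms
#'
#' Solves the linear system whose cumulative constraints are the nine
#' Gaussian lagged mutual informations plus the seven MMI redundancies
#' over the product redundancy lattice. The synergy measure carried
#' forward by the pipeline is the persistent-synergy atom `Syn->Syn`;
#' the redundancy measure is `Red->Red`.
#'
#' @param cov A `lagged_cov` (see [lagged_covariance()]) or 4 x 4 matrix.
#' @param redundancy Redundancy-constraint convention: `"channelwise"`
#'   (default; every MMI minimum runs over single-channel lagged MIs, so
#'   independent channels carry zero persistent synergy) or
#'   `"collection"` (one-sided redundancies evaluated against the joint
#'   collection).
#' @return Object of class `phid_atoms`: list with `atoms` (named
#'   16-vector, nats), `tdmi` (time-delayed mutual information
#'   I(X_t; X_{t+tau}), nats), and convenience scalars `synergy`
#'   (`Syn->Syn`) and `redundancy` (`Red->Red`).
#' @examples
#' ts <- matrix(rnorm(400), 200, 2)
#' at <- phid_decompose(lagged_covariance(ts[, 1], ts[, 2], 1))
#' abs(sum(at$atoms) - at$tdmi) < 1e-8
#' @export
phid_decompose <- function(cov, redundancy = c("channelwise", "collection")) {
  redundancy <- match.arg(redundancy)
  S <- .as_cov4(cov)
  fr <- .phid_f(S, redundancy)
  atoms <- drop(.phid_solver() %*% fr$f)
  names(atoms) <- .phid_atom_names
  if (any(!is.finite(atoms)))
    stop("internal-inconsistency: non-finite atom solution")
  structure(list(atoms = atoms, tdmi = fr$tdmi,
                 synergy = atoms[["Syn->Syn"]],
                 redundancy = atoms[["Red->Red"]]),
            class = "phid_atoms")
}

#' PhiID atoms by explicit Moebius inversion (independent oracle)
#'
#' Computes the same 16 atoms as [phid_decompose()] by recursive Moebius
#' inversion over the product redundancy lattice instead of solving the
#' cumulative linear system. Used as an internal cross-check.
#'
#' @inheritParams phid_decompose
#' @return Named 16-vector of atoms (nats).
#' @export
phid_mobius <- function(cov, redundancy = c("channelwise", "collection")) {
  redundancy <- match.arg(redundancy)
  S <- .as_cov4(cov)
  f <- .phid_f(S, redundancy)$f
  atoms <- numeric(16); names(atoms) <- .phid_atom_names
  below <- function(a, b) {
    setdiff(as.vector(outer(.phid_downsets[[a]], .phid_downsets[[b]],
                            function(x, y) paste0(x, "->", y))),
            paste0(a, "->", b))
  }
  pairs <- expand.grid(a = .phid_nodes, b = .phid_nodes,
                       stringsAsFactors = FALSE)
  pairs$rank <- lengths(.phid_downsets[pairs$a]) * lengths(.phid_downsets[pairs$b])
  pairs <- pairs[order(pairs$rank), ]
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    nm <- paste0(a, "->", b)
    atoms[nm] <- f[nm] - sum(atoms[below(a, b)])
  }
  atoms
}

#' Analytic lagged covariance of a stationary VAR(1) process
#'
#' For x_{t+1} = A x_t + e, e ~ N(0, Q), solves the discrete Lyapunov
#' equation for the stationary covariance and returns the joint
#' covariance of (x_t, x_{t+tau}).
#'
#' @param A N x N coefficient matrix with spectral radius < 1.
#' @param Q N x N innovation covariance (default identity).
#' @param tau Lag in samples.
#' @return 2N x 2N joint covariance; the upper-right N x N block is
#'   Cov(x_t, x_{t+tau}).
#' @export
var1_lagged_cov <- function(A, Q = diag(nrow(A)), tau = 1L) {
  A <- as.matrix(A); N <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1)
    stop("VAR(1) coefficient matrix is not stable")
  S0 <- matrix(solve(diag(N * N) - kronecker(A, A), as.vector(Q)), N, N)
  S0 <- (S0 + t(S0)) / 2
  Atau <- diag(N)
  for (k in seq_len(tau)) Atau <- A %*% Atau
  cross <- S0 %*% t(Atau)          # Cov(x_t, x_{t+tau}) = S0 A'^tau
  rbind(cbind(S0, cross), cbind(t(cross), S0))
}

# 4 x 4 lagged covariance of a region pair (i, j) from a full VAR(1)
# joint covariance as returned by var1_lagged_cov
.pair_cov_from_joint <- function(J, i, j) {
  N <- nrow(J) / 2
  ix <- c(i, j, N + i, N + j)
  J[ix, ix]
}
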