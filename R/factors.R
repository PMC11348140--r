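# From patient synergy matrices to latent dysfunction factors:
# z-normalization against controls, document construction, factor
# matching, model-order selection, factor maps and subtypes.

#' Z-normalize patient matrices against the control distribution
#'
#' Per matrix entry (i, j): z = (x_scz - mean_NC) / sd_NC, with the
#' control sd in its n-1 (Bessel-corrected) form.
#'
#' @param scz List of patient interaction matrices.
#' @param nc List of control interaction matrices (>= 3).
#' @return List of symmetric z-score matrices (one per patient).
#' @export
znormalize_to_controls <- function(scz, nc) {
  if (length(nc) < 3) stop("need at least 3 control subjects")
  N <- nrow(nc[[1]])
  V <- matrix(vapply(nc, lower_tri_vec, numeric(N * (N - 1) / 2)),
              nrow = N * (N - 1) / 2)
  mu <- rowMeans(V)
  sdv <- apply(V, 1, stats::sd)
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    pix <- pair_index(N)
    stop("degenerate-normalization: control sd is zero for pair (",
         pix$row[bad], ", ", pix$col[bad], ")")
  }
  lapply(scz, function(m) {
    z <- (lower_tri_vec(m) - mu) / sdv
    unvec_lower_tri(z, N)
  })
}

#' Build LDA count documents from z-score matrices
#'
#' Positive z-scores (synergy increases) are reset to zero; absolute
#' values of negative z-scores (synergy reductions) are taken, scaled,
#' and rounded to counts. The pair order is the fixed lower-triangle
#' vectorization of [lower_tri_vec()].
#'
#' @param z List of symmetric z-score matrices (one per patient).
#' @param scale Discretization multiplier (> 0); z = -1.7 at the
#'   default 10 becomes 17 counts.
#' @return Object of class `document_matrix`: list with `counts`
#'   (S x P integer matrix) and `scale`.
#' @export
prepare_documents <- function(z, scale = 10) {
  if (scale <= 0) stop("invalid argument: scale must be positive")
  N <- nrow(z[[1]])
  W <- do.call(rbind, lapply(z, function(m) pmax(0, -lower_tri_vec(m))))
  counts <- round(scale * W)
  empty <- rowSums(counts) == 0
  if (any(empty))
    warning(sum(empty), " subject(s) with no synergy reduction retained ",
            "as empty documents")
  structure(list(counts = counts, scale = scale, n_regions = N),
            class = "document_matrix")
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Match factors between two models
#'
#' Finds the one-to-one assignment of modelB's factors onto modelA's
#' that maximizes the summed Pearson correlation between pattern rows
#' (exhaustive assignment search; K is small).
#'
#' @param modelA,modelB `factor_model` objects (or K x P pattern
#'   matrices) with equal K.
#' @return List with `permutation` (modelB row matched to each modelA
#'   row), `correlations` (per matched pair), `mean_correlation`.
#' @export
match_factors <- function(modelA, modelB) {
  pa <- if (inherits(modelA, "factor_model")) modelA$patterns else as.matrix(modelA)
  pb <- if (inherits(modelB, "factor_model")) modelB$patterns else as.matrix(modelB)
  if (nrow(pa) != nrow(pb)) stop("invalid argument: models differ in K")
  K <- nrow(pa)
  C <- stats::cor(t(pa), t(pb))
  perms <- .permutations(K)
  scores <- apply(perms, 1, function(p) sum(C[cbind(seq_len(K), p)]))
  best <- unname(as.integer(perms[which.max(scores), ]))
  corrs <- unname(C[cbind(seq_len(K), best)])
  list(permutation = best, correlations = corrs,
       mean_correlation = mean(corrs))
}

#' Select the number of factors by split-half stability
#'
#' For each candidate K, subjects are split in half `n_splits` times;
#' models fitted on the two halves are matched and the mean matched
#' pattern correlation recorded. The chosen K maximizes mean stability.
#'
#' @param docs A `document_matrix` or count matrix.
#' @param K_grid Candidate factor counts.
#' @param n_splits Number of random split-half repetitions.
#' @param seed Integer seed.
#' @param ... Passed to [fit_lda()].
#' @return List with `K` (chosen) and `stability` (data frame: K,
#'   mean_correlation, sd).
#' @export
select_k <- function(docs, K_grid = 2:4, n_splits = 5, seed = 1, ...) {
  n <- if (inherits(docs, "document_matrix")) docs$counts else as.matrix(docs)
  S <- nrow(n)
  if (S < 2 * n_splits) stop("too few subjects for split-half stability")
  .with_seed(seed, {
    tab <- lapply(K_grid, function(K) {
      r <- vapply(seq_len(n_splits), function(s) {
        half <- sample(S, floor(S / 2))
        fa <- fit_lda(n[half, , drop = FALSE], K, seed = seed + 1000 * s, ...)
        fb <- fit_lda(n[-half, , drop = FALSE], K, seed = seed + 1000 * s + 1, ...)
        match_factors(fa, fb)$mean_correlation
      }, numeric(1))
      data.frame(K = K, mean_correlation = mean(r), sd = stats::sd(r))
    })
    tab <- do.call(rbind, tab)
    list(K = tab$K[which.max(tab$mean_correlation)], stability = tab)
  })
}

#' Regional factor map
#'
#' Aggregates a pair-level factor pattern to regions: region r's value
#' is the sum of the pattern over all pairs containing r.
#'
#' @param model A `factor_model` (or K x P pattern matrix).
#' @param k Factor index.
#' @return N-vector (regional map).
#' @export
factor_map <- function(model, k) {
  pat <- if (inherits(model, "factor_model")) model$patterns else as.matrix(model)
  if (k > nrow(pat)) stop("invalid argument: k exceeds K")
  P <- ncol(pat)
  N <- (1 + sqrt(1 + 8 * P)) / 2
  if (N != round(N)) stop("pattern length is not a valid pair count")
  pix <- pair_index(N)
  v <- numeric(N)
  for (i in seq_len(P)) {
    v[pix$row[i]] <- v[pix$row[i]] + pat[k, i]
    v[pix$col[i]] <- v[pix$col[i]] + pat[k, i]
  }
  v
}

#' Assign each patient to a subtype by dominant factor expression
#'
#' @param loadings S x K simplex rows.
#' @return Data frame with `subtype` (argmax factor index, ties broken
#'   by lowest index) and `tie` flag.
#' @export
assign_subtype <- function(loadings) {
  loadings <- as.matrix(loadings)
  sub <- apply(loadings, 1, which.max)
  tie <- apply(loadings, 1, function(r) sum(r == max(r)) > 1)
  data.frame(subtype = as.integer(sub), tie = tie)
}

#' Top-magnitude section masks of a regional map
#'
#' Ranks regions by value (descending), divides them into
#' `n_sections` equal-size sections (quantile rank when N is not
#' divisible), and returns the top `n_sections * top_fraction` section
#' masks.
#'
#' @param map N-vector.
#' @param n_sections Number of rank sections (default 20).
#' @param top_fraction Fraction of sections returned from the top.
#' @return List with `masks` (list of logical N-vectors, best section
#'   first) and `tie` flag (TRUE when ties cross a section boundary;
#'   broken by region index).
#' @export
top_sections_mask <- function(map, n_sections = 20, top_fraction = 0.2) {
  N <- length(map)
  ord <- order(-map, seq_len(N))          # ties broken by region index
  section <- ceiling(seq_len(N) / (N / n_sections))
  section <- pmin(section, n_sections)
  n_top <- round(n_sections * top_fraction)
  ranked_vals <- map[ord]
  tie <- any(vapply(seq_len(n_sections - 1), function(s) {
    b <- max(which(section == s))
    ranked_vals[b] == ranked_vals[b + 1]
  }, logical(1)))
  masks <- lapply(seq_len(n_top), function(s) {
    m <- rep(FALSE, N)
    m[ord[section == s]] <- TRUE
    m
  })
  list(masks = masks, tie = tie)
}
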