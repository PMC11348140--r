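# Imaging-transcriptomics: gene-factor correlations, risk-gene
# selection, regional co-expression, and the virtual gene-knockout
# contribution indicator (GCI).

#' Per-gene correlation with a factor map
#'
#' Pearson correlation between each gene's regional expression profile
#' and a regional factor map. Constant gene columns get r = 0 and a
#' flag instead of an error.
#'
#' @param expr Region x gene expression matrix (regions in rows).
#' @param fmap Regional factor map (length = number of regions).
#' @return Data frame: gene, r, constant (flag).
#' @export
gene_factor_correlations <- function(expr, fmap) {
  expr <- as.matrix(expr)
  if (nrow(expr) != length(fmap)) stop("region counts differ")
  sds <- apply(expr, 2, stats::sd)
  r <- rep(0, ncol(expr))
  ok <- sds > 0
  if (stats::sd(fmap) == 0) stop("undefined-correlation: constant factor map")
  r[ok] <- drop(stats::cor(expr[, ok, drop = FALSE], fmap))
  data.frame(gene = colnames(expr) %||% seq_len(ncol(expr)),
             r = r, constant = !ok, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select top/bottom ranked risk genes
#'
#' Ranks genes by correlation (descending); the top `n_top` and bottom
#' `n_bottom` form the factor's risk sets. Ties are broken by gene id
#' and flagged.
#'
#' @param rs Data frame from [gene_factor_correlations()] (or a named
#'   numeric vector of correlations).
#' @param n_top,n_bottom Set sizes (the analysis default at full
#'   transcriptome scale is 1500 each).
#' @return List with `top`, `bottom`, `union` (gene id vectors) and
#'   `tie` flag.
#' @export
select_risk_genes <- function(rs, n_top = 1500, n_bottom = 1500) {
  if (is.data.frame(rs)) { r <- rs$r; g <- rs$gene } else {
    r <- as.numeric(rs); g <- names(rs) %||% seq_along(rs)
  }
  if (n_top + n_bottom > length(r))
    stop("invalid argument: set sizes exceed gene count")
  ord <- order(-r, g)
  tie <- any(duplicated(r[ord][c(n_top, n_top + 1)])) ||
    any(duplicated(r[rev(ord)][c(n_bottom, n_bottom + 1)]))
  top <- g[ord[seq_len(n_top)]]
  bottom <- g[rev(ord)[seq_len(n_bottom)]]
  list(top = top, bottom = bottom, union = union(top, bottom), tie = tie)
}

#' Regional gene co-expression matrix (Fisher-z Spearman)
#'
#' Spearman correlation between every pair of regional expression
#' profiles across the selected genes, Fisher z-transformed
#' (atanh); the diagonal is set to 0 and off-diagonal correlations of
#' exactly 1 (duplicated regions) are capped at 1 - 1e-6 before the
#' transform, with a warning.
#'
#' @param expr Region x gene matrix restricted to the risk-gene set
#'   (>= 3 genes).
#' @return N x N symmetric Fisher-z co-expression matrix.
#' @export
coexpression_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 genes")
  if (any(apply(expr, 1, function(x) length(unique(x))) == 1))
    stop("degenerate-rank: a region has an all-tied expression profile")
  rho <- stats::cor(t(expr), method = "spearman")
  diag(rho) <- 0
  if (any(abs(rho) >= 1 - 1e-12)) {
    warning("off-diagonal |rho| = 1 capped before Fisher transform")
    rho <- pmin(pmax(rho, -(1 - 1e-6)), 1 - 1e-6)
  }
  z <- atanh(rho)
  diag(z) <- 0
  z
}

#' Correlate regional co-expression strength with a factor map
#'
#' The regional co-expression strength is the row mean of the Fisher-z
#' co-expression matrix (diagonal excluded); its Pearson correlation
#' with the factor map is tested with the SA permutation test when a
#' distance matrix is supplied.
#'
#' @param coexp N x N Fisher-z co-expression matrix.
#' @param fmap Regional factor map.
#' @param distmat Optional N x N distance matrix for the SA test.
#' @param n_surrogates,seed SA test settings.
#' @return List with `r`, `strength`, and (when `distmat` is given)
#'   `p_sa`.
#' @export
coexpression_factor_corr <- function(coexp, fmap, distmat = NULL,
                                     n_surrogates = 1000, seed = 1) {
  N <- nrow(coexp)
  strength <- rowSums(coexp) / (N - 1)
  if (stats::sd(strength) == 0 || stats::sd(fmap) == 0)
    stop("undefined-correlation: constant input")
  r <- stats::cor(strength, fmap)
  out <- list(r = r, strength = strength)
  if (!is.null(distmat))
    out$p_sa <- sa_corr_test(strength, fmap, distmat,
                             n = n_surrogates, seed = seed)$p_sa
  out
}

#' Virtual gene knockout: gene contribution indicators
#'
#' For each gene in the risk set, rebuilds the co-expression matrix
#' without that gene and records GCI = r_all - r_knockout, the change
#' in the co-expression-vs-factor-map correlation caused by removing
#' the gene. Positive GCI means the gene supports the association.
#'
#' @param expr Region x gene matrix restricted to the risk set (>= 4
#'   genes).
#' @param fmap Regional factor map.
#' @return Data frame of class `gci_table`: gene, gci, class
#'   ("GCI+", "GCI-", or "zero").
#' @export
virtual_knockout <- function(expr, fmap) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 4) stop("need at least 4 genes")
  r_all <- coexpression_factor_corr(coexpression_matrix(expr), fmap)$r
  gci <- vapply(seq_len(ncol(expr)), function(g) {
    r_ko <- coexpression_factor_corr(
      coexpression_matrix(expr[, -g, drop = FALSE]), fmap)$r
    r_all - r_ko
  }, numeric(1))
  out <- data.frame(gene = colnames(expr) %||% seq_len(ncol(expr)),
                    gci = gci,
                    class = ifelse(gci > 0, "GCI+",
                                   ifelse(gci < 0, "GCI-", "zero")),
                    stringsAsFactors = FALSE)
  class(out) <- c("gci_table", "data.frame")
  out
}
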