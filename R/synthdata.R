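# Synthetic two-group cohort with the statistical structure the analysis
# assumes: stable VAR(1) regional dynamics in controls, with patient
# cross-regional couplings attenuated along K planted factor patterns
# carrying Dirichlet-distributed subject loadings.

.cortical_networks <- c("VIS", "SOM", "DAN", "SAL", "LIM", "FPN", "DMN")

# evaluate code under a temporary RNG state so generators are pure in (seed)
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

#' Synthetic brain parcellation
#'
#' Builds a parcellation of `n_cortical` cortical regions assigned in
#' contiguous blocks to the seven canonical resting-state networks plus
#' `n_subcortical` subcortical (SUB) regions, with 3-D coordinates
#' sampled on two hemispheric spheres (cortex) and an inner shell
#' (subcortex). Deterministic given `seed`.
#'
#' @param n_cortical Number of cortical regions (>= 8).
#' @param n_subcortical Number of subcortical regions (may be 0).
#' @param seed Integer seed.
#' @return Data frame of class `parcellation` with columns `region_id`,
#'   `label`, `network`, `hemisphere`, `x`, `y`, `z`, `is_cortical`.
#' @export
make_parcellation <- function(n_cortical = 100, n_subcortical = 15, seed = 1) {
  if (n_cortical < 8) stop("invalid argument: n_cortical must be >= 8")
  .with_seed(seed, {
    nets <- rep(.cortical_networks,
                diff(round(seq(0, n_cortical, length.out = 8))))
    N <- n_cortical + n_subcortical
    hemi <- c(rep(c("L", "R"), length.out = n_cortical),
              rep(c("L", "R"), length.out = n_subcortical))
    # cortical coords: unit-sphere directions scaled to a 60 mm shell,
    # hemispheres offset along x
    dir <- matrix(stats::rnorm(3 * N), N, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    radius <- c(rep(60, n_cortical), rep(20, n_subcortical))
    xyz <- dir * radius
    xyz[, 1] <- abs(xyz[, 1]) * ifelse(hemi == "L", -1, 1) +
      ifelse(hemi == "L", -8, 8)
    out <- data.frame(
      region_id = seq_len(N),
      label = sprintf("%s_%s_%03d",
                      c(nets, rep("SUB", n_subcortical)), hemi, seq_len(N)),
      network = c(nets, rep("SUB", n_subcortical)),
      hemisphere = hemi,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      is_cortical = c(rep(TRUE, n_cortical), rep(FALSE, n_subcortical)),
      stringsAsFactors = FALSE
    )
    class(out) <- c("parcellation", "data.frame")
    out
  })
}

#' Euclidean distance matrix of a parcellation
#' @param parc A `parcellation`.
#' @return N x N distance matrix (mm).
#' @export
parcellation_dist <- function(parc) {
  as.matrix(stats::dist(as.matrix(parc[, c("x", "y", "z")])))
}

# K sets of disjoint coupled region dyads -> K x P {0,1} pair patterns
# (P = N(N-1)/2). Dyads are disjoint across factors, so the planted
# innovation correlations stay block-diagonal (guaranteed PSD) and the
# patterns are mutually near-orthogonal.
.planted_patterns <- function(N, K, n_dyads) {
  regions <- matrix(sample(N, 2L * n_dyads * K), nrow = K)
  P <- N * (N - 1) / 2
  pairmat <- matrix(0L, N, N)
  pairmat[lower.tri(pairmat)] <- seq_len(P)
  pairmat <- pairmat + t(pairmat)
  pat <- matrix(0, K, P)
  dyads <- vector("list", K)
  for (k in seq_len(K)) {
    d <- matrix(regions[k, ], ncol = 2)
    dyads[[k]] <- d
    pat[k, pairmat[d]] <- 1
  }
  list(patterns = pat, regions = regions, dyads = dyads)
}

# Stable NC coupling matrix plus innovation covariance. Planted
# within-block couplings are negative while the corresponding
# innovations are positively correlated: this sign opposition is what
# gives the planted pairs genuinely positive persistent synergy that
# coupling attenuation destroys (same-sign coupling and innovation
# correlation yields redundancy instead).
.make_var_coupling <- function(N, patterns, self = 0.4, w_planted = 0.55,
                               q_planted = 0.85, background_sd = 0.03,
                               background_density = 0.1) {
  B <- matrix(0, N, N)
  mask <- matrix(stats::runif(N * N) < background_density, N, N)
  B[mask] <- stats::rnorm(sum(mask), 0, background_sd)
  B <- (B + t(B)) / 2
  planted <- unvec_lower_tri(colSums(patterns) > 0, N)
  B[planted > 0] <- -w_planted
  diag(B) <- 0
  A <- diag(self, N) + B
  Q <- diag(N)
  Q[planted > 0] <- q_planted
  r <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (r >= 0.97) {
    off <- A; diag(off) <- 0
    A <- diag(diag(A)) + off * (0.95 / r)
  }
  list(A = A, Q = Q)
}

.stabilize <- function(A, rho_max = 0.97) {
  for (k in 1:50) {
    r <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (r < rho_max) return(A)
    off <- A; diag(off) <- 0
    A <- diag(diag(A)) + off * 0.93
  }
  stop("could not stabilize attenuated coupling matrix")
}

.simulate_var1 <- function(A, T, Q = NULL, burn = 50L) {
  N <- nrow(A)
  x <- numeric(N)
  out <- matrix(0, T, N)
  E <- matrix(stats::rnorm((T + burn) * N), T + burn, N)
  if (!is.null(Q)) E <- E %*% chol(Q)
  for (t in seq_len(T + burn)) {
    x <- drop(A %*% x) + E[t, ]
    if (t > burn) out[t - burn, ] <- x
  }
  out
}

.affine_to_range <- function(v, lo, hi) {
  z <- (v - mean(v)) / max(stats::sd(v), 1e-12)
  mid <- (lo + hi) / 2
  pmin(hi, pmax(lo, round(mid + z * (hi - lo) / 8)))
}

#' Simulate a two-group cohort of regional BOLD time series
#'
#' Control (NC) subjects follow a stable VAR(1) process
#' `x_{t+1} = A x_t + e`. For each patient (SCZ), every off-diagonal
#' coupling `A_ij` is multiplied by
#' `1 - effect * sum_k loading_k * pattern_k(i,j)`, which weakens
#' cross-predictive structure - and hence pairwise synergy - on the
#' planted factor-pattern pairs. PANSS subscales are linear in the
#' subject loadings plus Gaussian noise, then mapped into the standard
#' score ranges. Site, age, and gender are drawn independently of the
#' loadings.
#'
#' The default clinical coupling plants a positive association between
#' factor 1 and the positive subscale and negative associations between
#' factor 3 and the negative/general subscales.
#'
#' @param parc A `parcellation`.
#' @param n_nc,n_scz Group sizes.
#' @param T Time points per subject (>= 50).
#' @param K Number of planted factors.
#' @param effect Coupling attenuation strength in \[0, 1\].
#' @param seed Integer seed.
#' @param loading_alpha Dirichlet concentration of subject loadings.
#' @param clinical_noise_sd Noise sd on the latent clinical scale
#'   (signal sd is ~0.3, so the default gives a true r near 0.3).
#' @param n_sites Number of acquisition sites, balanced across groups.
#' @param clinical_weights Optional K x 3 matrix coupling loadings to
#'   the (positive, negative, general) latent scales; an all-zero
#'   matrix gives noise-only clinical scores.
#' @return List with `cohort` (data frame), `series` (named list of
#'   `regional_ts`), and `truth` (planted factor patterns, loadings,
#'   clinical weights, coupling matrices).
#' @export
simulate_cohort <- function(parc, n_nc = 60, n_scz = 60, T = 240, K = 3,
                            effect = 0.6, seed = 1, loading_alpha = 0.5,
                            clinical_noise_sd = 0.95, n_sites = 3,
                            clinical_weights = NULL) {
  if (T < 50) stop("invalid argument: T must be >= 50")
  if (effect < 0 || effect > 1) stop("invalid argument: effect must be in [0,1]")
  N <- nrow(parc)
  .with_seed(seed, {
    n_dyads <- max(2L, floor(N / (2L * K)))
    if (2L * n_dyads * K > N) n_dyads <- max(1L, floor(N / (2L * K)))
    pl <- .planted_patterns(N, K, n_dyads)
    cpl <- .make_var_coupling(N, pl$patterns)
    A <- cpl$A; Q <- cpl$Q
    loadings <- .rdirichlet(n_scz, rep(loading_alpha, K))

    ids <- sprintf("sub-%03d", seq_len(n_nc + n_scz))
    grp <- c(rep("NC", n_nc), rep("SCZ", n_scz))
    series <- vector("list", n_nc + n_scz)
    names(series) <- ids
    for (s in seq_len(n_nc + n_scz)) {
      As <- A
      if (grp[s] == "SCZ") {
        m <- drop(loadings[s - n_nc, ] %*% pl$patterns)   # in [0,1]
        att <- unvec_lower_tri(1 - effect * m, N)
        diag(att) <- 1
        off <- A * att
        diag(off) <- diag(A)
        As <- .stabilize(off)
      }
      series[[s]] <- regional_ts(.simulate_var1(As, T, Q), ids[s])
    }

    # clinical weights: rows = factors, cols = (pos, neg, gen)
    if (is.null(clinical_weights)) {
      W <- matrix(0, K, 3, dimnames = list(NULL, c("pos", "neg", "gen")))
      W[1, "pos"] <- 1
      if (K >= 3) { W[3, "neg"] <- -1; W[3, "gen"] <- -1 }
      else W[K, c("neg", "gen")] <- -1
    } else {
      W <- clinical_weights
      stopifnot(nrow(W) == K, ncol(W) == 3)
      colnames(W) <- c("pos", "neg", "gen")
    }
    raw <- loadings %*% W +
      matrix(stats::rnorm(n_scz * 3, 0, clinical_noise_sd), n_scz, 3)
    pos <- .affine_to_range(raw[, 1], 7, 49)
    neg <- .affine_to_range(raw[, 2], 7, 49)
    gen <- .affine_to_range(raw[, 3], 16, 112)
    n_items <- c(rep(7, 7), rep(7, 7), rep(16, 16))     # subscale sizes per item
    sub_of_item <- c(rep(1, 7), rep(2, 7), rep(3, 16))
    items <- matrix(NA_real_, n_nc + n_scz, 30)
    subm <- cbind(pos, neg, gen)
    for (it in 1:30) {
      v <- subm[, sub_of_item[it]] / n_items[it] + stats::rnorm(n_scz, 0, 0.5)
      items[grp == "SCZ", it] <- pmin(7, pmax(1, round(v)))
    }
    colnames(items) <- sprintf("panss_item_%02d", 1:30)

    site <- unlist(lapply(c(n_nc, n_scz), function(n)
      rep(paste0("site", seq_len(n_sites)), length.out = n)))
    cohort <- data.frame(
      subject_id = ids, group = grp,
      age = round(pmin(65, pmax(18, stats::rnorm(n_nc + n_scz, 32, 9)))),
      gender = sample(c("M", "F"), n_nc + n_scz, replace = TRUE),
      site = site,
      motion = stats::rlnorm(n_nc + n_scz, log(0.12), 0.4),
      PANSS_pos = ifelse(grp == "SCZ", c(rep(NA, n_nc), pos), NA),
      PANSS_neg = ifelse(grp == "SCZ", c(rep(NA, n_nc), neg), NA),
      PANSS_gen = ifelse(grp == "SCZ", c(rep(NA, n_nc), gen), NA),
      cpz_eq = ifelse(grp == "SCZ",
                      round(stats::rlnorm(n_nc + n_scz, log(400), 0.5)), NA),
      illness_duration = ifelse(grp == "SCZ",
                                round(stats::rgamma(n_nc + n_scz, 2, 0.3), 1), NA),
      gmv = stats::rnorm(n_nc + n_scz, 600, 40),
      stringsAsFactors = FALSE
    )
    cohort <- cbind(cohort, items)

    truth <- list(
      factor_patterns = pl$patterns,
      factor_regions = pl$regions,
      loadings = loadings,
      clinical_weights = W,
      planted_pairs = which(colSums(pl$patterns) > 0),
      coupling = A,
      innovation_cov = Q,
      risk_gene_index = integer(0)
    )
    list(cohort = cohort, series = series, truth = truth)
  })
}

# smooth Gaussian field on parcellation coordinates, z-scored
.smooth_field <- function(D, lambda, n = 1) {
  Kmat <- exp(-D / lambda)
  out <- Kmat %*% matrix(stats::rnorm(nrow(D) * n), nrow(D), n)
  scale(out)
}

#' Simulate a region x gene expression table with planted factor genes
#'
#' Planted genes equal a (z-scored) factor map plus Gaussian noise; half
#' of each factor's planted genes carry the negated map so both tails of
#' the gene-factor correlation ranking are populated. Remaining genes
#' are spatially smooth noise.
#'
#' @param parc A `parcellation`.
#' @param n_genes Total number of genes (> 0).
#' @param factor_maps K x N matrix (rows = factor maps on regions).
#' @param n_planted Planted genes per factor (`n_planted * K <= n_genes`).
#' @param noise_sd Noise sd added to planted genes (map is unit
#'   variance).
#' @param seed Integer seed.
#' @return N x n_genes matrix with gene-id colnames and attribute
#'   `planted` (data frame: gene, factor, sign).
#' @export
simulate_gene_expression <- function(parc, n_genes, factor_maps, n_planted,
                                     noise_sd = 0.5, seed = 1) {
  if (n_genes <= 0) stop("invalid argument: n_genes must be positive")
  factor_maps <- rbind(factor_maps)
  K <- nrow(factor_maps); N <- nrow(parc)
  if (n_planted * K > n_genes) stop("invalid argument: too many planted genes")
  .with_seed(seed, {
    D <- parcellation_dist(parc)
    expr <- .smooth_field(D, lambda = 30, n = n_genes)
    planted <- data.frame(gene = integer(0), factor = integer(0), sign = integer(0))
    g <- 0L
    for (k in seq_len(K)) {
      fmap <- as.vector(scale(factor_maps[k, ]))
      for (i in seq_len(n_planted)) {
        g <- g + 1L
        sgn <- if (i <= ceiling(n_planted / 2)) 1L else -1L
        expr[, g] <- sgn * fmap + stats::rnorm(N, 0, noise_sd)
        planted <- rbind(planted, data.frame(gene = g, factor = k, sign = sgn))
      }
    }
    colnames(expr) <- sprintf("gene%05d", seq_len(n_genes))
    planted$gene_id <- colnames(expr)[planted$gene]
    attr(expr, "planted") <- planted
    expr
  })
}

#' Simulate structural maps: connectome, myelin and gradient fields
#'
#' The structural connectome is symmetric, nonnegative and
#' distance-decaying with zero diagonal, rescaled to a unit maximum;
#' myelin and principal-gradient maps are smooth fields on the
#' parcellation coordinates, z-scored.
#'
#' @param parc A `parcellation`.
#' @param density Fraction of region pairs with nonzero connection
#'   weight, in (0, 1\].
#' @param seed Integer seed.
#' @return List with `sc` (N x N), `myelin`, `gradient` (N-vectors).
#' @export
simulate_structural <- function(parc, density = 0.35, seed = 1) {
  if (density <= 0 || density > 1) stop("invalid argument: density in (0,1]")
  N <- nrow(parc)
  .with_seed(seed, {
    D <- parcellation_dist(parc)
    W <- exp(-D / 40) * matrix(stats::rlnorm(N * N, 0, 0.4), N, N)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    if (density < 1) {
      v <- W[lower.tri(W)]
      thr <- stats::quantile(v, 1 - density)
      W[W < thr] <- 0
      diag(W) <- 0
    }
    W <- W / max(W)
    list(sc = W,
         myelin = as.vector(.smooth_field(D, 35)),
         gradient = as.vector(.smooth_field(D, 50)))
  })
}
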