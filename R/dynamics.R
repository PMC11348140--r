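# Heterogeneous dynamic mean-field model of cortical BOLD dynamics:
# regional parameters as linear combinations of myelin and gradient
# maps, Euler-Maruyama integration, Balloon-Windkessel hemodynamics,
# FC/FCD cost, and CMA-ES fitting.

#' Fixed mean-field constants
#'
#' Transfer-function constants (a, b, d), synaptic time constant
#' `tau_s`, kinetic rate `gamma`, and synaptic coupling `J`, following
#' the standard reduced mean-field parameterization. All exposed as
#' configuration; units: a \[nC^-1\], b \[Hz\], d \[s\], tau_s \[s\],
#' J \[nA\].
#'
#' @return Named list.
#' @export
mfm_constants <- function() {
  list(a = 270, b = 108, d = 0.154, tau_s = 0.1, gamma = 0.641, J = 0.2609)
}

#' Population transfer function H(x)
#'
#' H(x) = (a x - b) / (1 - exp(-d (a x - b))), with the removable
#' singularity at a x = b evaluated as its limit 1/d.
#'
#' @param x Total input (nA).
#' @param a,b,d Transfer constants (see [mfm_constants()]).
#' @return Firing rate (Hz).
#' @export
h_rate <- function(x, a = 270, b = 108, d = 0.154) {
  u <- a * x - b
  ifelse(abs(u) < 1e-9, 1 / d, u / (1 - exp(-d * u)))
}

#' Regional parameters from myelin and gradient maps
#'
#' W_i = a_w Mye_i + b_w Grad_i + c_w, and likewise for the external
#' input I_i and noise sigma_i. W and sigma are floored at 1e-4 (flag
#' returned when the floor binds).
#'
#' @param myelin,gradient Z-scored regional maps (cortical regions).
#' @param coeffs Numeric vector (a_w, b_w, c_w, a_I, b_I, c_I,
#'   a_sig, b_sig, c_sig) or a list with elements `w`, `i`, `sigma`
#'   (each length 3).
#' @return List with `W`, `I`, `sigma`, `clipped` (flag).
#' @export
regional_params <- function(myelin, gradient, coeffs) {
  if (is.list(coeffs)) coeffs <- c(coeffs$w, coeffs$i, coeffs$sigma)
  stopifnot(length(coeffs) == 9)
  lin <- function(a, b, cc) a * myelin + b * gradient + cc
  W <- lin(coeffs[1], coeffs[2], coeffs[3])
  I <- lin(coeffs[4], coeffs[5], coeffs[6])
  sig <- lin(coeffs[7], coeffs[8], coeffs[9])
  clipped <- any(W < 1e-4) || any(sig < 1e-4)
  list(W = pmax(W, 1e-4), I = I, sigma = pmax(sig, 1e-4), clipped = clipped)
}

#' Integrate the mean-field model
#'
#' Euler-Maruyama integration of the coupled gating equations
#' dS_i = \[-S_i/tau_s + gamma (1 - S_i) H(x_i)\] dt + sigma_i dW with
#' x_i = W_i J S_i + G J sum_j C_ij S_j + I_i; S is clipped to \[0, 1\].
#'
#' @param sc N x N structural connectome (zero diagonal, max 1).
#' @param params List with `W`, `I`, `sigma` (regional vectors) and `G`
#'   (global coupling); see [regional_params()].
#' @param dt Integration step (s), <= 0.01.
#' @param duration Simulated time (s).
#' @param seed Integer seed (noise draws).
#' @param store_every Store every k-th step.
#' @param constants Fixed constants, see [mfm_constants()].
#' @param S0 Initial gating values (default 0.2).
#' @return Object of class `mfm_sim`: `S_trace` (time x N), `dt_store`.
#' @export
simulate_mfm <- function(sc, params, dt = 0.01, duration = 120, seed = 1,
                         store_every = 1L, constants = mfm_constants(),
                         S0 = NULL) {
  if (dt > 0.01 + 1e-12) stop("invalid argument: dt must be <= 10 ms")
  N <- nrow(sc)
  if (is.null(S0)) S0 <- rep(0.2, N)
  tr <- .mfm_integrate_cpp(as.matrix(sc), params$W, params$I, params$sigma,
                           params$G, constants$J, constants$a, constants$b,
                           constants$d, constants$tau_s, constants$gamma,
                           dt, duration, as.integer(store_every), S0,
                           as.double(seed))
  if (any(!is.finite(tr))) {
    bad <- which(!is.finite(tr), arr.ind = TRUE)[1, ]
    stop("divergence at t = ", bad[1] * dt * store_every,
         " s, region ", bad[2])
  }
  structure(list(S_trace = tr, dt_store = dt * store_every), class = "mfm_sim")
}

#' Deterministic fixed point of an isolated region
#'
#' Solves S / tau_s = gamma (1 - S) H(W J S + I) for an uncoupled
#' region (G = 0) by root finding.
#'
#' @param W,I Regional recurrent strength and input.
#' @param constants See [mfm_constants()].
#' @return Fixed-point gating value in (0, 1).
#' @export
mfm_fixed_point <- function(W, I, constants = mfm_constants()) {
  f <- function(S)
    -S / constants$tau_s + constants$gamma * (1 - S) *
      h_rate(W * constants$J * S + I, constants$a, constants$b, constants$d)
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Balloon-Windkessel hemodynamics
#'
#' Transforms a synaptic-gating trace into BOLD signals per region,
#' downsampled to the repetition time, with the burn-in discarded.
#'
#' @param sim An `mfm_sim` (or time x N gating matrix at step `dt`).
#' @param dt Step of the input trace (s).
#' @param TR Output sampling interval (s); must be a multiple of dt.
#' @param burn_in Seconds discarded from the start.
#' @return T_out x N BOLD matrix.
#' @export
hemodynamics <- function(sim, dt = NULL, TR = 2, burn_in = 60) {
  S <- if (inherits(sim, "mfm_sim")) sim$S_trace else as.matrix(sim)
  if (is.null(dt)) dt <- if (inherits(sim, "mfm_sim")) sim$dt_store else
    stop("dt required for a plain matrix input")
  if (abs(TR / dt - round(TR / dt)) > 1e-9)
    stop("invalid argument: TR must be a multiple of dt")
  .balloon_bold_cpp(S, dt, TR, burn_in)
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Sliding-window FC patterns (upper triangles) correlated between all
#' window pairs.
#'
#' @param bold T x N BOLD matrix.
#' @param window Window length (TRs).
#' @param stride Window stride (TRs).
#' @return W x W symmetric FCD matrix (unit diagonal).
#' @export
fcd <- function(bold, window = 30, stride = 3) {
  T <- nrow(bold)
  if (window >= T) stop("invalid argument: window must be shorter than the series")
  starts <- seq(1, T - window + 1, by = stride)
  vecs <- list(); dropped <- 0
  for (s in starts) {
    w <- bold[s:(s + window - 1), , drop = FALSE]
    v <- colMeans(w^2) - colMeans(w)^2
    if (any(v <= 0)) { dropped <- dropped + 1; next }
    fc <- stats::cor(w)
    vecs[[length(vecs) + 1]] <- fc[upper.tri(fc)]
  }
  if (dropped > 0) message(dropped, " zero-variance window(s) dropped")
  V <- do.call(cbind, vecs)
  stats::cor(V)
}

#' FC + FCD fitting cost
#'
#' cost = (1 - Pearson r between the upper FC triangles) +
#' (Kolmogorov-Smirnov distance between the upper-triangle FCD entry
#' distributions).
#'
#' @param fc_sim,fc_emp N x N FC matrices.
#' @param fcd_sim,fcd_emp FCD matrices (shapes may differ; compared as
#'   entry distributions). Either may be NULL to skip the KS term.
#' @return List with `total`, `fc_term`, `ks_term`.
#' @export
fit_cost <- function(fc_sim, fc_emp, fcd_sim = NULL, fcd_emp = NULL) {
  a <- fc_sim[upper.tri(fc_sim)]; b <- fc_emp[upper.tri(fc_emp)]
  fc_term <- 1 - stats::cor(a, b)
  ks_term <- 0
  if (!is.null(fcd_sim) && !is.null(fcd_emp)) {
    x <- if (is.matrix(fcd_sim)) fcd_sim[upper.tri(fcd_sim)] else fcd_sim
    y <- if (is.matrix(fcd_emp)) fcd_emp[upper.tri(fcd_emp)] else fcd_emp
    ks_term <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  }
  list(total = fc_term + ks_term, fc_term = fc_term, ks_term = ks_term)
}

# Default box constraints for the 10-parameter search
# (a_w, b_w, c_w, a_I, b_I, c_I, a_sig, b_sig, c_sig, G). The G box
# assumes a max-normalized structural connectome, for which the
# low-activity branch destabilizes well below G = 2; wider boxes are
# accepted via the `bounds` argument of fit_pmfm.
.pmfm_bounds <- function() {
  list(lower = c(-0.3, -0.3, 0.3, -0.1, -0.1, 0.25, -0.002, -0.002, 0.002, 0),
       upper = c(0.3, 0.3, 1.0, 0.1, 0.1, 0.40, 0.002, 0.002, 0.008, 1))
}

# simulate BOLD for a parameter vector via the fused kernel; fixed
# noise seed = common random numbers across CMA-ES candidates
.pmfm_forward <- function(theta, sc, myelin, gradient, sim_cfg) {
  rp <- regional_params(myelin, gradient, theta[1:9])
  cst <- mfm_constants()
  N <- nrow(sc)
  bold <- .mfm_bold_cpp(as.matrix(sc), rp$W, rp$I, rp$sigma, theta[10],
                        cst$J, cst$a, cst$b, cst$d, cst$tau_s, cst$gamma,
                        sim_cfg$dt, sim_cfg$duration, sim_cfg$TR,
                        sim_cfg$burn_in, rep(0.2, N), sim_cfg$hemo_every,
                        as.double(sim_cfg$noise_seed))
  if (any(!is.finite(bold))) stop("divergence in forward simulation")
  bold
}

#' Simulate pMFM BOLD for explicit regional parameters
#'
#' Convenience wrapper over the fused integration + hemodynamics
#' kernel, used both to generate synthetic "empirical" BOLD and inside
#' the fitting objective.
#'
#' @param sc Structural connectome.
#' @param params List with `W`, `I`, `sigma`, `G`.
#' @param sim_cfg See [pmfm_sim_config()].
#' @param seed Noise seed.
#' @return T_out x N BOLD matrix at TR resolution.
#' @export
simulate_pmfm_bold <- function(sc, params, sim_cfg = pmfm_sim_config(),
                               seed = 1) {
  cst <- mfm_constants()
  N <- nrow(sc)
  .mfm_bold_cpp(as.matrix(sc), params$W, params$I, params$sigma,
                params$G, cst$J, cst$a, cst$b, cst$d, cst$tau_s,
                cst$gamma, sim_cfg$dt, sim_cfg$duration, sim_cfg$TR,
                sim_cfg$burn_in, rep(0.2, N), sim_cfg$hemo_every,
                as.double(seed))
}

.pmfm_cost <- function(theta, sc, myelin, gradient, fc_emp, fcd_emp, sim_cfg) {
  # saturated or divergent candidates get the worst attainable cost
  # (FC term <= 2, KS term <= 1) so the optimizer still sees a finite,
  # ordered landscape
  bold <- tryCatch(.pmfm_forward(theta, sc, myelin, gradient, sim_cfg),
                   error = function(e) NULL)
  if (is.null(bold) || any(apply(bold, 2, stats::sd) == 0)) return(3)
  fc_sim <- stats::cor(bold)
  fcd_sim <- tryCatch(suppressMessages(
    fcd(bold, sim_cfg$fcd_window, sim_cfg$fcd_stride)),
    error = function(e) NULL)
  if (is.null(fcd_sim)) return(3)
  fit_cost(fc_sim, fc_emp, fcd_sim, fcd_emp)$total
}

#' Default pMFM simulation settings
#'
#' @param dt Integration step (s).
#' @param duration Simulated seconds (including burn-in).
#' @param burn_in Discarded seconds.
#' @param TR Output sampling interval (s).
#' @param fcd_window,fcd_stride FCD sliding-window settings (TRs).
#' @param store_every Steps between stored gating samples.
#' @param noise_seed Seed of the integration noise (common random
#'   numbers across candidate evaluations).
#' @return List of settings.
#' @export
pmfm_sim_config <- function(dt = 0.01, duration = 180, burn_in = 30, TR = 2,
                            fcd_window = 30, fcd_stride = 3,
                            store_every = 1L, noise_seed = 1L,
                            hemo_every = 5L) {
  list(dt = dt, duration = duration, burn_in = burn_in, TR = TR,
       fcd_window = fcd_window, fcd_stride = fcd_stride,
       store_every = store_every, noise_seed = noise_seed,
       hemo_every = as.integer(hemo_every))
}

#' Fit the pMFM to empirical group FC/FCD by CMA-ES
#'
#' Optimizes the nine linear map coefficients plus the global coupling
#' G against the group-mean FC and pooled FCD entries of the training
#' subjects, with k-fold cross-validation over subjects (folds = 1 fits
#' all subjects without validation).
#'
#' @param sc Structural connectome (cortical).
#' @param myelin,gradient Z-scored cortical maps.
#' @param bold_list List of empirical T x N BOLD matrices (one per
#'   subject).
#' @param folds Cross-validation folds (>= 1; each fold needs >= 1
#'   subject).
#' @param generations,popsize CMA-ES budget.
#' @param seed Integer seed (fold assignment, CMA-ES sampling).
#' @param sim_cfg See [pmfm_sim_config()].
#' @param bounds List with `lower` and `upper` 10-vectors (box
#'   constraints of the search).
#' @param sigma0 Initial CMA-ES step size in box-normalized
#'   coordinates; the default box is narrow, so a conservative step
#'   keeps early generations in the informative (non-saturated) regime.
#' @return List with `params` (best 10-vector, named), `regional`
#'   (derived W, I, sigma), `cv` (per-fold train/validation costs),
#'   `best_cost`.
#' @export
fit_pmfm <- function(sc, myelin, gradient, bold_list, folds = 5,
                     generations = 64, popsize = NULL, seed = 1,
                     sim_cfg = pmfm_sim_config(), bounds = .pmfm_bounds(),
                     sigma0 = 0.15) {
  S <- length(bold_list)
  if (S < folds) stop("need at least `folds` subjects")
  bb <- bounds
  emp <- function(ix) {
    fcs <- lapply(bold_list[ix], stats::cor)
    fc <- Reduce(`+`, fcs) / length(fcs)
    fcd_entries <- unlist(lapply(bold_list[ix], function(b) {
      m <- suppressMessages(fcd(b, sim_cfg$fcd_window, sim_cfg$fcd_stride))
      m[upper.tri(m)]
    }))
    list(fc = fc, fcd = fcd_entries)
  }
  .with_seed(seed, {
    fold_id <- if (folds == 1) rep(1L, S) else
      sample(rep(seq_len(folds), length.out = S))
    cv <- data.frame(fold = integer(0), train_cost = numeric(0),
                     validation_cost = numeric(0))
    best <- NULL
    for (f in seq_len(max(fold_id))) {
      tr_ix <- if (folds == 1) seq_len(S) else which(fold_id != f)
      va_ix <- if (folds == 1) integer(0) else which(fold_id == f)
      e_tr <- emp(tr_ix)
      obj <- function(th) .pmfm_cost(th, sc, myelin, gradient,
                                     e_tr$fc, e_tr$fcd, sim_cfg)
      fit <- cmaes_minimize(obj, lower = bb$lower, upper = bb$upper,
                            sigma0 = sigma0, generations = generations,
                            popsize = popsize, seed = seed + 17 * f)
      va_cost <- if (length(va_ix)) {
        e_va <- emp(va_ix)
        .pmfm_cost(fit$par, sc, myelin, gradient, e_va$fc, e_va$fcd, sim_cfg)
      } else NA_real_
      cv <- rbind(cv, data.frame(fold = f, train_cost = fit$value,
                                 validation_cost = va_cost))
      score <- if (is.na(va_cost)) fit$value else va_cost
      if (is.null(best) || score < best$score)
        best <- list(par = fit$par, score = score)
    }
    names(best$par) <- c("a_w", "b_w", "c_w", "a_I", "b_I", "c_I",
                         "a_sig", "b_sig", "c_sig", "G")
    reg <- regional_params(myelin, gradient, best$par[1:9])
    list(params = best$par, regional = reg, cv = cv, best_cost = best$score)
  })
}

#' Correlate group parameter differences with factor maps
#'
#' Pearson correlation (with SA permutation p) between the SCZ - NC
#' difference of each regional parameter of interest (W, I) and each
#' cortical factor map.
#'
#' @param params_scz,params_nc Lists with regional `W` and `I` vectors
#'   (cortical).
#' @param factor_maps K x N matrix or list of regional maps (full
#'   parcellation).
#' @param distmat Distance matrix of the *cortical* regions.
#' @param cortical Index of cortical regions into the factor maps.
#' @param n_surrogates,seed SA test settings.
#' @return Data frame: parameter, factor, r, p_sa (NA with a flag
#'   when a difference is constant).
#' @export
param_diff_factor_corr <- function(params_scz, params_nc, factor_maps,
                                   distmat, cortical = NULL,
                                   n_surrogates = 1000, seed = 1) {
  fm <- if (is.list(factor_maps) && !is.matrix(factor_maps))
    do.call(rbind, factor_maps) else rbind(factor_maps)
  if (!is.null(cortical)) fm <- fm[, cortical, drop = FALSE]
  diffs <- list(W = params_scz$W - params_nc$W,
                I = params_scz$I - params_nc$I)
  out <- expand.grid(parameter = names(diffs), factor = seq_len(nrow(fm)),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p_sa <- NA_real_; out$constant <- FALSE
  for (i in seq_len(nrow(out))) {
    d <- diffs[[out$parameter[i]]]
    m <- fm[out$factor[i], ]
    if (stats::sd(d) == 0 || stats::sd(m) == 0) {
      out$constant[i] <- TRUE
      next
    }
    ts <- sa_corr_test(d, m, distmat, n = n_surrogates, seed = seed + i)
    out$r[i] <- ts$r; out$p_sa[i] <- ts$p_sa
  }
  out
}
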