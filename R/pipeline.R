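# End-to-end orchestration: simulate -> PhiID -> group stats -> factors
# -> clinical associations -> transcriptomics (-> dynamics), with a
# single config document, plain-text outputs and a machine-readable
# report.

#' Default pipeline configuration
#'
#' Every constant the analysis depends on lives here so deviations are
#' auditable in one place: parcellation sizes, cohort sizes, PhiID lag,
#' LDA settings (K grid, alpha, eta, discretization scale, runs),
#' surrogate count, FDR level, and the optional mean-field block.
#'
#' @param ... Named overrides of the defaults (unknown names are
#'   rejected).
#' @return Config list of class `synfactor_config`.
#' @export
synfactor_config <- function(...) {
  cfg <- list(
    seed = 1L,
    parcellation = list(n_cortical = 40L, n_subcortical = 10L),
    cohort = list(n_nc = 60L, n_scz = 60L, T = 240L, K = 3L, effect = 0.6,
                  loading_alpha = 0.5, clinical_noise_sd = 0.95, n_sites = 3L),
    phid = list(tau = 1L, redundancy = "channelwise"),
    factors = list(K_grid = c(2L, 3L, 4L), K = NULL, alpha = NULL, eta = 0.01,
                   scale = 10, runs = 20L, n_splits = 5L),
    association = list(fdr_q = 0.05),
    genes = list(enabled = TRUE, n_genes = 400L, n_planted = 40L,
                 noise_sd = 0.5, n_top = 40L, n_bottom = 40L),
    sa = list(n_surrogates = 199L),
    pmfm = list(enabled = FALSE, n_subjects = 5L, folds = 1L,
                generations = 64L, duration = 300, burn_in = 30),
    stages = c("simulate", "phid", "groupdiff", "factors", "associate",
               "genes")
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("config error: unknown field `", nm, "`")
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop("config error: unknown field `", nm, "$", bad[1], "`")
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- c("synfactor_config", "list")
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort bundle as plain-text files
#'
#' Writes `participants.tsv`, `parcellation.tsv`, per-subject
#' `sub-<id>_ts.tsv` time-series tables (rows = time), optional
#' `expression.tsv` and `sc.tsv`, and `truth.json`.
#'
#' @param dir Output directory (created if missing).
#' @param cohort,series,parc,truth As returned by [simulate_cohort()] /
#'   [make_parcellation()].
#' @param expression,sc Optional matrices.
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(dir, cohort, series, parc, truth = NULL,
                                expression = NULL, sc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(cohort, file.path(dir, "participants.tsv"))
  .write_tsv(parc, file.path(dir, "parcellation.tsv"))
  for (id in names(series)) {
    m <- as.data.frame(series[[id]]$data)
    names(m) <- sprintf("region_%03d", seq_along(m))
    .write_tsv(m, file.path(dir, paste0(id, "_ts.tsv")))
  }
  if (!is.null(expression))
    .write_tsv(as.data.frame(expression), file.path(dir, "expression.tsv"))
  if (!is.null(sc))
    .write_tsv(as.data.frame(sc), file.path(dir, "sc.tsv"))
  if (!is.null(truth)) {
    tr <- truth
    tr$factor_patterns <- unclass(tr$factor_patterns)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         matrix = "rowmajor", digits = NA)
  }
  invisible(dir)
}

#' Validate a cohort bundle on disk
#'
#' Checks file presence, matrix shapes, region-count agreement across
#' files, and missing values. Problems are reported, not raised.
#'
#' @param dir Bundle directory.
#' @return Data frame with columns `file` and `problem` (zero rows when
#'   the bundle is consistent).
#' @export
validate_inputs <- function(dir) {
  problems <- data.frame(file = character(0), problem = character(0))
  note <- function(f, p)
    problems <<- rbind(problems, data.frame(file = f, problem = p))
  pfile <- file.path(dir, "participants.tsv")
  parcfile <- file.path(dir, "parcellation.tsv")
  if (!file.exists(pfile)) { note("participants.tsv", "missing"); return(problems) }
  if (!file.exists(parcfile)) { note("parcellation.tsv", "missing"); return(problems) }
  part <- utils::read.delim(pfile)
  parc <- utils::read.delim(parcfile)
  N <- nrow(parc)
  for (id in part$subject_id) {
    f <- file.path(dir, paste0(id, "_ts.tsv"))
    if (!file.exists(f)) { note(basename(f), "missing time series"); next }
    ts <- as.matrix(utils::read.delim(f))
    if (ncol(ts) != N)
      note(basename(f), sprintf("%d regions, parcellation has %d", ncol(ts), N))
    if (any(!is.finite(ts)))
      note(basename(f), paste0("non-finite values (subject ", id, ")"))
  }
  ef <- file.path(dir, "expression.tsv")
  if (file.exists(ef)) {
    expr <- as.matrix(utils::read.delim(ef))
    if (nrow(expr) != N)
      note("expression.tsv", sprintf("%d regions, parcellation has %d",
                                     nrow(expr), N))
  }
  sf <- file.path(dir, "sc.tsv")
  if (file.exists(sf)) {
    sc <- as.matrix(utils::read.delim(sf))
    if (!all(dim(sc) == c(N, N)))
      note("sc.tsv", "not a square region-by-region matrix")
  }
  problems
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order and returns a
#' machine-readable report. Identical config (including seed) gives
#' identical numeric outputs.
#'
#' @param config A `synfactor_config`.
#' @param out_dir Optional directory for tab-separated stage outputs.
#' @param verbose Print stage progress.
#' @return Report list with per-stage results, seeds and timings.
#' @export
run_pipeline <- function(config = synfactor_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "synfactor_config"))
    stop("config error: expected a synfactor_config")
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(...)
  report <- list(config = unclass(config), stages = list())
  stage_on <- function(s) s %in% config$stages
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate -------------------------------------------------------
  say("stage: simulate")
  parc <- make_parcellation(config$parcellation$n_cortical,
                            config$parcellation$n_subcortical,
                            seed = config$seed)
  co <- with(config$cohort,
             simulate_cohort(parc, n_nc, n_scz, T, K, effect,
                             seed = config$seed + 1,
                             loading_alpha = loading_alpha,
                             clinical_noise_sd = clinical_noise_sd,
                             n_sites = n_sites))
  report$stages$simulate <- list(
    n_regions = nrow(parc),
    n_pairs = nrow(parc) * (nrow(parc) - 1) / 2,
    n_nc = config$cohort$n_nc, n_scz = config$cohort$n_scz)
  if (!stage_on("phid")) return(report)

  # --- PhiID ----------------------------------------------------------
  say("stage: phid")
  mats <- lapply(co$series, pairwise_interaction_matrices,
                 tau = config$phid$tau, redundancy = config$phid$redundancy)
  fcs <- lapply(co$series, functional_connectivity)
  syn <- lapply(mats, `[[`, "synergy")
  red <- lapply(mats, `[[`, "redundancy")
  grp <- co$cohort$group
  report$stages$phid <- list(
    mean_synergy_nc = mean(vapply(syn[grp == "NC"], subject_mean_score, 0)),
    mean_synergy_scz = mean(vapply(syn[grp == "SCZ"], subject_mean_score, 0)))

  # --- group statistics ----------------------------------------------
  res <- list()
  if (stage_on("groupdiff")) {
    say("stage: groupdiff")
    covars <- co$cohort[, c("age", "gender", "site")]
    tmaps <- list(synergy = group_t_map(syn, grp, covars),
                  redundancy = group_t_map(red, grp, covars),
                  fc = group_t_map(fcs, grp, covars))
    profs <- lapply(tmaps, regional_profile)
    ptest <- paired_profile_test(profs$synergy, profs$redundancy)
    report$stages$groupdiff <- list(
      mean_regional_t = vapply(profs, mean, 0),
      synergy_vs_redundancy_t = ptest$t,
      synergy_vs_redundancy_p = ptest$p,
      network_summary = network_summary(profs$synergy, parc))
    if (!is.null(out_dir)) {
      .write_tsv(as.data.frame(tmaps$synergy$t_values),
                 file.path(out_dir, "tmap_synergy.tsv"))
      .write_tsv(data.frame(region = parc$region_id,
                            synergy = profs$synergy,
                            redundancy = profs$redundancy,
                            fc = profs$fc),
                 file.path(out_dir, "regional_profiles.tsv"))
    }
    res$tmaps <- tmaps
  }

  # --- factors --------------------------------------------------------
  if (stage_on("factors")) {
    say("stage: factors")
    z <- znormalize_to_controls(syn[grp == "SCZ"], syn[grp == "NC"])
    docs <- prepare_documents(z, scale = config$factors$scale)
    fc_cfg <- config$factors
    K <- fc_cfg$K
    sel <- NULL
    if (is.null(K)) {
      sel <- select_k(docs, fc_cfg$K_grid, n_splits = fc_cfg$n_splits,
                      seed = config$seed + 2, eta = fc_cfg$eta)
      K <- sel$K
    }
    alpha <- if (is.null(fc_cfg$alpha)) 100 / K else fc_cfg$alpha
    runs <- lapply(seq_len(fc_cfg$runs), function(r)
      fit_lda(docs, K, alpha = alpha, eta = fc_cfg$eta,
              seed = config$seed + 100 + r))
    ll <- vapply(runs, function(m) utils::tail(m$log_likelihood, 1), 0)
    best <- runs[[which.max(ll)]]
    fmaps <- do.call(rbind, lapply(seq_len(K), function(k) factor_map(best, k)))
    subtypes <- assign_subtype(best$loadings)
    # planted-truth comparison only applies at the generating K
    mt <- if (K == nrow(co$truth$factor_patterns))
      match_factors(best$patterns, co$truth$factor_patterns) else NULL
    report$stages$factors <- list(
      K = K, selection = if (is.null(sel)) NULL else sel$stability,
      planted_match_correlations = if (is.null(mt)) NULL else mt$correlations,
      planted_permutation = if (is.null(mt)) NULL else mt$permutation,
      subtype_counts = as.vector(table(factor(subtypes$subtype,
                                              levels = seq_len(K)))))
    if (!is.null(out_dir)) {
      .write_tsv(as.data.frame(best$patterns), file.path(out_dir, "patterns.tsv"))
      .write_tsv(as.data.frame(best$loadings), file.path(out_dir, "loadings.tsv"))
      .write_tsv(as.data.frame(t(fmaps)), file.path(out_dir, "factor_maps.tsv"))
      .write_tsv(subtypes, file.path(out_dir, "subtypes.tsv"))
    }
    res$model <- best; res$runs <- runs; res$fmaps <- fmaps
    res$docs <- docs; res$z <- z
  }

  # --- clinical associations -----------------------------------------
  if (stage_on("associate") && !is.null(res$model)) {
    say("stage: associate")
    scz_rows <- co$cohort[grp == "SCZ", ]
    clin <- scz_rows[, c("PANSS_pos", "PANSS_neg", "PANSS_gen")]
    covars <- scz_rows[, c("age", "gender", "site")]
    cc <- clinical_correlations(res$model$loadings, clin, covars)
    rawz <- t(vapply(res$z, lower_tri_vec,
                     numeric(nrow(parc) * (nrow(parc) - 1) / 2)))
    chars <- scz_rows[, c("age", "gender", "site", "PANSS_pos",
                          "PANSS_neg", "PANSS_gen")]
    rsa <- rsa_compare(res$runs, rawz, chars,
                       final = which.max(vapply(res$runs, function(m)
                         utils::tail(m$log_likelihood, 1), 0)))
    report$stages$associate <- list(
      clinical = cc[cc$site == "overall", ],
      rsa = rsa)
    if (!is.null(out_dir)) {
      .write_tsv(cc, file.path(out_dir, "clinical_correlations.tsv"))
      .write_tsv(rsa, file.path(out_dir, "rsa.tsv"))
    }
  }

  # --- transcriptomics ------------------------------------------------
  if (stage_on("genes") && config$genes$enabled && !is.null(res$fmaps)) {
    say("stage: genes")
    g <- config$genes
    # planted genes follow the *planted* factor maps; recovery is tested
    # against the fitted maps
    true_maps <- do.call(rbind, lapply(seq_len(nrow(co$truth$factor_patterns)),
                                       function(k) factor_map(co$truth$factor_patterns, k)))
    expr <- simulate_gene_expression(parc, g$n_genes, true_maps, g$n_planted,
                                     noise_sd = g$noise_sd,
                                     seed = config$seed + 3)
    D <- parcellation_dist(parc)
    per_factor <- lapply(seq_len(nrow(res$fmaps)), function(k) {
      gf <- gene_factor_correlations(expr, res$fmaps[k, ])
      risk <- select_risk_genes(gf, g$n_top, g$n_bottom)
      list(gf = gf, risk = risk)
    })
    risk_union <- Reduce(union, lapply(per_factor, function(x) x$risk$union))
    coexp <- coexpression_matrix(expr[, risk_union, drop = FALSE])
    cfc <- lapply(seq_len(nrow(res$fmaps)), function(k)
      coexpression_factor_corr(coexp, res$fmaps[k, ], D,
                               n_surrogates = config$sa$n_surrogates,
                               seed = config$seed + 4))
    report$stages$genes <- list(
      risk_set_sizes = vapply(per_factor, function(x) length(x$risk$union), 0L),
      risk_union_size = length(risk_union),
      coexpression_factor_r = vapply(cfc, `[[`, 0, "r"),
      coexpression_factor_p_sa = vapply(cfc, `[[`, 0, "p_sa"))
    if (!is.null(out_dir)) {
      gf_all <- do.call(rbind, lapply(seq_along(per_factor), function(k)
        cbind(factor = k, per_factor[[k]]$gf)))
      .write_tsv(gf_all, file.path(out_dir, "gene_factor_r.tsv"))
      writeLines(risk_union, file.path(out_dir, "risk_sets.txt"))
    }
    res$expr <- expr; res$risk_union <- risk_union
  }

  report$wall_time_s <- as.numeric(Sys.time() - t_start, units = "secs")
  report$result_objects <- res
  report$cohort <- co
  report$parcellation <- parc
  invisible(report)
}
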