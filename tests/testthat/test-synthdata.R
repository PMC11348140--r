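# Synthetic cohort generator: parcellation, VAR(1) cohort, gene
# expression, structural maps.

test_that("parcellation has the documented structure", {
  p <- make_parcellation(100, 15, seed = 1)
  expect_equal(nrow(p), 115)
  expect_setequal(unique(p$network),
                  c("VIS", "SOM", "DAN", "SAL", "LIM", "FPN", "DMN", "SUB"))
  expect_true(all(p$network[!p$is_cortical] == "SUB"))
  expect_equal(sum(p$is_cortical), 100)
  expect_identical(p, make_parcellation(100, 15, seed = 1))
  expect_false(identical(p$x, make_parcellation(100, 15, seed = 2)$x))
  p8 <- make_parcellation(8, 0, seed = 1)
  expect_equal(nrow(p8), 8)
  expect_false("SUB" %in% p8$network)
  expect_error(make_parcellation(5, 0), "invalid")
})

test_that("cohort generator is deterministic and obeys its contracts", {
  co <- mini_cohort()
  co2 <- simulate_cohort(mini_parc(), n_nc = 12, n_scz = 12, T = 160, K = 2,
                         effect = 0.6, seed = 7)
  expect_identical(co$series[[1]]$data, co2$series[[1]]$data)
  expect_identical(co$cohort, co2$cohort)
  # PANSS only for patients
  expect_true(all(is.na(co$cohort$PANSS_pos[co$cohort$group == "NC"])))
  expect_true(all(!is.na(co$cohort$PANSS_pos[co$cohort$group == "SCZ"])))
  expect_true(all(co$cohort$PANSS_pos >= 7 & co$cohort$PANSS_pos <= 49,
                  na.rm = TRUE))
  expect_true(all(co$cohort$PANSS_gen >= 16 & co$cohort$PANSS_gen <= 112,
                  na.rm = TRUE))
  # loading rows on the simplex
  expect_equal(rowSums(co$truth$loadings), rep(1, 12))
  # patterns nonnegative, distinct
  pat <- co$truth$factor_patterns
  expect_true(all(pat >= 0))
  expect_lt(abs(cor(pat[1, ], pat[2, ])), 0.5)
  # sites balanced across groups
  tab <- table(co$cohort$site, co$cohort$group)
  expect_true(max(abs(tab[, 1] - tab[, 2])) <= 1)
  expect_error(simulate_cohort(mini_parc(), T = 30), "T")
  expect_error(simulate_cohort(mini_parc(), effect = 1.5), "effect")
})

test_that("null cohorts draw both groups from the same law", {
  # with effect = 0 the FC group difference is calibrated at ~5%
  set.seed(99)
  rates <- replicate(20, {
    seed <- sample.int(1e6, 1)
    co <- simulate_cohort(mini_parc(12, 0, seed = 3), n_nc = 10, n_scz = 10,
                          T = 120, K = 2, effect = 0, seed = seed)
    fcs <- lapply(co$series, functional_connectivity)
    gm <- group_t_map(fcs, co$cohort$group)
    mean(gm$p_values[lower.tri(gm$p_values)] < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.025)
})

test_that("planted attenuation lowers patient synergy on planted pairs", {
  co <- mini_cohort()
  syn <- sapply(co$series, function(s)
    lower_tri_vec(pairwise_interaction_matrices(s)$synergy))
  grp <- co$cohort$group
  pp <- co$truth$planted_pairs
  d_planted <- rowMeans(syn[pp, grp == "NC", drop = FALSE]) -
    rowMeans(syn[pp, grp == "SCZ", drop = FALSE])
  d_other <- rowMeans(syn[-pp, grp == "NC", drop = FALSE]) -
    rowMeans(syn[-pp, grp == "SCZ", drop = FALSE])
  expect_gt(mean(d_planted), 0)
  expect_gt(mean(d_planted), mean(d_other) + 0.02)
})

test_that("gene expression plants factor-correlated genes in both tails", {
  parc <- mini_parc()
  maps <- rbind(sin(seq_len(nrow(parc))), cos(seq_len(nrow(parc))))
  e0 <- simulate_gene_expression(parc, 50, maps, n_planted = 10,
                                 noise_sd = 0, seed = 2)
  pl <- attr(e0, "planted")
  for (i in seq_len(nrow(pl)))
    expect_equal(abs(cor(e0[, pl$gene[i]], maps[pl$factor[i], ])), 1,
                 tolerance = 1e-10)
  expect_setequal(unique(pl$sign), c(1, -1))
  # no planting: correlations centred at zero
  e1 <- simulate_gene_expression(parc, 200, maps, n_planted = 0,
                                 noise_sd = 0.5, seed = 3)
  expect_lt(abs(mean(cor(e1, maps[1, ]))), 0.1)
  # planted genes occupy the extreme ranks
  e2 <- simulate_gene_expression(parc, 300, maps, n_planted = 40,
                                 noise_sd = 0.5, seed = 4)
  pl2 <- attr(e2, "planted")
  r <- drop(cor(e2, maps[1, ]))
  f1 <- pl2[pl2$factor == 1, ]
  pos <- f1$gene[f1$sign == 1]; neg <- f1$gene[f1$sign == -1]
  expect_gt(mean(rank(-r)[pos] <= 40), 0.9)
  expect_gt(mean(rank(r)[neg] <= 40), 0.9)
  expect_error(simulate_gene_expression(parc, 0, maps, 0), "invalid")
  expect_error(simulate_gene_expression(parc, 10, maps, 20), "invalid")
})

test_that("structural maps are well-formed and distance-decaying", {
  parc <- mini_parc()
  st <- simulate_structural(parc, density = 0.4, seed = 5)
  expect_identical(st$sc, t(st$sc))
  expect_equal(unname(diag(st$sc)), rep(0, nrow(parc)))
  expect_true(all(st$sc >= 0))
  expect_equal(max(st$sc), 1)
  v <- st$sc[lower.tri(st$sc)]
  expect_equal(mean(v > 0), 0.4, tolerance = 0.02)
  # log-weight declines with distance
  D <- parcellation_dist(parc)
  d <- D[lower.tri(D)][v > 0]
  expect_lt(coef(lm(log(v[v > 0]) ~ d))[2], 0)
  # full density keeps every pair connected
  st1 <- simulate_structural(parc, density = 1, seed = 5)
  expect_true(all(st1$sc[lower.tri(st1$sc)] > 0))
  expect_equal(sd(st$myelin), 1, tolerance = 1e-9)
  expect_error(simulate_structural(parc, density = 0), "invalid")
})
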