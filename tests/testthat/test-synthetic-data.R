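test_that("generator is deterministic and validates its configuration", {
  cfg <- tiny_config()
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(simulate_cohort(cfg)$phenotypes,
                   simulate_cohort(cfg)$phenotypes)

  expect_error(sim_cohort_config(maf_range = c(0.4, 0.1)),
               class = "temqtl_invalid_config")
  expect_error(sim_cohort_config(maf_range = c(-0.1, 0.3)),
               class = "temqtl_invalid_config")
  expect_error(sim_cohort_config(fst = 1), class = "temqtl_invalid_config")
  expect_error(sim_cohort_config(noise_sd = 0),
               class = "temqtl_invalid_config")
})

test_that("dosages are hard calls with sane metadata", {
  g <- simulate_genotypes(tiny_config())
  expect_true(all(g$dosage %in% 0:2))
  expect_false(anyDuplicated(g$snps$snp_id) > 0)
  for (ch in unique(g$snps$chr)) {
    expect_false(is.unsorted(g$snps$pos[g$snps$chr == ch]))
  }
  expect_equal(g$snps$maf, pmin(colMeans(g$dosage) / 2,
                                1 - colMeans(g$dosage) / 2),
               ignore_attr = TRUE)
})

test_that("Balding-Nichols differentiation matches a Weir-Cockerham oracle", {
  cfg <- sim_cohort_config(n_individuals = 500, n_snps = 2000,
                           n_subpops = 2, fst = 0.1, ld_block_size = 1,
                           seed = 1L)
  g <- simulate_genotypes(cfg)
  fst_hat <- weir_cockerham_fst(g$dosage, g$subpop)
  expect_gt(mean(fst_hat, na.rm = TRUE), 0.05)
  expect_lt(mean(fst_hat, na.rm = TRUE), 0.15)
})

test_that("fst = 0 collapses subpopulation differences to sampling noise", {
  cfg <- sim_cohort_config(n_individuals = 400, n_snps = 500,
                           n_subpops = 2, fst = 0, ld_block_size = 1,
                           seed = 2L)
  g <- simulate_genotypes(cfg)
  fst_hat <- weir_cockerham_fst(g$dosage, g$subpop)
  # Weir-Cockerham is unbiased around zero under panmixia
  expect_lt(abs(mean(fst_hat, na.rm = TRUE)), 0.01)
})

test_that("LD blocks show r2 decaying with distance and no cross-block LD", {
  cfg <- sim_cohort_config(n_individuals = 600, n_snps = 400,
                           n_subpops = 1, fst = 0, ld_block_size = 10,
                           ld_rho = 0.9, seed = 3L)
  g <- simulate_genotypes(cfg)
  lag1 <- lag3 <- cross <- numeric(0)
  for (b in seq_len(40)) {
    i0 <- (b - 1) * 10 + 1
    lag1 <- c(lag1, cor(g$dosage[, i0], g$dosage[, i0 + 1])^2)
    lag3 <- c(lag3, cor(g$dosage[, i0], g$dosage[, i0 + 3])^2)
    if (b < 40) cross <- c(cross, cor(g$dosage[, i0 + 9],
                                      g$dosage[, i0 + 10])^2)
  }
  expect_gt(mean(lag1), mean(lag3))
  expect_gt(mean(lag1), 0.5)
  expect_lt(mean(cross), 0.05)
})

test_that("planted causal SNPs sit inside their gene's cis window", {
  co <- small_cohort()
  em <- co$truth$eqtl_map
  for (i in seq_len(nrow(em))) {
    gene <- co$genes[co$genes$gene_id == em$gene_id[i], ]
    expect_true(em$snp_id[i] %in% cis_window_snps(gene, co$genotypes))
  }
  spec <- em$beta_rest == 0 | em$beta_stim == 0
  expect_true(all(xor(em$beta_rest[spec] == 0, em$beta_stim[spec] == 0)))
})

test_that("null expression gives uniform association p-values", {
  # 250 null genes x 20 unlinked SNPs each: 5000 near-independent fits
  cfg <- sim_cohort_config(n_individuals = 100, n_snps = 250, n_genes = 250,
                           eqtl_fraction = 0, sig_gene_loading = 1e-3,
                           ld_block_size = 1, seed = 5L)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression_pair(g, cfg)
  cov <- e$covariates[, c("individual_id", "gender", paste0("PC", 1:5))]
  set.seed(11)
  ps <- unlist(lapply(colnames(e$rest), function(gene) {
    snps <- sample(colnames(g$dosage), 20)
    vapply(snps, function(s) {
      fit_snp_association(e$rest[, gene], g$dosage[, s], cov)$analytic_p
    }, numeric(1))
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cfse well simulation respects weights, spacing and edge cases", {
  cfg <- tiny_config()
  expect_error(simulate_cfse_experiment(c(0.5, 0.6), cfg),
               class = "temqtl_invalid_weights")
  expect_error(simulate_cfse_experiment(rep(1 / 7, 7), cfg),
               class = "temqtl_invalid_weights")

  # undivided-only: stimulated well distributionally identical to resting
  ws <- simulate_cfse_experiment(c(1, 0, 0, 0, 0, 0), cfg, n_events = 5000)
  expect_gt(suppressWarnings(
    ks.test(ws$resting[[1]], ws$stimulated[[1]])
  )$p.value, 0.001)

  # mixture mean identity: E[x] = mu0 - DI * spacing
  w <- c(0.5, 0.25, 0.25)
  ws <- simulate_cfse_experiment(w, cfg, n_events = 20000)
  di_true <- sum((0:2) * w)
  x <- ws$stimulated[[1]]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - (cfg$cfse$mu0 - di_true * cfg$cfse$spacing)),
            3 * se)

  # empty well flagged, not an exception
  ws0 <- simulate_cfse_experiment(c(1, 0, 0), cfg, n_events = 0)
  expect_length(ws0$stimulated[[1]], 0)
  expect_true(isTRUE(attr(ws0$stimulated[[1]], "empty")))
})

test_that("flow sample mixing proportions match the multinomial oracle", {
  tm <- default_population_template()
  w <- rep(1 / 7, 7)
  n <- 14000
  fs <- simulate_flow_sample(tm, w, n_events = n, seed = 9L)
  props <- table(factor(fs$labels, levels = tm$labels)) / n
  expect_true(all(abs(props - 1 / 7) < 3 * sqrt((1 / 7) * (6 / 7) / n)))
  fs2 <- simulate_flow_sample(tm, w, n_events = n, seed = 9L)
  expect_identical(fs$events, fs2$events)

  bad <- tm
  bad$covs[[1]] <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(temqtl:::new_population_template(bad$labels, bad$weights,
                                                bad$means, bad$covs),
               class = "temqtl_invalid_template")
})

test_that("cohort phenotype model plants the stated age and gender effects", {
  cfg <- sim_cohort_config(n_individuals = 5000, n_snps = 60, n_genes = 5,
                           seed = 8L)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  fit <- lm(abundance ~ age + I(gender == "male"), data = ph)
  expect_lt(abs(coef(fit)["age"] - 0.11), 0.02)
  expect_lt(abs(coef(fit)[3] - 2.22), 0.5)
  expect_true(all(ph$abundance > 0 & ph$abundance < 100))

  # null truth: with both effects off, coefficients are indistinct from 0
  cfg0 <- sim_cohort_config(n_individuals = 400, n_snps = 60, n_genes = 5,
                            age_slope = 0, gender_diff = 0, seed = 9L)
  tstats <- vapply(1:20, function(i) {
    cfg_i <- cfg0
    cfg_i$seed <- 9L + i
    ph_i <- simulate_cohort(cfg_i)$phenotypes
    f <- summary(lm(abundance ~ age + I(gender == "male"), data = ph_i))
    max(abs(coef(f)[2:3, "t value"]))
  }, numeric(1))
  expect_gte(mean(tstats < 3), 0.9)
})

test_that("cytometry bundle ties flow and CFSE truths to the phenotypes", {
  co <- simulate_cohort(tiny_config(), cytometry = TRUE, n_cytometry = 2,
                        flow_events = 2000, cfse_events = 1000)
  expect_length(co$cytometry, 2)
  cy <- co$cytometry[[1]]
  ph <- co$phenotypes[co$phenotypes$individual_id == cy$individual_id, ]
  w <- cy$cfse$truth$weights
  expect_equal(sum((0:5) * w), ph$di, tolerance = 1e-8)
  expect_identical(colnames(cy$flow$events), c("CD45RA", "CD45RO", "CD62L"))
})
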