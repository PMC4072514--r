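test_that("QC filter applies strict MAF and imputation-quality thresholds", {
  co <- small_cohort()
  g <- co$genotypes
  n_snps <- nrow(g$snps)
  g$snps$maf[1] <- 0.009          # removed
  g$snps$maf[2] <- 0.01           # boundary: retained
  g$snps$impute_r2[3] <- 0.39     # removed
  g$snps$impute_r2[4] <- 0.4      # boundary: retained
  out <- genotype_qc_filter(g)
  expect_false("snp00001" %in% out$snps$snp_id)
  expect_true("snp00002" %in% out$snps$snp_id)
  expect_false("snp00003" %in% out$snps$snp_id)
  expect_true("snp00004" %in% out$snps$snp_id)
  expect_identical(ncol(out$dosage), ncol(g$dosage) - 2L)
  expect_equal(sum(attr(out, "qc_log")$removed), 2)

  g$snps$maf <- rep(0.001, n_snps)
  expect_error(genotype_qc_filter(g), class = "temqtl_empty_panel")
})

test_that("genotype PCs separate planted structure and behave on null panels", {
  cfg <- sim_cohort_config(n_individuals = 200, n_snps = 500,
                           n_subpops = 2, fst = 0.1, ld_block_size = 1,
                           seed = 11L)
  g <- simulate_genotypes(cfg)
  pcs <- compute_genotype_pcs(g)
  lab <- as.numeric(g$subpop == 1)
  expect_gt(abs(cor(pcs$scores$PC1, lab)), 0.9)
  expect_length(pcs$var_frac, min(dim(g$dosage)))

  # no structure: top-5 variance fractions near the Marchenko-Pastur bulk
  cfg0 <- sim_cohort_config(n_individuals = 200, n_snps = 500,
                            n_subpops = 1, fst = 0, ld_block_size = 1,
                            seed = 12L)
  p0 <- compute_genotype_pcs(simulate_genotypes(cfg0))
  expect_true(all(p0$var_frac[1:5] < 3 / 200 + 0.02))

  # duplicated individual -> identical PC rows
  g2 <- g
  g2$dosage <- rbind(g$dosage, dup = g$dosage[1, ])
  rownames(g2$dosage)[201] <- "dup"
  p2 <- compute_genotype_pcs(g2)
  expect_equal(unlist(p2$scores[1, -1]), unlist(p2$scores[201, -1]),
               tolerance = 1e-10, ignore_attr = TRUE)

  # monomorphic SNPs are dropped with a warning
  g3 <- g
  g3$dosage[, 1] <- 0
  expect_warning(compute_genotype_pcs(g3), "monomorphic")
})

test_that("cis windows are inclusive, symmetric and position-ordered", {
  offsets <- c(-300000, -250001, -250000, -100000, -1, 0, 1, 125000,
               250000, 250001)
  tss <- 400000
  panel <- handmade_panel(
    matrix(rep(c(0, 1, 2), length.out = 30 * 10), 30, 10),
    positions = tss + offsets
  )
  gene <- list(gene_id = "g", chr = "1", tss = tss)
  hits <- cis_window_snps(gene, panel)
  expect_identical(hits, sprintf("snp%02d", 3:9))  # 7 inside, in order
  # empty window is a plain empty vector
  gene2 <- list(gene_id = "g2", chr = "2", tss = tss)
  expect_length(cis_window_snps(gene2, panel), 0)
})

test_that("association fit equals lm and the Frisch-Waugh oracle", {
  set.seed(21)
  n <- 12
  dos <- rbinom(n, 2, 0.4)
  cov <- tibble::tibble(gender = sample(c("male", "female"), n, TRUE),
                        PC1 = rnorm(n))
  y <- 0.5 * dos + 0.3 * rnorm(n)
  f <- fit_snp_association(y, dos, cov)
  ml <- summary(lm(y ~ dos + I(cov$gender == "male") + cov$PC1))
  expect_equal(f$beta, coef(ml)["dos", "Estimate"], tolerance = 1e-12)
  expect_equal(f$se, coef(ml)["dos", "Std. Error"], tolerance = 1e-12)
  expect_equal(f$analytic_p, coef(ml)["dos", "Pr(>|t|)"], tolerance = 1e-12)

  # Frisch-Waugh: residualize y and dosage on covariates, slope matches
  X0 <- cbind(1, as.numeric(cov$gender == "male"), cov$PC1)
  ry <- resid(lm.fit(X0, y)); rg <- resid(lm.fit(X0, dos))
  expect_equal(f$beta, sum(ry * rg) / sum(rg^2), tolerance = 1e-8)

  # expression exactly equal to dosage: beta 1, p ~ 0
  fe <- fit_snp_association(as.numeric(dos), dos, cov)
  expect_equal(fe$beta, 1, tolerance = 1e-10)
  expect_lt(fe$analytic_p, 1e-12)

  expect_error(fit_snp_association(y, rep(1, n), cov),
               class = "temqtl_monomorphic_snp")
  cov_bad <- dplyr::mutate(cov, PC2 = PC1)
  err <- tryCatch(fit_snp_association(y, dos, cov_bad), error = identity)
  expect_s3_class(err, "temqtl_rank_deficient")
  expect_match(conditionMessage(err), "PC2")
  expect_error(fit_snp_association(y[1:5], dos[1:5], cov[1:5, ]),
               class = "temqtl_insufficient_data")
})

test_that("permutation scan recovers a planted eQTL and floors empirical p", {
  cfg <- sim_cohort_config(n_individuals = 150, n_snps = 200, n_genes = 10,
                           eqtl_fraction = 0.5, effect_sd = 1.2, seed = 13L)
  co <- simulate_cohort(cfg)
  em <- co$truth$eqtl_map
  gid <- em$gene_id[which.max(abs(em$beta_rest))]
  gene <- co$genes[co$genes$gene_id == gid, ]
  cov <- eqtl_covariates(co)
  sc <- scan_gene_cis(gene, co$genotypes, co$rest, cov, n_perm = 1000,
                      seed = 3L, state = "rest")
  truth_snp <- em$snp_id[em$gene_id == gid]
  lead <- attr(sc, "lead_snp")
  r2 <- ld_r2(co$genotypes$dosage[, lead], co$genotypes$dosage[, truth_snp])
  expect_true(lead == truth_snp || r2 > 0.8)
  # add-one floor: nothing beats a strong observed association
  expect_equal(min(sc$empirical_p), 1 / 1001)
  expect_equal(attr(sc, "gene_perm_p"), 1 / 1001)
  expect_true(all(sc$empirical_p >= 1 / 1001))
  expect_equal(sc$fold, exp(sc$beta))

  # determinism across invocation order: same gene stream from the master seed
  sc2 <- scan_gene_cis(gene, co$genotypes, co$rest, cov, n_perm = 1000,
                       seed = 3L, state = "rest")
  expect_identical(sc$empirical_p, sc2$empirical_p)

  expect_error(scan_gene_cis(gene, co$genotypes, co$rest, cov, n_perm = 50),
               class = "temqtl_invalid_config")
})

test_that("residual-permutation scan tracks the exact full-model permutation", {
  co <- small_cohort()
  gene <- co$genes[1, ]
  cov <- eqtl_covariates(co)
  fast <- scan_gene_cis(gene, co$genotypes, co$rest, cov, n_perm = 400,
                        seed = 5L)
  exact <- scan_gene_cis(gene, co$genotypes, co$rest, cov, n_perm = 400,
                         seed = 5L, permute = "exact")
  expect_equal(fast$empirical_p, exact$empirical_p, tolerance = 0.08)
  expect_identical(fast$beta, exact$beta)
})

test_that("BH selection matches the hand-computed adjustment", {
  leads <- tibble::tibble(gene_id = c("a", "b", "c"), state = "rest",
                          gene_perm_p = c(0.0001, 0.002, 0.9))
  out <- fdr_select(leads)
  expect_equal(out$fdr_q, c(0.0003, 0.003, 0.9))
  expect_identical(out$significant, c(TRUE, TRUE, FALSE))
  all1 <- fdr_select(tibble::tibble(gene_id = letters[1:4], state = "rest",
                                    gene_perm_p = rep(1, 4)))
  expect_false(any(all1$significant))
})

test_that("conditioning on a perfect proxy of the causal SNP removes signal", {
  cfg <- sim_cohort_config(n_individuals = 150, n_snps = 100, n_genes = 6,
                           eqtl_fraction = 0.5, effect_sd = 1.5, seed = 17L)
  co <- simulate_cohort(cfg)
  em <- co$truth$eqtl_map
  gid <- em$gene_id[which.max(abs(em$beta_rest))]
  gene <- co$genes[co$genes$gene_id == gid, ]
  truth_snp <- em$snp_id[em$gene_id == gid]
  cov <- eqtl_covariates(co)

  # duplicate the causal SNP into the panel: r2 = 1 proxy
  g2 <- co$genotypes
  g2$dosage <- cbind(g2$dosage, dup99999 = g2$dosage[, truth_snp])
  g2$snps <- dplyr::bind_rows(
    g2$snps,
    dplyr::mutate(g2$snps[g2$snps$snp_id == truth_snp, ],
                  snp_id = "dup99999")
  )
  cr <- conditional_scan(gene, "dup99999", g2, co$rest, cov, n_perm = 500,
                         seed = 7L)
  expect_true(cr$fully_explained)
  expect_false("dup99999" %in% cr$results$snp_id)

  expect_error(conditional_scan(gene, "absent", co$genotypes, co$rest, cov),
               class = "temqtl_missing_snp")
  cov_dup <- dplyr::mutate(cov, cond = g2$dosage[, "dup99999"])
  expect_error(conditional_scan(gene, "dup99999", g2, co$rest, cov_dup,
                                n_perm = 200),
               class = "temqtl_rank_deficient")
})

test_that("cross-state z-test reproduces the printed BLK comparison", {
  # printed effect estimates: rest -0.366 (0.085), stim -0.805 (0.071)
  res <- state_difference_test(-0.366, 0.085, -0.805, 0.071)
  expect_lt(abs(res$p_delta - 7.38e-5) / 7.38e-5, 0.02)
  expect_lt(res$z, 0)

  eq <- state_difference_test(0.5, 0.1, 0.5, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_delta, 1)
  expect_error(state_difference_test(0, 0, 1, 0.1),
               class = "temqtl_invalid_se")
})

test_that("fold-change convention is exp(beta) on the natural-log scale", {
  expect_equal(round(beta_to_fold(-0.805), 2), 0.45)
  expect_equal(beta_to_fold(0), 1)
  expect_equal(round(beta_to_fold(1.112), 2), 3.04)
  f <- c(0.45, 1, 2.5)
  expect_equal(beta_to_fold(log(f)), f, tolerance = 1e-12)
})

test_that("LD r2 is allele-flip invariant and matches hand arithmetic", {
  a <- c(0, 0, 1, 1, 2, 2)
  b <- c(0, 1, 0, 1, 2, 2)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, 2 - a), 1)
  # hand Pearson: cov = 3/5, var_a = var_b = 4/5, r = 3/4
  expect_equal(ld_r2(a, b), 0.5625)
  expect_error(ld_r2(a, rep(2, 6)), class = "temqtl_monomorphic_snp")
})

test_that("disease-locus definition follows LD span, hotspots and gene pad", {
  # block of 5 SNPs: perfect proxies at +/-40 kb, unlinked beyond
  set.seed(31)
  base <- rbinom(200, 2, 0.5)
  other <- rbinom(200, 2, 0.5)
  third <- rbinom(200, 2, 0.5)
  dos <- cbind(other, base, base, base, third)
  panel <- handmade_panel(dos, positions = c(100000, 160000, 200000,
                                             240000, 300000))
  hotspots <- tibble::tibble(chr = "1", pos = c(140000, 260000))
  loc <- define_disease_locus("snp03", panel, hotspots)
  expect_equal(loc$start, 140000)
  expect_equal(loc$end, 260000)

  # no LD partners: interval is the hotspot-bounded window around the SNP
  loc2 <- define_disease_locus("snp01", panel, hotspots)
  expect_equal(loc2$start, 1)
  expect_equal(loc2$end, 140000)

  # gene-free interval: extended 250 kb each side (clamped at chr start)
  genes <- tibble::tibble(gene_id = "g", chr = "1", tss = 9e6)
  loc3 <- define_disease_locus("snp03", panel, hotspots, genes = genes)
  expect_equal(loc3$start, 1)
  expect_equal(loc3$end, 260000 + 250000)

  expect_error(define_disease_locus("nope", panel, hotspots),
               class = "temqtl_missing_snp")
})
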