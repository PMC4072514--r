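# a cohort with a planted proliferation-potential signature
sig_cohort <- function(seed = 51L, n = 182) {
  simulate_cohort(sim_cohort_config(n_individuals = n, n_snps = 60,
                                    n_genes = 60, eqtl_fraction = 0,
                                    seed = seed))
}

test_that("per-gene correlations: trivial cases and constant-gene handling", {
  co <- sig_cohort()
  pi_vec <- co$phenotypes$pi
  expr <- co$rest
  expr[, 1] <- pi_vec  # gene identical to the proliferation vector
  corr <- correlate_genes(expr, pi_vec, n_perm = 200, seed = 1L)
  expect_equal(corr$r[1], 1)
  expect_equal(corr$permutation_p[1], 1 / 201)

  expr[, 2] <- 3.14
  expect_warning(c2 <- correlate_genes(expr, pi_vec, n_perm = 200),
                 "constant")
  expect_false(colnames(expr)[2] %in% c2$gene_id)

  expect_error(correlate_genes(expr[1:10, ], pi_vec[1:10]),
               class = "temqtl_insufficient_data")
})

test_that("signature selection keeps sub-threshold genes with signed weights", {
  co <- sig_cohort()
  corr <- correlate_genes(co$rest, co$phenotypes$pi, n_perm = 1000,
                          seed = 2L)
  model <- build_signature(corr, threshold = 0.01)
  expect_true(all(model$weight == sign(model$r)))
  expect_true(all(model$weight %in% c(-1, 1)))
  # planted truth: most signature genes recovered, signs match
  truth <- co$truth$signature_genes
  hit <- dplyr::inner_join(model, truth, by = "gene_id")
  expect_gt(nrow(hit) / nrow(truth), 0.8)
  expect_true(all(hit$weight == hit$sign))

  # boundary thresholds
  expect_identical(nrow(build_signature(corr, threshold = 1)), nrow(corr))
  none <- build_signature(corr, threshold = 1e-9)
  expect_true(attr(none, "empty"))
  expect_error(score_individuals(none, co$rest),
               class = "temqtl_empty_signature")
})

test_that("scores are standardized weighted sums with exact symmetries", {
  co <- sig_cohort()
  corr <- correlate_genes(co$rest, co$phenotypes$pi, n_perm = 500, seed = 3L)
  model <- build_signature(corr)
  sc <- score_individuals(model, co$rest, co$phenotypes$pi)
  expect_gt(attr(sc, "r"), 0.4)

  # single gene, weight +1: score equals that gene's z-scores
  m1 <- model[1, ]
  m1$weight <- 1
  s1 <- score_individuals(m1, co$rest)
  expect_equal(s1$score, as.numeric(scale(co$rest[, m1$gene_id])),
               tolerance = 1e-12)

  # weight flip negates scores exactly; gene order is irrelevant
  mflip <- model; mflip$weight <- -model$weight
  expect_equal(score_individuals(mflip, co$rest)$score, -sc$score,
               tolerance = 1e-12)
  mshuf <- model[rev(seq_len(nrow(model))), ]
  expect_equal(score_individuals(mshuf, co$rest)$score, sc$score,
               tolerance = 1e-12)

  expect_error(score_individuals(dplyr::mutate(model, gene_id = "nope"),
                                 co$rest),
               class = "temqtl_missing_gene")
})

test_that("null significant-gene count follows Binomial(n_genes, threshold)", {
  # independent null genes: the count distribution has a brute-force oracle
  set.seed(52)
  n <- 182; G <- 215
  expr <- matrix(rnorm(n * G), n, G,
                 dimnames = list(NULL, sprintf("g%03d", 1:G)))
  pi_vec <- rnorm(n)
  ngc <- null_gene_count(expr, pi_vec, n_perm = 1000, seed = 4L)
  expect_equal(ngc$median, 2)
  # total-variation distance to Binomial(215, 0.01) below 0.05
  emp <- tabulate(ngc$counts + 1, nbins = 30) / length(ngc$counts)
  theo <- dbinom(0:29, G, 0.01)
  expect_lt(0.5 * sum(abs(emp - theo)), 0.05)

  # add-one floor when the observed count tops every permutation
  ngc2 <- null_gene_count(expr, pi_vec, n_perm = 500, seed = 5L,
                          observed_count = G)
  expect_equal(ngc2$p, 1 / 501)
  # threshold 1 counts every gene in every permutation
  ngc3 <- null_gene_count(expr[, 1:20], pi_vec, n_perm = 100,
                          threshold = 1, seed = 6L)
  expect_true(all(ngc3$counts == 20))
})

test_that("split-half validation detects the planted signature, not null data", {
  co <- sig_cohort()
  sh <- split_half_validate(co$rest, co$phenotypes$pi, seed = 7L,
                            n_perm = 300, n_perm_test = 300)
  expect_identical(nrow(sh), 2L)
  expect_true(all(sh$informative))
  expect_true(all(sh$r > 0))
  expect_true(all(sh$p < 0.05))
  sh2 <- split_half_validate(co$rest, co$phenotypes$pi, seed = 7L,
                             n_perm = 300, n_perm_test = 300)
  expect_identical(sh, sh2)  # deterministic under a fixed seed

  # training on the same data overestimates r relative to held-out halves
  corr <- correlate_genes(co$rest, co$phenotypes$pi, n_perm = 300, seed = 8L)
  full <- score_individuals(build_signature(corr), co$rest,
                            co$phenotypes$pi)
  expect_gt(attr(full, "r"), mean(sh$r))

  expect_error(split_half_validate(co$rest[1:30, ], co$phenotypes$pi[1:30]),
               class = "temqtl_insufficient_data")
})

test_that("cross-visit replication works both ways and validates overlap", {
  co <- sig_cohort()
  ids <- co$phenotypes$individual_id
  # second visit: same truth, fresh noise on expression and proliferation
  set.seed(53)
  expr2 <- co$rest + matrix(rnorm(length(co$rest), 0, 0.4),
                            nrow(co$rest))
  pi2 <- co$phenotypes$pi +
    rnorm(nrow(co$rest), 0, 0.5 * sd(co$phenotypes$pi))
  v1 <- list(expression = co$rest,
             proliferation = setNames(co$phenotypes$pi, ids))
  v2 <- list(expression = expr2, proliferation = setNames(pi2, ids))
  cv <- cross_visit_replicate(v1, v2, n_perm = 300, seed = 9L)
  expect_identical(nrow(cv), 2L)
  expect_true(all(cv$r > 0))
  expect_true(all(cv$p < 0.05))

  # identical visits: forward r equals the training r
  cvid <- cross_visit_replicate(v1, v1, n_perm = 200, seed = 10L)
  corr <- correlate_genes(co$rest, co$phenotypes$pi, n_perm = 200,
                          seed = temqtl:::derive_seed(10L, "fwd"))
  tr <- score_individuals(build_signature(corr), co$rest, co$phenotypes$pi)
  expect_equal(cvid$r[1], attr(tr, "r"), tolerance = 1e-10)

  v3 <- list(expression = expr2[1:5, , drop = FALSE],
             proliferation = pi2[1:5])
  rownames(v3$expression) <- paste0("x", 1:5)
  names(v3$proliferation) <- paste0("x", 1:5)
  expect_error(cross_visit_replicate(v1, v3),
               class = "temqtl_insufficient_data")
})
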