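# Shared fixture builders. Everything is generated in code under fixed seeds.

tiny_config <- function(...) {
  sim_cohort_config(n_individuals = 60, n_snps = 120, n_genes = 10,
                    seed = 42L, ...)
}

small_cohort <- function(...) {
  simulate_cohort(tiny_config(...))
}

# covariate table in the layout the eQTL model expects: 5 PCs + gender
eqtl_covariates <- function(cohort) {
  cohort$covariates[, c("individual_id", "gender",
                        paste0("PC", 1:5))]
}

# a one-gene panel with hand-placed SNPs for window/LD arithmetic
handmade_panel <- function(dosages, positions, chr = "1") {
  n <- nrow(dosages)
  ids <- sprintf("snp%02d", seq_len(ncol(dosages)))
  dimnames(dosages) <- list(sprintf("ind%02d", seq_len(n)), ids)
  af <- colMeans(dosages) / 2
  temqtl:::new_geno_matrix(
    dosages,
    tibble::tibble(snp_id = ids, chr = chr, pos = as.integer(positions),
                   ref = "A", alt = "G", maf = pmin(af, 1 - af),
                   impute_r2 = NA_real_)
  )
}

# Weir-Cockerham per-SNP Fst estimate for two-or-more equal-size
# subpopulations; independent oracle for the Balding-Nichols generator.
weir_cockerham_fst <- function(dosage, subpop) {
  pops <- split(seq_len(nrow(dosage)), subpop)
  r <- length(pops)
  n_i <- vapply(pops, length, numeric(1))
  n_bar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  apply(dosage, 2, function(g) {
    p_i <- vapply(pops, function(idx) mean(g[idx]) / 2, numeric(1))
    h_i <- vapply(pops, function(idx) mean(g[idx] == 1), numeric(1))
    p_bar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / sum(n_i)
    a <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                               h_bar / 4) / (n_bar - 1))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    if (a + b + cc == 0) return(NA_real_)
    a / (a + b + cc)
  })
}
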