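#' Simulate paired resting/stimulated expression with planted cis-eQTLs
#'
#' Generates natural-log-scale expression for the same individuals in two
#' cell states. A fraction `eqtl_fraction` of genes receives a causal SNP
#' within 250 kb of its transcription start site and a per-allele effect
#' `beta` on the log scale; a fraction `state_specific_fraction` of those
#' effects is active in exactly one state (the other state's beta is zero).
#' Each gene's value is
#' `mu_g + beta_state * dosage + gamma_gender * male + sum(gamma_k * PC_k) + eps`,
#' with `eps ~ N(0, noise_sd^2)`. Genes selected as the planted proliferation
#' signature additionally load on a shared per-individual factor (resting
#' state only) so that baseline expression predicts proliferative response.
#'
#' @param genotypes A `geno_matrix` for the cohort.
#' @param config The [sim_cohort_config()] used to generate `genotypes`.
#' @return A list of class `sim_expression`: `rest` and `stim` (individuals x
#'   genes matrices), `genes` (annotation tibble: `gene_id`, `chr`, `tss`,
#'   `strand`), `covariates` (tibble: `individual_id`, `age`, `gender`,
#'   `PC1..PC5`), and `truth` (list with `eqtl_map`, `signature_genes`,
#'   `prolif_factor`).
#' @export
simulate_expression_pair <- function(genotypes, config) {
  validate_sim_config(config)
  n <- nrow(genotypes$dosage)
  if (n != config$n_individuals) {
    abort("genotype individuals do not match `config$n_individuals`.",
          class = "temqtl_invalid_config")
  }
  G <- config$n_genes
  ids <- rownames(genotypes$dosage)
  snps <- genotypes$snps

  covariates <- simulate_covariates(ids, config)
  n_pcs <- min(5L, n - 1L)
  pcs <- compute_genotype_pcs(genotypes, k = n_pcs)
  covariates <- dplyr::left_join(covariates, pcs$scores, by = "individual_id")

  with_seed(derive_seed(config$seed, "expression"), {
    # gene annotation: TSS dropped near a random SNP so cis windows are populated
    anchor <- sample.int(nrow(snps), G, replace = TRUE)
    genes <- tibble(
      gene_id = sprintf("gene%03d", seq_len(G)),
      chr = snps$chr[anchor],
      tss = pmax(1L, snps$pos[anchor] +
                   as.integer(round(runif(G, -5e4, 5e4)))),
      strand = sample(c("+", "-"), G, replace = TRUE)
    )

    n_eqtl <- round(config$eqtl_fraction * G)
    eqtl_genes <- sort(sample.int(G, n_eqtl))
    n_spec <- round(config$state_specific_fraction * n_eqtl)
    spec_flags <- c(rep(TRUE, n_spec), rep(FALSE, n_eqtl - n_spec))
    spec_flags <- sample(spec_flags)

    eqtl_map <- vector("list", n_eqtl)
    for (i in seq_along(eqtl_genes)) {
      gi <- eqtl_genes[i]
      cis <- cis_window_snps(genes[gi, ], genotypes)
      cis_var <- apply(genotypes$dosage[, cis, drop = FALSE], 2, var)
      cis <- cis[cis_var > 0]
      if (length(cis) == 0) {
        abort(sprintf("no polymorphic SNP within the cis window of %s",
                      genes$gene_id[gi]),
              class = "temqtl_generation_error")
      }
      beta <- rnorm(1, 0, config$effect_sd)
      if (spec_flags[i]) {
        stim_only <- runif(1) < 0.5
        b_rest <- if (stim_only) 0 else beta
        b_stim <- if (stim_only) beta else 0
      } else {
        b_rest <- beta
        b_stim <- beta
      }
      eqtl_map[[i]] <- tibble(gene_id = genes$gene_id[gi],
                              snp_id = sample(cis, 1),
                              beta_rest = b_rest, beta_stim = b_stim)
    }
    eqtl_map <- if (n_eqtl > 0) dplyr::bind_rows(eqtl_map) else
      tibble(gene_id = character(), snp_id = character(),
             beta_rest = numeric(), beta_stim = numeric())

    n_sig <- min(config$n_signature_genes, G)
    signature_idx <- sample.int(G, n_sig)
    sig_sign <- rep(-1, n_sig)
    if (n_sig > 0) sig_sign[seq_len(min(config$n_signature_pos, n_sig))] <- 1
    prolif_factor <- rnorm(n)

    male <- as.numeric(covariates$gender == "male")
    pc_mat <- as.matrix(covariates[paste0("PC", seq_len(n_pcs))])
    gamma_gender <- rnorm(G, 0, 0.1)
    gamma_pc <- matrix(rnorm(G * n_pcs, 0, 0.1), G, n_pcs)
    mu_g <- rnorm(G, 5, 1)

    make_state <- function(state) {
      base <- matrix(rep(mu_g, each = n), n, G) +
        outer(male, gamma_gender) + pc_mat %*% t(gamma_pc)
      y <- base + matrix(rnorm(n * G, 0, config$noise_sd), n, G)
      b <- if (state == "rest") eqtl_map$beta_rest else eqtl_map$beta_stim
      if (nrow(eqtl_map) > 0) {
        for (i in seq_len(nrow(eqtl_map))) {
          gi <- match(eqtl_map$gene_id[i], genes$gene_id)
          y[, gi] <- y[, gi] + b[i] * genotypes$dosage[, eqtl_map$snp_id[i]]
        }
      }
      if (state == "rest" && n_sig > 0) {
        lambda <- config$sig_gene_loading
        for (j in seq_len(n_sig)) {
          gi <- signature_idx[j]
          y[, gi] <- y[, gi] + sig_sign[j] * config$noise_sd *
            (lambda / sqrt(1 - lambda^2)) * prolif_factor
        }
      }
      dimnames(y) <- list(ids, genes$gene_id)
      y
    }
    rest <- make_state("rest")
    stim <- make_state("stim")
  })

  truth <- list(
    eqtl_map = eqtl_map,
    signature_genes = tibble(gene_id = genes$gene_id[signature_idx],
                             sign = sig_sign),
    prolif_factor = setNames(prolif_factor, ids)
  )
  structure(list(rest = rest, stim = stim, genes = genes,
                 covariates = covariates, truth = truth),
            class = "sim_expression")
}

# Ages uniform on 19-57 and gender Bernoulli(134/225 female), mirroring the
# cohort the generator emulates.
simulate_covariates <- function(ids, config) {
  with_seed(derive_seed(config$seed, "covariates"), {
    tibble(
      individual_id = ids,
      age = runif(length(ids), 19, 57),
      gender = ifelse(runif(length(ids)) < 134 / 225, "female", "male")
    )
  })
}
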