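#' Simulate a complete synthetic cohort
#'
#' Orchestrates the full generator: structured genotypes, paired
#' resting/stimulated expression with planted cis-eQTLs, covariates,
#' phenotypes and (optionally) per-individual cytometry event data, all
#' keyed by a shared individual identifier and accompanied by a ground-truth
#' bundle for parameter-recovery testing.
#'
#' Phenotype model: TEM abundance (%) is
#' `abundance_mean + age_slope * (age - mean(age)) + gender_diff * male + noise`,
#' truncated to (0, 100), with the noise SD chosen so the marginal SD matches
#' `abundance_sd`. The division index is built from the signed combination of
#' the planted signature genes' baseline (resting) expression plus a negative
#' abundance term plus noise, rescaled to `di_mean`/`di_sd`; the
#' proliferation index correlates with DI at `pi_di_r` and is rescaled to
#' `pi_mean`/`pi_sd`.
#'
#' @param config A [sim_cohort_config()].
#' @param cytometry If `TRUE`, also simulate per-individual flow samples and
#'   CFSE well sets (division weights `Binomial(5, DI/5)` so the planted DI
#'   is the mixture mean; flow TEM share equal to the individual's planted
#'   abundance).
#' @param n_cytometry Number of individuals to simulate cytometry for.
#' @param flow_events,cfse_events Events per flow sample / CFSE well.
#' @return A `sim_cohort` list: `genotypes`, `rest`, `stim`, `genes`,
#'   `covariates`, `phenotypes`, `truth`, and optionally `cytometry`.
#' @examples
#' cohort <- simulate_cohort(sim_cohort_config(n_individuals = 30,
#'                                             n_snps = 100, n_genes = 20))
#' head(cohort$phenotypes)
#' @export
simulate_cohort <- function(config, cytometry = FALSE,
                            n_cytometry = config$n_individuals,
                            flow_events = 5000, cfse_events = 5000) {
  validate_sim_config(config)
  geno <- simulate_genotypes(config)
  expr <- simulate_expression_pair(geno, config)
  n <- config$n_individuals
  ids <- rownames(geno$dosage)
  cov <- expr$covariates
  male <- as.numeric(cov$gender == "male")

  with_seed(derive_seed(config$seed, "phenotypes"), {
    explained <- config$age_slope^2 * var(cov$age) +
      config$gender_diff^2 * var(male)
    noise_sd <- sqrt(max(config$abundance_sd^2 - explained, 1))
    abundance <- config$abundance_mean +
      config$age_slope * (cov$age - mean(cov$age)) +
      config$gender_diff * male +
      rnorm(n, 0, noise_sd)
    abundance <- pmin(pmax(abundance, 1e-3), 100 - 1e-3)

    sig <- expr$truth$signature_genes
    L <- as.numeric(
      scale(expr$rest[, sig$gene_id, drop = FALSE]) %*% sig$sign
    )
    r_sig <- config$sig_di_r
    r_ab <- config$abundance_di_r
    resid_var <- max(1 - r_sig^2 - r_ab^2, 0.05)
    e1 <- rnorm(n)
    di_std <- r_sig * as.numeric(scale(L)) +
      r_ab * as.numeric(scale(abundance)) +
      sqrt(resid_var) * e1
    di <- pmax(config$di_mean + config$di_sd * di_std, 0)
    # PI loads on the same proliferation-potential factor as DI (both are
    # read-outs of one dilution experiment); the residual coupling through
    # e1 sets the DI-PI correlation to pi_di_r
    c1 <- max(config$pi_di_r - r_sig^2, 0) / sqrt(resid_var)
    c2 <- sqrt(max(1 - r_sig^2 - c1^2, 0.05))
    pi_std <- r_sig * as.numeric(scale(L)) + c1 * e1 + c2 * rnorm(n)
    pi <- pmax(config$pi_mean + config$pi_sd * pi_std, 1)
  })

  phenotypes <- tibble(
    individual_id = ids, age = cov$age, gender = cov$gender,
    abundance = abundance, di = di, pi = pi
  )
  truth <- c(expr$truth, list(
    subpop_labels = geno$subpop,
    phenotypes = phenotypes
  ))
  out <- list(genotypes = geno, rest = expr$rest, stim = expr$stim,
              genes = expr$genes, covariates = cov,
              phenotypes = phenotypes, truth = truth)

  if (cytometry) {
    idx <- seq_len(min(n_cytometry, n))
    out$cytometry <- lapply(idx, function(i) {
      tem_share <- abundance[i] / 100
      tmpl <- default_population_template(tem_weight = tem_share)
      flow <- simulate_flow_sample(
        tmpl, n_events = flow_events,
        seed = derive_seed(config$seed, paste0("flow", ids[i]))
      )
      w <- stats::dbinom(0:5, 5, min(di[i] / 5, 1))
      w <- w / sum(w)
      cfse <- simulate_cfse_experiment(
        w, config, n_events = cfse_events,
        seed = derive_seed(config$seed, paste0("cfse", ids[i]))
      )
      list(individual_id = ids[i], flow = flow, cfse = cfse)
    })
    names(out$cytometry) <- ids[idx]
  }
  structure(out, class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d individuals, %d SNPs, %d genes (%d planted eQTLs)\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              ncol(x$rest), nrow(x$truth$eqtl_map)))
  invisible(x)
}
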