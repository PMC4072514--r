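#' Configuration for a synthetic TEM-cell cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults reproduce
#' the phenotype structure of the study cohort the package is designed for:
#' CD4+ effector-memory T-cell (TEM) relative abundance with mean 9.57% and
#' SD 4.85%, increasing by 0.11 percentage points per year of age, with men
#' carrying on average 2.22 percentage points more than women; a division
#' index (DI) of mean 1.46, SD 0.35 and proliferation index (PI) of mean
#' 2.16, SD 0.21; 215 assayed genes; and a 17-gene proliferation-potential
#' signature in which 15 genes track reduced and 2 genes increased
#' proliferation.
#'
#' @param n_individuals Cohort size. Default 174, the number of subjects with
#'   complete genotype, expression, abundance and proliferation data.
#' @param n_snps Number of genotyped SNPs (desk-scale stand-in for a
#'   genome-wide panel).
#' @param n_genes Number of assayed genes.
#' @param maf_range Range of ancestral minor-allele frequencies, in (0, 0.5).
#' @param n_subpops Number of Balding-Nichols subpopulations.
#' @param fst Fixation index driving subpopulation differentiation, in [0, 1).
#' @param ld_block_size SNPs per linkage-disequilibrium block.
#' @param ld_rho First-order haplotype copying probability between adjacent
#'   SNPs in a block; pairwise r-squared decays roughly as `ld_rho^(2*lag)`.
#' @param snp_spacing Base pairs between adjacent SNPs.
#' @param eqtl_fraction Fraction of genes given a planted cis-eQTL
#'   (default 46/205, the observed fraction among disease-locus genes).
#' @param state_specific_fraction Fraction of planted eQTLs active in exactly
#'   one cell state (default 11/46, the stimulation-specific fraction).
#' @param effect_sd SD of planted natural-log effect sizes per allele.
#' @param noise_sd Residual expression SD on the natural-log scale.
#' @param age_slope Abundance increase per year of age (percentage points).
#' @param gender_diff Male minus female abundance difference (percentage points).
#' @param abundance_mean,abundance_sd Marginal TEM abundance distribution (%).
#' @param di_mean,di_sd Marginal division-index distribution.
#' @param pi_mean,pi_sd Marginal proliferation-index distribution.
#' @param n_signature_genes,n_signature_pos Size of the planted proliferation
#'   signature and how many of its genes correlate positively with PI.
#' @param sig_gene_loading Loading of each signature gene on the shared
#'   proliferation-potential factor (gives per-gene |r| of about
#'   `sig_gene_loading * sig_di_r` with DI).
#' @param sig_di_r Correlation between the shared factor and DI.
#' @param abundance_di_r Partial correlation of abundance with DI (negative:
#'   more abundant TEM compartments proliferate less on restimulation).
#' @param pi_di_r Correlation between PI and DI.
#' @param cfse CFSE dye-dilution parameters: list with `mu0` (undivided-peak
#'   log10 intensity), `spacing` (log10 peak-to-peak distance; log10(2)
#'   because CFSE halves each division), `sigma` (common peak SD, log10
#'   units) and `n_events` (events per well).
#' @param seed Master seed; every stream the generator uses derives from it.
#'
#' @return A validated list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_individuals = 174,
                              n_snps = 1000,
                              n_genes = 215,
                              maf_range = c(0.05, 0.5),
                              n_subpops = 2,
                              fst = 0.01,
                              ld_block_size = 10,
                              ld_rho = 0.9,
                              snp_spacing = 5000,
                              eqtl_fraction = 46 / 205,
                              state_specific_fraction = 11 / 46,
                              effect_sd = 0.5,
                              noise_sd = 0.5,
                              age_slope = 0.11,
                              gender_diff = 2.22,
                              abundance_mean = 9.57,
                              abundance_sd = 4.85,
                              di_mean = 1.46,
                              di_sd = 0.35,
                              pi_mean = 2.16,
                              pi_sd = 0.21,
                              n_signature_genes = 17,
                              n_signature_pos = 2,
                              sig_gene_loading = 0.6,
                              sig_di_r = 0.6,
                              abundance_di_r = -0.25,
                              pi_di_r = 0.7,
                              cfse = list(mu0 = 2.5, spacing = log10(2),
                                          sigma = 0.08, n_events = 10000),
                              seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), maf_range = as.numeric(maf_range),
    n_subpops = as.integer(n_subpops), fst = fst,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    snp_spacing = as.integer(snp_spacing),
    eqtl_fraction = eqtl_fraction,
    state_specific_fraction = state_specific_fraction,
    effect_sd = effect_sd, noise_sd = noise_sd,
    age_slope = age_slope, gender_diff = gender_diff,
    abundance_mean = abundance_mean, abundance_sd = abundance_sd,
    di_mean = di_mean, di_sd = di_sd, pi_mean = pi_mean, pi_sd = pi_sd,
    n_signature_genes = as.integer(n_signature_genes),
    n_signature_pos = as.integer(n_signature_pos),
    sig_gene_loading = sig_gene_loading, sig_di_r = sig_di_r,
    abundance_di_r = abundance_di_r, pi_di_r = pi_di_r,
    cfse = cfse, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_cohort_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$n_snps >= 1, cfg$n_genes >= 0,
            cfg$n_subpops >= 1, cfg$ld_block_size >= 1)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] >= cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    abort("`maf_range` must be an ordered pair inside (0, 0.5].",
          class = "temqtl_invalid_config")
  }
  if (cfg$fst < 0 || cfg$fst >= 1) {
    abort("`fst` must lie in [0, 1).", class = "temqtl_invalid_config")
  }
  fracs <- c(cfg$eqtl_fraction, cfg$state_specific_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions must lie in [0, 1].", class = "temqtl_invalid_config")
  }
  sds <- c(cfg$effect_sd, cfg$noise_sd, cfg$abundance_sd, cfg$di_sd,
           cfg$pi_sd, cfg$cfse$sigma)
  if (any(sds <= 0)) {
    abort("all SDs must be positive.", class = "temqtl_invalid_config")
  }
  invisible(cfg)
}

#' @export
print.sim_cohort_config <- function(x, ...) {
  cat("<sim_cohort_config>\n")
  cat(sprintf("  %d individuals, %d SNPs (%d subpop(s), Fst = %g), %d genes\n",
              x$n_individuals, x$n_snps, x$n_subpops, x$fst, x$n_genes))
  cat(sprintf("  eQTL fraction %.3f (state-specific %.3f), effect SD %g, noise SD %g\n",
              x$eqtl_fraction, x$state_specific_fraction, x$effect_sd, x$noise_sd))
  cat(sprintf("  abundance %g%% (SD %g), DI %g (SD %g), PI %g (SD %g), seed %d\n",
              x$abundance_mean, x$abundance_sd, x$di_mean, x$di_sd,
              x$pi_mean, x$pi_sd, x$seed))
  invisible(x)
}
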