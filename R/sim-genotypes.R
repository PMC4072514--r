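#' Simulate structured diploid genotypes
#'
#' Draws hard-call dosages (0/1/2) for a stratified cohort under the
#' Balding-Nichols model: each SNP has an ancestral allele frequency drawn
#' uniformly from `maf_range`, and each subpopulation's frequency is drawn
#' from `Beta(p(1-F)/F, (1-p)(1-F)/F)` so that differentiation matches the
#' fixation index `F`. Linkage disequilibrium is induced within blocks of
#' `ld_block_size` adjacent SNPs by a first-order haplotype copying process:
#' each haplotype allele copies the previous SNP's allele with probability
#' `ld_rho` and is otherwise drawn fresh, giving pairwise r-squared decaying
#' with distance.
#'
#' @param config A [sim_cohort_config()].
#' @return A `geno_matrix`: list with `dosage` (individuals x SNPs integer
#'   matrix, dimnames set), `snps` (tibble: `snp_id`, `chr`, `pos`, `ref`,
#'   `alt`, `maf`, `impute_r2`) and `subpop` (integer vector per individual).
#' @examples
#' g <- simulate_genotypes(sim_cohort_config(n_individuals = 20, n_snps = 50))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  S <- config$n_snps
  F <- config$fst
  K <- config$n_subpops

  with_seed(derive_seed(config$seed, "genotypes"), {
    p_anc <- runif(S, config$maf_range[1], config$maf_range[2])
    # subpopulation allele frequencies (K x S)
    if (F == 0 || K == 1) {
      p_sub <- matrix(rep(p_anc, each = K), nrow = K)
    } else {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      p_sub <- matrix(rbeta(K * S, rep(a, each = K), rep(b, each = K)),
                      nrow = K)
      p_sub <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
    }
    subpop <- rep_len(seq_len(K), n)

    block <- ((seq_len(S) - 1L) %/% config$ld_block_size) + 1L
    pf <- p_sub[subpop, , drop = FALSE]  # n x S per-individual frequencies

    draw_haplotype <- function() {
      h <- matrix(0L, n, S)
      fresh <- matrix(runif(n * S) < pf, n, S)
      h[, 1] <- fresh[, 1]
      copy <- matrix(runif(n * S) < config$ld_rho, n, S)
      for (j in seq_len(S)[-1]) {
        if (block[j] == block[j - 1L]) {
          h[, j] <- ifelse(copy[, j], h[, j - 1L], fresh[, j])
        } else {
          h[, j] <- fresh[, j]
        }
      }
      h
    }
    dosage <- draw_haplotype() + draw_haplotype()
  })

  ids <- sprintf("ind%03d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(S))
  dimnames(dosage) <- list(ids, snp_ids)

  # blocks laid on chromosomes so that each chromosome holds ~250 SNPs
  blocks_per_chr <- max(1L, 250L %/% config$ld_block_size)
  chr <- as.character(((block - 1L) %/% blocks_per_chr) + 1L)
  pos <- integer(S)
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    pos[idx] <- seq_along(idx) * config$snp_spacing
  }
  af <- colMeans(dosage) / 2
  snps <- tibble(
    snp_id = snp_ids, chr = chr, pos = pos,
    ref = "A", alt = "G",
    maf = pmin(af, 1 - af), impute_r2 = NA_real_
  )
  names(subpop) <- ids
  new_geno_matrix(dosage, snps, subpop)
}

new_geno_matrix <- function(dosage, snps, subpop = NULL) {
  stopifnot(ncol(dosage) == nrow(snps), !anyDuplicated(snps$snp_id))
  if (any(dosage < 0 | dosage > 2)) {
    abort("dosages must lie in [0, 2].", class = "temqtl_invalid_genotypes")
  }
  structure(list(dosage = dosage, snps = snps, subpop = subpop),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chr))))
  invisible(x)
}

#' Subset a genotype panel by SNP id
#'
#' @param geno A `geno_matrix`.
#' @param snp_ids Character vector of SNP ids to keep, in panel order.
#' @return A `geno_matrix` restricted to those SNPs.
#' @export
subset_snps <- function(geno, snp_ids) {
  keep <- geno$snps$snp_id %in% snp_ids
  new_geno_matrix(geno$dosage[, keep, drop = FALSE],
                  geno$snps[keep, , drop = FALSE], geno$subpop)
}
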