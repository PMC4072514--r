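#' Filter a genotype panel on MAF and imputation quality
#'
#' Removes SNPs with minor-allele frequency below `min_maf` or an imputation
#' quality score below `min_imputation_r2` (both strict: a SNP sitting
#' exactly on either threshold is retained). SNPs with a missing quality
#' score are treated as directly genotyped and pass the quality filter.
#'
#' @param genotypes A `geno_matrix` with `maf` and (optionally) `impute_r2`
#'   columns in its SNP metadata.
#' @param min_maf MAF below which a SNP is removed (default 0.01).
#' @param min_imputation_r2 Quality score below which a SNP is removed
#'   (default 0.4).
#' @return The filtered `geno_matrix`, with attribute `qc_log` (tibble of
#'   counts removed per filter).
#' @export
genotype_qc_filter <- function(genotypes, min_maf = 0.01,
                               min_imputation_r2 = 0.4) {
  snps <- genotypes$snps
  fail_maf <- snps$maf < min_maf
  r2 <- snps$impute_r2 %||% rep(NA_real_, nrow(snps))
  fail_r2 <- !is.na(r2) & r2 < min_imputation_r2
  keep <- !(fail_maf | fail_r2)
  if (!any(keep)) {
    abort("no SNPs pass QC filters.", class = "temqtl_empty_panel")
  }
  out <- subset_snps(genotypes, snps$snp_id[keep])
  attr(out, "qc_log") <- tibble(
    filter = c("maf", "imputation_r2"),
    removed = c(sum(fail_maf), sum(fail_r2 & !fail_maf))
  )
  out
}

#' Top principal components of a genotype panel
#'
#' EIGENSTRAT-style unsupervised PCA: dosages are centred on twice the
#' allele frequency and scaled by `sqrt(2p(1-p))`, and the top `k`
#' eigenvectors of the individual-by-individual covariance are returned.
#' Monomorphic SNPs are dropped with a warning before scaling. Each
#' component's sign is fixed so that its largest-magnitude entry is
#' positive.
#'
#' @param genotypes A `geno_matrix`.
#' @param k Number of components (default 5, the number used as regression
#'   covariates downstream).
#' @return A list: `scores` (tibble `individual_id`, `PC1..PCk`) and
#'   `var_frac` (fraction of total variance per component).
#' @export
compute_genotype_pcs <- function(genotypes, k = 5) {
  D <- genotypes$dosage
  n <- nrow(D)
  if (n < k + 1) abort("need at least k + 1 individuals.",
                       class = "temqtl_insufficient_data")
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warn(sprintf("dropping %d monomorphic SNP(s) before PCA.", sum(!poly)))
    D <- D[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (ncol(D) < k) abort("need at least k polymorphic SNPs.",
                         class = "temqtl_insufficient_data")
  X <- sweep(D, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = n)
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = n)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  list(
    scores = dplyr::bind_cols(
      tibble(individual_id = rownames(D) %||% as.character(seq_len(n))),
      as_tibble(scores)
    ),
    var_frac = sv$d^2 / sum(sv$d^2)
  )
}

#' SNPs within a gene's cis window
#'
#' Returns the SNPs on the gene's chromosome whose position falls within
#' `half_window` base pairs of the transcription start site, both boundaries
#' inclusive; the window is symmetric and strand is ignored.
#'
#' @param gene One-row tibble or list with `gene_id`, `chr`, `tss`.
#' @param genotypes A `geno_matrix`.
#' @param half_window Half-width in bp (default 250000, i.e. a 500 kb
#'   window).
#' @return Character vector of SNP ids in position order (possibly empty).
#' @export
cis_window_snps <- function(gene, genotypes, half_window = 250000) {
  snps <- genotypes$snps
  hit <- snps$chr == gene$chr &
    snps$pos >= gene$tss - half_window &
    snps$pos <= gene$tss + half_window
  out <- snps[hit, ]
  out$snp_id[order(out$pos)]
}

# Build a numeric covariate design matrix from a covariate tibble:
# gender becomes a male indicator, individual_id is dropped, everything else
# must already be numeric.
covariate_design <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  df <- as.data.frame(covariates)
  df$individual_id <- NULL
  if ("gender" %in% names(df)) {
    df$gender <- as.numeric(df$gender == "male")
  }
  if (any(!vapply(df, is.numeric, logical(1)))) {
    abort("all covariates (after gender coding) must be numeric.",
          class = "temqtl_invalid_covariates")
  }
  X <- as.matrix(df)
  if (anyNA(X)) abort("covariates contain missing values.",
                      class = "temqtl_invalid_covariates")
  X
}

#' Single SNP-gene association by covariate-adjusted least squares
#'
#' Fits `expression = b0 + b1 * dosage + covariates` by ordinary least
#' squares and reports the allelic dosage effect `b1` with its standard
#' error and two-tailed t-test p-value (residual degrees of freedom
#' `n - 2 - ncol(covariates)`; with the default five genotype PCs plus
#' gender this is `n - 8`).
#'
#' @param expression Numeric vector of natural-log expression values.
#' @param dosage Numeric vector of allelic dosages in [0, 2].
#' @param covariates Optional covariate tibble/data frame (see
#'   [covariate_design()]): typically `PC1..PC5` and `gender`.
#' @return A list: `beta`, `se`, `analytic_p`, `residuals` (full-model), `n`,
#'   `df`.
#' @export
fit_snp_association <- function(expression, dosage, covariates = NULL) {
  n <- length(expression)
  stopifnot(length(dosage) == n)
  if (n < 10) abort("need at least 10 complete cases.",
                    class = "temqtl_insufficient_data")
  if (var(dosage) == 0) {
    abort("monomorphic SNP: dosage has zero variance.",
          class = "temqtl_monomorphic_snp")
  }
  C <- covariate_design(covariates)
  X <- cbind(`(Intercept)` = 1, dosage = dosage, C)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "temqtl_rank_deficient")
  }
  fit <- lm.fit(X, expression)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients["dosage"])
  tval <- beta / se
  list(beta = beta, se = se,
       analytic_p = 2 * pt(-abs(tval), df),
       residuals = unname(fit$residuals), n = n, df = df)
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors; invariant to allele
#' flips (`2 - dosage`).
#'
#' @param dosage_a,dosage_b Numeric dosage vectors over the same individuals.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (var(dosage_a) == 0 || var(dosage_b) == 0) {
    abort("LD undefined for a monomorphic SNP.",
          class = "temqtl_monomorphic_snp")
  }
  cor(dosage_a, dosage_b)^2
}

#' Convert a log-scale effect to a fold change per allele
#'
#' Effects are estimated on natural-log expression, so the multiplicative
#' change per copy of the alternate allele is `exp(beta)`.
#'
#' @param beta Effect size(s) on the natural-log scale.
#' @return `exp(beta)`.
#' @examples
#' beta_to_fold(-0.805) # ~0.45, i.e. a 55% reduction per allele
#' @export
beta_to_fold <- function(beta) {
  stopifnot(all(is.finite(beta)))
  exp(beta)
}
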