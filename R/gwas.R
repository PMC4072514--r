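#' Genome-wide association scan for a cell trait
#'
#' Regresses a quantitative phenotype (TEM abundance, division index or
#' proliferation index) on each SNP's allelic dosage with covariates by
#' ordinary least squares. For abundance the covariates are gender, age and
#' the top five genotype principal components; proliferation scans
#' additionally include the measured TEM relative abundance. Monomorphic
#' SNPs are skipped and logged. The genomic-control inflation factor of the
#' resulting p-values is attached.
#'
#' @param phenotype Named numeric vector or tibble column of trait values
#'   aligned to the genotype rows.
#' @param genotypes A `geno_matrix`.
#' @param covariates Covariate tibble (see [covariate_design()]).
#' @param phenotype_name Label stored in the result.
#' @param sig_threshold,suggestive_threshold Genome-wide significance and
#'   suggestive thresholds (defaults 5e-8 and 5e-5).
#' @return A `gwas_scan` tibble sorted by p: `snp_id`, `chr`, `pos`, `beta`,
#'   `se`, `p`, `significant`, `suggestive`. Attributes: `lambda_gc`,
#'   `phenotype`, `covariate_names`, `skipped_monomorphic`.
#' @export
genome_scan <- function(phenotype, genotypes, covariates = NULL,
                        phenotype_name = "trait",
                        sig_threshold = 5e-8, suggestive_threshold = 5e-5) {
  y <- as.numeric(phenotype)
  D <- genotypes$dosage
  n <- nrow(D)
  stopifnot(length(y) == n)
  C <- covariate_design(covariates)
  if (!is.null(C)) {
    if (qr(cbind(1, C))$rank < ncol(C) + 1) {
      abort("covariates are rank deficient (collinear columns).",
            class = "temqtl_rank_deficient")
    }
    if (qr(cbind(1, C, y))$rank < ncol(C) + 2) {
      abort("phenotype is collinear with the covariates.",
            class = "temqtl_rank_deficient")
    }
  }
  X0 <- cbind(1, C)
  Q <- qr.Q(qr(X0))
  ry <- y - Q %*% crossprod(Q, y)
  gvar <- matrixStats_colVars(D)
  skipped <- genotypes$snps$snp_id[gvar == 0]
  keep <- gvar > 0
  G <- D[, keep, drop = FALSE]
  RG <- G - Q %*% crossprod(Q, G)
  df <- n - ncol(X0) - 1L
  rg2 <- colSums(RG^2)
  beta <- unname(colSums(RG * as.numeric(ry)) / rg2)
  rss <- sum(ry^2) - beta^2 * unname(rg2)
  se <- unname(sqrt(rss / df / rg2))
  p <- 2 * pt(-abs(beta / se), df)

  meta <- genotypes$snps[keep, ]
  res <- tibble(snp_id = meta$snp_id, chr = meta$chr, pos = meta$pos,
                beta = beta, se = se, p = p,
                significant = p < sig_threshold,
                suggestive = p < suggestive_threshold)
  res <- res[order(res$p), ]
  structure(res, class = c("gwas_scan", class(res)),
            lambda_gc = lambda_gc(p), phenotype = phenotype_name,
            covariate_names = colnames(C),
            skipped_monomorphic = skipped)
}

matrixStats_colVars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1)
}

#' Genomic-control inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median
#' by the null median `qchisq(0.5, 1) = 0.4549364`. Values near 1 indicate
#' no systematic inflation (e.g. from population stratification).
#'
#' @param p_values Vector of at least 100 p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
lambda_gc <- function(p_values) {
  if (length(p_values) < 100) {
    abort("need at least 100 p-values.", class = "temqtl_insufficient_data")
  }
  if (any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1].", class = "temqtl_invalid_p")
  }
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Enrichment of nominal associations among disease SNP-gene pairs
#'
#' Under the null each of `n_pairs` disease-SNP/gene pairs reaches nominal
#' significance with probability `alpha`, so the expected count is
#' `n_pairs * alpha` and the observed count follows Binomial(n_pairs,
#' alpha). Reports the exact one-tailed (upper) binomial p-value
#' `P(X >= n_nominal)`.
#'
#' @param n_pairs Number of SNP-gene pairs tested.
#' @param n_nominal Number observed at nominal significance.
#' @param alpha Nominal level (default 0.05).
#' @return Tibble: `n_pairs`, `n_nominal`, `alpha`, `expected`, `p`.
#' @examples
#' binomial_enrichment(182, 26)  # expected 9.1 pairs by chance
#' @export
binomial_enrichment <- function(n_pairs, n_nominal, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "temqtl_invalid_config")
  }
  stopifnot(n_nominal >= 0, n_nominal <= n_pairs)
  tibble(n_pairs = n_pairs, n_nominal = n_nominal, alpha = alpha,
         expected = n_pairs * alpha,
         p = pbinom(n_nominal - 1, n_pairs, alpha, lower.tail = FALSE))
}

#' QQ-plot table with an order-statistic confidence band
#'
#' Expected quantiles are `-log10` of uniform order statistics; the band is
#' built from Beta(i, n - i + 1) quantiles of the order statistics.
#'
#' @param p_values Vector of p-values.
#' @param ci Band coverage (default 0.95).
#' @return Tibble: `expected`, `observed`, `lower`, `upper` (all -log10).
#' @export
qq_table <- function(p_values, ci = 0.95) {
  n <- length(p_values)
  i <- seq_len(n)
  tibble(
    expected = -log10(i / (n + 1)),
    observed = -log10(sort(p_values)),
    lower = -log10(qbeta(1 - (1 - ci) / 2, i, n - i + 1)),
    upper = -log10(qbeta((1 - ci) / 2, i, n - i + 1))
  )
}

#' @export
glance.gwas_scan <- function(x, ...) {
  tibble(phenotype = attr(x, "phenotype"), n_snps = nrow(x),
         lambda_gc = attr(x, "lambda_gc"),
         n_significant = sum(x$significant),
         n_suggestive = sum(x$suggestive))
}
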