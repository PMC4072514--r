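#' Permutation-based cis-eQTL scan for one gene
#'
#' Tests every SNP within the gene's cis window for association with
#' covariate-adjusted expression, and attaches permutation empirical
#' p-values. Expression is residualized on the covariates once; each of the
#' `n_perm` permutations shuffles those residuals and re-tests every cis SNP
#' with the same permutation (one shared stream per gene), so the
#' permutation null preserves the local LD structure. Two empirical
#' p-values are produced:
#'
#' * `empirical_p` (per SNP): share of permutations in which that SNP's
#'   permuted p-value is at or below its observed analytic p-value, with
#'   add-one smoothing, `(1 + hits) / (n_perm + 1)`.
#' * `gene_perm_p` (per gene, attached as an attribute and on the lead row):
#'   the family-wise version comparing the regional minimum p across SNPs,
#'   which is uniform under the null and is what [fdr_select()] consumes.
#'
#' The lead SNP is the smallest `empirical_p`, ties broken by smaller
#' analytic p then smaller position.
#'
#' @param gene One-row tibble/list with `gene_id`, `chr`, `tss`.
#' @param genotypes A `geno_matrix`; rows must match `expression` rows.
#' @param expression Either a numeric vector (one gene, aligned to
#'   individuals) or an individuals x genes matrix with the gene id among
#'   its column names.
#' @param covariates Covariate tibble (`individual_id` optional; typically
#'   `PC1..PC5` and `gender`), aligned to the genotype rows.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Master seed; the gene's stream is derived from it and the
#'   gene id, so scans agree across orderings and parallel schedules.
#' @param half_window Cis half-window in bp (default 250000).
#' @param state Optional state tag ("rest"/"stim") copied into the output.
#' @param permute `"residual"` (default) re-tests permuted covariate
#'   residuals against dosage alone; `"exact"` refits the full model for
#'   every permutation.
#' @return A tibble of class `eqtl_scan` with one row per tested SNP:
#'   `gene_id`, `snp_id`, `state`, `pos`, `beta`, `se`, `analytic_p`,
#'   `empirical_p`, `fold`, `n`, `lead`. Attributes: `lead_snp`,
#'   `gene_perm_p`, `n_perm`, `skipped_monomorphic`.
#' @export
scan_gene_cis <- function(gene, genotypes, expression, covariates = NULL,
                          n_perm = 10000, seed = 1L, half_window = 250000,
                          state = NA_character_,
                          permute = c("residual", "exact")) {
  permute <- match.arg(permute)
  if (n_perm < 100) {
    abort("`n_perm` must be at least 100 for usable resolution.",
          class = "temqtl_invalid_config")
  }
  y <- if (is.matrix(expression)) expression[, gene$gene_id] else expression
  n <- length(y)
  stopifnot(nrow(genotypes$dosage) == n)

  cis <- cis_window_snps(gene, genotypes, half_window)
  G <- genotypes$dosage[, cis, drop = FALSE]
  gvar <- apply(G, 2, var)
  skipped <- cis[gvar == 0]
  cis <- cis[gvar > 0]
  empty <- tibble(gene_id = character(), snp_id = character(),
                  state = character(), pos = integer(), beta = numeric(),
                  se = numeric(), analytic_p = numeric(),
                  empirical_p = numeric(), fold = numeric(), n = integer(),
                  lead = logical())
  if (length(cis) == 0) {
    warn(sprintf("no polymorphic cis SNP for %s.", gene$gene_id))
    return(structure(empty, class = c("eqtl_scan", class(empty)),
                     lead_snp = NA_character_, gene_perm_p = NA_real_,
                     n_perm = n_perm, skipped_monomorphic = skipped))
  }
  G <- G[, cis, drop = FALSE]

  C <- covariate_design(covariates)
  X0 <- cbind(1, C)
  Q <- qr.Q(qr(X0))
  ry <- as.numeric(y - Q %*% crossprod(Q, y))   # covariate residuals
  RG <- G - Q %*% crossprod(Q, G)          # residualized dosages
  df <- n - ncol(X0) - 1L

  # SNPs whose dosage is (numerically) in the covariate span are
  # untestable: e.g. the conditioned SNP and its perfect proxies
  rg2 <- colSums(RG^2)
  testable <- rg2 > 1e-8 * colSums(G^2)
  if (!all(testable)) {
    skipped <- c(skipped, cis[!testable])
    cis <- cis[testable]
    if (length(cis) == 0) {
      warn(sprintf("no testable cis SNP for %s.", gene$gene_id))
      return(structure(empty, class = c("eqtl_scan", class(empty)),
                       lead_snp = NA_character_, gene_perm_p = NA_real_,
                       n_perm = n_perm, skipped_monomorphic = skipped))
    }
    G <- G[, testable, drop = FALSE]
    RG <- RG[, testable, drop = FALSE]
    rg2 <- rg2[testable]
  }

  # observed full-model statistics via Frisch-Waugh
  beta <- colSums(RG * ry) / rg2
  rss <- sum(ry^2) - beta^2 * rg2
  se <- sqrt(rss / df / rg2)
  analytic_p <- 2 * pt(-abs(beta / se), df)

  perm_seed <- derive_seed(seed, gene$gene_id)
  ry <- as.numeric(ry)
  P <- with_seed(perm_seed, {
    vapply(seq_len(n_perm), function(i) ry[sample.int(n)], numeric(n))
  })
  if (permute == "residual") {
    # permuted covariate-residuals vs the covariate-residualized dosage:
    # t from the Pearson correlation. Using the residualized dosage keeps
    # the permuted statistic on the same footing as the observed one
    # (raw dosage partially overlaps the genotype-PC covariates, which
    # would attenuate the permutation null and deflate empirical p).
    Gc <- sweep(RG, 2, colMeans(RG))
    Gc <- Gc / rep(sqrt(colSums(Gc^2)), each = n)
    Pn <- sweep(P, 2, colMeans(P))
    Pn <- Pn / rep(sqrt(colSums(Pn^2)), each = n)
    r <- crossprod(Gc, Pn)                  # SNPs x permutations
    r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    t_perm <- r * sqrt(df / (1 - r^2))
    p_perm <- 2 * pt(-abs(t_perm), df)
  } else {
    p_perm <- apply(P, 2, function(py) {
      rpy <- as.numeric(py - Q %*% crossprod(Q, py))
      b <- colSums(RG * rpy) / rg2
      s2 <- (sum(rpy^2) - b^2 * rg2) / df
      2 * pt(-abs(b / sqrt(s2 / rg2)), df)
    })
    p_perm <- matrix(p_perm, nrow = length(cis))
  }

  hits <- rowSums(p_perm <= analytic_p)
  empirical_p <- (1 + hits) / (n_perm + 1)
  min_perm <- apply(p_perm, 2, min)
  gene_perm_p <- (1 + sum(min_perm <= min(analytic_p))) / (n_perm + 1)

  beta <- unname(beta); se <- unname(se)
  analytic_p <- unname(analytic_p); empirical_p <- unname(empirical_p)
  pos <- genotypes$snps$pos[match(cis, genotypes$snps$snp_id)]
  res <- tibble(
    gene_id = gene$gene_id, snp_id = cis, state = state, pos = pos,
    beta = beta, se = se, analytic_p = analytic_p,
    empirical_p = empirical_p, fold = exp(beta), n = n, lead = FALSE
  )
  ord <- order(res$empirical_p, res$analytic_p, res$pos)
  res$lead[ord[1]] <- TRUE
  res <- res[order(res$pos), ]
  structure(res, class = c("eqtl_scan", class(empty)),
            lead_snp = res$snp_id[res$lead], gene_perm_p = gene_perm_p,
            n_perm = n_perm, skipped_monomorphic = skipped)
}

#' Scan every gene and collect per-gene lead results
#'
#' Convenience wrapper running [scan_gene_cis()] over an annotation table
#' and returning one row per gene: the lead SNP's statistics plus the
#' gene-level family-wise permutation p (`gene_perm_p`).
#'
#' @inheritParams scan_gene_cis
#' @param genes Gene annotation tibble (`gene_id`, `chr`, `tss`).
#' @return Tibble with one row per scanned gene.
#' @export
scan_all_genes <- function(genes, genotypes, expression, covariates = NULL,
                           n_perm = 10000, seed = 1L, half_window = 250000,
                           state = NA_character_) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    sc <- scan_gene_cis(genes[i, ], genotypes, expression, covariates,
                        n_perm = n_perm, seed = seed,
                        half_window = half_window, state = state)
    if (nrow(sc) == 0) return(NULL)
    lead <- sc[sc$lead, ]
    lead$gene_perm_p <- attr(sc, "gene_perm_p")
    lead$lead <- NULL
    lead
  })
}

#' Benjamini-Hochberg selection of eQTL genes
#'
#' Applies BH across the per-gene lead p-values within each state and flags
#' genes at the requested false discovery rate.
#'
#' @param leads Tibble with one row per gene per state, carrying `gene_id`,
#'   `state` and the p-value column named by `p_col`.
#' @param q FDR level (default 0.05).
#' @param p_col Which p-value to adjust; default `"gene_perm_p"`, the
#'   family-wise regional permutation p, which is uniform per gene under the
#'   null (the per-SNP `empirical_p` of a lead SNP is a regional minimum and
#'   is not).
#' @return `leads` with `fdr_q` and logical `significant` appended.
#' @export
fdr_select <- function(leads, q = 0.05, p_col = "gene_perm_p") {
  stopifnot(p_col %in% names(leads))
  leads |>
    dplyr::group_by(.data$state) |>
    dplyr::mutate(fdr_q = p.adjust(.data[[p_col]], method = "BH"),
                  significant = .data$fdr_q <= q) |>
    dplyr::ungroup()
}

#' Conditional cis-eQTL scan on a candidate variant
#'
#' Re-runs [scan_gene_cis()] with the candidate SNP's allelic dosage
#' appended to the covariates, asking whether any residual cis signal
#' remains once that variant is accounted for. The region is called fully
#' explained when the residual scan's family-wise permutation p
#' (`gene_perm_p`, the region-minimum statistic, which is uniform under the
#' null) is at or above `alpha`; judging the per-SNP `empirical_p` minimum
#' against `alpha` instead would flag residual signal in almost every
#' multi-SNP region by multiplicity alone. The per-SNP empirical p-values
#' are returned for inspection.
#'
#' @inheritParams scan_gene_cis
#' @param condition_snp SNP id to condition on (must be in the panel).
#' @param alpha Residual-signal threshold (default 0.05).
#' @return A list of class `conditional_result`: `gene_id`,
#'   `condition_snp`, `results` (the residual scan, condition SNP excluded)
#'   and `fully_explained`.
#' @export
conditional_scan <- function(gene, condition_snp, genotypes, expression,
                             covariates = NULL, n_perm = 10000, seed = 1L,
                             half_window = 250000, state = NA_character_,
                             alpha = 0.05) {
  if (!condition_snp %in% genotypes$snps$snp_id) {
    abort(sprintf("condition SNP %s not in panel.", condition_snp),
          class = "temqtl_missing_snp")
  }
  cond <- genotypes$dosage[, condition_snp]
  C <- covariate_design(covariates)
  aug <- cbind(C, cond_dosage = cond)
  if (qr(cbind(1, aug))$rank < ncol(aug) + 1) {
    abort("condition SNP is collinear with the covariates.",
          class = "temqtl_rank_deficient")
  }
  cov2 <- as_tibble(aug)
  res <- scan_gene_cis(gene, genotypes, expression, cov2, n_perm = n_perm,
                       seed = seed, half_window = half_window, state = state)
  gene_perm_p <- attr(res, "gene_perm_p")
  res <- res[res$snp_id != condition_snp, ]
  structure(list(gene_id = gene$gene_id, condition_snp = condition_snp,
                 results = res, gene_perm_p = gene_perm_p,
                 fully_explained = is.na(gene_perm_p) ||
                   gene_perm_p >= alpha),
            class = "conditional_result")
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf("<conditional_result> %s | %s: %s (min residual empirical p = %s)\n",
              x$gene_id, x$condition_snp,
              if (x$fully_explained) "fully explained" else "residual signal",
              format(suppressWarnings(min(x$results$empirical_p)), digits = 3)))
  invisible(x)
}

#' Cross-state effect-difference z-test
#'
#' Given per-allele effect estimates for the same SNP-gene pair in resting
#' and stimulated cells, tests whether the effects differ:
#' `z = (beta_stim - beta_rest) / sqrt(se_rest^2 + se_stim^2)`, with a
#' two-tailed standard-normal p-value; the two states are treated as
#' independent samples.
#'
#' @param beta_rest,se_rest,beta_stim,se_stim Numeric vectors (recycled to
#'   common length); SEs must be positive.
#' @param gene_id,snp_id Optional identifiers carried into the output.
#' @return Tibble: `gene_id`, `snp_id`, `z`, `p_delta`.
#' @examples
#' state_difference_test(-0.366, 0.085, -0.805, 0.071)  # p_delta ~ 7.4e-5
#' @export
state_difference_test <- function(beta_rest, se_rest, beta_stim, se_stim,
                                  gene_id = NA_character_,
                                  snp_id = NA_character_) {
  if (any(se_rest <= 0) || any(se_stim <= 0)) {
    abort("standard errors must be positive.", class = "temqtl_invalid_se")
  }
  z <- (beta_stim - beta_rest) / sqrt(se_rest^2 + se_stim^2)
  tibble(gene_id = gene_id, snp_id = snp_id, z = z,
         p_delta = 2 * pnorm(-abs(z)))
}

#' Delimit the disease locus implicated by a lead SNP
#'
#' Finds the furthest SNPs in LD with the lead SNP (`r^2 >` threshold) in
#' each direction, extends outward to the nearest flanking recombination
#' hotspot, and - if no gene overlaps the resulting interval - extends a
#' further `pad` bp on each side.
#'
#' @param lead_snp SNP id present in the panel.
#' @param genotypes A `geno_matrix`.
#' @param hotspots Tibble of recombination hotspots (`chr`, `pos`).
#' @param ld_threshold r-squared above which a SNP counts as an LD partner
#'   (default 0.5, strict).
#' @param pad Extension applied when the interval contains no gene
#'   (default 250000 bp).
#' @param genes Optional gene annotation (`gene_id`, `chr`, `tss`) used for
#'   the gene-free check; skipped when `NULL`.
#' @return One-row tibble: `chr`, `start`, `end`, `lead_snp`.
#' @export
define_disease_locus <- function(lead_snp, genotypes, hotspots,
                                 ld_threshold = 0.5, pad = 250000,
                                 genes = NULL) {
  snps <- genotypes$snps
  i <- match(lead_snp, snps$snp_id)
  if (is.na(i)) abort(sprintf("lead SNP %s not in panel.", lead_snp),
                      class = "temqtl_missing_snp")
  chr <- snps$chr[i]
  on_chr <- which(snps$chr == chr)
  lead_dos <- genotypes$dosage[, i]
  if (var(lead_dos) == 0) abort("lead SNP is monomorphic.",
                                class = "temqtl_monomorphic_snp")
  r2 <- vapply(on_chr, function(j) {
    dj <- genotypes$dosage[, j]
    if (var(dj) == 0) return(0)
    cor(lead_dos, dj)^2
  }, numeric(1))
  partners <- on_chr[r2 > ld_threshold | on_chr == i]
  span <- range(snps$pos[partners])
  hs <- hotspots$pos[hotspots$chr == chr]
  left_hs <- hs[hs <= span[1]]
  right_hs <- hs[hs >= span[2]]
  start <- if (length(left_hs)) max(left_hs) else 1L
  end <- if (length(right_hs)) min(right_hs) else max(snps$pos[on_chr])
  if (!is.null(genes)) {
    overlapping <- genes$chr == chr & genes$tss >= start & genes$tss <= end
    if (!any(overlapping)) {
      start <- max(1L, start - pad)
      end <- end + pad
    }
  }
  tibble(chr = chr, start = as.integer(start), end = as.integer(end),
         lead_snp = lead_snp)
}
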