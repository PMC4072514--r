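#' Per-gene correlation with proliferation, with permutation p-values
#'
#' Computes each gene's Pearson correlation between baseline (resting)
#' expression and the proliferation index, and a two-tailed permutation
#' p-value: the proliferation vector is permuted `n_perm` times (one shared
#' stream across genes) and `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`.
#' Constant genes are skipped with a warning.
#'
#' @param expression Individuals x genes matrix of baseline expression.
#' @param proliferation Numeric proliferation-index vector aligned to rows.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the shared permutation stream.
#' @return Tibble: `gene_id`, `r`, `permutation_p`, `n`.
#' @export
correlate_genes <- function(expression, proliferation, n_perm = 1000,
                            seed = 1L) {
  n <- length(proliferation)
  stopifnot(nrow(expression) == n)
  if (n < 20) abort("need at least 20 individuals.",
                    class = "temqtl_insufficient_data")
  const <- apply(expression, 2, var) == 0
  if (any(const)) {
    warn(sprintf("skipping %d constant gene(s): %s", sum(const),
                 paste(head(colnames(expression)[const], 5), collapse = ", ")))
    expression <- expression[, !const, drop = FALSE]
  }
  r_obs <- as.numeric(cor(expression, proliferation))
  P <- with_seed(derive_seed(seed, "gene_perm"), {
    vapply(seq_len(n_perm), function(i) proliferation[sample.int(n)],
           numeric(n))
  })
  R_perm <- cor(expression, P)            # genes x permutations
  hits <- unname(rowSums(abs(R_perm) >= abs(r_obs)))
  tibble(gene_id = colnames(expression), r = r_obs,
         permutation_p = (1 + hits) / (n_perm + 1), n = n)
}

#' Build a signed proliferation-potential signature
#'
#' Retains genes whose permutation p-value is below `threshold` and assigns
#' each a weight of +1 or -1 according to the sign of its training
#' correlation with proliferation.
#'
#' @param corr Tibble from [correlate_genes()].
#' @param threshold Selection threshold on the permutation p (default 0.01).
#' @return A `signature_model`: tibble of `gene_id`, `weight`, `r` with
#'   attributes `threshold` and `empty`.
#' @export
build_signature <- function(corr, threshold = 0.01) {
  sel <- corr[corr$permutation_p < threshold & corr$r != 0, ]
  model <- tibble(gene_id = sel$gene_id,
                  weight = sign(sel$r), r = sel$r)
  structure(model, class = c("signature_model", class(model)),
            threshold = threshold, empty = nrow(model) == 0)
}

#' Score individuals with a signature and correlate with proliferation
#'
#' The score is the weighted sum of the signature genes' expression after
#' per-gene standardization across the scored individuals:
#' `score_i = sum_g weight_g * z_g(i)`.
#'
#' @param model A `signature_model`.
#' @param expression Individuals x genes baseline expression matrix
#'   containing every signature gene.
#' @param proliferation Optional proliferation vector; when supplied, the
#'   Pearson correlation of score with proliferation is attached.
#' @param standardize Standardize genes before summing (default TRUE; raw
#'   sums are dominated by high-expression genes).
#' @return Tibble `individual_id`, `score`, with attribute `r` (or NA).
#' @export
score_individuals <- function(model, expression, proliferation = NULL,
                              standardize = TRUE) {
  if (isTRUE(attr(model, "empty")) || nrow(model) == 0) {
    abort("cannot score with an empty signature.",
          class = "temqtl_empty_signature")
  }
  missing <- setdiff(model$gene_id, colnames(expression))
  if (length(missing)) {
    abort(paste0("signature gene(s) absent from expression: ",
                 paste(missing, collapse = ", ")),
          class = "temqtl_missing_gene")
  }
  E <- expression[, model$gene_id, drop = FALSE]
  if (standardize) E <- scale(E)
  score <- as.numeric(E %*% model$weight)
  out <- tibble(
    individual_id = rownames(expression) %||%
      as.character(seq_len(nrow(expression))),
    score = score
  )
  attr(out, "r") <- if (is.null(proliferation)) NA_real_ else
    cor(score, proliferation)
  out
}

#' Permutation null for the number of proliferation-correlated genes
#'
#' How many genes would pass the selection threshold by chance? For each of
#' `n_perm` permutations of the proliferation vector, counts genes whose
#' two-tailed correlation test (analytic t-based p inside the null loop)
#' falls below `threshold`, and reports the null distribution together with
#' a one-tailed permutation p for the observed count.
#'
#' @inheritParams correlate_genes
#' @param threshold Per-gene selection threshold (default 0.01).
#' @param observed_count Observed number of selected genes; when `NULL` it
#'   is computed from the unpermuted data with the same analytic test.
#' @return List: `counts` (null distribution), `median`, `max`,
#'   `observed`, `p` (one-tailed, add-one smoothed).
#' @export
null_gene_count <- function(expression, proliferation, n_perm = 1000,
                            threshold = 0.01, seed = 1L,
                            observed_count = NULL) {
  n <- length(proliferation)
  stopifnot(nrow(expression) == n)
  const <- apply(expression, 2, var) == 0
  expression <- expression[, !const, drop = FALSE]
  df <- n - 2
  # |r| above which the analytic two-tailed p drops below threshold
  t_crit <- stats::qt(1 - threshold / 2, df)
  r_crit <- t_crit / sqrt(df + t_crit^2)
  P <- with_seed(derive_seed(seed, "null_count"), {
    vapply(seq_len(n_perm), function(i) proliferation[sample.int(n)],
           numeric(n))
  })
  R_perm <- cor(expression, P)
  counts <- colSums(abs(R_perm) > r_crit)
  if (is.null(observed_count)) {
    observed_count <- sum(abs(cor(expression, proliferation)) > r_crit)
  }
  list(counts = counts, median = median(counts), max = max(counts),
       observed = observed_count,
       p = (1 + sum(counts >= observed_count)) / (n_perm + 1))
}

#' Split-half cross-validation of the proliferation signature
#'
#' Randomly splits the cohort in half, builds the signature on one half and
#' evaluates the score-proliferation correlation on the held-out half, with
#' a one-tailed permutation p (the held-out proliferation vector is
#' permuted). Both directions of the split are reported.
#'
#' @inheritParams correlate_genes
#' @param threshold Signature selection threshold (default 0.01).
#' @param n_perm_test Permutations for the held-out p-value (default 1000).
#' @return Tibble with one row per fold: `fold`, `n_train`, `n_test`,
#'   `n_genes`, `r`, `p`, `informative`.
#' @export
split_half_validate <- function(expression, proliferation, seed = 1L,
                                n_perm = 1000, threshold = 0.01,
                                n_perm_test = 1000) {
  n <- length(proliferation)
  if (n < 40) abort("need at least 40 individuals for split-half validation.",
                    class = "temqtl_insufficient_data")
  half <- with_seed(derive_seed(seed, "split"), sample.int(n, n %/% 2))
  folds <- list(list(train = half, test = setdiff(seq_len(n), half)),
                list(train = setdiff(seq_len(n), half), test = half))
  purrr::map_dfr(seq_along(folds), function(fi) {
    f <- folds[[fi]]
    corr <- correlate_genes(expression[f$train, , drop = FALSE],
                            proliferation[f$train], n_perm = n_perm,
                            seed = derive_seed(seed, paste0("fold", fi)))
    model <- build_signature(corr, threshold)
    if (isTRUE(attr(model, "empty"))) {
      return(tibble(fold = fi, n_train = length(f$train),
                    n_test = length(f$test), n_genes = 0L, r = NA_real_,
                    p = NA_real_, informative = FALSE))
    }
    sc <- score_individuals(model, expression[f$test, , drop = FALSE])
    r_test <- cor(sc$score, proliferation[f$test])
    null_r <- with_seed(derive_seed(seed, paste0("foldperm", fi)), {
      vapply(seq_len(n_perm_test), function(i) {
        cor(sc$score, proliferation[f$test][sample.int(length(f$test))])
      }, numeric(1))
    })
    tibble(fold = fi, n_train = length(f$train), n_test = length(f$test),
           n_genes = nrow(model), r = r_test,
           p = (1 + sum(null_r >= r_test)) / (n_perm_test + 1),
           informative = TRUE)
  })
}

#' Cross-visit replication of the proliferation signature
#'
#' For individuals sampled at two visits, trains the signature on each
#' visit's data and scores the other visit, reporting the correlation and a
#' one-tailed permutation p in both directions.
#'
#' @param visit1,visit2 Lists with `expression` (individuals x genes, rows
#'   named by individual id) and `proliferation` (named vector).
#' @param n_perm Permutations per direction (default 1000).
#' @param threshold Selection threshold (default 0.01).
#' @param seed Integer seed.
#' @return Tibble with rows `visit1 -> visit2` and `visit2 -> visit1`:
#'   `direction`, `n_genes`, `r`, `p`.
#' @export
cross_visit_replicate <- function(visit1, visit2, n_perm = 1000,
                                  threshold = 0.01, seed = 1L) {
  shared <- intersect(rownames(visit1$expression), rownames(visit2$expression))
  if (length(shared) < 10) {
    abort("need at least 10 shared individuals across visits.",
          class = "temqtl_insufficient_data")
  }
  one_way <- function(train, test, tag, sub_seed) {
    corr <- correlate_genes(train$expression[shared, , drop = FALSE],
                            train$proliferation[shared], n_perm = n_perm,
                            seed = sub_seed)
    model <- build_signature(corr, threshold)
    if (isTRUE(attr(model, "empty"))) {
      return(tibble(direction = tag, n_genes = 0L, r = NA_real_,
                    p = NA_real_))
    }
    sc <- score_individuals(model, test$expression[shared, , drop = FALSE])
    r <- cor(sc$score, test$proliferation[shared])
    null_r <- with_seed(derive_seed(sub_seed, "xvisit"), {
      vapply(seq_len(n_perm), function(i) {
        cor(sc$score,
            test$proliferation[shared][sample.int(length(shared))])
      }, numeric(1))
    })
    tibble(direction = tag, n_genes = nrow(model), r = r,
           p = (1 + sum(null_r >= r)) / (n_perm + 1))
  }
  dplyr::bind_rows(
    one_way(visit1, visit2, "visit1 -> visit2", derive_seed(seed, "fwd")),
    one_way(visit2, visit1, "visit2 -> visit1", derive_seed(seed, "bwd"))
  )
}

#' @export
glance.signature_model <- function(x, ...) {
  tibble(n_genes = nrow(x), n_positive = sum(x$weight > 0),
         n_negative = sum(x$weight < 0), threshold = attr(x, "threshold"))
}
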