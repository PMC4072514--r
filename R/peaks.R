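#' LD partners of an index SNP
#'
#' All same-chromosome SNPs whose dosage r-squared with the index SNP meets
#' the threshold, index included.
#'
#' @param snp Index SNP id.
#' @param genotypes A `geno_matrix`.
#' @param r2_threshold Partner threshold (default 0.8, inclusive).
#' @return Tibble: `snp_id`, `chr`, `pos`, `r2`, `index` (logical).
#' @export
ld_partners <- function(snp, genotypes, r2_threshold = 0.8) {
  snps <- genotypes$snps
  i <- match(snp, snps$snp_id)
  if (is.na(i)) abort(sprintf("SNP %s not in panel.", snp),
                      class = "temqtl_missing_snp")
  d0 <- genotypes$dosage[, i]
  if (var(d0) == 0) abort("index SNP is monomorphic.",
                          class = "temqtl_monomorphic_snp")
  on_chr <- which(snps$chr == snps$chr[i])
  r2 <- vapply(on_chr, function(j) {
    dj <- genotypes$dosage[, j]
    if (var(dj) == 0) return(NA_real_)
    cor(d0, dj)^2
  }, numeric(1))
  keep <- on_chr == i | (!is.na(r2) & r2 >= r2_threshold)
  tibble(snp_id = snps$snp_id[on_chr[keep]], chr = snps$chr[on_chr[keep]],
         pos = snps$pos[on_chr[keep]], r2 = r2[keep],
         index = snps$snp_id[on_chr[keep]] == snp)
}

#' Nearest H3K4me3 peak to a SNP set
#'
#' For an index SNP together with its LD partners, finds the minimum
#' distance to any peak interval and the height of that nearest peak.
#' Peaks use the BED convention (0-based half-open) and SNPs 1-based
#' positions; distance is the number of bases strictly between SNP and peak
#' (0 when the SNP falls inside a peak), computed with GenomicRanges. Ties
#' in distance are broken in favour of the taller peak. The summit distance
#' (to `start + summit` when a summit offset is available) is also
#' reported.
#'
#' @param snp_set Tibble with `chr` and `pos` (1-based) per member, e.g.
#'   from [ld_partners()].
#' @param peaks Tibble of peaks: `chr`, `start`, `end` (0-based half-open),
#'   `height`, optional `summit` (offset from `start`).
#' @return One-row tibble: `distance`, `height`, `summit_distance`,
#'   `peak_chr`, `peak_start`, `peak_end`. With no peak on any member's
#'   chromosome, `distance = Inf` with a warning.
#' @export
nearest_peak_features <- function(snp_set, peaks) {
  stopifnot(nrow(snp_set) >= 1)
  pk <- peaks[peaks$chr %in% unique(snp_set$chr), ]
  if (nrow(pk) == 0) {
    warn("no peak on the SNP set's chromosome(s); distance is infinite.")
    return(tibble(distance = Inf, height = NA_real_,
                  summit_distance = Inf, peak_chr = NA_character_,
                  peak_start = NA_integer_, peak_end = NA_integer_))
  }
  snp_gr <- GenomicRanges::GRanges(
    snp_set$chr, IRanges::IRanges(snp_set$pos, width = 1)
  )
  peak_gr <- GenomicRanges::GRanges(
    pk$chr, IRanges::IRanges(pk$start + 1L, pk$end)
  )
  hits <- GenomicRanges::distanceToNearest(snp_gr, peak_gr, select = "all")
  ht <- tibble(
    distance = as.numeric(S4Vectors_mcols_distance(hits)),
    peak = S4Vectors_subjectHits(hits),
    height = pk$height[S4Vectors_subjectHits(hits)]
  )
  best <- ht[order(ht$distance, -ht$height), ][1, ]
  j <- best$peak
  summit_pos <- if (!is.null(pk$summit) && !is.na(pk$summit[j])) {
    pk$start[j] + pk$summit[j] + 1L
  } else {
    (pk$start[j] + 1L + pk$end[j]) %/% 2L
  }
  tibble(distance = best$distance, height = best$height,
         summit_distance = min(abs(snp_set$pos[snp_set$chr == pk$chr[j]] -
                                     summit_pos)),
         peak_chr = pk$chr[j], peak_start = pk$start[j],
         peak_end = pk$end[j])
}

# thin wrappers so the S4Vectors accessors read clearly above
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)
S4Vectors_mcols_distance <- function(h) S4Vectors::mcols(h)$distance

#' Compare peak-proximity features between two SNP sets
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) test per feature, exact when
#' both groups have at most 10 untied observations and otherwise the normal
#' approximation with tie and continuity corrections. Used to ask whether
#' significant eQTL SNPs sit closer to, or under taller, H3K4me3 marks than
#' non-significant lead SNPs.
#'
#' @param features_a,features_b Numeric vectors (e.g. distances or heights).
#' @param side `"less"` tests the alternative that `features_a` tends to be
#'   smaller than `features_b`; `"greater"` the reverse.
#' @return Tibble: `n_a`, `n_b`, `statistic` (rank-sum U for group a), `p`,
#'   `method`, `degenerate`.
#' @export
compare_snp_sets <- function(features_a, features_b,
                             side = c("less", "greater")) {
  side <- match.arg(side)
  a <- features_a[is.finite(features_a)]
  b <- features_b[is.finite(features_b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both SNP sets must be non-empty.",
          class = "temqtl_insufficient_data")
  }
  if (length(unique(c(a, b))) == 1) {
    return(tibble(n_a = length(a), n_b = length(b), statistic = NA_real_,
                  p = 1, method = "degenerate", degenerate = TRUE))
  }
  exact <- length(a) <= 10 && length(b) <= 10 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = side, exact = exact,
                       correct = TRUE)
  )
  tibble(n_a = length(a), n_b = length(b),
         statistic = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "exact" else "normal approximation",
         degenerate = FALSE)
}
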