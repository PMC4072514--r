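#' Write genotypes as a dosage TSV
#'
#' One row per SNP (`snp_id`, `chr`, `pos`, `ref`, `alt`, `maf`) followed by
#' one dosage column per individual.
#'
#' @param genotypes A `geno_matrix`.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  meta <- genotypes$snps[, c("snp_id", "chr", "pos", "ref", "alt", "maf")]
  dos <- as_tibble(t(genotypes$dosage))
  readr::write_tsv(dplyr::bind_cols(meta, dos), path)
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#'
#' @param path Input file.
#' @return A `geno_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chr", "pos", "ref", "alt", "maf")
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols)]))
  colnames(dos) <- df$snp_id
  snps <- as_tibble(df[, meta_cols])
  snps$chr <- as.character(snps$chr)
  snps$impute_r2 <- NA_real_
  new_geno_matrix(dos, snps)
}

#' Write hard-call genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with a GT FORMAT field (dosage 0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1). Dosages must be hard calls.
#'
#' @param genotypes A `geno_matrix`.
#' @param path Output file (plain text, uncompressed).
#' @export
write_genotype_vcf <- function(genotypes, path) {
  D <- round(genotypes$dosage)
  gt_codes <- c("0/0", "0/1", "1/1")
  snps <- genotypes$snps
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=temqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(D)), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(D))) {
    writeLines(paste(c(snps$chr[j], snps$pos[j], snps$snp_id[j],
                       snps$ref[j], snps$alt[j], ".", "PASS", ".", "GT",
                       gt_codes[D[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-field VCF into a genotype matrix
#'
#' Parses an uncompressed VCF with a GT FORMAT field into alternate-allele
#' dosages. Multi-allelic records are rejected.
#'
#' @param path VCF file.
#' @return A `geno_matrix` (with `maf` recomputed from the dosages).
#' @export
read_genotype_vcf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  ids <- header[-(1:9)]
  n <- length(ids)
  parse_row <- function(f) {
    if (grepl(",", f[5])) abort("multi-allelic VCF records are not supported.",
                                class = "temqtl_invalid_vcf")
    gt <- sub(":.*$", "", f[-(1:9)])
    dos <- vapply(strsplit(gt, "[/|]"), function(al) {
      sum(al == "1")
    }, numeric(1))
    list(meta = f[1:5], dos = dos)
  }
  rows <- lapply(body, parse_row)
  dos <- vapply(rows, `[[`, numeric(n), "dos")
  meta <- t(vapply(rows, `[[`, character(5), "meta"))
  rownames(dos) <- ids
  colnames(dos) <- meta[, 3]
  af <- colMeans(dos) / 2
  snps <- tibble(snp_id = meta[, 3], chr = meta[, 1],
                 pos = as.integer(meta[, 2]), ref = meta[, 4],
                 alt = meta[, 5], maf = pmin(af, 1 - af),
                 impute_r2 = NA_real_)
  new_geno_matrix(dos, snps)
}

#' Write an expression matrix (or any individuals-by-variables matrix) as TSV
#'
#' @param mat Matrix with individual ids as row names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- dplyr::bind_cols(
    tibble(individual_id = rownames(mat)), as_tibble(mat)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Input file.
#' @return Numeric matrix with individual ids as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Read a BED6(+1) peak file
#'
#' Columns: chrom, start, end, name, score, strand and optionally a summit
#' offset. The score column is taken as the peak height.
#'
#' @param path BED file (uncompressed).
#' @return Tibble: `chr`, `start`, `end`, `name`, `height`, `strand`,
#'   `summit` (NA when absent).
#' @export
read_peaks_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(df)[1:min(7, ncol(df))] <-
    c("chr", "start", "end", "name", "height", "strand", "summit")[1:min(7, ncol(df))]
  if (!"summit" %in% names(df)) df$summit <- NA_integer_
  if (!"height" %in% names(df)) df$height <- NA_real_
  if (!"name" %in% names(df)) df$name <- NA_character_
  if (!"strand" %in% names(df)) df$strand <- "."
  df$chr <- as.character(df$chr)
  as_tibble(df[, c("chr", "start", "end", "name", "height", "strand",
                   "summit")])
}

#' Write a flow or CFSE event table as CSV
#'
#' @param x A `flow_sample` (columns CD45RA, CD45RO, CD62L) or numeric
#'   vector of CFSE intensities (single `CFSE` column).
#' @param path Output file.
#' @export
write_events_csv <- function(x, path) {
  df <- if (inherits(x, "flow_sample")) as_tibble(x$events) else
    tibble(CFSE = as.numeric(x))
  readr::write_csv(df, path)
  invisible(path)
}
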