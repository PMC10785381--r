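#' Create a genotype matrix object
#'
#' Wraps a lines x SNPs dosage matrix (entries 0/1/2 or `NA`) with per-SNP
#' allele-frequency and missing-rate accounting.
#'
#' @param dosages numeric matrix, lines in rows (rownames = line ids), SNPs in
#'   columns (colnames = SNP ids).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("L%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%05d", seq_len(ncol(dosages)))
  structure(list(dosages = dosages), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("<genotype_matrix> %d lines x %d SNPs, %.2f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' Per-SNP minor allele frequency
#'
#' Counted-allele frequency `p = mean(dosage)/2` folded to the minor allele,
#' computed over non-missing entries.
#'
#' @param geno a [genotype_matrix()].
#' @return named numeric vector in `[0, 0.5]`.
#' @export
snp_maf <- function(geno) {
  p <- colMeans(geno$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Read a genotype dosage table from delimited text
#'
#' Expects a header row of SNP ids and a first column of line ids (or the
#' transpose, with `transposed = TRUE`). Missing dosages may be coded as
#' empty, `NA` or any code in `missing_codes`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param missing_codes values recoded to missing (default `-9`).
#' @param transposed set `TRUE` when the file is SNPs x lines.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, sep = "\t", missing_codes = c(-9),
                           transposed = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "numeric"
  m[m %in% missing_codes] <- NA
  if (transposed) m <- t(m)
  genotype_matrix(m)
}

#' SNP and line quality control
#'
#' Applies the marker filters in a fixed order: (1) SNPs and (2) lines with
#' more than `max_missing` missing data are removed, both judged on the
#' original matrix (the two missingness criteria are simultaneous), then (3)
#' SNPs with minor allele frequency below `min_maf` on the retained set are
#' removed. Defaults are a 10% missingness cap and a 3% MAF floor.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction per SNP and per line.
#' @param min_maf minimum minor allele frequency; monomorphic SNPs always fail.
#' @return the filtered [genotype_matrix()] with a `qc_report` attribute
#'   listing counts removed by each rule.
#' @export
filter_snps <- function(geno, max_missing = 0.10, min_maf = 0.03) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  snp_miss <- colMeans(is.na(d))
  line_miss <- rowMeans(is.na(d))
  drop_snp_miss <- snp_miss > max_missing
  drop_line <- line_miss > max_missing
  d <- d[!drop_line, !drop_snp_miss, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- !is.finite(maf) | maf < min_maf
  d <- d[, !drop_maf, drop = FALSE]
  if (ncol(d) == 0)
    stop("no SNPs left after quality control", call. = FALSE)
  out <- genotype_matrix(d)
  attr(out, "qc_report") <- data.frame(
    rule = c("snp_missing", "line_missing", "snp_maf"),
    removed = c(sum(drop_snp_miss), sum(drop_line), sum(drop_maf)),
    retained = c(ncol(geno$dosages) - sum(drop_snp_miss),
                 nrow(geno$dosages) - sum(drop_line),
                 ncol(d)))
  out
}

#' Mean imputation of residual missing dosages
#'
#' Replaces each missing dosage by the SNP mean `2 p_j`. Intended for the
#' small residual missingness left after [filter_snps()]; column means are
#' unchanged by construction.
#'
#' @param geno a [genotype_matrix()].
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(d, na.rm = TRUE)
    d[nas] <- mu[nas[, 2]]
  }
  genotype_matrix_unchecked(d)
}

## imputed dosages are fractional; bypass the 0/1/2 check
genotype_matrix_unchecked <- function(d) {
  structure(list(dosages = as.matrix(d)), class = "genotype_matrix")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = M M' / (2 * sum(p_j (1 - p_j)))` where `M` is the dosage
#' matrix centred by `2 p_j` per SNP and `p_j` the counted-allele frequency of
#' SNP j in the analysed sample. The average diagonal `d(G)` — close to 2 for
#' fully inbred lines — is reported alongside; it rescales additive variance
#' components to the observed-genotype scale in downstream genetic-parameter
#' formulas.
#'
#' @param geno a complete (imputed) [genotype_matrix()].
#' @return an object of class `grm`: list with `G` (lines x lines), `d_g`
#'   (mean diagonal), `denom` and `p` (allele frequencies).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2), ncol = 1,
#'                             dimnames = list(c("a", "b"), "s1")))
#' compute_grm(g)$G  # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (anyNA(d))
    stop("genotypes contain missing entries; run impute_missing() first",
         call. = FALSE)
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs are monomorphic; the relationship matrix is undefined",
         call. = FALSE)
  M <- sweep(d, 2, 2 * p)
  G <- tcrossprod(M) / denom
  structure(list(G = G, d_g = mean(diag(G)), denom = denom, p = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d lines, d(G) = %.3f\n", nrow(x$G), x$d_g))
  invisible(x)
}

#' Export a relationship matrix as delimited text
#' @param grm a [compute_grm()] object.
#' @param path output file; tab-separated with line-id headers.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  utils::write.table(grm$G, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
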