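#' Genotype container: allele dosages plus variant and sample metadata
#'
#' A light S3 container pairing a samples x variants dosage matrix with the
#' variant map and the sample-to-breed assignment. Dosages code the number of
#' alternate alleles: 0, 1, 2 for the AA, Aa and aa genotypes.
#'
#' @param dosage integer/numeric matrix, samples in rows, variants in columns,
#'   values in \{0, 1, 2\}. Row names are sample ids, column names variant ids
#'   (supplied metadata wins if both are present).
#' @param variants data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per dosage column, positions strictly increasing
#'   within each chromosome.
#' @param samples data frame with columns `id` and `breed`; one row per
#'   dosage row.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    ncol(dosage) == nrow(variants),
    nrow(dosage) == nrow(samples),
    all(c("id", "chrom", "pos") %in% names(variants)),
    all(c("id", "breed") %in% names(samples))
  )
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    rlang::abort("dosage values must be 0, 1 or 2")
  }
  for (chr in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == chr]
    if (is.unsorted(p, strictly = TRUE)) {
      rlang::abort(paste0("variant positions not strictly increasing on ", chr))
    }
  }
  rownames(dosage) <- samples$id
  colnames(dosage) <- variants$id
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " variants\n", sep = "")
  tab <- table(x$samples$breed)
  cat("breeds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param g a [genotype_matrix()].
#' @param samples,variants logical/integer/character index into samples and
#'   variants (defaults keep everything).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else samples
  if (is.character(si)) si <- match(si, g$samples$id)
  vi <- if (is.null(variants)) seq_len(ncol(g$dosage)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  genotype_matrix(g$dosage[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  g$samples[si, , drop = FALSE])
}

#' Expression container: genes x samples values staged through units
#'
#' Holds one expression matrix together with its unit tag — `"counts"`,
#' `"TPM"`, `"TMM"` (normalized counts-per-million after trimmed-mean
#' scaling) or `"INT"` (per-gene rank-based inverse normal transform) — and
#' the gene annotation used to anchor cis windows.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes data frame with columns `id`, `chrom`, `tss` (1-based),
#'   `strand`, `length` (bp); one row per value row.
#' @param unit one of `"counts"`, `"TPM"`, `"TMM"`, `"INT"`.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, unit = c("counts", "TPM", "TMM", "INT")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  genes <- tibble::as_tibble(genes)
  stopifnot(
    nrow(values) == nrow(genes),
    all(c("id", "chrom", "tss") %in% names(genes))
  )
  if (anyDuplicated(genes$id)) rlang::abort("duplicated gene ids")
  if (unit %in% c("counts", "TPM") && any(values < 0, na.rm = TRUE)) {
    rlang::abort(paste0(unit, " values must be non-negative"))
  }
  rownames(values) <- genes$id
  structure(list(values = values, genes = genes, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$unit, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by sample and/or gene
#'
#' @param x an [expression_matrix()].
#' @param samples logical/integer/character index into samples (columns).
#' @param genes logical/integer/character index into genes (rows).
#' @return An `expression_matrix`.
#' @export
subset_expr <- function(x, samples = NULL, genes = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  if (is.character(si)) si <- match(si, colnames(x$values))
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  if (is.character(gi)) gi <- match(gi, x$genes$id)
  expression_matrix(x$values[gi, si, drop = FALSE],
                    x$genes[gi, , drop = FALSE], x$unit)
}

# internal: relabel the unit after an in-place transformation
set_unit <- function(x, unit) {
  x$unit <- unit
  x
}
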