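#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x) with vcfR and converts GT calls to alternate-allele
#' dosages. Multi-allelic records are skipped (count recorded in the
#' `n_multiallelic` attribute and reported via a message); missing genotypes
#' are imputed to the variant's mean dosage rounded to the nearest integer
#' (`n_missing_imputed` attribute, with a warning).
#'
#' @param path VCF file path (plain text or gzipped).
#' @param sample_map optional data frame with columns `id`, `breed`
#'   assigning each VCF sample to a breed; unmapped samples get breed `NA`.
#' @return A [genotype_matrix()] with attributes `n_multiallelic` and
#'   `n_missing_imputed`.
#' @export
read_vcf <- function(path, sample_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  if (n_multi > 0) {
    rlang::inform(paste0("skipping ", n_multi, " multi-allelic record(s)"))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- which(!multi)
  if (!length(keep)) rlang::abort("no biallelic records in VCF")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  allele_counts <- function(calls) {
    # accepts 0/0, 0|1, ./., .
    a <- sub("[/|].*$", "", calls)
    b <- sub("^.*[/|]", "", calls)
    miss <- is.na(calls) | a == "." | b == "." | calls == "."
    d <- suppressWarnings(as.integer(a) + as.integer(b))
    d[miss] <- NA_integer_
    d
  }
  dos <- t(apply(gt, 1, allele_counts))
  if (ncol(gt) == 1) dos <- matrix(dos, ncol = 1)
  n_miss <- sum(is.na(dos))
  if (n_miss > 0) {
    for (i in seq_len(nrow(dos))) {
      na <- is.na(dos[i, ])
      if (any(na)) {
        mu <- mean(dos[i, !na])
        if (!is.finite(mu)) mu <- 0
        dos[i, na] <- as.integer(round(mu))
      }
    }
    rlang::warn(paste0("imputed ", n_miss, " missing genotype call(s) to the ",
                       "rounded mean dosage"))
  }
  variants <- tibble::tibble(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  ids <- colnames(gt)
  breeds <- rep(NA_character_, length(ids))
  if (!is.null(sample_map)) {
    sample_map <- as.data.frame(sample_map)
    breeds <- sample_map$breed[match(ids, sample_map$id)]
  }
  g <- genotype_matrix(t(dos), variants, tibble::tibble(id = ids, breed = breeds))
  attr(g, "n_multiallelic") <- n_multi
  attr(g, "n_missing_imputed") <- n_miss
  g
}

#' Write genotypes to a plain-text VCF v4.2 file
#'
#' @param g a [genotype_matrix()].
#' @param path output path (written uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$id), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")[g$dosage + 1L]
  gt_mat <- matrix(gt_str, nrow = nrow(g$dosage))
  body <- vapply(seq_len(ncol(g$dosage)), function(j) {
    paste(c(g$variants$chrom[j], g$variants$pos[j], g$variants$id[j],
            g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".", "GT",
            gt_mat[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' The matrix TSV has gene ids in the first column and sample ids in the
#' header; the unit is carried in a `#unit=` comment line. A companion gene
#' annotation TSV supplies `id`, `chrom`, `tss`, `strand`, `length`.
#'
#' @param path matrix TSV path.
#' @param annotation_path gene annotation TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path) {
  first <- readLines(path, n = 1L)
  unit <- "counts"
  if (startsWith(first, "#unit=")) unit <- sub("^#unit=", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    rlang::abort(paste0("duplicated gene id(s): ",
                        paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  vals <- df[, -1, drop = FALSE]
  non_num <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(non_num)) {
    for (j in non_num) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      rlang::abort(paste0("non-numeric value at row ", bad_row, ", column '",
                          names(vals)[j], "'"))
    }
  }
  ann <- tibble::as_tibble(utils::read.delim(annotation_path,
                                             stringsAsFactors = FALSE))
  missing_ann <- setdiff(gene_ids, ann$id)
  if (length(missing_ann)) {
    rlang::abort(paste0("annotation missing gene(s): ",
                        paste(missing_ann, collapse = ", ")))
  }
  ann <- ann[match(gene_ids, ann$id), , drop = FALSE]
  expression_matrix(as.matrix(vals), ann, unit = unit)
}

#' @rdname read_expression
#' @param x an [expression_matrix()].
#' @param annotation_path annotation output path (omitted if `NULL`).
#' @export
write_expression <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#unit=", x$unit), con)
  df <- data.frame(gene_id = x$genes$id, x$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(x$genes, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Requires columns `id`, `chrom`, `pos`, `beta`, `se`, `pvalue`, `n`.
#' Rows with `se <= 0` or with `pvalue` outside (0, 1] are dropped; the
#' counts are recorded in the `n_dropped_se` / `n_dropped_p` attributes and
#' reported with a warning.
#'
#' @param path TSV path.
#' @return A tibble of typed records.
#' @export
read_gwas <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  req <- c("id", "chrom", "pos", "beta", "se", "pvalue", "n")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    rlang::abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  bad_se <- !is.finite(df$se) | df$se <= 0
  bad_p <- !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  n_se <- sum(bad_se)
  n_p <- sum(bad_p & !bad_se)
  if (n_se + n_p > 0) {
    rlang::warn(paste0("dropped ", n_se, " row(s) with se <= 0 and ", n_p,
                       " row(s) with out-of-range p-values"))
  }
  out <- df[!(bad_se | bad_p), req]
  attr(out, "n_dropped_se") <- n_se
  attr(out, "n_dropped_p") <- n_p
  out
}

#' @rdname read_gwas
#' @param gwas a GWAS summary tibble.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
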