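#' Genotype quality control
#'
#' Two threshold sets, mirroring the two stages of a stratified eQTL design.
#' The pooled stage (applied across all samples) keeps variants with
#' MAF >= 0.05 and MAC >= 6. The per-breed stage applies, within each breed,
#' MAF > 0.01 (strict), MAC > 6 (strict) and heterozygote fraction < 0.99,
#' and then intersects the surviving variant sets across breeds, so only
#' variants passing in every breed are retained. The boundary conventions
#' differ between the stages deliberately (>= vs >).
#'
#' @param g a [genotype_matrix()].
#' @param stage `"pooled"` or `"per_breed"`.
#' @return A list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (tibble: stage, breed, filter, threshold, n_failing, plus a
#'   `kept` summary row).
#' @export
genotype_qc <- function(g, stage = c("pooled", "per_breed")) {
  stage <- match.arg(stage)
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  variant_stats <- function(dm) {
    n2 <- 2 * nrow(dm)
    ac <- colSums(dm)
    mac <- pmin(ac, n2 - ac)
    list(maf = mac / n2, mac = mac, het = colMeans(dm == 1))
  }
  report <- list()
  if (stage == "pooled") {
    st <- variant_stats(d)
    keep <- st$maf >= 0.05 & st$mac >= 6
    report <- tibble::tibble(
      stage = "pooled", breed = NA_character_,
      filter = c("maf", "mac"),
      threshold = c(">=0.05", ">=6"),
      n_failing = c(sum(st$maf < 0.05), sum(st$mac < 6))
    )
  } else {
    breeds <- unique(g$samples$breed)
    if (anyNA(breeds)) rlang::abort("unknown (NA) breed label in sample map")
    keep <- rep(TRUE, ncol(d))
    rows <- list()
    for (b in breeds) {
      st <- variant_stats(d[g$samples$breed == b, , drop = FALSE])
      kb <- st$maf > 0.01 & st$mac > 6 & st$het < 0.99
      keep <- keep & kb
      rows[[b]] <- tibble::tibble(
        stage = "per_breed", breed = b,
        filter = c("maf", "mac", "het"),
        threshold = c(">0.01", ">6", "<0.99"),
        n_failing = c(sum(st$maf <= 0.01), sum(st$mac <= 6), sum(st$het >= 0.99))
      )
    }
    report <- dplyr::bind_rows(rows)
  }
  report <- dplyr::bind_rows(
    report,
    tibble::tibble(stage = stage, breed = NA_character_, filter = "kept",
                   threshold = "", n_failing = sum(!keep))
  )
  list(genotypes = subset_genotypes(g, variants = which(keep)), report = report)
}

#' Convert raw counts to transcripts per million
#'
#' Per sample, each gene's count is divided by its length in kb, and the
#' resulting rates are rescaled to sum to 1e6.
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param lengths optional per-gene lengths in bp (defaults to the
#'   annotation's `length` column).
#' @return An [expression_matrix()] with unit `"TPM"`.
#' @export
counts_to_tpm <- function(counts, lengths = NULL) {
  stopifnot(inherits(counts, "expression_matrix"), counts$unit == "counts")
  if (is.null(lengths)) lengths <- counts$genes$length
  if (is.null(lengths) || any(!is.finite(lengths)) || any(lengths <= 0)) {
    rlang::abort("positive gene lengths required")
  }
  rate <- counts$values / (lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    rlang::abort(paste0("zero total expression in sample(s): ",
                        paste(colnames(counts$values)[tot == 0], collapse = ", ")))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  set_unit(expression_matrix(tpm, counts$genes, unit = "TPM"), "TPM")
}

#' Remove low-expressed genes
#'
#' Drops genes with TPM <= `tpm_cutoff` in strictly more than
#' `max_low_fraction` of the samples. Intended to be applied separately per
#' tissue x breed sub-matrix.
#'
#' @param tpm an [expression_matrix()] with unit `"TPM"`.
#' @param tpm_cutoff TPM value at or below which a sample counts as "low".
#' @param max_low_fraction maximum tolerated fraction of low samples
#'   (strictly exceeded means removal).
#' @return A list with `expression` (filtered) and `report` tibble.
#' @export
filter_low_expressed <- function(tpm, tpm_cutoff = 0.1, max_low_fraction = 0.8) {
  stopifnot(inherits(tpm, "expression_matrix"), tpm$unit == "TPM")
  frac_low <- rowMeans(tpm$values <= tpm_cutoff)
  keep <- frac_low <= max_low_fraction
  out <- expression_matrix(tpm$values[keep, , drop = FALSE],
                           tpm$genes[keep, , drop = FALSE], unit = "TPM")
  list(
    expression = out,
    report = tibble::tibble(filter = "low_expression",
                            threshold = paste0("TPM<=", tpm_cutoff, " in >",
                                               100 * max_low_fraction, "%"),
                            n_removed = sum(!keep), n_kept = sum(keep))
  )
}

#' TMM normalization of counts
#'
#' Between-sample normalization by the trimmed mean of M-values, as
#' implemented in edgeR: per-sample scaling factors are weighted trimmed
#' means of gene-wise log2 expression ratios against a reference sample
#' (the sample whose upper-quartile expression is closest to the mean upper
#' quartile), trimming the 30% most extreme M-values and 5% most extreme
#' average log-abundances, with inverse-asymptotic-variance weights, and
#' rescaled to unit geometric mean. Normalized values are counts per million
#' of the effective (factor-scaled) library.
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param reference optional reference sample id (default: edgeR's automatic
#'   upper-quartile rule).
#' @return A list with `expression` (unit `"TMM"`) and `factors` (named
#'   per-sample scaling factors, geometric mean 1).
#' @export
tmm_normalize <- function(counts, reference = NULL) {
  stopifnot(inherits(counts, "expression_matrix"), counts$unit == "counts")
  lib <- colSums(counts$values)
  if (any(lib == 0)) {
    rlang::abort(paste0("zero library size in sample(s): ",
                        paste(colnames(counts$values)[lib == 0], collapse = ", ")))
  }
  ref_col <- NULL
  if (!is.null(reference)) {
    ref_col <- match(reference, colnames(counts$values))
    if (is.na(ref_col)) rlang::abort(paste0("unknown reference sample: ", reference))
  }
  f <- edgeR::calcNormFactors(counts$values, method = "TMM", refColumn = ref_col)
  names(f) <- colnames(counts$values)
  norm <- sweep(counts$values, 2, lib * f, "/") * 1e6
  list(expression = expression_matrix(norm, counts$genes, unit = "TMM"),
       factors = f)
}

# internal: Blom rank-based inverse normal transform of one vector
int_transform <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Rank-based inverse normal transform, per gene
#'
#' Maps each gene's values to normal quantiles of their Blom-offset ranks:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties given average ranks. The
#' result depends on the input only through ranks, so any monotone
#' transformation of a gene's values leaves the output unchanged.
#'
#' @param x an [expression_matrix()] (any unit) or a numeric matrix with
#'   genes in rows.
#' @return Same shape as the input; unit `"INT"` for an expression matrix.
#' @export
inverse_normal_transform <- function(x) {
  vals <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (ncol(vals) < 2) rlang::abort("need at least 2 samples")
  out <- t(apply(vals, 1, int_transform))
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "expression_matrix")) {
    expression_matrix(out, x$genes, unit = "INT")
  } else {
    out
  }
}

#' Select expression principal components as covariates
#'
#' Computes sample-space principal components of the gene-standardized
#' expression matrix and selects the smallest n >= 1 such that the gain in
#' cumulative proportion of variance explained (PVE) from PC n+1 AND from
#' PC n+2 are each below 0.1% of PVE(n) (`rule = "conjunction"`); with
#' `rule = "combined"` the two increments are summed and compared once. If
#' the rule never fires, min(10, samples - 2) PCs are selected with a
#' warning.
#'
#' @param tmm an [expression_matrix()] with unit `"TMM"` (log2 of it is
#'   taken internally before standardization).
#' @param rule increment rule, `"conjunction"` (default) or `"combined"`.
#' @param dprop increment threshold as a fraction of PVE(n).
#' @return A list of class `covariate_set`: `pcs` (samples x k), `pve`
#'   (per-PC variance shares), `k_selected`.
#' @export
select_expression_pcs <- function(tmm, rule = c("conjunction", "combined"),
                                  dprop = 0.001) {
  rule <- match.arg(rule)
  vals <- if (inherits(tmm, "expression_matrix")) tmm$values else as.matrix(tmm)
  if (ncol(vals) < 4) rlang::abort("need at least 4 samples")
  if (inherits(tmm, "expression_matrix") && tmm$unit == "TMM") {
    vals <- log2(vals + 1)
  }
  sds <- apply(vals, 1, stats::sd)
  vals <- vals[sds > 0, , drop = FALSE]
  if (!nrow(vals)) rlang::abort("degenerate expression matrix: no variable genes")
  std <- (vals - rowMeans(vals)) / apply(vals, 1, stats::sd)
  pca <- stats::prcomp(t(std), center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  ev <- ev[ev > .Machine$double.eps * ev[1]]
  pve <- ev / sum(ev)
  cum <- cumsum(pve)
  k_max <- length(pve)
  k_sel <- NA_integer_
  for (n in seq_len(max(0, k_max - 2))) {
    inc1 <- cum[n + 1] - cum[n]
    inc2 <- cum[n + 2] - cum[n + 1]
    hit <- if (rule == "conjunction") {
      inc1 < dprop * cum[n] && inc2 < dprop * cum[n]
    } else {
      (inc1 + inc2) < dprop * cum[n]
    }
    if (hit) { k_sel <- n; break }
  }
  if (is.na(k_sel)) {
    k_sel <- min(10L, ncol(vals) - 2L)
    rlang::warn(paste0("PC-increment rule never fired; selecting ", k_sel, " PCs"))
  }
  structure(
    list(pcs = pca$x[, seq_len(k_sel), drop = FALSE], pve = pve,
         k_selected = k_sel),
    class = "covariate_set"
  )
}

#' Full expression preprocessing chain for one tissue x breed
#'
#' Counts to TPM, low-expression filtering, TMM normalization of the
#' filtered counts, and the per-gene inverse normal transform — the staging
#' used before cis-eQTL mapping.
#'
#' @param counts an [expression_matrix()] with unit `"counts"` for the
#'   samples of one tissue x breed.
#' @param tpm_cutoff,max_low_fraction low-expression filter settings (see
#'   [filter_low_expressed()]).
#' @return A list: `int` (INT [expression_matrix()]), `tmm`, `tpm`,
#'   `factors`, `filter_report`.
#' @export
preprocess_expression <- function(counts, tpm_cutoff = 0.1,
                                  max_low_fraction = 0.8) {
  tpm <- counts_to_tpm(counts)
  fl <- filter_low_expressed(tpm, tpm_cutoff, max_low_fraction)
  keep <- match(fl$expression$genes$id, counts$genes$id)
  counts_f <- expression_matrix(counts$values[keep, , drop = FALSE],
                                counts$genes[keep, , drop = FALSE], "counts")
  tmm <- tmm_normalize(counts_f)
  int <- inverse_normal_transform(tmm$expression)
  list(int = int, tmm = tmm$expression, tpm = fl$expression,
       factors = tmm$factors, filter_report = fl$report)
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("<covariate_set> ", x$k_selected, " PCs over ", nrow(x$pcs),
      " samples; PVE of selected = ",
      round(sum(x$pve[seq_len(x$k_selected)]), 4), "\n", sep = "")
  invisible(x)
}
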