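#' One-vs-rest differential expression across breeds
#'
#' Compares one breed against the pooled other breeds within a tissue, per
#' gene, on the log2(TPM + 1) scale: the log2 fold change is the difference
#' of group means, the test a two-sided pooled-variance t-test, and
#' significance requires |log2FC| > 1 together with Benjamini-Hochberg
#' FDR < 0.05.
#'
#' @param tpm an [expression_matrix()] with unit `"TPM"`.
#' @param breeds character vector assigning each sample (column) to a breed.
#' @param target_breed the breed to contrast against the rest.
#' @param lfc_cutoff,fdr_cutoff significance thresholds.
#' @return A tibble of class `de_result`: gene, log2fc, t_statistic, pvalue,
#'   fdr, significant.
#' @export
differential_expression <- function(tpm, breeds, target_breed,
                                    lfc_cutoff = 1, fdr_cutoff = 0.05) {
  stopifnot(inherits(tpm, "expression_matrix"), tpm$unit == "TPM")
  breeds <- as.character(breeds)
  if (length(breeds) != ncol(tpm$values)) {
    rlang::abort("breeds must have one entry per sample")
  }
  in_target <- breeds == target_breed
  n1 <- sum(in_target)
  n2 <- sum(!in_target)
  if (n1 < 2 || n2 < 2) rlang::abort("each group needs at least 2 samples")
  x <- log2(tpm$values + 1)
  m1 <- rowMeans(x[, in_target, drop = FALSE])
  m2 <- rowMeans(x[, !in_target, drop = FALSE])
  v1 <- apply(x[, in_target, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !in_target, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  tstat[se == 0 & m1 == m2] <- 0
  pv <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  pv[!is.finite(tstat)] <- NA_real_
  pv[se == 0 & m1 == m2] <- 1
  fdr <- stats::p.adjust(pv, method = "BH")
  out <- tibble::tibble(
    gene = tpm$genes$id,
    log2fc = unname(m1 - m2),
    t_statistic = unname(tstat),
    pvalue = unname(pv),
    fdr = unname(fdr),
    significant = unname(abs(m1 - m2) > lfc_cutoff & !is.na(fdr) &
                           fdr < fdr_cutoff)
  )
  class(out) <- c("de_result", class(out))
  attr(out, "target_breed") <- target_breed
  out
}
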