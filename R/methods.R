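#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted null LMM
#'
#' @param x an `lmm_fit`.
#' @param ... unused.
#' @return A tibble of covariate effect estimates.
#' @export
tidy.lmm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$alpha), estimate = unname(x$alpha))
}

#' One-row summary of a fitted null LMM
#'
#' @param x an `lmm_fit`.
#' @param ... unused.
#' @return A tibble: sigma2_g, sigma2_e, heritability, loglik, nobs.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
    heritability = x$sigma2_g / (x$sigma2_g + x$sigma2_e),
    loglik = x$loglik, nobs = x$n
  )
}

#' Volcano plot for a differential expression result
#'
#' @param object a `de_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2fc,
                                       y = -log10(.data$pvalue),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = 2, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (target vs rest)",
                  y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Gene-level p-value / q-value overview for an eQTL run
#'
#' @param object an `eqtl_summary`.
#' @param ... unused.
#' @return A ggplot (histogram of gene-level p-values, eGenes highlighted).
#' @export
autoplot.eqtl_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_gene,
                                       fill = .data$is_egene)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05), colour = "white",
                            linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "permutation gene-level p", y = "genes",
                  fill = "eGene (q < 0.05)") +
    ggplot2::theme_minimal()
}

#' Category counts for an eGene classification
#'
#' @param object an `egene_classification`.
#' @param ... unused.
#' @return A ggplot bar chart of genes per sharing category.
#' @export
autoplot.egene_classification <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$category)
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$category,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Sharing-proportion bars
#'
#' @param object a `sharing_estimate` (rows may cover several breed pairs).
#' @param ... unused.
#' @return A ggplot comparing sign / factor-2 / factor-4 sharing.
#' @export
autoplot.sharing_estimate <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("prop_sign", "prop_mag2", "prop_mag4"),
                              names_to = "criterion", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$breed_pair,
                                     y = .data$proportion,
                                     fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = NULL, y = "sharing proportion") +
    ggplot2::theme_minimal()
}

#' Fold-enrichment display
#'
#' @param object an `enrichment_result` (rows may cover several traits or
#'   categories; a `label` column is used for the x axis if present).
#' @param ... unused.
#' @return A ggplot of fold enrichment with the empirical p annotated.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"label" %in% names(df)) df$label <- as.character(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$fold)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$empirical_p < 0.05,
                                                   "*", "")),
                       vjust = -0.3, size = 6) +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_minimal()
}

#' Posterior-probability bars for colocalization results
#'
#' @param object a `coloc_result` (one or more rows).
#' @param ... unused.
#' @return A ggplot of stacked hypothesis posteriors per gene.
#' @export
autoplot.coloc_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::starts_with("pp_"),
                              names_to = "hypothesis", values_to = "pp")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$pp,
                                     fill = .data$hypothesis)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
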