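#' Retain GWAS traits with at least one genome-wide significant SNP
#'
#' @param gwas_list named list of GWAS summary tibbles (per trait).
#' @param p_cutoff genome-wide significance threshold.
#' @return The retained subset of `gwas_list` (empty traits are dropped
#'   with a warning).
#' @export
filter_gwas_traits <- function(gwas_list, p_cutoff = 5e-8) {
  stopifnot(is.list(gwas_list))
  keep <- vapply(gwas_list, function(g) {
    if (!nrow(g)) return(FALSE)
    min(g$pvalue, na.rm = TRUE) <= p_cutoff
  }, logical(1))
  empty <- vapply(gwas_list, function(g) nrow(g) == 0, logical(1))
  if (any(empty)) {
    rlang::warn(paste0("dropping ", sum(empty), " empty trait(s)"))
  }
  gwas_list[keep]
}

#' Cis regions of an eGene set
#'
#' Builds the +/- `window` bp interval around each gene's TSS (clipped at
#' position 1), restricted to a category filter, and merges overlapping
#' intervals per chromosome so that membership testing counts each SNP
#' once.
#'
#' @param genes data frame with `id`, `chrom`, `tss` (typically the gene
#'   annotation joined with a classification).
#' @param categories optional character vector: keep genes whose `category`
#'   column starts with any of these prefixes (e.g. `"shared"`,
#'   `"specific"`); `NULL` keeps all rows.
#' @param window half-window in bp.
#' @return A tibble of merged intervals: chrom, start, end (1-based
#'   inclusive).
#' @export
egene_regions <- function(genes, categories = NULL, window = 1e6) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("chrom", "tss") %in% names(genes)))
  if (!is.null(categories)) {
    stopifnot("category" %in% names(genes))
    hit <- Reduce(`|`, lapply(categories, function(cc) {
      startsWith(genes$category, cc)
    }))
    genes <- genes[hit, , drop = FALSE]
  }
  if (!nrow(genes)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  iv <- tibble::tibble(chrom = genes$chrom,
                       start = pmax(1, genes$tss - window),
                       end = genes$tss + window)
  iv <- dplyr::arrange(iv, .data$chrom, .data$start, .data$end)
  out <- list()
  for (chr in unique(iv$chrom)) {
    sub <- iv[iv$chrom == chr, ]
    st <- sub$start[1]; en <- sub$end[1]
    merged <- list()
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] <= en + 1) {
          en <- max(en, sub$end[i])
        } else {
          merged[[length(merged) + 1]] <- c(st, en)
          st <- sub$start[i]; en <- sub$end[i]
        }
      }
    }
    merged[[length(merged) + 1]] <- c(st, en)
    m <- do.call(rbind, merged)
    out[[chr]] <- tibble::tibble(chrom = chr, start = m[, 1], end = m[, 2])
  }
  dplyr::bind_rows(out)
}

#' Membership of positions in merged regions
#'
#' @param chrom,pos vectors of positions (1-based).
#' @param regions merged intervals from [egene_regions()].
#' @return Logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  out <- logical(length(pos))
  for (chr in unique(chrom)) {
    reg <- regions[regions$chrom == chr, ]
    ii <- which(chrom == chr)
    if (!nrow(reg)) next
    # regions are sorted and disjoint: position is inside iff the latest
    # region starting at or before it also ends at or after it
    j <- findInterval(pos[ii], reg$start)
    inside <- j >= 1 & pos[ii] <= reg$end[pmax(j, 1)]
    out[ii] <- inside
  }
  out
}

#' Permutation fold enrichment of GWAS signals in eGene regions
#'
#' Significant GWAS SNPs (p <= `p_cutoff`) form the observed set; each of
#' `n_resamples` control sets samples an equal number of SNPs without
#' replacement from the non-significant pool. Fold enrichment is the
#' observed in-region proportion divided by the mean control in-region
#' proportion, and the empirical p-value is the +1-smoothed fraction of
#' control proportions at least as large as the observed one.
#'
#' @param gwas GWAS summary tibble (id, chrom, pos, pvalue, ...).
#' @param regions merged intervals from [egene_regions()].
#' @param n_resamples number of control resamples.
#' @param seed integer seed.
#' @param p_cutoff significance threshold for the observed set.
#' @return A one-row tibble of class `enrichment_result`: n_sig_snps,
#'   observed_prop, null_mean_prop, fold, empirical_p, n_resamples.
#' @export
enrichment_permutation <- function(gwas, regions, n_resamples = 1000,
                                   seed = 1, p_cutoff = 5e-8) {
  gwas <- tibble::as_tibble(gwas)
  sig <- gwas$pvalue <= p_cutoff
  if (!any(sig)) rlang::abort("no significant GWAS SNP at the cutoff")
  pool <- which(!sig)
  n_sig <- sum(sig)
  if (length(pool) < n_sig) {
    rlang::abort("non-significant pool smaller than the significant set")
  }
  member <- in_regions(gwas$chrom, gwas$pos, regions)
  observed <- mean(member[sig])
  set.seed(seed)
  null_props <- vapply(seq_len(n_resamples), function(i) {
    mean(member[sample(pool, n_sig)])
  }, numeric(1))
  null_mean <- mean(null_props)
  out <- tibble::tibble(
    n_sig_snps = n_sig,
    observed_prop = observed,
    null_mean_prop = null_mean,
    fold = if (null_mean > 0) observed / null_mean else NA_real_,
    empirical_p = (1 + sum(null_props >= observed)) / (n_resamples + 1),
    n_resamples = n_resamples
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a single association with estimate `beta`, standard error `se` and a
#' N(0, prior_sd^2) effect prior: with `V = se^2`, `W = prior_sd^2`,
#' `r = W / (V + W)` and `z = beta / se`,
#' `log ABF = 0.5 * log(1 - r) + 0.5 * r * z^2` (evidence for a non-null
#' effect relative to the null).
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param prior_sd prior effect standard deviation.
#' @return Numeric vector of log ABFs.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0) ||
      !is.finite(prior_sd) || prior_sd <= 0) {
    rlang::abort("beta, se and prior_sd must be finite with se, prior_sd > 0")
  }
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

log_sum_exp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Colocalization posteriors from two sets of summary statistics
#'
#' Enumeration-based single-causal-variant colocalization: per-SNP
#' Wakefield log-ABFs are computed for both traits over the shared SNPs,
#' and the posteriors of the five hypotheses (H0 no signal, H1 trait-1
#' only, H2 trait-2 only, H3 two distinct causal variants, H4 one shared
#' causal variant) are obtained by log-sum-exp over SNP configurations with
#' per-SNP priors `p1`, `p2` and `p12`.
#'
#' @param stats1,stats2 tibbles with columns `id`, `beta`, `se` (e.g. the
#'   cis associations of one gene and the GWAS records of its window).
#' @param p1,p2,p12 per-SNP prior probabilities of association with trait 1
#'   only, trait 2 only, and both.
#' @param prior_sd1,prior_sd2 ABF prior effect scales for the two traits.
#' @param pp4_cutoff threshold on PP.H4 for the `colocalized` flag.
#' @param gene optional gene label for error messages and output.
#' @return A one-row tibble of class `coloc_result`: gene, n_snps,
#'   pp_h0..pp_h4, colocalized.
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15, pp4_cutoff = 0.8,
                      gene = NA_character_) {
  shared <- intersect(stats1$id, stats2$id)
  if (!length(shared)) {
    rlang::abort(paste0("no shared SNPs between datasets for gene ", gene))
  }
  s1 <- stats1[match(shared, stats1$id), ]
  s2 <- stats2[match(shared, stats2$id), ]
  l1 <- wakefield_abf(s1$beta, s1$se, prior_sd1)
  l2 <- wakefield_abf(s2$beta, s2$se, prior_sd2)
  S1 <- log_sum_exp(l1)
  S2 <- log_sum_exp(l2)
  S12 <- log_sum_exp(l1 + l2)
  # sum over i != j of exp(l1_i + l2_j) = exp(S1 + S2) - exp(S12)
  both <- S1 + S2
  S3 <- if (both > S12) both + log1p(-exp(S12 - both)) else -Inf
  lh <- c(
    h0 = 0,
    h1 = log(p1) + S1,
    h2 = log(p2) + S2,
    h3 = log(p1) + log(p2) + S3,
    h4 = log(p12) + S12
  )
  pp <- exp(lh - log_sum_exp(lh))
  pp <- as.numeric(pp / sum(pp))
  out <- tibble::tibble(
    gene = gene, n_snps = length(shared),
    pp_h0 = pp[1], pp_h1 = pp[2], pp_h2 = pp[3],
    pp_h3 = pp[4], pp_h4 = pp[5],
    colocalized = pp[5] > pp4_cutoff
  )
  class(out) <- c("coloc_result", class(out))
  out
}
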