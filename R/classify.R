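#' Classify eGenes into breed-shared and breed-specific categories
#'
#' Within one tissue, a gene flagged as eGene in exactly one breed is
#' breed-specific, in exactly two breeds two-breed-shared, in all three
#' breeds three-breed-shared, and in none a non-eGene. The gene universe is
#' the union of genes tested in any breed; a gene untested in some breed is
#' classified from the available flags (noted via a message).
#'
#' @param summaries named list of `eqtl_summary` tibbles, one per breed
#'   (names are the breed labels).
#' @param tissue optional tissue label carried into the output.
#' @return A tibble of class `egene_classification`: gene, tissue, one
#'   `egene_<breed>` flag per breed, n_breeds, category.
#' @export
classify_egenes <- function(summaries, tissue = NA_character_) {
  stopifnot(is.list(summaries), length(summaries) >= 2, !is.null(names(summaries)))
  breeds <- names(summaries)
  flags <- purrr::imap(summaries, function(s, b) {
    tibble::tibble(gene = s$gene, breed = b, is_egene = s$is_egene)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "breed", values_from = "is_egene",
                       names_prefix = "egene_")
  flag_cols <- paste0("egene_", breeds)
  fm <- as.matrix(flags[, flag_cols])
  n_untested <- sum(is.na(fm))
  if (n_untested > 0) {
    rlang::inform(paste0(n_untested, " gene x breed flag(s) untested; ",
                         "classified from available flags"))
  }
  on <- matrix(FALSE, nrow(fm), ncol(fm))
  on[!is.na(fm) & fm] <- TRUE
  n_on <- rowSums(on)
  category <- character(nrow(flags))
  for (i in seq_len(nrow(flags))) {
    hit <- breeds[on[i, ]]
    category[i] <- switch(as.character(n_on[i]),
      "0" = "non_egene",
      "1" = paste0("specific(", hit, ")"),
      "2" = paste0("shared2(", paste(hit, collapse = "+"), ")"),
      "3" = "shared3"
    )
  }
  out <- dplyr::mutate(flags, tissue = tissue, n_breeds = n_on,
                       category = category, .after = "gene")
  class(out) <- c("egene_classification", class(out))
  out
}

#' Summary counts for an eGene classification
#'
#' Per-breed eGene counts, the per-breed shared fraction (eGenes of that
#' breed also detected in at least one other breed, over that breed's
#' eGenes), and counts per category.
#'
#' @param classification an [classify_egenes()] result.
#' @return A list with `per_breed` and `per_category` tibbles.
#' @export
classification_summary <- function(classification) {
  flag_cols <- grep("^egene_", names(classification), value = TRUE)
  breeds <- sub("^egene_", "", flag_cols)
  per_breed <- purrr::map2_dfr(flag_cols, breeds, function(col, b) {
    is_e <- !is.na(classification[[col]]) & classification[[col]]
    shared <- is_e & classification$n_breeds >= 2
    tibble::tibble(breed = b, n_egenes = sum(is_e), n_shared = sum(shared),
                   shared_fraction = ifelse(sum(is_e) > 0,
                                            sum(shared) / sum(is_e), NA_real_))
  })
  per_category <- dplyr::count(tibble::as_tibble(classification),
                               .data$category, name = "n_genes")
  list(per_breed = per_breed, per_category = per_category)
}

#' Lead-variant effect pairs for two breeds
#'
#' For each gene mapped in both breeds, picks the lead variant of the breed
#' with the stronger gene-level signal and extracts the effect estimate and
#' standard error at that same variant in both breeds — so the cross-breed
#' comparison is anchored on one common cis-eQTL per gene, as in
#' multivariate shrinkage analyses.
#'
#' @param map_a,map_b per-breed results from [map_cis_eqtl()] /
#'   [map_breed_eqtl()] (lists with `summaries` and `associations`).
#' @param genes optional gene subset (e.g. the breed-shared eGenes).
#' @return A tibble: gene, variant, b1, se1, b2, se2.
#' @export
pair_lead_effects <- function(map_a, map_b, genes = NULL) {
  sa <- map_a$summaries
  sb <- map_b$summaries
  common <- intersect(sa$gene, sb$gene)
  if (!is.null(genes)) common <- intersect(common, genes)
  purrr::map_dfr(common, function(gk) {
    ia <- match(gk, sa$gene)
    ib <- match(gk, sb$gene)
    lead <- if (sa$p_gene[ia] <= sb$p_gene[ib]) sa$lead_variant[ia] else sb$lead_variant[ib]
    aa <- map_a$associations
    ab <- map_b$associations
    ra <- which(aa$gene == gk & aa$variant == lead)
    rb <- which(ab$gene == gk & ab$variant == lead)
    if (!length(ra) || !length(rb)) return(NULL)
    tibble::tibble(gene = gk, variant = lead,
                   b1 = aa$beta[ra], se1 = aa$se[ra],
                   b2 = ab$beta[rb], se2 = ab$se[rb])
  })
}

#' Pairwise cross-breed effect sharing
#'
#' Restricted to effects significant (lfsr below `lfsr_cutoff`) in at least
#' one breed of the pair (or in both, with `gate = "both"`), computes the
#' fraction sharing direction (`prop_sign`) and the fractions additionally
#' within a factor 2 / factor 4 in magnitude (`prop_mag2`, `prop_mag4`),
#' using posterior-mean effects by default.
#'
#' @param effects tibble with one row per gene and columns `b1`, `b2`
#'   (effect estimates in the two breeds), `lfsr1`, `lfsr2`.
#' @param breed_pair length-2 character label for the pair.
#' @param lfsr_cutoff significance gate on the local false sign rate.
#' @param gate `"either"` (default) or `"both"`.
#' @return A one-row tibble of class `sharing_estimate`.
#' @export
pairwise_sharing <- function(effects, breed_pair = c("b1", "b2"),
                             lfsr_cutoff = 0.05, gate = c("either", "both")) {
  gate <- match.arg(gate)
  stopifnot(all(c("b1", "b2", "lfsr1", "lfsr2") %in% names(effects)))
  sig <- if (gate == "either") {
    effects$lfsr1 < lfsr_cutoff | effects$lfsr2 < lfsr_cutoff
  } else {
    effects$lfsr1 < lfsr_cutoff & effects$lfsr2 < lfsr_cutoff
  }
  e <- effects[sig & is.finite(effects$b1) & is.finite(effects$b2), ]
  if (!nrow(e)) rlang::abort("no significant effect pairs to compare")
  same_sign <- sign(e$b1) == sign(e$b2) & e$b1 != 0 & e$b2 != 0
  ratio <- pmax(abs(e$b1), abs(e$b2)) / pmin(abs(e$b1), abs(e$b2))
  out <- tibble::tibble(
    breed_pair = paste(breed_pair, collapse = "-"),
    n_effects = nrow(e),
    prop_sign = mean(same_sign),
    prop_mag2 = mean(same_sign & ratio <= 2),
    prop_mag4 = mean(same_sign & ratio <= 4)
  )
  stopifnot(out$prop_mag2 <= out$prop_mag4 + 1e-12,
            out$prop_mag4 <= out$prop_sign + 1e-12)
  class(out) <- c("sharing_estimate", class(out))
  out
}

#' Per-variant LD scores within a region
#'
#' For every variant in the region, the LD score is the sum over region
#' variants of the squared Pearson correlation of dosages, including the
#' self term (so scores are >= 1). Zero-variance variants are excluded from
#' both sides of the sum with a warning.
#'
#' @param g a [genotype_matrix()] (typically one breed).
#' @param chrom,from,to region (1-based inclusive); defaults cover all
#'   variants.
#' @return A tibble: variant, chrom, pos, ld_score.
#' @export
ld_scores <- function(g, chrom = NULL, from = -Inf, to = Inf) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 2) rlang::abort("need at least 2 samples")
  idx <- seq_len(ncol(g$dosage))
  if (!is.null(chrom)) idx <- idx[g$variants$chrom[idx] == chrom]
  idx <- idx[g$variants$pos[idx] >= from & g$variants$pos[idx] <= to]
  if (!length(idx)) rlang::abort("no variants in region")
  D <- g$dosage[, idx, drop = FALSE]
  v <- apply(D, 2, stats::var)
  if (any(v == 0)) {
    rlang::warn(paste0("excluding ", sum(v == 0),
                       " zero-variance variant(s) from LD scores"))
    idx <- idx[v > 0]
    D <- D[, v > 0, drop = FALSE]
    if (!ncol(D)) rlang::abort("no polymorphic variants in region")
  }
  r2 <- stats::cor(D)^2
  tibble::tibble(
    variant = g$variants$id[idx], chrom = g$variants$chrom[idx],
    pos = g$variants$pos[idx], ld_score = unname(rowSums(r2))
  )
}

#' Folded allele frequency per breed
#'
#' @param g a [genotype_matrix()] with breed labels.
#' @param variant_ids variants to report (default all).
#' @return A tibble: variant, breed, maf.
#' @export
maf_by_breed <- function(g, variant_ids = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(variant_ids)) variant_ids <- g$variants$id
  vi <- match(variant_ids, g$variants$id)
  if (anyNA(vi)) {
    rlang::abort(paste0("unknown variant(s): ",
                        paste(variant_ids[is.na(vi)], collapse = ", ")))
  }
  purrr::map_dfr(unique(g$samples$breed), function(b) {
    d <- g$dosage[g$samples$breed == b, vi, drop = FALSE]
    p <- colMeans(d) / 2
    tibble::tibble(variant = variant_ids, breed = b,
                   maf = unname(pmin(p, 1 - p)))
  })
}

#' Mean conservation score per gene
#'
#' Averages per-base scores of a conservation track (0-based half-open
#' intervals, e.g. converted PhastCons) over each gene body
#' (`[tss, tss + length - 1]`, 1-based inclusive, strand ignored). The mean
#' is reported only when at least `min_coverage` of the gene's length is
#' covered by the track; otherwise it is `NA`.
#'
#' @param track data frame with columns `chrom`, `start`, `end`, `score`
#'   (0-based half-open; non-overlapping within chromosome; scores in
#'   \[0, 1\]).
#' @param genes data frame with `id`, `chrom`, `tss`, `length`.
#' @param min_coverage minimum covered fraction for a defined mean.
#' @return A tibble: gene, mean_score, covered_fraction.
#' @export
gene_conservation <- function(track, genes, min_coverage = 0.5) {
  track <- tibble::as_tibble(track)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)),
            all(c("id", "chrom", "tss", "length") %in% names(genes)))
  if (any(genes$length <= 0)) rlang::abort("zero-length gene")
  purrr::pmap_dfr(genes[, c("id", "chrom", "tss", "length")],
                  function(id, chrom, tss, length) {
    # gene body in 0-based half-open coordinates
    g0 <- tss - 1
    g1 <- g0 + length
    tr <- track[track$chrom == chrom & track$end > g0 & track$start < g1, ]
    ov_start <- pmax(tr$start, g0)
    ov_end <- pmin(tr$end, g1)
    bases <- ov_end - ov_start
    covered <- sum(bases)
    frac <- covered / length
    mean_score <- if (frac >= min_coverage && covered > 0) {
      sum(bases * tr$score) / covered
    } else {
      NA_real_
    }
    tibble::tibble(gene = id, mean_score = mean_score, covered_fraction = frac)
  })
}
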