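#' Configuration for the three-breed simulation
#'
#' Bundles every knob of the synthetic cohort. Defaults emulate a balanced
#' three-breed pig design of 100 individuals per breed with moderately
#' diverged allele frequencies (Fst ~ 0.2, in the range reported between
#' commercial Duroc/Landrace/Yorkshire lines), appreciable local LD, and a
#' cis effect explaining 30% of expression variance on top of a polygenic
#' background.
#'
#' @param n_per_breed individuals per breed (3 breeds are always simulated).
#' @param n_variants biallelic SNPs on the single synthetic chromosome.
#' @param n_genes genes with TSS spread along the chromosome.
#' @param chrom_length chromosome length in bp.
#' @param fst Balding-Nichols divergence parameter, in (0, 1).
#' @param ld_rho first-order correlation of the latent haplotype field
#'   between adjacent variants, in \[0, 1).
#' @param frac_shared_egenes fraction of genes with a cis effect in more than
#'   one breed (split between three-breed and two-breed sharing, see
#'   [simulate_expression()]).
#' @param frac_specific_egenes fraction with a cis effect in exactly one breed.
#' @param cis_h2 variance share of the causal cis variant in the latent trait.
#' @param polygenic_h2 variance share of the GRM-structured background.
#' @param gwas_n GWAS sample size for simulated summary statistics.
#' @param gwas_var_explained trait variance explained by each planted GWAS
#'   causal variant.
#' @param gwas_frac_coloc fraction of selected trait signals whose causal
#'   variant is the eQTL causal variant (the rest are planted at a distinct,
#'   low-LD cis variant).
#' @param seed integer seed; all outputs are reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_breed = 100,
                       n_variants = 2500,
                       n_genes = 200,
                       chrom_length = 5e7,
                       fst = 0.2,
                       ld_rho = 0.5,
                       frac_shared_egenes = 0.7,
                       frac_specific_egenes = 0.2,
                       cis_h2 = 0.3,
                       polygenic_h2 = 0.3,
                       gwas_n = 10000,
                       gwas_var_explained = 0.005,
                       gwas_frac_coloc = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_per_breed = as.integer(n_per_breed), n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes), chrom_length = as.numeric(chrom_length),
    fst = fst, ld_rho = ld_rho,
    frac_shared_egenes = frac_shared_egenes,
    frac_specific_egenes = frac_specific_egenes,
    cis_h2 = cis_h2, polygenic_h2 = polygenic_h2,
    gwas_n = as.integer(gwas_n), gwas_var_explained = gwas_var_explained,
    gwas_frac_coloc = gwas_frac_coloc, seed = as.integer(seed)
  )
  if (!is.finite(cfg$fst) || cfg$fst <= 0 || cfg$fst >= 1) {
    rlang::abort("fst must lie strictly between 0 and 1")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) rlang::abort("ld_rho must be in [0, 1)")
  fr <- c(cfg$frac_shared_egenes, cfg$frac_specific_egenes, cfg$cis_h2,
          cfg$polygenic_h2, cfg$gwas_frac_coloc)
  if (any(fr < 0 | fr > 1)) rlang::abort("fractions must lie in [0, 1]")
  if (cfg$frac_shared_egenes + cfg$frac_specific_egenes > 1) {
    rlang::abort("frac_shared_egenes + frac_specific_egenes must be <= 1")
  }
  if (cfg$cis_h2 + cfg$polygenic_h2 >= 1) {
    rlang::abort("cis_h2 + polygenic_h2 must be < 1")
  }
  if (cfg$n_per_breed < 2 || cfg$n_variants < 2 || cfg$n_genes < 1) {
    rlang::abort("counts too small to simulate")
  }
  structure(cfg, class = "sim_config")
}

breed_names <- function() c("Duroc", "Landrace", "Yorkshire")

#' Simulate three-breed genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on \[0.05, 0.95\]; each
#' breed's frequency is drawn from the Balding-Nichols distribution
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so breed frequencies scatter around the
#' ancestral value with variance F p (1 - p). Haplotypes are generated by
#' thresholding a latent Gaussian field with first-order autocorrelation
#' `ld_rho` along the chromosome, which induces LD decaying with distance;
#' dosage is the sum of two independent haplotypes. Variants are placed at
#' even spacing along one synthetic chromosome ("chr1").
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] for `3 * n_per_breed` samples.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  n <- config$n_per_breed
  p_anc <- stats::runif(m, 0.05, 0.95)
  f <- config$fst
  shp <- (1 - f) / f
  dosage <- matrix(0L, nrow = 3L * n, ncol = m)
  breeds <- rep(breed_names(), each = n)
  for (b in 1:3) {
    p_b <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
    # keep variants segregating within the breed field; thresholds at 0/1
    # would make the latent threshold infinite
    p_b <- pmin(pmax(p_b, 1e-4), 1 - 1e-4)
    thr <- stats::qnorm(p_b)
    hap <- matrix(0L, nrow = 2L * n, ncol = m)
    z <- stats::rnorm(2L * n)
    hap[, 1] <- (z < thr[1]) + 0L
    rho <- config$ld_rho
    sd_innov <- sqrt(1 - rho^2)
    for (j in 2:m) {
      z <- rho * z + stats::rnorm(2L * n, sd = sd_innov)
      hap[, j] <- (z < thr[j]) + 0L
    }
    rows <- ((b - 1L) * n + 1L):(b * n)
    dosage[rows, ] <- hap[seq_len(n), ] + hap[n + seq_len(n), ]
  }
  pos <- round(seq(1, config$chrom_length, length.out = m))
  variants <- tibble::tibble(
    id = sprintf("snp%05d", seq_len(m)), chrom = "chr1", pos = pos,
    ref = "A", alt = "G"
  )
  samples <- tibble::tibble(
    id = sprintf("%s_%03d", breeds, rep(seq_len(n), times = 3)),
    breed = breeds
  )
  genotype_matrix(dosage, variants, samples)
}

# internal: draw gene categories in the configured fractions.
# Shared genes are split 2:1 between three-breed and two-breed sharing, the
# pair drawn uniformly; the remainder after shared + specific is null.
draw_categories <- function(n_genes, frac_shared, frac_specific) {
  n_shared <- round(frac_shared * n_genes)
  n_specific <- round(frac_specific * n_genes)
  if (n_shared + n_specific > n_genes) n_specific <- n_genes - n_shared
  n_null <- n_genes - n_shared - n_specific
  n_shared3 <- round(2 / 3 * n_shared)
  n_shared2 <- n_shared - n_shared3
  br <- breed_names()
  pairs <- utils::combn(br, 2, paste, collapse = "+")
  cats <- c(
    rep("shared3", n_shared3),
    if (n_shared2 > 0) paste0("shared2(", sample(pairs, n_shared2, replace = TRUE), ")"),
    if (n_specific > 0) paste0("specific(", sample(br, n_specific, replace = TRUE), ")"),
    rep("null", n_null)
  )
  sample(cats)
}

category_breeds <- function(category) {
  if (category == "shared3") return(breed_names())
  if (startsWith(category, "shared2")) {
    return(strsplit(sub("^shared2\\((.*)\\)$", "\\1", category), "\\+")[[1]])
  }
  if (startsWith(category, "specific")) {
    return(sub("^specific\\((.*)\\)$", "\\1", category))
  }
  character(0)
}

#' Simulate expression counts with planted cis effects
#'
#' For each gene a latent trait is built per breed as
#' `beta * centered causal dosage + polygenic + noise`, with the causal term
#' scaled so it explains `cis_h2` of the latent variance (zero for null
#' genes/breeds), the polygenic term drawn from N(0, G_b * polygenic_h2)
#' using the breed's realized genomic relationship matrix, and independent
#' Gaussian noise filling the remainder to unit variance. Counts are then
#' generated through a monotone positive link: a log-normal gene baseline
#' times `exp(latent)`, times a log-normal sample library-size factor, fed
#' through a Poisson draw. Only monotonicity of the link is relied on
#' downstream.
#'
#' The causal variant is drawn among variants within 1 Mb of the gene's TSS
#' that are common (MAF >= 0.05) in every breed — so planted causals stay in
#' the per-breed QC'd common panel the mapper scans; shared genes use the
#' same causal variant and sign-concordant effects in all their breeds.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return A list with `expression` (counts [expression_matrix()]) and
#'   `truth` (tibble: gene, category, per-breed causal variant and true beta).
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (3L * config$n_per_breed != nrow(genotypes$dosage)) {
    rlang::abort("genotype panel does not match config sample counts")
  }
  if (config$n_variants != ncol(genotypes$dosage)) {
    rlang::abort("genotype panel does not match config variant count")
  }
  set.seed(config$seed + 1L)
  n_genes <- config$n_genes
  br <- breed_names()
  n <- config$n_per_breed
  idx_breed <- split(seq_len(3L * n), genotypes$samples$breed)[br]

  # TSS evenly spread, away from the chromosome ends so cis windows are full
  tss <- round(seq(0.02, 0.98, length.out = n_genes) * config$chrom_length)
  genes <- tibble::tibble(
    id = sprintf("gene%04d", seq_len(n_genes)), chrom = "chr1", tss = tss,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    length = round(stats::runif(n_genes, 500, 5000))
  )

  # candidate causal variants must be common in every breed, so they remain
  # in the per-breed QC'd common panel the mapper actually scans
  breed_maf <- sapply(idx_breed, function(ii) {
    p <- colMeans(genotypes$dosage[ii, , drop = FALSE]) / 2
    pmin(p, 1 - p)
  })
  causal_ok <- apply(breed_maf, 1, min) >= 0.05
  categories <- draw_categories(n_genes, config$frac_shared_egenes,
                                config$frac_specific_egenes)

  # per-breed GRM Cholesky-type factor for the polygenic term
  poly_fac <- lapply(idx_breed, function(ii) {
    d <- genotypes$dosage[ii, , drop = FALSE]
    poly <- which(colMeans(d) > 0 & colMeans(d) < 2)
    G <- compute_grm(subset_genotypes(genotypes, samples = ii, variants = poly))$values
    eg <- eigen(G, symmetric = TRUE)
    eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  })

  latent <- matrix(0, nrow = n_genes, ncol = 3L * n)
  truth <- vector("list", n_genes)
  h2c <- config$cis_h2
  h2g <- config$polygenic_h2
  for (g in seq_len(n_genes)) {
    cat_g <- categories[g]
    eff_breeds <- category_breeds(cat_g)
    cis <- which(genotypes$variants$chrom == genes$chrom[g] &
                   abs(genotypes$variants$pos - genes$tss[g]) <= 1e6 &
                   causal_ok)
    if (!length(cis)) cat_g <- "null"
    causal <- if (length(eff_breeds) && length(cis)) sample(cis, 1L) else NA_integer_
    sign_g <- sample(c(-1, 1), 1L)
    beta_b <- stats::setNames(rep(NA_real_, 3), br)
    causal_b <- stats::setNames(rep(NA_character_, 3), br)
    for (b in br) {
      ii <- idx_breed[[b]]
      y <- rep(0, length(ii))
      has_eff <- b %in% eff_breeds && !is.na(causal) && h2c > 0
      if (has_eff) {
        s <- genotypes$dosage[ii, causal]
        s <- s - mean(s)
        v <- mean(s^2)
        if (v > 1e-8) {
          beta <- sign_g * sqrt(h2c / v)
          y <- y + beta * s
          beta_b[b] <- beta
          causal_b[b] <- genotypes$variants$id[causal]
        } else {
          has_eff <- FALSE
        }
      }
      if (h2g > 0) {
        y <- y + sqrt(h2g) * as.numeric(poly_fac[[b]] %*% stats::rnorm(length(ii)))
      }
      noise_var <- 1 - h2g - if (has_eff) h2c else 0
      y <- y + stats::rnorm(length(ii), sd = sqrt(noise_var))
      latent[g, ii] <- y
    }
    truth[[g]] <- tibble::tibble(
      gene = genes$id[g], category = cat_g,
      breed = br, causal_variant = unname(causal_b), true_beta = unname(beta_b)
    )
  }

  baseline <- exp(stats::rnorm(n_genes, mean = 4, sd = 1))
  libfac <- exp(stats::rnorm(3L * n, mean = 0, sd = 0.2))
  mu <- (baseline * exp(latent)) * rep(libfac, each = n_genes)
  counts <- matrix(stats::rpois(length(mu), lambda = mu), nrow = n_genes)
  colnames(counts) <- genotypes$samples$id

  list(
    expression = expression_matrix(counts, genes, unit = "counts"),
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate GWAS summary statistics with planted shared causal variants
#'
#' Builds one synthetic quantitative trait. Trait loci are a sparse
#' selection of genes with a true cis effect, chosen so that selected causal
#' variants are at least `min_spacing` bp apart (real complex-trait signals
#' are sparse on a chromosome, and the single-causal-variant assumption of
#' enumeration colocalization requires one signal per cis window). Among the
#' selected genes, a fraction `gwas_frac_coloc` contributes its eQTL causal
#' variant as the trait causal variant; each remaining selected gene
#' contributes a distinct cis variant chosen to have r^2 < 0.2 with the
#' eQTL variant. Each causal variant explains `gwas_var_explained` of trait
#' variance.
#' Marginal (single-SNP) effects are propagated through the pooled genotype
#' correlation structure, so z-scores of variants in LD with a causal
#' variant are inflated accordingly; the estimate for each variant is then
#' drawn as `beta_hat ~ N(beta_marginal, se^2)` with
#' `se^2 = 1 / (2 n p (1 - p))` (unit trait variance).
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth the truth tibble from [simulate_expression()].
#' @param config the same [sim_config()].
#' @param seed seed for this trait (several traits can be generated from one
#'   cohort by varying it); defaults to `config$seed + 2`.
#' @param min_spacing minimum distance between selected trait loci in bp.
#' @return A list with `gwas` (tibble: id, chrom, pos, beta, se, pvalue, n)
#'   and `trait_truth` (tibble: gene, eqtl_variant, trait_variant, shared).
#' @export
simulate_gwas <- function(genotypes, truth, config, seed = NULL,
                          min_spacing = 2.5e6) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (config$gwas_n <= 0) rlang::abort("gwas_n must be positive")
  set.seed(if (is.null(seed)) config$seed + 2L else as.integer(seed))
  D <- genotypes$dosage
  m <- ncol(D)
  p <- colMeans(D) / 2
  sdg <- sqrt(2 * p * (1 - p))
  Zs <- scale(D)

  eff <- truth |>
    dplyr::filter(!is.na(.data$causal_variant)) |>
    dplyr::distinct(.data$gene, .data$causal_variant)
  # sparse selection: greedily keep genes whose causal variants are at
  # least min_spacing apart, in a random order
  if (nrow(eff) > 0) {
    eff <- eff[sample(nrow(eff)), ]
    cpos <- genotypes$variants$pos[match(eff$causal_variant,
                                         genotypes$variants$id)]
    keep <- logical(nrow(eff))
    taken <- numeric(0)
    for (k in seq_len(nrow(eff))) {
      if (!length(taken) || min(abs(taken - cpos[k])) >= min_spacing) {
        keep[k] <- TRUE
        taken <- c(taken, cpos[k])
      }
    }
    eff <- eff[keep, ]
  }
  n_sel <- nrow(eff)
  shared_flag <- logical(0)
  trait_var <- character(0)
  if (n_sel > 0) {
    # distinct trait variants must sit inside the focal gene's cis window
    # (the tested region) and be common in every breed so they survive QC
    tss_all <- round(seq(0.02, 0.98, length.out = config$n_genes) *
                       config$chrom_length)
    gene_order <- sort(unique(truth$gene))
    breed_maf <- sapply(split(seq_len(nrow(D)), genotypes$samples$breed),
                        function(ii) {
                          pb <- colMeans(D[ii, , drop = FALSE]) / 2
                          pmin(pb, 1 - pb)
                        })
    common_all <- apply(breed_maf, 1, min) >= 0.05
    n_coloc <- round(config$gwas_frac_coloc * n_sel)
    shared_flag <- seq_len(n_sel) %in% sample(n_sel, n_coloc)
    trait_var <- character(n_sel)
    for (k in seq_len(n_sel)) {
      j <- match(eff$causal_variant[k], genotypes$variants$id)
      if (shared_flag[k]) {
        trait_var[k] <- eff$causal_variant[k]
      } else {
        tss_k <- tss_all[match(eff$gene[k], gene_order)]
        win <- which(abs(genotypes$variants$pos - tss_k) <= 1e6 & common_all)
        r2 <- as.numeric(stats::cor(Zs[, j], Zs[, win]))^2
        cand <- win[r2 < 0.2]
        trait_var[k] <- if (length(cand)) {
          genotypes$variants$id[sample(cand, 1L)]
        } else NA_character_
      }
    }
  }
  causal_idx <- match(stats::na.omit(unique(trait_var)), genotypes$variants$id)

  beta_std <- rep(0, m)
  if (length(causal_idx)) {
    bc <- sqrt(config$gwas_var_explained)
    # marginal standardized effect = LD correlation times causal effect;
    # correlations are propagated only within +/- 2 Mb of each causal
    # variant — LD is local under the AR(1) haplotype field, and sample
    # correlations beyond it are reference-panel noise that would leak
    # spurious signal into distant null variants
    for (j in causal_idx) {
      near <- which(abs(genotypes$variants$pos - genotypes$variants$pos[j]) <= 2e6)
      r <- as.numeric(stats::cor(Zs[, near, drop = FALSE], Zs[, j]))
      r[!is.finite(r)] <- 0
      beta_std[near] <- beta_std[near] + r * bc
    }
  }
  # monomorphic variants carry no information; give them a tiny frequency so
  # se stays finite (they are removed by QC in any real run)
  sdg[sdg == 0] <- sqrt(2 * (1 / (2 * nrow(D))) * (1 - 1 / (2 * nrow(D))))
  n <- config$gwas_n
  se <- 1 / (sdg * sqrt(n))
  beta_true <- beta_std / sdg
  beta_hat <- stats::rnorm(m, mean = beta_true, sd = se)
  z <- beta_hat / se
  gwas <- tibble::tibble(
    id = genotypes$variants$id, chrom = genotypes$variants$chrom,
    pos = genotypes$variants$pos,
    beta = beta_hat, se = se,
    pvalue = 2 * stats::pnorm(-abs(z)), n = n
  )
  trait_truth <- if (n_sel > 0) {
    tibble::tibble(gene = eff$gene, eqtl_variant = eff$causal_variant,
                   trait_variant = trait_var, shared = shared_flag)
  } else {
    tibble::tibble(gene = character(), eqtl_variant = character(),
                   trait_variant = character(), shared = logical())
  }
  list(gwas = gwas, trait_truth = trait_truth)
}
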