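#' One-breed end-to-end mapping from counts and QC'd genotypes
#'
#' Convenience driver for a single breed of a stratified design: subsets
#' samples to the breed, runs the expression chain
#' ([preprocess_expression()]), builds the breed GRM and maps cis-eQTLs
#' ([map_cis_eqtl()]).
#'
#' @param genotypes a [genotype_matrix()] (all breeds, post-QC variants).
#' @param counts an [expression_matrix()] of raw counts over the same
#'   samples.
#' @param breed breed label to analyse.
#' @param covariates covariates forwarded to [map_cis_eqtl()].
#' @param ... further arguments to [map_cis_eqtl()] (`k_perm`, `seed`, ...).
#' @return The [map_cis_eqtl()] result, plus `breed` and the preprocessing
#'   stage outputs.
#' @export
map_breed_eqtl <- function(genotypes, counts, breed, covariates = NULL, ...) {
  stopifnot(breed %in% genotypes$samples$breed)
  ii <- which(genotypes$samples$breed == breed)
  gb <- subset_genotypes(genotypes, samples = ii)
  keep_var <- which(apply(gb$dosage, 2, stats::var) > 0)
  gb <- subset_genotypes(gb, variants = keep_var)
  pp <- preprocess_expression(subset_expr(counts, samples = ii))
  res <- map_cis_eqtl(pp$int, gb, covariates = covariates, ...)
  c(res, list(breed = breed, preprocess = pp))
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM: `G = M M' / (2 * sum p_i (1 - p_i))`, with `M` the
#' column-centered dosage matrix and `p_i` each variant's allele frequency.
#' Built from genome-wide post-QC variants of one population; monomorphic
#' variants are not allowed (their denominator contribution is zero), so QC
#' must precede.
#'
#' @param g a [genotype_matrix()] for one breed, post-QC.
#' @return A list of class `grm_matrix` with `values` (n x n) and `denom`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosage) / 2
  if (any(p == 0 | p == 1)) {
    rlang::abort("monomorphic variant present; run genotype QC first")
  }
  M <- sweep(g$dosage, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  structure(list(values = tcrossprod(M) / denom, denom = denom),
            class = "grm_matrix")
}

#' @export
print.grm_matrix <- function(x, ...) {
  cat("<grm_matrix> ", nrow(x$values), " x ", ncol(x$values),
      "; mean diagonal = ", round(mean(diag(x$values)), 3), "\n", sep = "")
  invisible(x)
}

#' Eigendecomposition of a GRM, reusable across genes
#'
#' Numerically non-PSD matrices are repaired by flooring eigenvalues at
#' 1e-8 with a warning.
#'
#' @param grm a `grm_matrix` (or plain symmetric matrix).
#' @return A list with `U` (eigenvectors) and `d` (eigenvalues).
#' @export
grm_eigen <- function(grm) {
  G <- if (inherits(grm, "grm_matrix")) grm$values else as.matrix(grm)
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    rlang::warn("GRM is numerically non-PSD; flooring eigenvalues at 1e-8")
  }
  list(U = e$vectors, d = pmax(e$values, 1e-8))
}

# internal: restricted log-likelihood of the variance-ratio parameterization.
# delta = sigma2_g / sigma2_e; yt, Xt already rotated by U'.
reml_loglik <- function(delta, yt, Xt, d) {
  n <- length(yt)
  c_ <- ncol(Xt)
  w <- 1 / (delta * d + 1)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qrX <- qr(Xw)
  rss <- sum(qr.resid(qrX, yw)^2)
  sigma2e <- rss / (n - c_)
  ldXWX <- sum(log(abs(diag(qr.R(qrX))^2)))
  -0.5 * ((n - c_) * (log(2 * pi) + log(sigma2e) + 1) +
            sum(log(delta * d + 1)) + ldXWX)
}

#' Fit the null linear mixed model for one gene
#'
#' Model: `y = X alpha + g + e` with `g ~ N(0, G sigma2_g)` and
#' `e ~ N(0, I sigma2_e)`. REML estimation works in the eigenbasis of `G`:
#' the variance ratio `delta = sigma2_g / sigma2_e` is profiled on a
#' log-scale grid and refined by golden-section search; `alpha` is the
#' generalized-least-squares solution at the optimum. The returned object
#' caches the rotation and weights so cis scans and permutations reuse them
#' with variance components held fixed.
#'
#' @param y numeric response (typically an INT expression vector).
#' @param covariates a `covariate_set`, a numeric matrix (samples x k), or
#'   `NULL`; an intercept column is always added.
#' @param grm a `grm_matrix` (ignored if `eig` given).
#' @param eig optional precomputed [grm_eigen()] result.
#' @return A list of class `lmm_fit` with `sigma2_g`, `sigma2_e`, `alpha`,
#'   `loglik`, and cached rotation pieces.
#' @export
fit_null_lmm <- function(y, covariates = NULL, grm = NULL, eig = NULL) {
  if (is.null(eig)) eig <- grm_eigen(grm)
  n <- length(y)
  stopifnot(all(is.finite(y)), nrow(eig$U) == n)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    pcs <- if (inherits(covariates, "covariate_set")) covariates$pcs else as.matrix(covariates)
    stopifnot(nrow(pcs) == n)
    X <- cbind(X, pcs)
  }
  yt <- as.numeric(crossprod(eig$U, y))
  Xt <- crossprod(eig$U, X)
  ll_log10 <- function(l10) reml_loglik(10^l10, yt, Xt, eig$d)
  grid <- seq(-6, 5, length.out = 23)
  ll_grid <- vapply(grid, ll_log10, numeric(1))
  ll0 <- reml_loglik(0, yt, Xt, eig$d)
  best <- which.max(ll_grid)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(ll_log10, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  if (ll0 >= opt$objective) {
    delta <- 0
    loglik <- ll0
  } else {
    delta <- 10^opt$maximum
    loglik <- opt$objective
  }
  w <- 1 / (delta * eig$d + 1)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  qrX <- qr(Xw)
  cfs <- qr.coef(qrX, yw)
  rss <- sum(qr.resid(qrX, yw)^2)
  sigma2e <- rss / (n - ncol(X))
  structure(
    list(
      sigma2_g = delta * sigma2e, sigma2_e = sigma2e, delta = delta,
      alpha = stats::setNames(as.numeric(cfs), colnames(X)),
      loglik = loglik,
      U = eig$U, d = eig$d, sw = sw, Xw = Xw, qrXw = qrX, yw = yw,
      n = n, n_covar = ncol(X)
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  h2 <- x$sigma2_g / (x$sigma2_g + x$sigma2_e)
  cat("<lmm_fit> sigma2_g = ", signif(x$sigma2_g, 4), ", sigma2_e = ",
      signif(x$sigma2_e, 4), " (h2 = ", round(h2, 3), "), REML loglik = ",
      round(x$loglik, 3), "\n", sep = "")
  invisible(x)
}

# internal: Wald statistics for centered regressors S against responses Y
# (both in original sample space) with variance components fixed at the fit.
# Returns list(beta, se, p) of dimension (variants x responses).
scan_stats <- function(fit, S, Y) {
  Sw <- crossprod(fit$U, S) * fit$sw
  Yw <- crossprod(fit$U, Y) * fit$sw
  Sr <- qr.resid(fit$qrXw, Sw)
  Yr <- qr.resid(fit$qrXw, Yw)
  ss <- colSums(Sr^2)
  yss <- colSums(Yr^2)
  cross <- crossprod(Sr, Yr)
  beta <- cross / ss
  df <- fit$n - fit$n_covar - 1
  rss <- sweep(-beta^2 * ss, 2, yss, "+")
  rss[rss < 0] <- 0
  se <- sqrt(rss / (df * ss))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(beta = beta, se = se, p = p)
}

# internal: indices and centered dosages of cis variants for one gene;
# zero-variance variants within the sample subset are excluded.
cis_variants <- function(genotypes, chrom, tss, window = 1e6) {
  idx <- which(genotypes$variants$chrom == chrom &
                 genotypes$variants$pos >= tss - window &
                 genotypes$variants$pos <= tss + window)
  if (!length(idx)) return(list(idx = integer(0), S = NULL))
  S <- genotypes$dosage[, idx, drop = FALSE]
  S <- sweep(S, 2, colMeans(S))
  v <- colMeans(S^2)
  keep <- v > 1e-10
  list(idx = idx[keep], S = S[, keep, drop = FALSE])
}

#' Cis-window association scan for one gene
#'
#' Tests every variant within `window` bp of the gene's TSS (both boundaries
#' inclusive; the window ignores strand) with a Wald test of the variant
#' effect, variance components fixed at the null fit. The regressor is the
#' mean-centered dosage.
#'
#' @param fit an [fit_null_lmm()] result (its `yw` is the gene's rotated,
#'   weighted expression).
#' @param y the gene's expression vector (same one the fit used).
#' @param genotypes a [genotype_matrix()] aligned to the fit's samples.
#' @param gene one-row data frame (or list) with `id`, `chrom`, `tss`.
#' @param window cis window half-width in bp.
#' @return A tibble: gene, variant, beta, se, p_nominal (empty, with a
#'   message, when the window holds no variant).
#' @export
test_cis <- function(fit, y, genotypes, gene, window = 1e6) {
  cv <- cis_variants(genotypes, gene$chrom, gene$tss, window)
  if (!length(cv$idx)) {
    rlang::inform(paste0("no cis variants for gene ", gene$id))
    return(tibble::tibble(gene = character(), variant = character(),
                          beta = numeric(), se = numeric(),
                          p_nominal = numeric()))
  }
  st <- scan_stats(fit, cv$S, matrix(y, ncol = 1))
  tibble::tibble(
    gene = gene$id,
    variant = genotypes$variants$id[cv$idx],
    beta = as.numeric(st$beta), se = as.numeric(st$se),
    p_nominal = as.numeric(st$p)
  )
}

#' Permutation gene-level p-value
#'
#' Permutes the expression vector `k_perm` times, re-runs the cis scan with
#' variance components fixed, and records the minimum nominal p of each
#' permutation. The gene-level p is the +1-smoothed empirical tail
#' probability `(1 + #\{perm min-p <= observed\}) / (k_perm + 1)`; with
#' `beta_approx = TRUE` a Beta(a, b) distribution is fitted to the permuted
#' min-p by maximum likelihood and the smoothed `pbeta` value is returned
#' instead.
#'
#' @inheritParams test_cis
#' @param k_perm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param beta_approx use the Beta-fitted smoothed p.
#' @return A list: `p_gene`, `min_p_observed`, `perm_min_p` (length
#'   `k_perm`), `beta_shape` (NULL unless `beta_approx`).
#' @export
permutation_gene_p <- function(fit, y, genotypes, gene, k_perm = 1000,
                               seed = 1, window = 1e6, beta_approx = FALSE) {
  if (k_perm < 100) rlang::abort("k_perm must be at least 100")
  cv <- cis_variants(genotypes, gene$chrom, gene$tss, window)
  if (!length(cv$idx)) rlang::abort(paste0("no cis variants for gene ", gene$id))
  obs <- min(scan_stats(fit, cv$S, matrix(y, ncol = 1))$p)
  set.seed(seed)
  n <- length(y)
  P <- vapply(seq_len(k_perm), function(i) y[sample.int(n)], numeric(n))
  perm_min <- apply(scan_stats(fit, cv$S, P)$p, 2, min)
  p_emp <- (1 + sum(perm_min <= obs)) / (k_perm + 1)
  shape <- NULL
  p_gene <- p_emp
  if (beta_approx) {
    x <- pmin(pmax(perm_min, 1e-12), 1 - 1e-12)
    nll <- function(par) -sum(stats::dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
    o <- stats::optim(c(0, log(max(1, length(cv$idx) / 2))), nll)
    shape <- exp(o$par)
    p_gene <- stats::pbeta(obs, shape[1], shape[2])
    p_gene <- max(p_gene, .Machine$double.xmin)
  }
  list(p_gene = p_gene, min_p_observed = obs, perm_min_p = perm_min,
       beta_shape = shape)
}

#' Call eGenes by Benjamini-Hochberg correction of gene-level p-values
#'
#' Computes BH q-values across genes (within one tissue x breed run), flags
#' eGenes at `q < q_cutoff`, and derives each eGene's nominal-p
#' significance threshold for its cis variants: the empirical quantile of
#' the gene's permuted min-p distribution at the largest gene-level p that
#' still satisfies the q cutoff.
#'
#' @param summaries tibble with columns `gene`, `p_gene`, and (optionally)
#'   `perm_min_p` (list-column of permuted min-p vectors).
#' @param q_cutoff eGene significance threshold on the q-value.
#' @return The input tibble with `q_value`, `is_egene`, `variant_threshold`
#'   added, of class `eqtl_summary`.
#' @export
call_egenes <- function(summaries, q_cutoff = 0.05) {
  summaries <- tibble::as_tibble(summaries)
  if (!nrow(summaries)) rlang::abort("no gene-level p-values supplied")
  stopifnot(all(c("gene", "p_gene") %in% names(summaries)))
  q <- stats::p.adjust(summaries$p_gene, method = "BH")
  is_egene <- q < q_cutoff
  thr <- rep(NA_real_, nrow(summaries))
  if (any(is_egene) && "perm_min_p" %in% names(summaries)) {
    p_star <- max(summaries$p_gene[is_egene])
    thr[is_egene] <- vapply(which(is_egene), function(i) {
      stats::quantile(summaries$perm_min_p[[i]], probs = p_star, type = 1,
                      names = FALSE)
    }, numeric(1))
  }
  out <- dplyr::mutate(summaries, q_value = q, is_egene = is_egene,
                       variant_threshold = thr)
  class(out) <- c("eqtl_summary", class(out))
  out
}

#' Map cis-eQTLs for one breed and tissue
#'
#' Runs the whole per-breed chain: null LMM per gene (REML with the GRM),
#' cis-window Wald scan, permutation gene-level p-values, and BH eGene
#' calling. Expression must already be preprocessed to INT units and the
#' genotypes QC'd.
#'
#' @param expr an [expression_matrix()] with unit `"INT"`, samples matching
#'   `genotypes`.
#' @param genotypes a [genotype_matrix()] for the same samples.
#' @param covariates a `covariate_set`, matrix, or `NULL`.
#' @param grm optional precomputed `grm_matrix` (default: from `genotypes`).
#' @param k_perm permutations per gene.
#' @param seed integer seed; each gene uses `seed + gene index`.
#' @param window cis half-window in bp.
#' @param q_cutoff eGene q-value threshold.
#' @param beta_approx use Beta-smoothed permutation p-values.
#' @return A list with `summaries` (an `eqtl_summary` tibble: gene, lead
#'   variant/beta/se, min nominal p, gene-level p, q, eGene flag, variant
#'   threshold) and `associations` (all cis tests).
#' @export
map_cis_eqtl <- function(expr, genotypes, covariates = NULL, grm = NULL,
                         k_perm = 1000, seed = 1, window = 1e6,
                         q_cutoff = 0.05, beta_approx = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(genotypes, "genotype_matrix"),
            ncol(expr$values) == nrow(genotypes$dosage))
  if (expr$unit != "INT") {
    rlang::warn("expression unit is not INT; mapping on values as given")
  }
  if (is.null(grm)) grm <- compute_grm(genotypes)
  eig <- grm_eigen(grm)
  rows <- vector("list", nrow(expr$values))
  assoc <- vector("list", nrow(expr$values))
  for (i in seq_len(nrow(expr$values))) {
    gene <- expr$genes[i, ]
    y <- expr$values[i, ]
    cv <- cis_variants(genotypes, gene$chrom, gene$tss, window)
    if (!length(cv$idx)) next
    fit <- fit_null_lmm(y, covariates, eig = eig)
    a <- test_cis(fit, y, genotypes, gene, window)
    pg <- permutation_gene_p(fit, y, genotypes, gene, k_perm = k_perm,
                             seed = seed + i, window = window,
                             beta_approx = beta_approx)
    lead <- which.min(a$p_nominal)
    gene_id <- gene$id; gene_chrom <- gene$chrom; gene_tss <- gene$tss
    rows[[i]] <- tibble::tibble(
      gene = gene_id, chrom = gene_chrom, tss = gene_tss,
      lead_variant = a$variant[lead], lead_beta = a$beta[lead],
      lead_se = a$se[lead], min_p_nominal = a$p_nominal[lead],
      p_gene = pg$p_gene, n_cis_variants = nrow(a),
      perm_min_p = list(pg$perm_min_p)
    )
    assoc[[i]] <- a
  }
  summaries <- dplyr::bind_rows(rows)
  if (!nrow(summaries)) rlang::abort("no gene had cis variants")
  summaries <- call_egenes(summaries, q_cutoff = q_cutoff)
  list(summaries = summaries, associations = dplyr::bind_rows(assoc))
}
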