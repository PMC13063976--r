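test_that("GRM matches the closed form and a double-loop oracle", {
  g1 <- toy_genotypes(matrix(c(0L, 1L, 2L), ncol = 1))
  G <- compute_grm(g1)
  expect_equal(G$values,
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(20)
  d <- matrix(rbinom(30 * 40, 2, runif(40, 0.1, 0.9)), nrow = 30, byrow = TRUE)
  d <- d[, apply(d, 2, function(x) length(unique(x)) > 1)]
  g <- toy_genotypes(d)
  G <- compute_grm(g)$values
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, nrow(d), nrow(d))
  for (i in seq_len(nrow(d))) for (j in seq_len(nrow(d))) {
    oracle[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p)) / denom
  }
  expect_equal(G, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(compute_grm(toy_genotypes(matrix(c(0L, 0L, 0L), ncol = 1))),
               "monomorphic")
})

test_that("GRM diagonal averages one over many independent variants", {
  cfg <- sim_config(n_per_breed = 80, n_variants = 1000, fst = 0.05,
                    ld_rho = 0, chrom_length = 2e7, seed = 30)
  g <- simulate_genotypes(cfg)
  ii <- g$samples$breed == "Duroc"
  d <- g$dosage[ii, ]
  d <- d[, apply(d, 2, var) > 0]
  G <- compute_grm(toy_genotypes(d))$values
  expect_equal(mean(diag(G)), 1, tolerance = 0.1)
})

test_that("with an identity GRM the mapper reduces to an OLS scan", {
  set.seed(21)
  n <- 60
  d <- matrix(rbinom(n * 25, 2, 0.4), nrow = n)
  d <- d[, apply(d, 2, var) > 0]
  g <- toy_genotypes(d, pos = seq_len(ncol(d)) * 100L)
  y <- rnorm(n)
  eig <- grm_eigen(diag(n))
  fit <- fit_null_lmm(y, NULL, eig = eig)
  # variance decomposition covers total variance, alpha is the OLS intercept
  expect_equal(fit$sigma2_g + fit$sigma2_e, var(y), tolerance = 1e-6)
  expect_equal(unname(fit$alpha[1]), mean(y), tolerance = 1e-8)

  gene <- list(id = "g1", chrom = "chr1", tss = 1200)
  a <- test_cis(fit, y, g, gene, window = 1e6)
  for (k in seq_len(nrow(a))) {
    ols <- summary(lm(y ~ d[, match(a$variant[k], g$variants$id)]))
    expect_equal(a$beta[k], ols$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(a$se[k], ols$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(a$p_nominal[k], ols$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("REML optimum beats a brute-force grid on the restricted likelihood", {
  cfg <- sim_config(n_per_breed = 60, n_variants = 500, chrom_length = 1e7,
                    ld_rho = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  d <- g$dosage[g$samples$breed == "Duroc", ]
  d <- d[, apply(d, 2, var) > 0]
  G <- compute_grm(toy_genotypes(d))
  eig <- grm_eigen(G)
  set.seed(31)
  y <- as.numeric(eig$U %*% (sqrt(0.5 * eig$d + 0.5) * rnorm(60)))
  fit <- fit_null_lmm(y, NULL, eig = eig)
  yt <- as.numeric(crossprod(eig$U, y))
  Xt <- crossprod(eig$U, matrix(1, 60, 1))
  grid_ll <- vapply(10^seq(-6, 5, length.out = 100), function(delta) {
    breedeqtl:::reml_loglik(delta, yt, Xt, eig$d)
  }, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
})

test_that("the heritability ratio is recovered on structured GRMs", {
  cfg <- sim_config(n_per_breed = 100, n_variants = 1200, chrom_length = 2.4e7,
                    seed = 32)
  g <- simulate_genotypes(cfg)
  g <- subset_genotypes(g, variants = which(apply(g$dosage, 2, var) > 0))
  G <- compute_grm(g)   # pooled three-breed GRM: strong eigen structure
  eig <- grm_eigen(G)
  n <- nrow(G$values)
  set.seed(32)
  h2_hat <- replicate(12, {
    y <- as.numeric(eig$U %*% (sqrt(0.5 * eig$d + 0.5) * rnorm(n)))
    f <- fit_null_lmm(y, NULL, eig = eig)
    f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  })
  expect_equal(mean(h2_hat), 0.5, tolerance = 0.15)
})

test_that("cis window boundaries are inclusive at exactly 1 Mb", {
  n <- 40
  set.seed(22)
  d <- matrix(rbinom(n * 3, 2, 0.5), nrow = n)
  g <- toy_genotypes(d, pos = c(1e6, 3e6, 3e6 + 1))
  y <- rnorm(n)
  fit <- fit_null_lmm(y, NULL, eig = grm_eigen(diag(n)))
  gene <- list(id = "g1", chrom = "chr1", tss = 2e6)
  a <- test_cis(fit, y, g, gene, window = 1e6)
  expect_setequal(a$variant, c("v1", "v2"))  # TSS +/- 1e6 inclusive; v3 out
  far <- list(id = "g2", chrom = "chr1", tss = 9e6)
  expect_message(a2 <- test_cis(fit, y, g, far), "no cis variants")
  expect_equal(nrow(a2), 0)
})

test_that("permuted phenotypes give uniform nominal p-values", {
  p <- small_panel()
  qc <- genotype_qc(p$g, "per_breed")
  ii <- which(p$g$samples$breed == "Landrace")
  gb <- subset_genotypes(qc$genotypes, samples = ii)
  G <- compute_grm(gb)
  eig <- grm_eigen(G)
  set.seed(40)
  pv <- c()
  for (r in 1:40) {
    y <- rnorm(length(ii))
    fit <- fit_null_lmm(y, NULL, eig = eig)
    gene <- list(id = "gX", chrom = "chr1",
                 tss = sample(seq(2e6, 14e6, by = 1e5), 1))
    pv <- c(pv, test_cis(fit, y, gb, gene)$p_nominal)
  }
  ks <- suppressWarnings(ks.test(pv, "punif"))
  # correlated within windows, so only a coarse uniformity check is fair
  expect_gt(ks$p.value, 1e-4)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("permutation gene-level p behaves at the boundary and is deterministic", {
  set.seed(23)
  n <- 50
  d <- matrix(rbinom(n * 10, 2, 0.5), nrow = n)
  d <- d[, apply(d, 2, var) > 0]
  g <- toy_genotypes(d, pos = seq_len(ncol(d)) * 1000L)
  s <- d[, 3] - mean(d[, 3])
  y <- 2 * s + rnorm(n, sd = 0.3)  # overwhelming signal
  fit <- fit_null_lmm(y, NULL, eig = grm_eigen(diag(n)))
  gene <- list(id = "g1", chrom = "chr1", tss = 5000)
  pg1 <- permutation_gene_p(fit, y, g, gene, k_perm = 150, seed = 99)
  expect_equal(pg1$p_gene, 1 / 151)
  pg2 <- permutation_gene_p(fit, y, g, gene, k_perm = 150, seed = 99)
  expect_identical(pg1$p_gene, pg2$p_gene)
  expect_identical(pg1$perm_min_p, pg2$perm_min_p)
  expect_error(permutation_gene_p(fit, y, g, gene, k_perm = 50), "at least 100")
  # Beta-smoothed variant stays extreme for an extreme observation
  pg3 <- permutation_gene_p(fit, y, g, gene, k_perm = 150, seed = 99,
                            beta_approx = TRUE)
  expect_lt(pg3$p_gene, 0.01)
})

test_that("eGene calling applies BH with order invariance", {
  s <- tibble::tibble(gene = paste0("g", 1:4),
                      p_gene = c(0.001, 0.02, 0.3, 0.9))
  out <- call_egenes(s)
  expect_equal(out$q_value, c(0.004, 0.04, 0.4, 0.9))
  expect_equal(out$is_egene, c(TRUE, TRUE, FALSE, FALSE))

  sh <- s[c(3, 1, 4, 2), ]
  out2 <- call_egenes(sh)
  expect_equal(out2$q_value[match(s$gene, out2$gene)], out$q_value)

  allsig <- tibble::tibble(gene = paste0("g", 1:100), p_gene = 1e-6)
  expect_equal(call_egenes(allsig)$q_value, rep(1e-6, 100))
  expect_error(call_egenes(tibble::tibble(gene = character(),
                                          p_gene = numeric())), "no gene")
})

test_that("variant thresholds map q = 0.05 back to the permutation scale", {
  set.seed(24)
  perms <- lapply(1:3, function(i) sort(runif(200)))
  s <- tibble::tibble(gene = paste0("g", 1:3),
                      p_gene = c(0.001, 0.04, 0.5),
                      perm_min_p = perms)
  out <- call_egenes(s)
  p_star <- max(out$p_gene[out$is_egene])
  for (i in which(out$is_egene)) {
    expect_equal(out$variant_threshold[i],
                 quantile(perms[[i]], probs = p_star, type = 1, names = FALSE))
  }
  expect_true(all(is.na(out$variant_threshold[!out$is_egene])))
})
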