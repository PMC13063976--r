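mk_summary <- function(genes, egene) {
  tibble::tibble(gene = genes, p_gene = ifelse(egene, 1e-6, 0.9),
                 q_value = ifelse(egene, 1e-5, 0.9), is_egene = egene)
}

test_that("eGene classification partitions the gene universe", {
  genes <- paste0("g", 1:6)
  s <- list(
    Duroc     = mk_summary(genes, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    Landrace  = mk_summary(genes, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)),
    Yorkshire = mk_summary(genes, c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  )
  cl <- classify_egenes(s, tissue = "muscle")
  expect_equal(cl$category,
               c("specific(Duroc)", "shared2(Duroc+Landrace)", "shared3",
                 "non_egene", "shared2(Landrace+Yorkshire)", "non_egene"))
  counts <- classification_summary(cl)
  expect_equal(sum(counts$per_category$n_genes), length(genes))
  # Duroc has 3 eGenes of which 2 shared
  d <- counts$per_breed[counts$per_breed$breed == "Duroc", ]
  expect_equal(d$n_egenes, 3)
  expect_equal(d$shared_fraction, 2 / 3)
})

test_that("genes untested in a breed are classified from available flags", {
  s <- list(
    Duroc    = mk_summary(c("g1", "g2"), c(TRUE, TRUE)),
    Landrace = mk_summary(c("g1"), TRUE)
  )
  expect_message(cl <- classify_egenes(s), "untested")
  expect_equal(cl$category[cl$gene == "g1"], "shared2(Duroc+Landrace)")
  expect_equal(cl$category[cl$gene == "g2"], "specific(Duroc)")
})

test_that("lfsr shrinkage separates strong effects from nulls", {
  set.seed(50)
  n_null <- 500
  betahat <- c(rnorm(n_null, 0, 1), 8)   # all se = 1; one 8-sigma effect
  se <- rep(1, n_null + 1)
  sh <- shrink_lfsr(betahat, se)
  expect_lt(sh$lfsr[n_null + 1], 0.05)
  # posterior mean shrinks toward, but stays near, the big estimate
  expect_lt(sh$posterior_mean[n_null + 1], 8)
  expect_gt(sh$posterior_mean[n_null + 1], 6)
  # pure-null ensemble: sign cannot be determined for most effects
  expect_gt(median(sh$lfsr[seq_len(n_null)]), 0.4)
})

test_that("lfsr is at least one half when the estimate is zero", {
  sh <- shrink_lfsr(rep(0, 20), rep(1, 20))
  expect_true(all(sh$lfsr >= 0.5 - 1e-9))
})

test_that("lfsr agrees with numerical posterior integration on the fitted mixture", {
  set.seed(51)
  betahat <- c(rnorm(30), 3, -4)
  se <- rep(0.8, 32)
  sh <- shrink_lfsr(betahat, se)
  mix <- attr(sh, "mixture")
  for (i in c(31, 32)) {
    liks <- dnorm(betahat[i], 0, sqrt(se[i]^2 + mix$scale^2))
    resp <- mix$weight * liks / sum(mix$weight * liks)
    p_neg <- p_pos <- 0
    pm <- 0
    for (k in seq_along(mix$scale)[-1]) {
      s2 <- mix$scale[k]^2
      shr <- s2 / (s2 + se[i]^2)
      f <- function(b) dnorm(b, shr * betahat[i], sqrt(shr * se[i]^2))
      p_neg <- p_neg + resp[k] * integrate(f, -Inf, 0)$value
      p_pos <- p_pos + resp[k] * integrate(f, 0, Inf)$value
      pm <- pm + resp[k] * shr * betahat[i]
    }
    expect_equal(sh$lfsr[i], min(resp[1] + p_neg, resp[1] + p_pos),
                 tolerance = 1e-6)
    expect_equal(sh$posterior_mean[i], pm, tolerance = 1e-8)
  }
})

test_that("pairwise sharing applies the factor-2/factor-4 magnitude rules", {
  eff <- tibble::tibble(
    b1 = c(0.5, 0.5, 0.5, -0.3),
    b2 = c(0.9, 1.2, -0.5, -0.31),
    lfsr1 = 0.01, lfsr2 = 0.01
  )
  sh <- pairwise_sharing(eff, c("D", "L"))
  # (0.5,0.9): ratio 1.8 counts for mag2; (0.5,1.2): ratio 2.4 only mag4;
  # (0.5,-0.5): sign-discordant; (-0.3,-0.31) counts everywhere
  expect_equal(sh$prop_sign, 3 / 4)
  expect_equal(sh$prop_mag2, 2 / 4)
  expect_equal(sh$prop_mag4, 3 / 4)
  expect_true(sh$prop_mag2 <= sh$prop_mag4 && sh$prop_mag4 <= sh$prop_sign)

  # lfsr gating: "either" keeps a pair significant in one breed, "both" drops it
  eff2 <- tibble::tibble(b1 = 1, b2 = 1, lfsr1 = 0.01, lfsr2 = 0.5)
  expect_equal(pairwise_sharing(eff2, c("D", "L"))$n_effects, 1)
  expect_error(pairwise_sharing(eff2, c("D", "L"), gate = "both"),
               "no significant")
})

test_that("sharing ordering invariant holds on random inputs", {
  set.seed(52)
  for (i in 1:10) {
    eff <- tibble::tibble(b1 = rnorm(100), b2 = rnorm(100),
                          lfsr1 = runif(100, 0, 0.2),
                          lfsr2 = runif(100, 0, 0.2))
    sh <- pairwise_sharing(eff, c("A", "B"))
    expect_true(sh$prop_mag2 <= sh$prop_mag4 + 1e-12)
    expect_true(sh$prop_mag4 <= sh$prop_sign + 1e-12)
  }
})

test_that("LD scores match a brute-force pairwise oracle", {
  set.seed(53)
  n <- 200
  d <- matrix(rbinom(n * 12, 2, 0.5), nrow = n)
  d[, 2] <- d[, 1]                       # perfect duplicate pair
  g <- toy_genotypes(d)
  expect_warning(ld <- ld_scores(toy_genotypes(cbind(d, 0L))), "zero-variance")
  ld <- ld_scores(g)
  oracle <- numeric(ncol(d))
  for (j in seq_len(ncol(d))) {
    for (k in seq_len(ncol(d))) {
      oracle[j] <- oracle[j] + cor(d[, j], d[, k])^2
    }
  }
  expect_equal(ld$ld_score, oracle, tolerance = 1e-10)
  expect_gt(ld$ld_score[1], 2 - 0.01)    # self + twin
  # independent variants: scores near 1 + (m-1)/n sampling bias
  m <- ncol(d) - 2
  expect_equal(mean(ld$ld_score[-(1:2)]), 1 + (ncol(d) - 1) / n,
               tolerance = 0.05)
  one <- ld_scores(toy_genotypes(d[, 3, drop = FALSE]))
  expect_equal(one$ld_score, 1)
})

test_that("per-breed MAF folds correctly", {
  d <- matrix(c(0L, 0L, 1L, 1L,
                2L, 2L, 2L, 2L), ncol = 2)
  g <- toy_genotypes(d, breeds = rep("D", 4))
  maf <- maf_by_breed(g)
  expect_equal(maf$maf, c(0.25, 0))
  expect_error(maf_by_breed(g, "nope"), "unknown variant")
})

test_that("gene conservation applies the 50% coverage rule and averages scores", {
  genes <- tibble::tibble(id = c("gA", "gB", "gC"), chrom = "chr1",
                          tss = c(1001, 5001, 9001), length = c(1000, 1000, 1000))
  track <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 1500, 5000, 9000),
    end   = c(1500, 2000, 5400, 10000),
    score = c(0.2, 0.4, 0.5, 0.7)
  )
  cons <- gene_conservation(track, genes)
  # gA fully covered, half 0.2 / half 0.4
  expect_equal(cons$mean_score[cons$gene == "gA"], 0.3)
  expect_equal(cons$covered_fraction[cons$gene == "gA"], 1)
  # gB covered 400/1000 < 50% -> no score
  expect_true(is.na(cons$mean_score[cons$gene == "gB"]))
  expect_equal(cons$covered_fraction[cons$gene == "gB"], 0.4)
  # gC: track [9000,10000) abuts the gene body [9000,10000) exactly
  expect_equal(cons$covered_fraction[cons$gene == "gC"], 1)
  expect_equal(cons$mean_score[cons$gene == "gC"], 0.7)
  expect_error(gene_conservation(track, dplyr::mutate(genes, length = 0)),
               "zero-length")
})
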