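# Shared small simulated panel, built once per test run.
.panel_cache <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    cfg <- sim_config(n_per_breed = 60, n_variants = 800, n_genes = 40,
                      chrom_length = 1.6e7, seed = 42)
    g <- simulate_genotypes(cfg)
    sim <- simulate_expression(g, cfg)
    .panel_cache$panel <- list(cfg = cfg, g = g, expr = sim$expression,
                               truth = sim$truth)
  }
  .panel_cache$panel
}

# tiny hand-buildable genotype matrix
toy_genotypes <- function(dosage, pos = NULL, breeds = NULL) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(breeds)) breeds <- rep("B1", n)
  genotype_matrix(
    dosage,
    tibble::tibble(id = paste0("v", seq_len(m)), chrom = "chr1", pos = pos,
                   ref = "A", alt = "G"),
    tibble::tibble(id = paste0("s", seq_len(n)), breed = breeds)
  )
}

toy_expression <- function(values, unit = "counts", tss = NULL, lengths = NULL) {
  ng <- nrow(values)
  if (is.null(tss)) tss <- seq_len(ng) * 10000L
  if (is.null(lengths)) lengths <- rep(1000L, ng)
  expression_matrix(
    values,
    tibble::tibble(id = paste0("g", seq_len(ng)), chrom = "chr1", tss = tss,
                   strand = "+", length = lengths),
    unit = unit
  )
}
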