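# Shared fixtures, built in code. Heavier simulations are cached per test
# run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, maker(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 4 genes x 3 cells toy with a mito gene and an all-zero cell.
toy_counts <- function() {
  mat <- rbind(geneA   = c(5, 2, 0),
               geneB   = c(0, 3, 0),
               geneC   = c(0, 1, 0),
               `mt-nd1` = c(5, 0, 0))
  count_matrix(mat, rownames(mat), c("c1", "c2", "c3"),
               c(c1 = "s1", c2 = "s1", c3 = "s2"))
}

# One-type exchangeable null atlas: no DE, no sample effects.
null_sim_config <- function(seed, n_genes = 300, cells = 100) {
  sim_config(cells_per_sample = cells,
             cell_types = list(TypeA = cell_type_spec("TypeA", 1, 1,
                                                      character(0))),
             n_genes = n_genes, sample_effect_sd = 0, seed = seed)
}

# Small three-program atlas (two plain types + planted DE) for unit tests.
small_sim <- function() cached("small_sim", function() {
  types <- list(
    TypeA = cell_type_spec("TypeA", 0.5, 0.3,
                           sprintf("amark%02d", 1:10),
                           age_de_genes = data.frame(
                             gene = sprintf("ade%02d", 1:10),
                             log2fc = rep(c(1.2, -1.2), 5))),
    TypeB = cell_type_spec("TypeB", 0.5, 0.7,
                           sprintf("bmark%02d", 1:10)))
  simulate_atlas(sim_config(cells_per_sample = 150, cell_types = types,
                            n_genes = 300, seed = 424))
})

# Luminal trio with a hybrid carrying 20 private up-genes.
hybrid_sim <- function() cached("hybrid_sim", function() {
  types <- list(
    HS = cell_type_spec("HS", 0.4, 0.4, sprintf("hsmark%02d", 1:15)),
    AV = cell_type_spec("AV", 0.4, 0.4, sprintf("avmark%02d", 1:15)),
    `HS-AV` = cell_type_spec("HS-AV", 0.2, 0.2,
                             sprintf("hybpriv%02d", 1:20), marker_fold = 4,
                             hybrid_of = c("HS", "AV")))
  simulate_atlas(sim_config(cells_per_sample = 300, cell_types = types,
                            n_genes = 400, seed = 77))
})

# The desk-scale power design shared by the DE and acceptance tests.
recovery_sim <- function() cached("recovery_sim", function() {
  simulate_atlas(sim_config_recovery(seed = 11))
})

de_hits <- function(de) de$gene[de$consensus]

sens_fdr <- function(de, truth_genes) {
  hits <- de_hits(de)
  list(sensitivity = mean(truth_genes %in% hits),
       fdr = if (length(hits)) mean(!hits %in% truth_genes) else 0)
}
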