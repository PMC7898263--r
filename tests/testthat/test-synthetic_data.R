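test_that("identical config and seed give bit-identical atlases", {
  cfg <- null_sim_config(seed = 9, n_genes = 100, cells = 40)
  s1 <- simulate_atlas(cfg)
  s2 <- simulate_atlas(cfg)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$truth$type_of_cell, s2$truth$type_of_cell)
})

test_that("counts follow the NB mean-variance law and the Poisson limit", {
  # one type, no DE, pi = 0, constant library size => marginal NB per gene
  base <- sim_config(n_samples_young = 1, n_samples_aged = 1,
                     cells_per_sample = 2500,
                     cell_types = list(T1 = cell_type_spec("T1", 1, 1,
                                                           character(0))),
                     n_genes = 200, libsize_lognormal = c(log(4000), 0),
                     nb_dispersion = 0.4, zero_inflation_pi = 0,
                     sample_effect_sd = 0, mito_cell_sd = 0, seed = 31)
  sim <- simulate_atlas(base)
  y <- as.matrix(sim$counts$counts)
  mu <- rowMeans(y); v <- apply(y, 1, var)
  hi <- mu > 2
  phi_hat <- (v[hi] - mu[hi]) / mu[hi]^2
  expect_gt(sum(hi), 30)
  expect_lt(abs(median(phi_hat) - 0.4), 0.08)

  pois <- sim_config(n_samples_young = 1, n_samples_aged = 1,
                     cells_per_sample = 2500,
                     cell_types = list(T1 = cell_type_spec("T1", 1, 1,
                                                           character(0))),
                     n_genes = 200, libsize_lognormal = c(log(4000), 0),
                     nb_dispersion = 0, zero_inflation_pi = 0,
                     sample_effect_sd = 0, mito_cell_sd = 0, seed = 32)
  yp <- as.matrix(simulate_atlas(pois)$counts$counts)
  mup <- rowMeans(yp); vp <- apply(yp, 1, var)
  disp_index <- vp[mup > 2] / mup[mup > 2]
  expect_lt(abs(median(disp_index) - 1), 0.05)
})

test_that("zero inflation adds zeros beyond the NB baseline", {
  mk <- function(pi, seed) {
    cfg <- sim_config(n_samples_young = 1, n_samples_aged = 1,
                      cells_per_sample = 500,
                      cell_types = list(T1 = cell_type_spec("T1", 1, 1,
                                                            character(0))),
                      n_genes = 150, zero_inflation_pi = pi,
                      sample_effect_sd = 0, seed = seed)
    mean(as.matrix(simulate_atlas(cfg)$counts$counts) == 0)
  }
  expect_gt(mk(0.3, 5) - mk(0, 5), 0.15)
})

test_that("realized type proportions stay inside binomial 99% bounds", {
  types <- list(
    AV = cell_type_spec("AV", 0.26, 0.69, character(0)),
    HS = cell_type_spec("HS", 0.74, 0.31, character(0)))
  cfg <- sim_config(n_samples_young = 1, n_samples_aged = 1,
                    cells_per_sample = 2000, cell_types = types,
                    n_genes = 60, seed = 12)
  sim <- simulate_atlas(cfg)
  age_of <- setNames(sim$meta$age_group, sim$meta$sample_id)
  for (ag in c("young", "aged")) {
    cells <- names(sim$truth$type_of_cell)[
      age_of[sim$counts$sample_of_cell] == ag]
    n <- length(cells)
    p <- unname(sim$truth$planted_props["AV", ag])
    k <- sum(sim$truth$type_of_cell[cells] == "AV")
    expect_gte(k, qbinom(0.005, n, p))
    expect_lte(k, qbinom(0.995, n, p))
  }
})

test_that("truth_de_table reports exactly the planted effects", {
  sim <- small_sim()
  tab <- truth_de_table(sim$truth, "TypeA")
  expect_equal(nrow(tab), 10)
  expect_identical(tab$gene, sprintf("ade%02d", 1:10))
  expect_identical(sign(tab$log2fc), rep(c(1, -1), 5))
  expect_equal(nrow(truth_de_table(sim$truth, "TypeB")), 0)
  expect_error(truth_de_table(sim$truth, "nosuch"), "unknown cell type")
})

test_that("doublets are flagged and summed into the matrix", {
  cfg <- sim_config(n_samples_young = 1, n_samples_aged = 1,
                    cells_per_sample = 200,
                    cell_types = list(T1 = cell_type_spec("T1", 1, 1,
                                                          character(0))),
                    n_genes = 80, doublet_rate = 0.1, seed = 3)
  sim <- simulate_atlas(cfg)
  flags <- sim$truth$doublet_flags
  expect_equal(sum(flags), 2 * round(0.1 * 200))
  expect_setequal(names(flags), sim$counts$barcodes)
  # doublets carry roughly double the library of singlets on average
  ls <- library_sizes(sim$counts)
  expect_gt(mean(ls[flags]) / mean(ls[!flags]), 1.5)
})

test_that("invalid proportion vectors are rejected", {
  expect_error(sim_config(cell_types = list(
    A = cell_type_spec("A", 0.6, 1, character(0)),
    B = cell_type_spec("B", 0.6, 0, character(0)))), "sum to")
})
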