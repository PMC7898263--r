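test_that("log-normalization matches its closed form and a naive loop", {
  m <- count_matrix(matrix(c(10, 0, 0, 0, 3, 1), nrow = 3),
                    c("g1", "g2", "g3"), c("c1", "c2"), c("s1", "s1"))
  nm <- log_normalize(m, scale_factor = 10000)
  expect_equal(as.numeric(nm$values["g1", "c1"]), log1p(10000))
  # scale invariance: doubling all counts in a cell changes nothing
  m2 <- count_matrix(matrix(c(20, 0, 0, 0, 3, 1), nrow = 3),
                     c("g1", "g2", "g3"), c("c1", "c2"), c("s1", "s1"))
  expect_equal(as.matrix(log_normalize(m2)$values[, "c1"]),
               as.matrix(nm$values[, "c1"]))

  set.seed(2)
  toy <- matrix(rpois(60, 3), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  mt <- count_matrix(toy, rownames(toy), colnames(toy), rep("s1", 6))
  nmt <- as.matrix(log_normalize(mt, 100)$values)
  naive <- toy
  for (j in 1:6) for (i in 1:10)
    naive[i, j] <- log(1 + toy[i, j] * 100 / sum(toy[, j]))
  expect_equal(nmt, naive, tolerance = 1e-12)

  zerocell <- count_matrix(cbind(c(1, 2), c(0, 0)), c("g1", "g2"),
                           c("c1", "c2"), c("s1", "s1"))
  expect_warning(nz <- log_normalize(zerocell), "all-zero")
  expect_equal(as.numeric(nz$values[, "c2"]), c(0, 0))
})

test_that("clustering separates planted programs and collapses at tiny resolution", {
  sim <- small_sim()
  kept <- filter_cells(compute_cell_qc(sim$counts),
                       qc_thresholds(genes_min = 0, umi_min = 0))
  sub <- subset_cells(sim$counts,
                      cells = withr::with_seed(1, sample(kept, 500)))
  nm <- log_normalize(sub)
  cl <- cluster_cells(nm, n_hvg = 150, n_pcs = 15, k = 15, seed = 4)
  truth <- sim$truth$type_of_cell[sub$barcodes]
  expect_gte(ari(cl, truth), 0.95)
  expect_identical(cl, cluster_cells(nm, n_hvg = 150, n_pcs = 15, k = 15,
                                     seed = 4))
  cl0 <- cluster_cells(nm, n_hvg = 150, n_pcs = 15, k = 15,
                       resolution = 0.01, seed = 4)
  expect_equal(length(unique(cl0)), 1)
})

test_that("module scores respond additively and monotonically", {
  set.seed(6)
  G <- 400; n <- 30
  base <- matrix(rpois(G * n, 5), G, n,
                 dimnames = list(sprintf("g%03d", 1:G), sprintf("c%02d", 1:n)))
  sig <- sprintf("g%03d", 1:10)
  shifted <- base; shifted[sig, ] <- shifted[sig, ] + 20
  m <- count_matrix(shifted, rownames(base), colnames(base), rep("s1", n))
  nm <- log_normalize(m)
  # equalize: feed the normalized values directly through a constant-lib toy
  nm$values <- Matrix::Matrix(shifted * 1.0, sparse = TRUE)
  sc <- score_signature(nm, sig, seed = 2)
  expect_true(all(sc > 10))  # ~ +20 shift against bin-matched controls
  # raising one cell's signature genes makes it the strict maximum
  bumped <- shifted; bumped[sig, 7] <- bumped[sig, 7] + 50
  nm2 <- nm; nm2$values <- Matrix::Matrix(bumped * 1.0, sparse = TRUE)
  sc2 <- score_signature(nm2, sig, seed = 2)
  expect_equal(which.max(sc2), 7, ignore_attr = TRUE)
  expect_error(score_signature(nm, c("absent1", "absent2")), "missing")
})

test_that("zero signal gives zero score", {
  vals <- matrix(0, 50, 5, dimnames = list(sprintf("g%02d", 1:50),
                                           sprintf("c%d", 1:5)))
  m <- count_matrix(vals, rownames(vals), colnames(vals), rep("s1", 5))
  suppressWarnings(nm <- log_normalize(m))
  expect_equal(unname(score_signature(nm, c("g01", "g02"))), rep(0, 5))
})

test_that("cell-cycle phases follow the score rules with the S tie-break", {
  expect_identical(assign_cell_cycle(-0.1, -0.2), "G1")
  expect_identical(assign_cell_cycle(0.5, 0.1), "S")
  expect_identical(assign_cell_cycle(0.2, 0.2), "S")
  expect_identical(assign_cell_cycle(0.1, 0.3), "G2M")
  expect_identical(assign_cell_cycle(c(0, -1), c(-1, 2)), c("G1", "G2M"))
})

test_that("shipped mouse cell-cycle gene lists are well-formed", {
  s <- readLines(system.file("extdata", "s_genes_mouse.txt",
                             package = "mammaging"))
  g2m <- readLines(system.file("extdata", "g2m_genes_mouse.txt",
                               package = "mammaging"))
  expect_gt(length(s), 30)
  expect_gt(length(g2m), 40)
  expect_false(anyDuplicated(c(s, g2m)) > 0)  # disjoint, mouse-cased
  expect_true(all(grepl("^[A-Z][a-z0-9]*$", c(s, g2m))))
})

test_that("clusters are annotated by marker panels, hybrids via the margin rule", {
  sim <- hybrid_sim()
  nm <- log_normalize(sim$counts)
  truth <- sim$truth$type_of_cell[sim$counts$barcodes]
  clusters <- as.integer(factor(truth))
  panel <- list(HS = sprintf("hsmark%02d", 1:15),
                AV = sprintf("avmark%02d", 1:15))
  ann <- annotate_clusters(clusters, nm, panel, seed = 3)
  for (t in c("HS", "AV", "HS-AV")) {
    cl <- unique(clusters[truth == t])
    expect_identical(unname(ann$cluster_type[as.character(cl)]), t)
  }
  # invariance to cluster relabeling
  perm <- c(3L, 1L, 2L)
  ann2 <- annotate_clusters(perm[clusters], nm, panel, seed = 3)
  expect_identical(unname(ann2$cell_type), unname(ann$cell_type))
})

test_that("one-vs-each signatures recover planted programs without leakage", {
  sim <- small_sim()
  nm <- log_normalize(sim$counts)
  labels <- sim$truth$type_of_cell[sim$counts$barcodes]
  sigs <- derive_type_signatures(nm, labels)$signatures
  expect_true(all(sprintf("amark%02d", 1:10) %in% sigs$TypeA))
  expect_true(all(sprintf("bmark%02d", 1:10) %in% sigs$TypeB))
  expect_length(intersect(sigs$TypeA, sprintf("bmark%02d", 1:10)), 0)
  expect_length(intersect(sigs$TypeB, sprintf("amark%02d", 1:10)), 0)
  expect_length(intersect(sigs$TypeA, sigs$TypeB), 0)
})

test_that("exchangeable labels give empty signatures", {
  sim <- small_sim()
  nm <- log_normalize(sim$counts)
  cells <- names(sim$truth$type_of_cell)[sim$truth$type_of_cell == "TypeA"]
  set.seed(5)
  fake <- setNames(sample(c("L", "R"), length(cells), replace = TRUE), cells)
  sigs <- derive_type_signatures(nm, fake)$signatures
  expect_length(sigs$L, 0)
  expect_length(sigs$R, 0)
})

test_that("a gene that beats all opponents but one is excluded", {
  # typeA mean 4 vs typeB mean 1 (clear win) vs typeC mean 3.6 (1.11x only)
  set.seed(9)
  n <- 40
  mk <- function(lambda) matrix(rpois(50 * n, lambda), 50, n)
  mat <- cbind(mk(2), mk(2), mk(2))
  mat[1, 1:n] <- rpois(n, 40); mat[1, n + 1:n] <- rpois(n, 10)
  mat[1, 2 * n + 1:n] <- rpois(n, 36)
  rownames(mat) <- sprintf("g%02d", 1:50)
  colnames(mat) <- sprintf("c%03d", seq_len(3 * n))
  m <- count_matrix(mat, rownames(mat), colnames(mat), rep("s1", 3 * n))
  nm <- log_normalize(m)
  # pin the de-logged scale to the raw counts so group means are the
  # Poisson means above
  nm$values <- Matrix::Matrix(log1p(mat), sparse = TRUE)
  labels <- setNames(rep(c("A", "B", "C"), each = n), colnames(mat))
  sigs <- derive_type_signatures(nm, labels)
  expect_false("g01" %in% sigs$signatures$A)
  # against B alone it would qualify
  ev <- sigs$evidence$A
  expect_gt(ev$min_fold[ev$gene == "g01"], 1)  # beaten only by the 1.25 bar
})

test_that("with thresholds disabled, signatures degenerate to strict argmax", {
  set.seed(13)
  n <- 25
  mat <- matrix(rpois(20 * 3 * n, 8), 20, 3 * n,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%03d", seq_len(3 * n))))
  m <- count_matrix(mat, rownames(mat), colnames(mat), rep("s1", 3 * n))
  nm <- log_normalize(m)
  labels <- setNames(rep(c("A", "B", "C"), each = n), colnames(mat))
  sigs <- derive_type_signatures(nm, labels, min_fc = 1, alpha = 1)$signatures
  dl <- as.matrix(nm$values); dl <- expm1(dl)
  means <- sapply(c("A", "B", "C"), function(t)
    rowMeans(dl[, labels == t, drop = FALSE]))
  argmax <- colnames(means)[max.col(means, ties.method = "first")]
  for (t in c("A", "B", "C"))
    expect_setequal(sigs[[t]], rownames(mat)[argmax == t &
      apply(means, 1, function(r) sum(r == max(r)) == 1)])
})

test_that("hybrid signatures require both parents and direction agreement", {
  sim <- hybrid_sim()
  nm <- log_normalize(sim$counts)
  labels <- sim$truth$type_of_cell[sim$counts$barcodes]
  hs <- derive_hybrid_signature(nm, labels)
  expect_true(all(sprintf("hybpriv%02d", 1:20) %in% hs$up))
  # each parent's markers are higher than one side, lower than the other:
  # the direction conflict must keep them out of both lists
  parent_markers <- c(sprintf("hsmark%02d", 1:15), sprintf("avmark%02d", 1:15))
  expect_length(intersect(hs$up, parent_markers), 0)
  ev <- hs$evidence
  hsm <- ev[ev$gene == "hsmark01", ]
  expect_gt(hsm$fold_vs_2, 1)  # above AV cells
  expect_lt(hsm$fold_vs_1, 1)  # below HS cells
  expect_error(derive_hybrid_signature(nm, labels, hybrid = "absent"),
               "no cells")
})

test_that("pairwise markers recover planted folds with signs; null is empty", {
  sim <- hybrid_sim()
  nm <- log_normalize(sim$counts)
  labels <- sim$truth$type_of_cell[sim$counts$barcodes]
  mk <- derive_pairwise_markers(nm, labels, "HS", "AV", min_fc = 2)
  expect_true(all(sprintf("hsmark%02d", 1:15) %in%
                    mk$gene[mk$direction == "up_in_A"]))
  expect_true(all(sprintf("avmark%02d", 1:15) %in%
                    mk$gene[mk$direction == "up_in_B"]))
  cells <- names(labels)[labels == "HS"]
  set.seed(21)
  fake <- setNames(sample(c("X", "Y"), length(cells), TRUE), cells)
  nullmk <- derive_pairwise_markers(nm, fake, "X", "Y", min_fc = 2)
  expect_lte(nrow(nullmk), ceiling(0.05 * length(nm$gene_ids)))
})
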