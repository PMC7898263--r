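test_that("wilcoxon_test is exact for small samples", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p, 0.1)  # 2/20 assignments
  expect_equal(wilcoxon_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  expect_equal(wilcoxon_test(1, 2)$p, 1)  # no assignment is more extreme
})

test_that("wilcoxon_test equals exhaustive enumeration for combined n <= 10", {
  set.seed(17)
  for (rep in 1:20) {
    nA <- sample(1:5, 1); nB <- sample(1:5, 1)
    xA <- sample(0:4, nA, replace = TRUE)  # integer data, ties guaranteed
    xB <- sample(0:4, nB, replace = TRUE)
    expect_equal(wilcoxon_test(xA, xB)$p, enum_wilcoxon(xA, xB),
                 tolerance = 1e-12)
  }
})

test_that("the large-sample branch matches the tie-corrected normal reference", {
  set.seed(18)
  for (rep in 1:10) {
    xA <- rpois(40, 4); xB <- rpois(55, 5)
    ours <- wilcoxon_test(xA, xB)
    ref <- suppressWarnings(wilcox.test(xA, xB, correct = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("wilcoxon_test holds its nominal level", {
  set.seed(19)
  rej <- mean(replicate(4000, {
    wilcoxon_test(rnorm(30), rnorm(30))$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("BH adjustment follows the step-up rule and propagates NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], naive_bh(c(0.01, NA, 0.04))[c(1, 3)])
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("ZINB weights are unity for genes without zeros and recover pi/phi", {
  set.seed(23)
  n <- 1200; G <- 25
  groups <- factor(rep(c("y", "a"), each = n / 2))
  Y <- t(sapply(seq_len(G), function(g) rzinb(n, 5, 0.5, 0.3)))
  Y <- rbind(Y, nozero = rpois(n, 50) + 1)
  rownames(Y) <- c(sprintf("g%02d", seq_len(G)), "nozero")
  fit <- fit_zinb_weights(Y, rep(1, n), groups)
  expect_equal(unname(fit$pi_hat[G + 1]), 0)
  expect_true(all(fit$weights[G + 1, ] == 1))
  expect_true(all(fit$weights[Y > 0] == 1))
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_lt(max(abs(fit$pi_hat[1:G] - 0.3)), 0.05)
  expect_lt(max(abs(fit$phi_hat[1:G] / 0.5 - 1)), 0.25)
  expect_error(fit_zinb_weights(rbind(Y, zero = 0), rep(1, n), groups),
               "all-zero")
})

test_that("the weighted LRT matches the plain NB LRT when pi = 0", {
  set.seed(24)
  n <- 800; G <- 40
  groups <- factor(rep(c("y", "a"), each = n / 2))
  Y <- t(sapply(seq_len(G), function(g) rzinb(n, 5, 0.5, 0)))
  rownames(Y) <- sprintf("g%02d", seq_len(G))
  fit <- fit_zinb_weights(Y, rep(1, n), groups)
  pz <- zinb_nb_lrt(fit, Y)$p
  pn <- nb_lrt(Y, rep(1, n), groups)$p
  expect_lt(max(abs(pz - pn)), 1e-6)
})

test_that("equal groups give a null LRT; planted folds give decisive p", {
  y <- matrix(rep(c(3, 1, 4, 0, 2, 5), 40), nrow = 2)
  rownames(y) <- c("gA", "gB")
  groups <- factor(rep(c("y", "a"), each = 60))
  # both groups see the identical value multiset: weighted means equal
  fit <- fit_zinb_weights(y, rep(1, 120), groups)
  res <- zinb_nb_lrt(fit, y)
  expect_lt(max(res$stat), 1e-6)
  expect_gt(min(res$p), 1 - 1e-6)

  set.seed(25)
  G <- 40
  Yp <- t(sapply(seq_len(G), function(g)
    c(rzinb(200, 20, 0.4, 0.1), rzinb(200, 5, 0.4, 0.1))))
  rownames(Yp) <- sprintf("g%02d", seq_len(G))
  gp <- factor(rep(c("hi", "lo"), each = 200))
  pfit <- fit_zinb_weights(Yp, rep(1, 400), gp)
  pv <- zinb_nb_lrt(pfit, Yp)$p
  expect_gte(mean(pv < 1e-4), 0.95)
})

test_that("criterion boundaries follow the quoted thresholds exactly", {
  cfg <- de_config()
  expect_true(grouped_criterion(1.5, 0.049, cfg))     # fold at bar: "at least"
  expect_false(grouped_criterion(2.0, 0.05, cfg))     # padj at bar: "< 0.05"
  expect_true(grouped_criterion(1 / 1.6, 0.01, cfg))  # downregulation
  expect_false(grouped_criterion(1.49, 0.001, cfg))
  expect_false(grouped_criterion(1.8, NA, cfg))

  f12 <- matrix(1.3, nrow = 3, ncol = 4)
  expect_identical(per_sample_criterion(f12, cfg),
                   list(pass = TRUE, direction = "up_in_aged"))
  f_one_low <- f12; f_one_low[2, 3] <- 1.1
  expect_false(per_sample_criterion(f_one_low, cfg)$pass)
  f_mixed <- matrix(rep(c(1.4, 1 / 1.4), 6), nrow = 3)
  expect_false(per_sample_criterion(f_mixed, cfg)$pass)
  f_na <- f12; f_na[1, 1] <- NA
  expect_false(per_sample_criterion(f_na, cfg)$pass)
  expect_identical(per_sample_criterion(matrix(1 / 1.3, 3, 4), cfg)$direction,
                   "down_in_aged")
  expect_true(per_sample_criterion(matrix(1.25, 3, 4), cfg)$pass)  # inclusive
})

test_that("consensus is the intersection of its three criteria", {
  sim <- small_sim()
  de <- consensus_de(sim$counts, sim$truth$type_of_cell, sim$meta, "TypeA")
  expect_true(all(de$gene[de$consensus] %in%
                    de$gene[de$pass_grouped_wilcoxon]))
  expect_true(all(de$gene[de$consensus] %in% de$gene[de$pass_grouped_zinb]))
  expect_true(all(de$gene[de$consensus] %in% de$gene[de$pass_per_sample]))
  expect_true(all(de$padj_wilcoxon >= de$p_wilcoxon, na.rm = TRUE))
  expect_true(all(de$padj_zinb >= de$p_zinb, na.rm = TRUE))
  # 3 young x 4 aged = 12 per-sample fold columns
  expect_length(grep("^fold_young", names(de)), 12)
})

test_that("tightening thresholds never grows the consensus list", {
  sim <- small_sim()
  base <- consensus_de(sim$counts, sim$truth$type_of_cell, sim$meta, "TypeA")
  tighter <- list(de_config(fc_grouped_min = 2),
                  de_config(fc_persample_min = 1.5),
                  de_config(alpha_adj = 0.01))
  for (cfg in tighter) {
    de2 <- consensus_de(sim$counts, sim$truth$type_of_cell, sim$meta,
                        "TypeA", cfg)
    expect_true(all(de_hits(de2) %in% de_hits(base)))
  }
})

test_that("swapping age labels inverts folds and preserves p-values", {
  sim <- small_sim()
  de <- consensus_de(sim$counts, sim$truth$type_of_cell, sim$meta, "TypeA")
  meta_sw <- sim$meta
  meta_sw$age_group <- ifelse(meta_sw$age_group == "young", "aged", "young")
  class(meta_sw) <- class(sim$meta)
  de_sw <- consensus_de(sim$counts, sim$truth$type_of_cell, meta_sw, "TypeA")
  common <- intersect(de$gene, de_sw$gene)
  i <- match(common, de$gene); j <- match(common, de_sw$gene)
  expect_equal(de_sw$fold_grouped[j], 1 / de$fold_grouped[i],
               tolerance = 1e-10)
  expect_equal(de_sw$p_wilcoxon[j], de$p_wilcoxon[i], tolerance = 1e-10)
  expect_equal(de_sw$p_zinb[j], de$p_zinb[i], tolerance = 1e-6)
})

test_that("a type missing from one age group is refused by name", {
  sim <- small_sim()
  labels <- sim$truth$type_of_cell
  age_of <- setNames(sim$meta$age_group, sim$meta$sample_id)
  aged_cells <- names(labels)[age_of[sim$counts$sample_of_cell[names(labels)]]
                              == "aged"]
  labels[aged_cells][labels[aged_cells] == "TypeA"] <- "TypeB"
  expect_error(consensus_de(sim$counts, labels, sim$meta, "TypeA"),
               "aged")
})
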