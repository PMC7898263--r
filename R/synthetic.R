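#' Specify a simulated cell type
#'
#' @param name cell-type name.
#' @param prop_young,prop_aged expected proportion of cells of this type in
#'   young and aged samples.
#' @param marker_genes character vector of genes forming this type's
#'   expression program.
#' @param marker_fold fold-up factor applied to marker genes (default 8).
#' @param age_de_genes optional data.frame with columns `gene` and `log2fc`
#'   giving the planted young-vs-aged effects for this type (positive
#'   log2fc = up in aged).
#' @param hybrid_of optional length-2 character vector naming two parent
#'   types; a hybrid expresses the union of both parents' marker programs
#'   at `hybrid_amplitude` times the parent amplitude.
#' @param hybrid_amplitude fraction of the parent marker amplitude a hybrid
#'   expresses (default 0.6).
#' @return list with class `CellTypeSpec`.
#' @export
cell_type_spec <- function(name, prop_young, prop_aged, marker_genes,
                           marker_fold = 8, age_de_genes = NULL,
                           hybrid_of = NULL, hybrid_amplitude = 0.6) {
  if (!is.null(age_de_genes)) {
    stopifnot(is.data.frame(age_de_genes),
              all(c("gene", "log2fc") %in% names(age_de_genes)))
    if (any(age_de_genes$log2fc == 0))
      stop("CellTypeSpec: planted DE genes must have |log2fc| > 0")
  }
  if (!is.null(hybrid_of)) stopifnot(length(hybrid_of) == 2)
  structure(list(name = name, prop_young = prop_young, prop_aged = prop_aged,
                 marker_genes = marker_genes, marker_fold = marker_fold,
                 age_de_genes = age_de_genes, hybrid_of = hybrid_of,
                 hybrid_amplitude = hybrid_amplitude),
            class = "CellTypeSpec")
}

canonical_markers <- list(
  Myoepithelial       = c("Krt17", "Krt14", "Krt5", "Acta2", "Myl9", "Mylk", "Myh11"),
  HS                  = c("Prlr", "Pgr", "Esr1", "Cited1", "Prom1"),
  AV                  = c("Mfge8", "Trf", "Csn3", "Wfdc18", "Ltf", "Elf5", "Kit"),
  Fibroblast          = c("Col1a1", "Col1a2", "Col3a1", "Fn1"),
  VascularEndothelial = c("Pecam1", "Cdh5", "Sox17", "Sele"),
  Pericyte            = c("Rgs5", "Des", "Notch3"),
  LymphaticEndothelial = c("Mmrn1", "Prox1", "Flt4", "Ccl21a"),
  DendriticCell       = c("Napsa", "Traf1", "Cd209a", "Flt3"),
  MacrophageMa        = c("Csf1r", "Mrc1", "Cd209f", "Cd163"),
  MacrophageMb        = c("Lyz2", "Mmp12", "Mmp13", "Spic"),
  NK                  = c("Gzma", "Ncr1", "Itgae"))

#' Default cell-type roster for the simulated atlas
#'
#' Twelve types mirroring the mammary atlas: myoepithelial, luminal HS and
#' AV, a rare HS-AV hybrid co-expressing both luminal programs, fibroblasts,
#' vascular/lymphatic endothelium, pericytes and four immune types. Planted
#' proportions encode the reported age shifts: the epithelial share of all
#' cells grows from 45% to 82%, and within the epithelium AV grows from 26%
#' to 69% while HS shrinks from 53% to 9%. Each type's markers start with
#' its canonical symbols, padded with generic genes to `n_markers`; the four
#' most abundant types carry `n_de` planted age-DE genes at `|log2fc| = 1`.
#'
#' @param n_markers markers per type.
#' @param n_de planted age-DE genes per DE-carrying type.
#' @param de_log2fc absolute planted log2 fold change.
#' @return named list of [cell_type_spec()] objects.
#' @export
default_cell_types <- function(n_markers = 20, n_de = 30, de_log2fc = 1) {
  props <- list( # name = c(prop_young, prop_aged)
    Myoepithelial        = c(0.45 * 0.10, 0.82 * 0.18),
    HS                   = c(0.45 * 0.53, 0.82 * 0.09),
    AV                   = c(0.45 * 0.26, 0.82 * 0.69),
    `HS-AV`              = c(0.45 * 0.11, 0.82 * 0.04),
    Fibroblast           = c(0.250, 0.050),
    VascularEndothelial  = c(0.150, 0.060),
    Pericyte             = c(0.050, 0.020),
    LymphaticEndothelial = c(0.010, 0.004),
    DendriticCell        = c(0.030, 0.008),
    MacrophageMa         = c(0.035, 0.002),
    MacrophageMb         = c(0.010, 0.020),
    NK                   = c(0.015, 0.016))
  de_types <- c("Myoepithelial", "HS", "AV", "Fibroblast")
  specs <- list()
  marker_cursor <- 0L
  de_cursor <- 0L
  for (nm in names(props)) {
    if (nm == "HS-AV") {
      specs[[nm]] <- cell_type_spec(nm, props[[nm]][1], props[[nm]][2],
                                    marker_genes = character(0),
                                    hybrid_of = c("HS", "AV"))
      next
    }
    canon <- canonical_markers[[nm]]
    pad <- max(0, n_markers - length(canon))
    generic <- sprintf("marker%04d", marker_cursor + seq_len(pad))
    marker_cursor <- marker_cursor + pad
    de <- NULL
    if (nm %in% de_types && n_de > 0) {
      de_genes <- sprintf("agede%04d", de_cursor + seq_len(n_de))
      de_cursor <- de_cursor + n_de
      de <- data.frame(gene = de_genes,
                       log2fc = rep(c(de_log2fc, -de_log2fc),
                                    length.out = n_de))
    }
    specs[[nm]] <- cell_type_spec(nm, props[[nm]][1], props[[nm]][2],
                                  marker_genes = c(canon, generic),
                                  age_de_genes = de)
  }
  specs
}

#' Simulation configuration
#'
#' Defaults emulate the study design: 3 young and 4 aged samples, 1,200 to
#' 2,800 cells per sample, zero-inflated negative binomial counts with
#' lognormal library sizes, lognormal per-sample-per-gene random effects,
#' and mitochondrial genes so QC is exercisable.
#'
#' @param n_samples_young,n_samples_aged samples per age group.
#' @param cells_per_sample length-2 integer range, cells drawn uniformly
#'   per sample; a single value fixes the count.
#' @param cell_types named list of [cell_type_spec()]; proportions must sum
#'   to 1 per age group (within 1e-8).
#' @param n_genes total genes, including markers, planted DE genes and
#'   `n_mito` mitochondrial genes.
#' @param n_mito number of `mt-` prefixed genes.
#' @param libsize_lognormal c(meanlog, sdlog) of per-cell library size.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param zero_inflation_pi structural-zero probability.
#' @param sample_effect_sd sdlog of per-sample-per-gene lognormal random
#'   effects.
#' @param mito_fraction expected mitochondrial share of a cell's library.
#' @param mito_cell_sd sdlog of the per-cell mitochondrial scaling (drives
#'   a tail of high-mito cells that QC removes).
#' @param doublet_rate fraction of barcodes that are synthetic doublets.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return list with class `SimConfig`.
#' @export
sim_config <- function(n_samples_young = 3, n_samples_aged = 4,
                       cells_per_sample = c(1200, 2800),
                       cell_types = default_cell_types(),
                       n_genes = 2000, n_mito = 10,
                       libsize_lognormal = c(log(5500), 0.5),
                       nb_dispersion = 0.4, zero_inflation_pi = 0.1,
                       sample_effect_sd = 0.1,
                       mito_fraction = 0.05, mito_cell_sd = 0.45,
                       doublet_rate = 0, seed = 1L) {
  if (length(cells_per_sample) == 1)
    cells_per_sample <- rep(cells_per_sample, 2)
  stopifnot(n_samples_young >= 1, n_samples_aged >= 1,
            zero_inflation_pi >= 0, zero_inflation_pi <= 1,
            doublet_rate >= 0, doublet_rate <= 1, nb_dispersion >= 0)
  for (ag in c("prop_young", "prop_aged")) {
    tot <- sum(vapply(cell_types, `[[`, 0, ag))
    if (abs(tot - 1) > 1e-8)
      stop("sim_config: ", ag, " proportions sum to ", tot, ", not 1")
  }
  structure(list(n_samples_young = n_samples_young,
                 n_samples_aged = n_samples_aged,
                 cells_per_sample = cells_per_sample,
                 cell_types = cell_types, n_genes = n_genes, n_mito = n_mito,
                 libsize_lognormal = libsize_lognormal,
                 nb_dispersion = nb_dispersion,
                 zero_inflation_pi = zero_inflation_pi,
                 sample_effect_sd = sample_effect_sd,
                 mito_fraction = mito_fraction, mito_cell_sd = mito_cell_sd,
                 doublet_rate = doublet_rate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Parameter-recovery simulation configuration
#'
#' The desk-scale power design: 3 young and 4 aged samples, five cell
#' types (the four DE-carrying types plus the HS-AV hybrid) at equal
#' proportions, 1,500 cells per sample (so ~300 cells per type per
#' sample), 1,000 genes, and 30 planted age-DE genes per DE-carrying type
#' at `|log2FC| = 1`. Used to measure the consensus procedure's
#' sensitivity and empirical FDR against ground truth.
#'
#' @param seed integer seed.
#' @param n_genes gene universe size.
#' @param de_log2fc absolute planted log2 fold change.
#' @return a [sim_config()].
#' @export
sim_config_recovery <- function(seed = 1L, n_genes = 1000, de_log2fc = 1) {
  all_types <- default_cell_types(n_de = 30, de_log2fc = de_log2fc)
  keep <- c("Myoepithelial", "HS", "AV", "HS-AV", "Fibroblast")
  types <- all_types[keep]
  for (nm in keep) {
    types[[nm]]$prop_young <- 1 / length(keep)
    types[[nm]]$prop_aged <- 1 / length(keep)
  }
  sim_config(cells_per_sample = 1500, cell_types = types,
             n_genes = n_genes, seed = seed)
}

#' Zero-inflated negative binomial draws
#'
#' Mixture pi * delta_0 + (1 - pi) * NB(mu, phi) with variance
#' mu + phi mu^2 on the NB component; `phi = 0` degenerates to Poisson.
#'
#' @param n number of draws.
#' @param mu NB mean (recycled).
#' @param phi dispersion (scalar).
#' @param pi structural-zero probability (scalar).
#' @return integer vector of counts.
#' @export
rzinb <- function(n, mu, phi, pi = 0) {
  y <- if (phi <= 1e-12) stats::rpois(n, lambda = mu)
       else stats::rnbinom(n, mu = mu, size = 1 / phi)
  if (pi > 0) y[stats::runif(n) < pi] <- 0L
  y
}

sim_gene_universe <- function(cfg) {
  mito <- paste0("mt-", sprintf("gene%02d", seq_len(cfg$n_mito)))
  named <- unique(unlist(lapply(cfg$cell_types, function(ct)
    c(ct$marker_genes, ct$age_de_genes$gene))))
  n_filler <- cfg$n_genes - cfg$n_mito - length(named)
  if (n_filler < 0)
    stop("sim_config: n_genes too small for markers + DE genes + mito genes")
  c(named, sprintf("gene%05d", seq_len(n_filler)), mito)
}

# Relative-expression profile per (type, age): baseline gamma profile,
# marker genes multiplied up (hybrids get both parents' programs at reduced
# amplitude), age-DE genes multiplied by 2^(+-log2fc/2) symmetrically around
# the baseline, mito genes pinned to their expected share. Profiles are
# normalized to sum to 1 over non-mito genes, then scaled by (1 - mito share).
sim_profiles <- function(cfg, genes, baseline) {
  types <- cfg$cell_types
  prof <- list()
  for (ct in types) {
    p <- baseline
    if (!is.null(ct$hybrid_of)) {
      for (parent in ct$hybrid_of) {
        par <- types[[parent]]
        if (is.null(par)) stop("hybrid_of names unknown type ", parent)
        idx <- match(par$marker_genes, genes)
        p[idx] <- p[idx] * (1 + ct$hybrid_amplitude * (par$marker_fold - 1))
      }
    }
    if (length(ct$marker_genes)) {
      idx <- match(ct$marker_genes, genes)
      p[idx] <- p[idx] * ct$marker_fold
    }
    py <- pa <- p
    if (!is.null(ct$age_de_genes)) {
      idx <- match(ct$age_de_genes$gene, genes)
      half <- ct$age_de_genes$log2fc / 2
      py[idx] <- py[idx] * 2^(-half)
      pa[idx] <- pa[idx] * 2^(half)
    }
    prof[[ct$name]] <- cbind(young = py / sum(py), aged = pa / sum(pa))
  }
  prof
}

#' Simulate a two-age-group single-cell atlas with ground truth
#'
#' Per cell: a type is drawn from the age group's planted proportion
#' vector and a library size from the lognormal; per gene the NB mean is
#' baseline x marker factor x age-DE factor x per-sample random effect x
#' library size, and the count is ZINB(mean, phi, pi). Mitochondrial genes
#' receive a per-cell lognormal scaling so a tail of cells exceeds the 10%
#' QC cutoff. If `doublet_rate > 0`, that fraction of barcodes is replaced
#' by the sum of two independent cells' draws and flagged in the truth.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]), `meta`
#'   (a [sample_meta()]) and `truth` (class `SimTruth`: `type_of_cell`,
#'   `planted_de`, `planted_props`, `doublet_flags`).
#' @export
simulate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, simulate_atlas_impl(cfg))
}

simulate_atlas_impl <- function(cfg) {
  genes <- sim_gene_universe(cfg)
  G <- length(genes)
  is_mito <- startsWith(genes, "mt-")
  baseline <- stats::rgamma(G, shape = 0.6, rate = 1) + 1e-4
  # marker and planted-DE genes represent quantifiably expressed programs:
  # floor their baselines at the median so planted truth is recoverable in
  # principle (a marker with vanishing expression is no marker)
  special <- unique(unlist(lapply(cfg$cell_types, function(ct)
    c(ct$marker_genes, ct$age_de_genes$gene))))
  si <- match(special, genes)
  baseline[si] <- pmax(baseline[si], stats::qgamma(0.5, shape = 0.6))
  baseline[is_mito] <- 0  # mito handled as its own budget below
  profiles <- sim_profiles(cfg, genes, baseline)
  type_names <- names(cfg$cell_types)

  sample_ids <- c(sprintf("young%d", seq_len(cfg$n_samples_young)),
                  sprintf("aged%d", seq_len(cfg$n_samples_aged)))
  ages <- rep(c("young", "aged"), c(cfg$n_samples_young, cfg$n_samples_aged))
  meta <- sample_meta(sample_ids, ages)

  prop_mat <- vapply(cfg$cell_types, function(ct)
    c(young = ct$prop_young, aged = ct$prop_aged), c(young = 0, aged = 0))

  blocks <- list(); bcs <- list(); samples <- list()
  types_all <- list(); doublet_all <- list()
  for (si in seq_along(sample_ids)) {
    age <- ages[si]
    n_cells <- if (cfg$cells_per_sample[1] == cfg$cells_per_sample[2])
      cfg$cells_per_sample[1] else
      sample(cfg$cells_per_sample[1]:cfg$cells_per_sample[2], 1)
    type_idx <- sample(length(type_names), n_cells, replace = TRUE,
                       prob = prop_mat[age, ])
    libsize <- stats::rlnorm(n_cells, cfg$libsize_lognormal[1],
                             cfg$libsize_lognormal[2])
    mito_scale <- stats::rlnorm(n_cells, 0, cfg$mito_cell_sd)
    mito_share <- pmin(cfg$mito_fraction * mito_scale, 0.9)
    sample_eff <- stats::rlnorm(G, 0, cfg$sample_effect_sd)

    counts <- matrix(0L, G, n_cells)
    mito_w <- rep(1 / max(1, sum(is_mito)), sum(is_mito))
    for (ti in seq_along(type_names)) {
      cells <- which(type_idx == ti)
      if (!length(cells)) next
      p <- profiles[[type_names[ti]]][, age] * sample_eff
      p[!is_mito] <- p[!is_mito] / sum(p[!is_mito])
      mu <- outer(p, libsize[cells] * (1 - mito_share[cells]))
      mu[is_mito, ] <- outer(mito_w, libsize[cells] * mito_share[cells])
      counts[, cells] <- rzinb(length(mu), mu, cfg$nb_dispersion,
                               cfg$zero_inflation_pi)
    }
    doublet <- rep(FALSE, n_cells)
    if (cfg$doublet_rate > 0) {
      n_db <- round(cfg$doublet_rate * n_cells)
      if (n_db > 0) {
        tgt <- sample(n_cells, n_db)
        src <- sample(n_cells, n_db, replace = TRUE)
        counts[, tgt] <- counts[, tgt] + counts[, src]
        doublet[tgt] <- TRUE
      }
    }
    blocks[[si]] <- counts
    bcs[[si]] <- sprintf("%s_cell%04d", sample_ids[si], seq_len(n_cells))
    samples[[si]] <- rep(sample_ids[si], n_cells)
    types_all[[si]] <- type_names[type_idx]
    doublet_all[[si]] <- doublet
  }

  barcodes <- unlist(bcs)
  cm <- count_matrix(do.call(cbind, blocks), genes, barcodes, unlist(samples))
  planted_de <- do.call(rbind, lapply(cfg$cell_types, function(ct)
    if (is.null(ct$age_de_genes)) NULL else
      data.frame(cell_type = ct$name, gene = ct$age_de_genes$gene,
                 log2fc = ct$age_de_genes$log2fc, stringsAsFactors = FALSE)))
  if (is.null(planted_de))
    planted_de <- data.frame(cell_type = character(0), gene = character(0),
                             log2fc = numeric(0))
  rownames(planted_de) <- NULL
  truth <- structure(list(
    type_of_cell = stats::setNames(unlist(types_all), barcodes),
    planted_de = planted_de,
    planted_props = t(prop_mat),
    doublet_flags = stats::setNames(unlist(doublet_all), barcodes)),
    class = "SimTruth")
  list(counts = cm, meta = meta, truth = truth)
}

#' Planted age-DE genes for one simulated cell type
#'
#' @param truth a `SimTruth` from [simulate_atlas()].
#' @param cell_type type name.
#' @return data.frame with columns `gene`, `log2fc` (possibly 0 rows).
#' @export
truth_de_table <- function(truth, cell_type) {
  stopifnot(inherits(truth, "SimTruth"))
  if (!cell_type %in% rownames(truth$planted_props))
    stop("truth_de_table: unknown cell type '", cell_type, "'")
  out <- truth$planted_de[truth$planted_de$cell_type == cell_type,
                          c("gene", "log2fc"), drop = FALSE]
  rownames(out) <- NULL
  out
}
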