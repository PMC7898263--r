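#' Library-size log-normalization
#'
#' Entry-wise `log(1 + count * scale_factor / cell_total)`. Zeros stay
#' zero, so sparsity is preserved; an all-zero cell maps to an all-zero
#' column (with a warning) rather than NaN.
#'
#' @param m a `CountMatrix`.
#' @param scale_factor counts-per-cell normalization target (default 1e4).
#' @return list with class `NormalizedMatrix`: `values` (sparse genes x
#'   cells), `gene_ids`, `barcodes`, `scale_factor`, `libsize`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "CountMatrix"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) warning("log_normalize: ", sum(tot == 0),
                             " all-zero cell(s) map to zero columns")
  div <- ifelse(tot > 0, tot, 1)
  scaled <- m$counts %*% Matrix::Diagonal(x = scale_factor / div)
  vals <- methods::as(scaled, "CsparseMatrix")
  vals@x <- log1p(vals@x)
  dimnames(vals) <- list(m$gene_ids, m$barcodes)
  structure(list(values = vals, gene_ids = m$gene_ids,
                 barcodes = m$barcodes, scale_factor = scale_factor,
                 libsize = stats::setNames(as.numeric(tot), m$barcodes)),
            class = "NormalizedMatrix")
}

# De-logged normalized expression (counts per scale_factor), genes x cells.
delog <- function(nm) {
  v <- nm$values
  v@x <- expm1(v@x)
  v
}

row_group_means <- function(mat, idx) {
  as.numeric(Matrix::rowSums(mat[, idx, drop = FALSE])) / length(idx)
}

# Shared fold-change estimator: ratio of de-logged normalized group means
# with a pseudocount guarding empty denominators.
fold_change <- function(meanA, meanB, pseudocount = 0.01) {
  (meanA + pseudocount) / (meanB + pseudocount)
}

#' Highly variable genes by binned dispersion
#'
#' Dispersion = variance/mean of the log-normalized values, z-scored within
#' 20 bins of mean expression; the top `n_hvg` by standardized dispersion
#' are returned.
#' @param nm a `NormalizedMatrix`.
#' @param n_hvg number of genes to keep.
#' @return integer vector of row indices.
#' @keywords internal
select_hvg <- function(nm, n_hvg = 2000) {
  v <- nm$values
  mu <- Matrix::rowMeans(v)
  ex2 <- Matrix::rowMeans(v^2)
  varr <- pmax(ex2 - mu^2, 0)
  disp <- ifelse(mu > 0, varr / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, 0.05))),
              include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::sd(d); if (!is.finite(s) || s == 0) return(rep(0, length(d)))
    (d - mean(d)) / s
  })
  head(order(z, decreasing = TRUE), min(n_hvg, length(z)))
}

knn_indices <- function(pcs, k, block = 512L) {
  n <- nrow(pcs)
  sq <- rowSums(pcs^2)
  out <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(pcs[idx, , drop = FALSE], pcs)
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Graph-based clustering of cells
#'
#' Dispersion-ranked highly variable genes, PCA on the scaled submatrix, a
#' shared-nearest-neighbor graph with Jaccard edge weights, and Louvain
#' community detection. Deterministic for a fixed seed.
#'
#' @param nm a `NormalizedMatrix`.
#' @param n_hvg number of highly variable genes (default 2000).
#' @param n_pcs principal components (default 30; reduced with a warning
#'   when fewer cells/genes are available).
#' @param k neighbors per cell (default 20).
#' @param resolution Louvain resolution (default 1); as it approaches 0
#'   everything collapses into one community.
#' @param seed integer seed.
#' @return integer vector of cluster labels (1-based), one per cell.
#' @export
cluster_cells <- function(nm, n_hvg = 2000, n_pcs = 30, k = 20,
                          resolution = 1, seed = 1L) {
  n <- length(nm$barcodes)
  if (n < k + 1) stop("cluster_cells: need at least k+1 cells")
  hvg <- select_hvg(nm, n_hvg)
  x <- t(as.matrix(nm$values[hvg, , drop = FALSE]))  # cells x genes
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0
  x[x > 10] <- 10
  max_pc <- min(dim(x)) - 1
  if (n_pcs > max_pc) {
    warning("cluster_cells: reducing n_pcs to ", max_pc)
    n_pcs <- max_pc
  }
  pcs <- withr::with_seed(seed, stats::prcomp(x, rank. = n_pcs)$x)
  nn <- knn_indices(pcs, k)
  # SNN with Jaccard weights over the directed kNN sets
  i <- rep(seq_len(n), each = k)
  j <- as.integer(t(nn))
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  tr <- Matrix::mat2triplet(shared)
  keep <- tr$i < tr$j & tr$x > 0
  jac <- tr$x[keep] / (2 * k - tr$x[keep])
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$i[keep], to = tr$j[keep], weight = jac),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(comm))
}

#' Module score for a gene signature
#'
#' Per cell: mean expression of the signature genes minus the mean of
#' control genes sampled from expression bins matched on average abundance
#' (the usual binned-control module score). Deterministic for a fixed seed.
#'
#' @param nm a `NormalizedMatrix`.
#' @param genes signature gene ids; at least one must be present (an error
#'   lists the misses otherwise; partial misses warn).
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
score_signature <- function(nm, genes, n_bins = 25, n_ctrl = 100, seed = 1L) {
  present <- intersect(genes, nm$gene_ids)
  if (!length(present))
    stop("score_signature: no signature gene present; missing: ",
         paste(utils::head(genes, 10), collapse = ", "))
  if (length(present) < length(genes))
    warning("score_signature: ", length(genes) - length(present),
            " signature gene(s) absent")
  avg <- Matrix::rowMeans(nm$values)
  brk <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(brk) < 2) factor(rep(1L, length(avg)))
          else cut(avg, breaks = brk, include.lowest = TRUE)
  sig_idx <- match(present, nm$gene_ids)
  ctrl_idx <- withr::with_seed(seed, unique(unlist(lapply(sig_idx, function(g) {
    pool <- setdiff(which(bins == bins[g]), sig_idx)
    if (!length(pool)) pool <- which(bins == bins[g])  # degenerate bin
    pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
  }))))
  sig_mean <- Matrix::colMeans(nm$values[sig_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(nm$values[ctrl_idx, , drop = FALSE])
  stats::setNames(as.numeric(sig_mean - ctrl_mean), nm$barcodes)
}

#' Cell-cycle phase from S and G2M module scores
#'
#' G1 when both scores are non-positive; otherwise the phase of the larger
#' score, ties broken toward S.
#'
#' @param s_score,g2m_score numeric vectors (recycled to common length).
#' @return character vector in `{"G1","S","G2M"}`.
#' @export
assign_cell_cycle <- function(s_score, g2m_score) {
  stopifnot(all(is.finite(s_score)), all(is.finite(g2m_score)))
  n <- max(length(s_score), length(g2m_score))
  s <- rep_len(s_score, n); g <- rep_len(g2m_score, n)
  ifelse(s <= 0 & g <= 0, "G1", ifelse(s >= g, "S", "G2M"))
}

#' Label clusters with cell types from a marker panel
#'
#' Each cluster is scored against every panel entry with
#' [score_signature()] and labeled by the best-scoring type; clusters with
#' no positive score are `"unassigned"`. Hybrid populations co-expressing
#' two programs are detected on relative marker expression rather than on
#' raw scores (which inherit each gene set's expression scale and are not
#' comparable across signatures): for every marker gene, the cluster-mean
#' de-logged expression is divided by the best cluster's mean for that
#' gene, and these per-gene ratios are averaged within each panel entry.
#' A value near 1 means the cluster expresses the full program at parent
#' level; near 0, not at all. A cluster gets a hybrid label `"<A>-<B>"`
#' (panel order fixes the name) when its top two types both reach a
#' relative expression of at least `hybrid_rel`.
#'
#' @param clusters integer cluster labels, one per cell.
#' @param nm a `NormalizedMatrix` over the same cells.
#' @param panel named list: cell-type name -> marker gene ids.
#' @param hybrid_rel relative-expression floor for calling a hybrid
#'   (default 1/3, half the amplitude at which the simulator's hybrids
#'   express their parent programs).
#' @param seed seed passed to [score_signature()].
#' @return list: `cell_type` (per-cell labels), `cluster_type` (per-cluster
#'   labels), `scores` (cluster x type module scores), `rel_expression`
#'   (cluster x type relative marker expression), `ambiguity` (per-cluster
#'   runner-up relative expression).
#' @export
annotate_clusters <- function(clusters, nm, panel, hybrid_rel = 1 / 3,
                              seed = 1L) {
  stopifnot(length(panel) >= 1, !is.null(names(panel)))
  score_mat <- vapply(panel, function(gs)
    score_signature(nm, gs, seed = seed), numeric(length(nm$barcodes)))
  ids <- sort(unique(clusters))
  cl_scores <- t(vapply(ids, function(cl)
    colMeans(score_mat[clusters == cl, , drop = FALSE]),
    numeric(length(panel))))
  rownames(cl_scores) <- ids

  dl <- delog(nm)
  rel <- vapply(panel, function(gs) {
    gs <- intersect(gs, nm$gene_ids)
    M <- vapply(ids, function(cl)
      row_group_means(dl[match(gs, nm$gene_ids), , drop = FALSE],
                      which(clusters == cl)), numeric(length(gs)))
    M <- matrix(M, nrow = length(gs))
    mx <- apply(M, 1, max)
    colMeans(M[mx > 0, , drop = FALSE] / mx[mx > 0])
  }, numeric(length(ids)))
  rel <- matrix(rel, nrow = length(ids),
                dimnames = list(ids, names(panel)))

  lab <- character(length(ids)); amb <- numeric(length(ids))
  for (r in seq_along(ids)) {
    s <- cl_scores[r, ]
    ord <- order(rel[r, ], decreasing = TRUE)
    amb[r] <- if (length(panel) >= 2) rel[r, ord[2]] else NA_real_
    if (max(s) <= 0) { lab[r] <- "unassigned"; next }
    if (length(panel) >= 2 && all(rel[r, ord[1:2]] >= hybrid_rel)) {
      pair <- names(panel)[sort(ord[1:2])]  # panel order fixes the name
      lab[r] <- paste(pair, collapse = "-")
    } else lab[r] <- names(panel)[which.max(s)]
  }
  list(cell_type = stats::setNames(lab[match(clusters, ids)], nm$barcodes),
       cluster_type = stats::setNames(lab, ids),
       scores = cl_scores, rel_expression = rel,
       ambiguity = stats::setNames(amb, ids))
}
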