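# Pairwise Wilcoxon + fold evidence between two labeled groups of cells.
# Returns per-gene fold (A over B, de-logged normalized means with
# pseudocount) and BH-adjusted p within this comparison only.
pairwise_evidence <- function(nm, cellsA, cellsB, pseudocount = 0.01) {
  ia <- match(cellsA, nm$barcodes); ib <- match(cellsB, nm$barcodes)
  if (anyNA(ia) || anyNA(ib)) stop("pairwise_evidence: unknown barcode")
  dl <- delog(nm)
  meanA <- row_group_means(dl, ia)
  meanB <- row_group_means(dl, ib)
  p <- wilcoxon_rows(nm$values, ia, ib)
  data.frame(gene = nm$gene_ids,
             fold = fold_change(meanA, meanB, pseudocount),
             p = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-vs-each cell-type signatures
#'
#' A gene joins type T's signature iff, against EVERY other type, its
#' expression is more than `min_fc`-fold greater (strict, per the
#' "> 1.25-fold" rule) with BH-adjusted Wilcoxon p < `alpha`; adjustment is
#' performed within each pairwise comparison independently. The conjunction
#' makes signatures disjoint across types. Types with fewer than
#' `min_cells` cells are excluded with a warning.
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels named character vector barcode -> type.
#' @param min_fc pairwise fold threshold (default 1.25, strict `>`).
#' @param alpha adjusted p-value cutoff (default 0.05, strict `<`).
#' @param min_cells minimum cells per type (default 3).
#' @param pseudocount passed to the fold estimator.
#' @return list with class `SignatureSet`: `signatures` (named list of
#'   gene vectors) and `evidence` (per-type data.frame of the worst-case
#'   pairwise fold and adjusted p across opponents).
#' @export
derive_type_signatures <- function(nm, labels, min_fc = 1.25, alpha = 0.05,
                                   min_cells = 3, pseudocount = 0.01) {
  labels <- labels[intersect(names(labels), nm$barcodes)]
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small))
    warning("derive_type_signatures: excluding types with < ", min_cells,
            " cells: ", paste(small, collapse = ", "))
  types <- setdiff(names(sizes), small)
  if (length(types) < 2)
    stop("derive_type_signatures: need at least 2 types with >= ",
         min_cells, " cells")
  cells_of <- lapply(stats::setNames(types, types),
                     function(t) names(labels)[labels == t])
  sigs <- list(); evid <- list()
  for (t in types) {
    worst_fold <- rep(Inf, length(nm$gene_ids))
    worst_padj <- rep(0, length(nm$gene_ids))
    for (o in setdiff(types, t)) {
      ev <- pairwise_evidence(nm, cells_of[[t]], cells_of[[o]], pseudocount)
      worst_fold <- pmin(worst_fold, ev$fold)
      worst_padj <- pmax(worst_padj, ev$padj)
    }
    p_ok <- if (alpha >= 1) rep(TRUE, length(worst_padj))
            else worst_padj < alpha  # alpha = 1 disables the p filter
    keep <- worst_fold > min_fc & p_ok
    sigs[[t]] <- nm$gene_ids[keep]
    evid[[t]] <- data.frame(gene = nm$gene_ids, min_fold = worst_fold,
                            max_padj = worst_padj, in_signature = keep,
                            stringsAsFactors = FALSE)
  }
  overlap <- unlist(sigs)[duplicated(unlist(sigs))]
  stopifnot("one-vs-each signatures must be disjoint" = !length(overlap))
  structure(list(signatures = sigs, evidence = evid), class = "SignatureSet")
}

#' Hybrid (e.g. HS-AV) up/down signature versus both parents
#'
#' A gene marks the hybrid iff it is at least `min_fc`-fold higher (or
#' lower) than BOTH parent types, with adjusted p < `alpha` in both
#' pairwise tests, and the direction agrees across the two comparisons;
#' direction conflicts disqualify a gene.
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels named character vector barcode -> type.
#' @param hybrid,parents hybrid type name and its two parent type names.
#' @param min_fc fold threshold (default 1.25, inclusive "at least").
#' @param alpha adjusted p cutoff (default 0.05, strict).
#' @param restrict optional barcodes to restrict the analysis to (e.g.
#'   young cells, to separate type identity from aging).
#' @param pseudocount passed to the fold estimator.
#' @return list: `up`, `down` (gene vectors), `evidence` (data.frame).
#' @export
derive_hybrid_signature <- function(nm, labels, hybrid = "HS-AV",
                                    parents = c("HS", "AV"), min_fc = 1.25,
                                    alpha = 0.05, restrict = NULL,
                                    pseudocount = 0.01) {
  stopifnot(length(parents) == 2)
  labels <- labels[intersect(names(labels), nm$barcodes)]
  if (!is.null(restrict)) labels <- labels[intersect(names(labels), restrict)]
  for (t in c(hybrid, parents))
    if (!any(labels == t))
      stop("derive_hybrid_signature: no cells labeled '", t, "'")
  hc <- names(labels)[labels == hybrid]
  ev <- lapply(parents, function(p)
    pairwise_evidence(nm, hc, names(labels)[labels == p], pseudocount))
  up <- ev[[1]]$fold >= min_fc & ev[[2]]$fold >= min_fc &
    ev[[1]]$padj < alpha & ev[[2]]$padj < alpha
  down <- ev[[1]]$fold <= 1 / min_fc & ev[[2]]$fold <= 1 / min_fc &
    ev[[1]]$padj < alpha & ev[[2]]$padj < alpha
  list(up = nm$gene_ids[up], down = nm$gene_ids[down],
       evidence = data.frame(gene = nm$gene_ids,
                             fold_vs_1 = ev[[1]]$fold, padj_vs_1 = ev[[1]]$padj,
                             fold_vs_2 = ev[[2]]$fold, padj_vs_2 = ev[[2]]$padj,
                             stringsAsFactors = FALSE))
}

#' Pairwise marker genes between two cell types
#'
#' Genes whose expression differs by at least `min_fc`-fold (either
#' direction, inclusive) with adjusted p < `alpha`, signed by direction.
#'
#' @param nm a `NormalizedMatrix`.
#' @param labels named character vector barcode -> type.
#' @param typeA,typeB the two types to contrast.
#' @param min_fc fold threshold (default 2).
#' @param alpha adjusted p cutoff (default 0.05).
#' @param pseudocount passed to the fold estimator.
#' @return data.frame: `gene`, `fold` (A over B), `padj`, `direction`
#'   (`"up_in_A"` / `"up_in_B"`), sorted by p.
#' @export
derive_pairwise_markers <- function(nm, labels, typeA, typeB, min_fc = 2,
                                    alpha = 0.05, pseudocount = 0.01) {
  labels <- labels[intersect(names(labels), nm$barcodes)]
  ca <- names(labels)[labels == typeA]; cb <- names(labels)[labels == typeB]
  if (!length(ca) || !length(cb))
    stop("derive_pairwise_markers: both types must be present")
  ev <- pairwise_evidence(nm, ca, cb, pseudocount)
  keep <- (ev$fold >= min_fc | ev$fold <= 1 / min_fc) & ev$padj < alpha
  out <- ev[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold >= min_fc, "up_in_A", "up_in_B")
  out[order(out$p), c("gene", "fold", "padj", "direction")]
}
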