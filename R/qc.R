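#' Per-cell QC metrics
#'
#' Computes, per barcode: total UMIs, number of detected genes (raw count
#' > 0), and the mitochondrial UMI fraction. A cell with zero total UMIs
#' gets `mito_fraction = 0` and can never pass filtering.
#'
#' @param m a `CountMatrix`.
#' @param mito a character vector of mitochondrial gene ids; defaults to
#'   genes with the `"mt-"` prefix. Ids absent from the matrix trigger a
#'   warning and are ignored.
#' @return data.frame with columns `barcode`, `umi_total`, `genes_detected`,
#'   `mito_fraction`.
#' @export
compute_cell_qc <- function(m, mito = mito_genes(m$gene_ids)) {
  stopifnot(inherits(m, "CountMatrix"))
  if (length(m$barcodes) == 0) {
    warning("compute_cell_qc: empty matrix")
    return(data.frame(barcode = character(0), umi_total = numeric(0),
                      genes_detected = integer(0), mito_fraction = numeric(0)))
  }
  miss <- setdiff(mito, m$gene_ids)
  if (length(miss))
    warning("compute_cell_qc: mito genes not in matrix: ",
            paste(utils::head(miss, 5), collapse = ", "))
  mito <- intersect(mito, m$gene_ids)
  umi <- Matrix::colSums(m$counts)
  detected <- Matrix::colSums(m$counts > 0)
  mito_umi <- if (length(mito))
    Matrix::colSums(m$counts[match(mito, m$gene_ids), , drop = FALSE])
    else rep(0, length(umi))
  frac <- ifelse(umi > 0, mito_umi / umi, 0)
  data.frame(barcode = m$barcodes, umi_total = as.numeric(umi),
             genes_detected = as.integer(detected),
             mito_fraction = as.numeric(frac),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' A cell is kept iff `umi_min <= umi <= umi_max`, `genes_min <= genes <=
#' genes_max` and `mito_fraction <= mito_max`. Elimination in the source
#' procedure is by strict inequality ("< 1,000 or > 60,000"), so cells
#' exactly at a boundary are kept. Zero-UMI cells fail the UMI floor.
#'
#' @param qc table from [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()].
#' @return character vector of kept barcodes, input order preserved.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  keep <- qc$umi_total > 0 &  # a zero-UMI cell can never pass
    qc$umi_total >= thresholds$umi_min &
    qc$umi_total <= thresholds$umi_max &
    qc$genes_detected >= thresholds$genes_min &
    qc$genes_detected <= thresholds$genes_max &
    qc$mito_fraction <= thresholds$mito_max
  qc$barcode[keep]
}

median_by <- function(x, convention) {
  if (convention == "interpolated") stats::median(x)
  else sort(x)[ceiling(length(x) / 2)]  # lower median for even n
}

#' Median genes and UMIs per kept cell
#'
#' @param m a `CountMatrix`.
#' @param kept barcodes to summarize.
#' @param convention `"interpolated"` (default; mean of the middle pair for
#'   even counts) or `"lower"`.
#' @return named list: `median_genes`, `median_umi`.
#' @export
summarize_depth <- function(m, kept = m$barcodes,
                            convention = c("interpolated", "lower")) {
  convention <- match.arg(convention)
  if (!length(kept)) stop("summarize_depth: empty kept set")
  idx <- match(kept, m$barcodes)
  if (anyNA(idx)) stop("summarize_depth: unknown barcode in kept set")
  sub <- m$counts[, idx, drop = FALSE]
  list(median_genes = median_by(as.numeric(Matrix::colSums(sub > 0)), convention),
       median_umi = median_by(as.numeric(Matrix::colSums(sub)), convention))
}

#' Detection-based gene filter for a two-group comparison
#'
#' Keeps genes detected (raw count > 0) in at least `min_frac` of the cells
#' of either group; "at least" makes the boundary inclusive.
#'
#' @param m a `CountMatrix`.
#' @param groupA,groupB disjoint, non-empty barcode vectors.
#' @param min_frac detection fraction floor (default 0.10).
#' @return character vector of kept gene ids, matrix order.
#' @export
filter_detected_genes <- function(m, groupA, groupB, min_frac = 0.10) {
  if (!length(groupA) || !length(groupB))
    stop("filter_detected_genes: both groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("filter_detected_genes: groups must be disjoint")
  ia <- match(groupA, m$barcodes); ib <- match(groupB, m$barcodes)
  if (anyNA(ia) || anyNA(ib))
    stop("filter_detected_genes: unknown barcode")
  fa <- Matrix::rowSums(m$counts[, ia, drop = FALSE] > 0) / length(ia)
  fb <- Matrix::rowSums(m$counts[, ib, drop = FALSE] > 0) / length(ib)
  m$gene_ids[fa >= min_frac | fb >= min_frac]
}
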